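#' Define a PLS path model
#'
#' A `plsc_model` holds the measurement model (reflective indicator blocks,
#' Mode A) and the recursive structural model (directed paths between latent
#' variables, plus correlations among exogenous latent variables).
#'
#' @param blocks named list; one element per latent variable, each a character
#'   vector of at least two indicator names. Every indicator may appear in
#'   exactly one block.
#' @param paths data.frame (or matrix/list coercible to one) with columns
#'   `source`, `target` and optionally `label`; each row is a directed
#'   structural path. The graph must be acyclic (recursive model). Missing
#'   labels are filled in as `"source->target"`.
#' @param exo_cor named numeric vector of correlations between pairs of
#'   exogenous latent variables, names of the form `"lv1~~lv2"`. Only latent
#'   variables with no incoming path may appear. Unlisted exogenous pairs are
#'   uncorrelated.
#'
#' @return An object of class `plsc_model` with elements `lv_names`, `blocks`,
#'   `paths`, `exo_cor`, `indicators`, and derived structural bookkeeping
#'   (`parents`, `endogenous`, `exogenous`, topological `order`).
#' @examples
#' m <- plsc_model(
#'   blocks = list(xi = c("x1", "x2"), eta = c("y1", "y2")),
#'   paths  = data.frame(source = "xi", target = "eta")
#' )
#' print(m)
#' @export
plsc_model <- function(blocks, paths, exo_cor = NULL) {
  if (!is.list(blocks) || is.null(names(blocks)) || any(names(blocks) == ""))
    stop("`blocks` must be a named list of indicator vectors", call. = FALSE)
  lv_names <- names(blocks)
  if (anyDuplicated(lv_names))
    stop("duplicated latent variable names in `blocks`", call. = FALSE)
  blocks <- lapply(blocks, as.character)
  sizes <- lengths(blocks)
  if (any(sizes < 2))
    stop("every block needs at least 2 indicators (reliability is undefined ",
         "for a single indicator): ",
         paste(lv_names[sizes < 2], collapse = ", "), call. = FALSE)
  indicators <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(indicators))
    stop("indicator(s) assigned to more than one block: ",
         paste(unique(indicators[duplicated(indicators)]), collapse = ", "),
         call. = FALSE)

  paths <- as.data.frame(paths, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(paths)))
    stop("`paths` needs columns `source` and `target`", call. = FALSE)
  if (is.null(paths$label)) paths$label <- NA_character_
  paths$label <- ifelse(is.na(paths$label) | paths$label == "",
                        paste0(paths$source, "->", paths$target), paths$label)
  paths <- paths[, c("source", "target", "label")]
  bad <- setdiff(c(paths$source, paths$target), lv_names)
  if (length(bad))
    stop("paths refer to unknown latent variable(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  if (any(paths$source == paths$target))
    stop("self-loop in structural paths", call. = FALSE)
  if (anyDuplicated(paths[c("source", "target")]))
    stop("duplicated structural path", call. = FALSE)
  if (anyDuplicated(paths$label))
    stop("duplicated path label", call. = FALSE)

  ord <- topological_order(lv_names, paths)
  if (is.null(ord))
    stop("structural model is not recursive (the path graph has a cycle)",
         call. = FALSE)

  parents <- lapply(lv_names, function(lv) paths$source[paths$target == lv])
  names(parents) <- lv_names
  endogenous <- lv_names[lengths(parents) > 0]
  exogenous <- setdiff(lv_names, endogenous)

  exo_cor <- validate_exo_cor(exo_cor, exogenous)

  structure(
    list(lv_names = lv_names, blocks = blocks, paths = paths,
         exo_cor = exo_cor, indicators = indicators, parents = parents,
         endogenous = endogenous, exogenous = exogenous, order = ord),
    class = "plsc_model"
  )
}

# Kahn's algorithm; NULL when a cycle remains.
topological_order <- function(lv_names, paths) {
  indeg <- stats::setNames(integer(length(lv_names)), lv_names)
  tab <- table(paths$target)
  indeg[names(tab)] <- as.integer(tab)
  ord <- character(0)
  active <- rep(TRUE, length(lv_names))
  names(active) <- lv_names
  repeat {
    ready <- lv_names[active & indeg == 0]
    if (!length(ready)) break
    ord <- c(ord, ready)
    active[ready] <- FALSE
    out <- paths$target[paths$source %in% ready]
    if (length(out)) {
      tab <- table(out)
      indeg[names(tab)] <- indeg[names(tab)] - as.integer(tab)
    }
  }
  if (any(active)) NULL else ord
}

validate_exo_cor <- function(exo_cor, exogenous) {
  if (is.null(exo_cor) || !length(exo_cor)) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(exo_cor)) || any(names(exo_cor) == ""))
    stop("`exo_cor` must be a named vector with names like \"lv1~~lv2\"",
         call. = FALSE)
  prs <- strsplit(names(exo_cor), "~~", fixed = TRUE)
  if (any(lengths(prs) != 2))
    stop("malformed `exo_cor` name(s); use \"lv1~~lv2\"", call. = FALSE)
  for (p in prs) {
    if (p[1] == p[2]) stop("`exo_cor` pairs a latent variable with itself", call. = FALSE)
    if (!all(p %in% exogenous))
      stop("`exo_cor` may only reference exogenous latent variables ",
           "(no incoming paths): ", paste(setdiff(p, exogenous), collapse = ", "),
           call. = FALSE)
  }
  keys <- vapply(prs, function(p) paste(sort(p), collapse = "~~"), character(1))
  if (anyDuplicated(keys)) stop("duplicated `exo_cor` pair", call. = FALSE)
  if (any(abs(exo_cor) > 1)) stop("`exo_cor` outside [-1, 1]", call. = FALSE)
  stats::setNames(as.numeric(exo_cor), keys)
}

#' @export
print.plsc_model <- function(x, ...) {
  cat("PLS path model:", length(x$lv_names), "latent variables,",
      length(x$indicators), "indicators\n")
  cat("  exogenous: ", paste(x$exogenous, collapse = ", "), "\n", sep = "")
  cat("  endogenous:", paste(x$endogenous, collapse = ", "), "\n")
  for (i in seq_len(nrow(x$paths)))
    cat(sprintf("  %s -> %s  (%s)\n", x$paths$source[i], x$paths$target[i],
                x$paths$label[i]))
  if (length(x$exo_cor))
    cat("  exogenous correlations:",
        paste(sprintf("%s = %g", names(x$exo_cor), x$exo_cor), collapse = ", "),
        "\n")
  invisible(x)
}

#' Read / write a model specification
#'
#' Serializes a [plsc_model()] to JSON or YAML with fields `latents`, `blocks`,
#' `paths` (list of `[source, target, label]`) and `exo_correlations`.
#' The format is chosen from the file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param path file path.
#' @param model a `plsc_model`.
#' @return `read_model_spec()` returns a `plsc_model`; `write_model_spec()`
#'   returns `path` invisibly.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("model spec file not found: ", path, call. = FALSE)
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  }
  if (is.null(obj$blocks) || is.null(obj$paths))
    stop("model spec must define `blocks` and `paths`", call. = FALSE)
  blocks <- lapply(obj$blocks, unlist)
  if (!is.null(obj$latents)) blocks <- blocks[unlist(obj$latents)]
  paths <- do.call(rbind, lapply(obj$paths, function(p) {
    p <- unlist(p)
    data.frame(source = p[[1]], target = p[[2]],
               label = if (length(p) >= 3) p[[3]] else NA_character_,
               stringsAsFactors = FALSE)
  }))
  exo <- unlist(obj$exo_correlations)
  plsc_model(blocks = blocks, paths = paths, exo_cor = exo)
}

#' @rdname read_model_spec
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "plsc_model"))
  obj <- list(
    latents = model$lv_names,
    blocks = model$blocks,
    paths = lapply(seq_len(nrow(model$paths)), function(i)
      list(model$paths$source[i], model$paths$target[i], model$paths$label[i])),
    exo_correlations = as.list(model$exo_cor)
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' The six-latent-variable simulation model
#'
#' Builds the structural model used throughout the package's Monte Carlo
#' study: three exogenous factors (`xi1`, `xi2`, `xi3`) and three endogenous
#' ones (`eta1`, `eta2`, `eta3`), each measured by four reflective indicators.
#' `eta1` is predicted by `xi1` and `xi2`; `eta2` by `xi1`, `xi2` (a true-zero
#' path, used to measure type-I error) and `xi3`; `eta3` by `eta1` and `eta2`.
#' `xi1` and `xi2` are correlated at `phi` (the multicollinearity level);
#' `xi3` is orthogonal to both.
#'
#' @param phi correlation between `xi1` and `xi2`, in (-1, 1).
#' @return a [plsc_model()].
#' @examples
#' simulation_model(phi = 0.4)
#' @export
simulation_model <- function(phi = 0.4) {
  stopifnot(is.numeric(phi), length(phi) == 1, abs(phi) < 1)
  lvs <- c("xi1", "xi2", "xi3", "eta1", "eta2", "eta3")
  blocks <- lapply(seq_along(lvs), function(i)
    paste0("x", (i - 1) * 4 + 1:4))
  names(blocks) <- lvs
  paths <- data.frame(
    source = c("xi1", "xi2", "xi1", "xi2", "xi3", "eta1", "eta2"),
    target = c("eta1", "eta1", "eta2", "eta2", "eta2", "eta3", "eta3"),
    label = c("gamma11", "gamma12", "gamma21", "gamma22", "gamma23",
              "beta31", "beta32"),
    stringsAsFactors = FALSE
  )
  plsc_model(blocks, paths,
             exo_cor = c("xi1~~xi2" = phi, "xi1~~xi3" = 0, "xi2~~xi3" = 0))
}
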