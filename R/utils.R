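# Set the RNG seed for the duration of the calling function only, restoring
# the caller's RNG state on exit. A NULL seed leaves the RNG untouched.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  expr <- if (is.null(old)) {
    quote(rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(NULL)
}

# Deterministic child seed derivation, kept within the 32-bit integer range.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 9973) %% 2147483587L) + 1L
}
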