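# Shared builders for the test suite. Everything is constructed in code;
# no stored fixtures beyond the packaged coefficient table.

# A minimal two-latent model: one exogenous block predicting one endogenous.
tiny_model <- function() {
  plsc_model(
    blocks = list(xi = c("x1", "x2", "x3"), eta = c("y1", "y2", "y3")),
    paths = data.frame(source = "xi", target = "eta", label = "b1")
  )
}

paper_cell <- function(N = 60, phi = 0.4, reliability = 0.8, r2 = 0.25) {
  list(N = N, phi = phi, reliability = reliability, r2 = r2)
}

# Population indicator correlation matrix for a single block with equal
# loadings lam (unit-variance factor, standardized indicators).
block_sigma <- function(lam, p = 4) {
  S <- matrix(lam^2, p, p)
  diag(S) <- 1
  S
}

# Naive double-loop evaluation of the consistent reliability coefficient,
# written independently of the package's linear-algebra form.
rho_a_naive <- function(w, S) {
  p <- length(w)
  ww <- sum(w * w)
  num <- 0
  den <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i != j) {
      num <- num + w[i] * S[i, j] * w[j]
      den <- den + w[i] * (w[i] * w[j]) * w[j]
    }
  }
  ww^2 * num / den
}
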