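# Small numerical helpers.

# Central finite-difference Hessian of a scalar function.
fd_hessian <- function(f, x, h = 1e-4 * pmax(1, abs(x))) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < p) {
      for (j in seq(i + 1, p)) {
        ej <- numeric(p); ej[j] <- h[j]
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

# Outer product of per-subject score vectors (forward differences of a
# function returning the per-subject objective contributions).
subject_score_outer <- function(f_sub, x, h = 1e-5 * pmax(1, abs(x))) {
  p <- length(x)
  f0 <- f_sub(x)
  scores <- matrix(0, length(f0), p)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    scores[, i] <- (f_sub(x + ei) - f0) / h[i]
  }
  crossprod(scores)
}
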