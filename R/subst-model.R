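#' Substitution models
#'
#' The supported models all have closed-form transition probabilities:
#' `JC` (Jukes-Cantor), `F81` (equal-input nucleotide), `HKY` (transition /
#' transversion ratio `kappa` with unequal frequencies), and `POISSON_F`
#' (equal-input amino acid: Poisson exchange with stationary frequencies).
#' Rate matrices are normalized to one expected substitution per site per
#' unit branch length.
#'
#' @param type model name.
#' @param freqs stationary frequencies (length 4 or 20); defaults to equal.
#' @param kappa HKY transition/transversion rate ratio.
#' @export
subst_model <- function(type = c("JC", "F81", "HKY", "POISSON_F"),
                        freqs = NULL, kappa = 2) {
  type <- match.arg(type)
  S <- if (type == "POISSON_F") 20L else 4L
  if (is.null(freqs)) freqs <- rep(1 / S, S)
  if (length(freqs) != S) stop("freqs must have length ", S)
  if (abs(sum(freqs) - 1) > 1e-8) stop("freqs must sum to 1")
  if (type == "JC") freqs <- rep(0.25, 4)
  structure(list(type = type, code = if (type == "HKY") 1L else 0L,
                 nstates = S, freqs = freqs, kappa = kappa,
                 alphabet = if (S == 4L) "nt" else "aa"),
            class = "subst_model")
}

# transition probability matrix (R mirror of the C++ kernel, used by the
# simulator so generator and likelihood share one parameterization)
trans_prob <- function(model, b) {
  S <- model$nstates
  f <- model$freqs
  if (model$code == 0L) {
    beta <- 1 / (1 - sum(f^2))
    e <- exp(-beta * b)
    P <- (1 - e) * matrix(f, S, S, byrow = TRUE) + diag(e, S)
  } else {
    piR <- f[1] + f[3]; piY <- f[2] + f[4]; k <- model$kappa
    beta <- 1 / (2 * k * (f[1] * f[3] + f[2] * f[4]) + 2 * piR * piY)
    e2 <- exp(-beta * b)
    P <- matrix(0, 4, 4)
    for (j in 1:4) {
      Pi <- if (j %in% c(1, 3)) piR else piY
      Aj <- 1 + Pi * (k - 1)
      eA <- exp(-beta * b * Aj)
      for (i in 1:4) {
        same_group <- (i %in% c(1, 3)) == (j %in% c(1, 3))
        P[i, j] <- if (i == j)
          f[j] + f[j] * (1 / Pi - 1) * e2 + ((Pi - f[j]) / Pi) * eA
        else if (same_group)
          f[j] + f[j] * (1 / Pi - 1) * e2 - (f[j] / Pi) * eA
        else f[j] * (1 - e2)
      }
    }
  }
  P
}
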