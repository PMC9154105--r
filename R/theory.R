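#' Mean fixation probability of exponentially distributed beneficial effects
#'
#' Averages Kimura's diffusion fixation probability of a new semidominant
#' mutation, `u(s) = (1 - exp(-s)) / (1 - exp(-2 N s))` with `s` the
#' homozygous coefficient, over an exponential distribution of effects with
#' mean `sbar`:
#' `P_fix = integral_0^inf u(x) exp(-x / sbar) / sbar dx`.
#' The neutral limit `sbar -> 0` recovers `1 / (2N)`.  Computed by adaptive
#' quadrature after substituting `x = sbar q` (relative tolerance 1e-9);
#' monotone increasing in `sbar`.
#'
#' @param sbar mean homozygous beneficial effect (> 0).
#' @param N diploid population size.
#' @return fixation probability in `[1/(2N), 1]`.
#' @export
pFix <- function(sbar, N) {
    if (sbar <= 0) stop("sbar must be > 0")
    if (N < 1) stop("N must be >= 1")
    integrand <- function(q) {
        x <- sbar * q
        num <- -expm1(-x)
        den <- -expm1(-2 * N * x)
        u <- ifelse(x < 1e-12, 1 / (2 * N), num / den)
        u * exp(-q)
    }
    res <- integrate(integrand, 0, Inf, rel.tol = 1e-9, abs.tol = 0,
                     stop.on.error = FALSE)
    if (res$message != "OK" || res$abs.error > 1e-6 * max(res$value, 1 / (2 * N)))
        stop("fixation-probability quadrature did not converge: ", res$message)
    res$value
}

#' Beneficial fraction of substitutions from the mutation-rate composition
#'
#' With beneficial mutation rate `mu_b = f_pos mu_tot` and neutral rate
#' `mu_neu = (1 - f_pos) mu_tot`, the per-site per-generation substitution
#' rates are `P_fix 2 N mu_b` (beneficial) and `mu_neu` (neutral), so
#' `lambda = P_fix 2 N mu_b / (P_fix 2 N mu_b + mu_neu)`.
#' The region length and the absolute scale of `mu_tot` cancel.
#'
#' @param fpos beneficial fraction of new mutations.
#' @param sbar mean homozygous beneficial effect.
#' @param N diploid population size.
#' @param muTot total per-bp mutation rate (cancels; kept for the record).
#' @return lambda in `[0, 1]`.
#' @export
lambdaFromRates <- function(fpos, sbar, N, muTot = 1e-6) {
    if (fpos < 0 || fpos > 1) stop("fpos must be in [0, 1]")
    muB <- fpos * muTot
    muNeu <- (1 - fpos) * muTot
    if (muB == 0 && muNeu == 0) stop("all substitution rates are zero")
    if (muB == 0) return(0)
    ben <- pFix(sbar, N) * 2 * N * muB
    ben / (ben + muNeu)
}

#' Beneficial fraction of new mutations implied by lambda
#'
#' Inverts [lambdaFromRates]:
#' `f_pos = lambda / ((1 - lambda) P_fix 2 N + lambda)`.
#' This is the conversion used to parameterize posterior predictive
#' simulations of an inferred recurrent-sweep model.  `lambda = 1` returns 1
#' (the limit).
#'
#' @param lambda beneficial fraction of substitutions in `[0, 1]`.
#' @param sbar mean homozygous beneficial effect.
#' @param N diploid population size.
#' @return f_pos in `[0, 1]`.
#' @export
fposFromLambda <- function(lambda, sbar, N) {
    if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
    if (lambda == 1) return(1)
    if (lambda == 0) return(0)
    lambda / ((1 - lambda) * pFix(sbar, N) * 2 * N + lambda)
}
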