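#' Negative-binomial neutral species abundance probability
#'
#' Stationary probability that a species has `n` individuals under the
#' neutral birth-death-immigration model with per-capita birth rate
#' `b_n = b(n + gamma)` and death rate `d_n = d n`:
#' \deqn{p(n) = \frac{(1-x)^\gamma}{\Gamma(\gamma)}
#'              \frac{x^n}{n!} \Gamma(n+\gamma)}
#' where `x = b/d` is the birth/death ratio and `gamma` the immigration
#' parameter. At `gamma = 1` this is the geometric distribution
#' `(1-x) x^n`.
#'
#' @param n non-negative integer abundance (vectorized).
#' @param x birth/death ratio in (0, 1).
#' @param gamma positive immigration parameter.
#' @param log return log probabilities.
#' @return probabilities (or logs).
#' @export
volkov_pmf <- function(n, x, gamma, log = FALSE) {
  if (x <= 0 || x >= 1) stop("x must lie in (0, 1)")
  if (gamma <= 0) stop("gamma must be > 0")
  if (any(n < 0) || any(n != round(n))) stop("n must be integer >= 0")
  lp <- gamma * log1p(-x) - lgamma(gamma) + n * log(x) -
    lgamma(n + 1) + lgamma(n + gamma)
  if (log) lp else exp(lp)
}

#' Expected number of species with a given abundance (one niche)
#'
#' Mean species abundance distribution of the neutral niche model,
#' \deqn{\langle\phi_n\rangle = \theta \frac{x^n}{n!} \Gamma(n+\gamma),}
#' evaluated in log space. `theta` enters linearly, so the ratio
#' identity `phi_{n+1}/phi_n = x (n+gamma)/(n+1)` holds for all `n`.
#'
#' @param n positive integer abundance (vectorized).
#' @param theta positive per-niche biodiversity parameter.
#' @param x birth/death ratio in (0, 1).
#' @param gamma positive immigration parameter.
#' @return expected species counts.
#' @examples
#' expected_sad(1:2, theta = 10, x = 0.5, gamma = 1) # 5.0, 2.5
#' @export
expected_sad <- function(n, theta, x, gamma) {
  if (any(n < 1) || any(n != round(n))) stop("n must be integer >= 1")
  if (theta <= 0) stop("theta must be > 0")
  if (x <= 0 || x >= 1) stop("x must lie in (0, 1)")
  if (gamma <= 0) stop("gamma must be > 0")
  exp(log(theta) + n * log(x) - lgamma(n + 1) + lgamma(n + gamma))
}

# total expected species beyond abundance M:
#   sum_{n>M} theta x^n Gamma(n+gamma)/n!
#   = theta Gamma(gamma) (1-x)^-gamma P(NB(gamma, 1-x) > M)
expected_sad_tail <- function(M, theta, x, gamma) {
  theta * exp(lgamma(gamma) - gamma * log1p(-x)) *
    pnbinom(M, size = gamma, prob = 1 - x, lower.tail = FALSE)
}

#' Fit the neutral species abundance model to one niche
#'
#' Maximum-likelihood fit of the zero-truncated abundance distribution
#' [volkov_pmf()] to the observed abundances of one niche (one local
#' community): `(x, gamma)` maximize
#' `sum_j log p(n_j) - S log(1 - p(0))`, optimized on the unconstrained
#' scale `(logit x, log gamma)` with multiple starts; `theta` is then
#' chosen so that the expected total richness matches the observed one,
#' using the closed form
#' `sum_{n>=1} phi_n = theta Gamma(gamma) ((1-x)^{-gamma} - 1)`.
#'
#' Degenerate niches (fewer than 3 distinct abundances, or a boundary
#' optimum with `x` within 1e-6 of 0 or 1) are flagged; flagged niches
#' are excluded from metacommunity averages.
#'
#' @param abundances positive integer counts, one per observed species.
#' @param n_starts number of optimizer starts.
#' @return list with `theta`, `x`, `gamma`, `J` (individuals), `S`
#'   (species), `converged`, `flagged`, and `flag_reason`.
#' @export
fit_niche <- function(abundances, n_starts = 3L) {
  abundances <- as.numeric(abundances)
  if (any(abundances < 1)) stop("abundances must be >= 1")
  S <- length(abundances)
  J <- sum(abundances)

  negll <- function(par) {
    x <- plogis(par[1]); g <- exp(par[2])
    if (x <= 0 || x >= 1 || !is.finite(g) || g <= 0) return(1e10)
    lp <- g * log1p(-x) - lgamma(g) + abundances * log(x) -
      lgamma(abundances + 1) + lgamma(abundances + g)
    lp0 <- g * log1p(-x) # log p(0)
    v <- -(sum(lp) - S * log1p(-exp(lp0)))
    if (!is.finite(v)) 1e10 else v
  }

  starts <- list(c(qlogis(0.7), log(1)),
                 c(qlogis(0.3), log(0.3)),
                 c(qlogis(0.9), log(3)))[seq_len(min(n_starts, 3L))]
  best <- NULL
  for (st in starts) {
    o <- tryCatch(optim(st, negll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-8)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }

  flagged <- FALSE; reason <- NA_character_
  if (is.null(best) || best$value >= 1e10) {
    return(list(theta = NA_real_, x = NA_real_, gamma = NA_real_,
                J = J, S = S, converged = FALSE, flagged = TRUE,
                flag_reason = "optimizer failed"))
  }
  x_hat <- plogis(best$par[1]); g_hat <- exp(best$par[2])
  if (best$convergence != 0) { flagged <- TRUE; reason <- "no convergence" }
  if (x_hat < 1e-6 || x_hat > 1 - 1e-6) {
    flagged <- TRUE; reason <- "x at boundary"
  }
  if (length(unique(abundances)) < 3L) {
    flagged <- TRUE
    reason <- if (is.na(reason)) "degenerate SAD" else reason
  }
  # richness matching: sum_{n>=1} phi_n = S
  denom <- exp(lgamma(g_hat) - g_hat * log1p(-x_hat)) *
    (1 - (1 - x_hat)^g_hat)
  theta_hat <- if (is.finite(denom) && denom > 0) S / denom else NA_real_
  if (!is.finite(theta_hat) || theta_hat <= 0) {
    flagged <- TRUE
    reason <- if (is.na(reason)) "theta not identifiable" else reason
    theta_hat <- NA_real_
  }

  list(theta = theta_hat, x = x_hat, gamma = g_hat, J = J, S = S,
       converged = best$convergence == 0, flagged = flagged,
       flag_reason = reason)
}
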