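#' Species-count distribution of a Dirichlet process (Antoniak equation)
#'
#' Log probability of observing `S` distinct species in `N` draws from a
#' Dirichlet process with concentration (fundamental biodiversity
#' number) `theta`:
#' \deqn{P(S \mid \theta, N) = s(N,S)\,\theta^S \Gamma(\theta) / \Gamma(\theta+N)}
#' where `s(N,S)` is the unsigned Stirling number of the first kind.
#' Stirling numbers are accumulated in log space via the recurrence
#' `s(n+1,k) = n s(n,k) + s(n,k-1)` with log-sum-exp, so the pmf is
#' stable for `N` in the hundreds.
#'
#' @param S integer number of distinct species, `1 <= S <= N` (vectorized).
#' @param theta positive concentration.
#' @param N integer number of draws.
#' @return log probabilities, same length as `S`.
#' @examples
#' exp(log_antoniak_pmf(1, theta = 1, N = 2)) # 0.5
#' sum(exp(log_antoniak_pmf(1:10, theta = 3.7, N = 10))) # 1
#' @export
log_antoniak_pmf <- function(S, theta, N) {
  if (theta <= 0) stop("theta must be > 0")
  N <- as.integer(N)
  if (N < 1L) stop("N must be >= 1")
  if (any(S < 1L | S > N)) stop("S must satisfy 1 <= S <= N")
  ls <- log_stirling_row(N)
  ls[S] + S * log(theta) + lgamma(theta) - lgamma(theta + N)
}

# log of unsigned Stirling numbers of the first kind s(N, 1..N)
log_stirling_row <- function(N) {
  row <- 0 # s(1,1) = 1
  if (N == 1L) return(row)
  for (n in 1L:(N - 1L)) {
    # s(n+1, k) = n*s(n, k) + s(n, k-1), k = 1..n+1
    a <- c(log(n) + row, -Inf)   # n*s(n,k)
    b <- c(-Inf, row)            # s(n,k-1)
    m <- pmax(a, b)
    row <- m + log(exp(a - m) + exp(b - m))
    row[is.nan(row)] <- -Inf
  }
  row
}

#' Sample Chinese-restaurant table counts
#'
#' Draws the number of occupied tables after `x` customers arrive at a
#' Chinese restaurant process with concentration `alpha`, using the exact
#' representation `t = sum_k Bernoulli(alpha/(alpha+k-1))`. The marginal
#' pmf of `t` is proportional to `s(x,t) * alpha^t`.
#'
#' @param n number of draws.
#' @param x customer count(s), integer `>= 1` (recycled).
#' @param alpha concentration(s) `>= 0` (recycled).
#' @return integer vector of length `n`, each in `1..x`.
#' @export
rcrt <- function(n, x, alpha) {
  x <- rep_len(as.integer(x), n)
  alpha <- rep_len(as.numeric(alpha), n)
  crt_sample_cpp(x, alpha)
}

#' Exact pmf of the Chinese-restaurant table count
#'
#' `P(t | x, alpha) = s(x,t) alpha^t / (alpha)_x` with `(alpha)_x` the
#' rising factorial; used as the reference distribution for [rcrt()].
#'
#' @param t table counts `1..x` (vectorized).
#' @param x customer count.
#' @param alpha positive concentration.
#' @return probabilities.
#' @export
dcrt <- function(t, x, alpha) {
  ls <- log_stirling_row(as.integer(x))
  lp <- ls + (1:x) * log(alpha) - (lgamma(alpha + x) - lgamma(alpha))
  exp(lp)[t]
}

#' Stick-breaking draw from a Dirichlet process
#'
#' Draws metacommunity relative abundances `beta ~ Stick(theta)`:
#' `V_k ~ Beta(1, theta)`, `beta_k = V_k prod_{j<k}(1 - V_j)`, truncated
#' once the remaining (unbroken) mass falls below `trunc_tol`; the
#' residual mass is assigned to the final component so the weights sum
#' to one exactly.
#'
#' @param theta positive concentration.
#' @param trunc_tol truncation tolerance on the remaining mass.
#' @return numeric vector of weights summing to 1.
#' @export
rstick <- function(theta, trunc_tol = 1e-10) {
  if (theta <= 0) stop("theta must be > 0")
  if (trunc_tol <= 0) stop("trunc_tol must be > 0")
  out <- numeric(0)
  remaining <- 1
  repeat {
    v <- rbeta(64L, 1, theta)
    w <- remaining * v * cumprod(c(1, 1 - v[-64L]))
    rem_after <- remaining * cumprod(1 - v)
    hit <- which(rem_after < trunc_tol)
    if (length(hit)) {
      k <- hit[1L]
      out <- c(out, w[seq_len(k)])
      out[length(out)] <- out[length(out)] + rem_after[k]
      return(out)
    }
    out <- c(out, w)
    remaining <- rem_after[64L]
  }
}

#' Dirichlet-multinomial log-likelihood
#'
#' Log probability of the count vector `x` under a multinomial whose
#' probability vector was drawn from `Dirichlet(alpha)`:
#' \deqn{\log\binom{N}{x} + \log\frac{\Gamma(A)}{\Gamma(A+N)}
#'       + \sum_j \log\frac{\Gamma(\alpha_j+x_j)}{\Gamma(\alpha_j)}}
#' with `A = sum(alpha)`. Categories with `alpha_j = 0` and `x_j = 0`
#' are dropped (they contribute probability one); a positive count on a
#' zero-concentration category is an error. In the neutral model
#' `alpha = I_i * beta` so `A = I_i`, and as `I -> Inf` the likelihood
#' approaches the plain multinomial with probabilities `beta`.
#'
#' @param x non-negative integer counts.
#' @param alpha non-negative concentrations, same length as `x`.
#' @param size optional total `N`; checked against `sum(x)` if given.
#' @return log-likelihood in nats.
#' @examples
#' ddirmult(c(1, 1), c(1, 1)) # log(1/3)
#' @export
ddirmult <- function(x, alpha, size = NULL) {
  if (length(x) != length(alpha)) stop("x and alpha lengths differ")
  N <- sum(x)
  if (!is.null(size) && size != N) stop("size does not match sum(x)")
  if (any(alpha < 0)) stop("alpha must be non-negative")
  if (any(alpha == 0 & x > 0)) stop("positive count on zero-mass category")
  keep <- alpha > 0
  x <- x[keep]; alpha <- alpha[keep]
  A <- sum(alpha)
  lgamma(N + 1) - sum(lgamma(x + 1)) +
    lgamma(A) - lgamma(A + N) +
    sum(lgamma(alpha + x) - lgamma(alpha))
}

#' Convert between immigration rate and migration probability
#'
#' The coupling of local community `i` of size `N_i` to the
#' metacommunity can be expressed as an immigration rate `I_i` or a
#' migration probability `m_i`, related by
#' `I_i = m_i (N_i - 1) / (1 - m_i)`, i.e. `m_i = I_i / (I_i + N_i - 1)`.
#'
#' @param I immigration rate(s), `> 0`.
#' @param m migration probability(ies) in (0, 1).
#' @param N local community size(s), `>= 2` for a well-defined ratio.
#' @return the converted quantity.
#' @export
migration_prob <- function(I, N) I / (I + N - 1)

#' @rdname migration_prob
#' @export
immigration_rate <- function(m, N) m * (N - 1) / (1 - m)
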