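#' Fit the multi-site neutral model by Gibbs sampling
#'
#' Fits the hierarchical-Dirichlet-process approximation of the
#' multi-site neutral model to one subject's metacommunity. The
#' generative chain is: metacommunity relative abundances
#' `beta ~ Stick(theta)`; each local community's composition
#' `pi_i ~ DP(I_i, beta)`; observed counts `X_i ~ Multinomial(N_i, pi_i)`.
#' `theta` is the fundamental biodiversity number and `I_i` the
#' immigration rate coupling local community `i` (of size `N_i`) to the
#' metacommunity, with migration probability `m_i = I_i/(I_i + N_i - 1)`.
#'
#' Each Gibbs sweep has four steps: (1) ancestral table counts
#' `t_ij ~ CRT(x_ij, I_i beta_j)`; (2) the metacommunity vector
#' `(beta_1..beta_S, beta_u) ~ Dirichlet(t_.1, .., t_.S, theta)` where
#' `beta_u` is the unseen-species mass; (3) `theta` and (4) each `I_i`
#' resampled under their Gamma priors by the standard beta-gamma
#' auxiliary-variable construction for Dirichlet-process concentrations.
#'
#' Post-burn-in chains are summarised by medians and 2.5/97.5%
#' quantiles; every `thin`-th post-burn-in draw is retained as a full
#' parameter set for the posterior-predictive neutrality tests.
#'
#' @param x an [abundance_matrix()] (or a bare count matrix).
#' @param n_iter,n_burn,thin total sweeps, burn-in sweeps, and thinning
#'   interval for the retained test sets. Defaults follow the reference
#'   protocol (50,000 / 25,000 / 10, giving 2,500 test sets); reduce for
#'   desk-scale runs.
#' @param prior_theta,prior_I `c(shape, rate)` of the Gamma priors on
#'   `theta` and on each `I_i` (weakly informative defaults).
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   so the chain is reproducible.
#' @return An object of class `msn_fit` with components `counts`,
#'   `chains` (post-burn-in `theta`, `I`, `m`), `sets` (thinned
#'   parameter sets incl. `beta`), `summaries`, the point estimates
#'   `theta` (chain median) and `M_value` (mean over communities of the
#'   chain-median `m_i`), and the sampler configuration.
#' @seealso [msn_neutrality_test()], [simulate.msn_fit()]
#' @examples
#' \donttest{
#' m <- gen_neutral(theta = 10, I = 8, sizes = rep(500, 5), seed = 1)
#' fit <- msn_fit(m, n_iter = 400, n_burn = 200, thin = 10, seed = 1)
#' coef(fit)
#' }
#' @export
msn_fit <- function(x, n_iter = 50000L, n_burn = 25000L, thin = 10L,
                    prior_theta = c(1, 0.1), prior_I = c(1, 0.1),
                    seed = NULL) {
  if (!inherits(x, "abundance_matrix")) x <- abundance_matrix(x)
  n_iter <- as.integer(n_iter); n_burn <- as.integer(n_burn)
  thin <- as.integer(thin)
  if (n_burn >= n_iter) stop("n_burn must be < n_iter")
  if (thin < 1L || (n_iter - n_burn) < thin)
    stop("thin must be in 1..(n_iter - n_burn)")
  if (!is.null(seed)) set.seed(seed)

  counts <- unclass(x)
  res <- gibbs_msn_cpp(counts, n_iter, n_burn, thin,
                       prior_theta[1], prior_theta[2],
                       prior_I[1], prior_I[2])
  N_i <- colSums(counts)
  m_chain <- res$I_chain / sweep(res$I_chain, 1L, N_i - 1, `+`)

  qs <- function(v) c(median = median(v),
                      q2.5 = unname(quantile(v, 0.025)),
                      q97.5 = unname(quantile(v, 0.975)))
  theta_summary <- qs(res$theta_chain)
  I_summary <- t(apply(res$I_chain, 1L, qs))
  m_summary <- t(apply(m_chain, 1L, qs))
  rownames(I_summary) <- rownames(m_summary) <- colnames(counts)

  structure(list(
    counts = x,
    N_i = N_i,
    chains = list(theta = res$theta_chain, I = res$I_chain, m = m_chain),
    sets = list(theta = res$sets_theta, I = res$sets_I,
                beta = res$sets_beta),
    summaries = list(theta = theta_summary, I = I_summary, m = m_summary),
    theta = unname(theta_summary["median"]),
    M_value = mean(m_summary[, "median"]),
    config = list(n_iter = n_iter, n_burn = n_burn, thin = thin,
                  prior_theta = prior_theta, prior_I = prior_I,
                  seed = seed),
    call = match.call()
  ), class = "msn_fit")
}

#' @export
print.msn_fit <- function(x, ...) {
  cat("Multi-site neutral model fit (HDP Gibbs sampler)\n")
  cat(sprintf("  subject: %s (%d species x %d local communities)\n",
              attr(x$counts, "subject_id"), nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  sweeps: %d (burn-in %d, %d retained test sets)\n",
              x$config$n_iter, x$config$n_burn, length(x$sets$theta)))
  cat(sprintf("  theta (median [95%% CrI]): %.3f [%.3f, %.3f]\n",
              x$theta, x$summaries$theta["q2.5"], x$summaries$theta["q97.5"]))
  cat(sprintf("  M-value (mean of median m_i): %.4f\n", x$M_value))
  invisible(x)
}

#' @export
coef.msn_fit <- function(object, ...) {
  c(theta = object$theta, M_value = object$M_value)
}

#' @export
summary.msn_fit <- function(object, ...) {
  s <- object$summaries
  out <- rbind(theta = s$theta,
               s$I[, , drop = FALSE])
  rownames(out) <- c("theta", paste0("I[", rownames(s$I), "]"))
  out <- rbind(out, `m (per community)` = colMeans(s$m))
  structure(list(table = out, M_value = object$M_value,
                 config = object$config),
            class = "summary.msn_fit")
}

#' @export
print.summary.msn_fit <- function(x, ...) {
  cat("Posterior summaries (median, 2.5%, 97.5%):\n")
  print(round(x$table, 4))
  cat(sprintf("M-value: %.4f\n", x$M_value))
  invisible(x)
}

#' Simulate metacommunity data from a fitted multi-site neutral model
#'
#' Draws posterior-predictive replicates: for each simulation a retained
#' parameter set `(theta_k, I_k, beta_k)` is picked at random and counts
#' are drawn as `pi_i ~ Dirichlet(I_i beta)`,
#' `X_i ~ Multinomial(N_i, pi_i)` at the observed depths, over the
#' observed species plus the pooled unseen category.
#'
#' @param object an `msn_fit`.
#' @param nsim number of replicate matrices.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of `nsim` integer matrices ((S+1) x T; the last row is
#'   the unseen-species category).
#' @export
simulate.msn_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n_sets <- length(object$sets$theta)
  ks <- sample.int(n_sets, nsim, replace = TRUE)
  lapply(ks, function(k) {
    sim_dm_counts(object$sets$beta[, k], object$sets$I[, k], object$N_i)
  })
}

# Draw (S+1) x T counts: pi_i ~ Dirichlet(I_i * beta), X_i ~ MN(N_i, pi_i)
sim_dm_counts <- function(beta, I, N_i) {
  Sp1 <- length(beta); T <- length(N_i)
  alpha <- outer(beta, I)
  g <- matrix(rgamma(Sp1 * T, shape = alpha), Sp1, T)
  cs <- colSums(g)
  for (i in which(cs == 0)) { # all mass underflowed: put it on the top class
    g[which.max(alpha[, i]), i] <- 1
    cs[i] <- 1
  }
  p <- sweep(g, 2L, cs, `/`)
  out <- matrix(0L, Sp1, T)
  for (i in seq_len(T)) out[, i] <- rmultinom(1L, N_i[i], p[, i])
  out
}

# Sum over local communities of Dirichlet-multinomial log-likelihoods
# with alpha = I_i * beta; xmat is (S+1) x T including the unseen row.
msn_loglik <- function(xmat, I, beta) {
  alpha <- outer(beta, I)
  if (any(alpha == 0 & xmat > 0)) return(-Inf)
  N <- colSums(xmat)
  A <- I * sum(beta)
  term <- lgamma(alpha + xmat) - lgamma(alpha)
  term[alpha == 0] <- 0
  sum(lgamma(N + 1) - colSums(lgamma(xmat + 1)) +
        lgamma(A) - lgamma(A + N) + colSums(term))
}
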