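#' Monte-Carlo neutrality test for a fitted multi-site neutral model
#'
#' Posterior-predictive check at two levels. For every retained
#' parameter set `k = 1..N` of the fit:
#'
#' * **metacommunity level** — a fresh metacommunity is drawn,
#'   `beta*_k ~ Stick(theta_k)`, counts are simulated as
#'   `X*_i ~ DirMult(N_i, I_ik beta*_k)` for every local community, and
#'   the simulated log-likelihood `L*_k` is evaluated under
#'   `(I_k, beta*_k)` while the observed log-likelihood `L0_k` is
#'   evaluated under `(I_k, beta_k)`;
#' * **local level** — the fitted metacommunity `beta_k` is kept and
#'   only local assembly is re-simulated,
#'   `X*_i ~ DirMult(N_i, I_ik beta_k)`, with both `L*_k` and `L0_k`
#'   evaluated under `(I_k, beta_k)`. This tests local neutral assembly
#'   under a fitted, possibly non-neutral metacommunity.
#'
#' The pseudo P-value is the proportion of simulations whose likelihood
#' does not exceed the observed one, `P = #\{L*_k <= L0_k\}/N` (ties
#' count as passing). A subject passes at threshold `P_t` iff `P > P_t`.
#'
#' Likelihoods are evaluated on a common support: the observed species
#' plus one pooled "unseen" category. At the metacommunity level the
#' first `S` stick-breaking components play the role of the observed
#' species and all remaining mass is pooled into the unseen category.
#'
#' @param fit an [msn_fit()].
#' @param level `"metacommunity"` or `"local"`.
#' @param trunc_tol stick-breaking truncation tolerance.
#' @param seed optional integer seed.
#' @return object of class `msn_neutrality_test`: list with `level`,
#'   `L_0` (median observed log-likelihood over sets), `L_sim_median`,
#'   `N_pass_sims`, `N`, and `P`.
#' @export
msn_neutrality_test <- function(fit,
                                level = c("metacommunity", "local"),
                                trunc_tol = 1e-10, seed = NULL) {
  level <- match.arg(level)
  if (!is.null(seed)) set.seed(seed)
  n_sets <- length(fit$sets$theta)
  if (n_sets < 1L) stop("fit has no retained parameter sets")
  S <- nrow(fit$counts)
  x_aug <- rbind(unclass(fit$counts), unseen = 0L)
  N_i <- fit$N_i

  L0 <- Lstar <- numeric(n_sets)
  for (k in seq_len(n_sets)) {
    I_k <- fit$sets$I[, k]
    beta_k <- fit$sets$beta[, k]
    L0[k] <- msn_loglik(x_aug, I_k, beta_k)
    if (level == "metacommunity") {
      bs <- rstick(fit$sets$theta[k], trunc_tol)
      if (length(bs) > S) {
        bsim <- c(bs[seq_len(S)], sum(bs[-seq_len(S)]))
      } else {
        bsim <- c(bs, rep(0, S - length(bs)), 0)
      }
    } else {
      bsim <- beta_k
    }
    xsim <- sim_dm_counts(bsim, I_k, N_i)
    Lstar[k] <- msn_loglik(xsim, I_k, bsim)
  }

  n_pass <- sum(Lstar <= L0)
  structure(list(level = level,
                 L_0 = median(L0),
                 L_sim_median = median(Lstar),
                 N_pass_sims = n_pass,
                 N = n_sets,
                 P = n_pass / n_sets),
            class = "msn_neutrality_test")
}

#' @export
print.msn_neutrality_test <- function(x, ...) {
  lbl <- if (x$level == "metacommunity") "P_M" else "P_L"
  cat(sprintf("MSN neutrality test (%s level)\n", x$level))
  cat(sprintf("  L_0 = %.3f, median simulated L = %.3f\n",
              x$L_0, x$L_sim_median))
  cat(sprintf("  %s = %d/%d = %.3f\n", lbl, x$N_pass_sims, x$N, x$P))
  invisible(x)
}

#' Full MSN analysis of one subject: fit plus both neutrality tests
#'
#' Convenience wrapper running [msn_fit()] and both levels of
#' [msn_neutrality_test()], returning the reporting row.
#'
#' @param x an [abundance_matrix()].
#' @param ... passed to [msn_fit()].
#' @param trunc_tol stick-breaking truncation tolerance for the tests.
#' @return list with `fit`, `meta`, `local` and the one-row data.frame
#'   `row` (see [msn_result_row()]).
#' @export
msn_analyze <- function(x, ..., trunc_tol = 1e-10) {
  fit <- msn_fit(x, ...)
  meta <- msn_neutrality_test(fit, "metacommunity", trunc_tol)
  loc <- msn_neutrality_test(fit, "local", trunc_tol)
  row <- msn_result_row(attr(x, "subject_id"),
                        L_0 = meta$L_0, theta = fit$theta,
                        M_value = fit$M_value,
                        L_M = meta$L_sim_median, N_M = meta$N_pass_sims,
                        N = meta$N, P_M = meta$P,
                        L_L = loc$L_sim_median, N_L = loc$N_pass_sims,
                        P_L = loc$P)
  list(fit = fit, meta = meta, local = loc, row = row)
}
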