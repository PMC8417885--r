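#' Bin a species abundance distribution into Preston-style octaves
#'
#' Observed and expected species counts are aggregated into doubling
#' abundance classes `[1], [2-3], [4-7], ...`; expected mass beyond the
#' largest observed abundance is added to the final class, and classes
#' are pooled from the right until every expected count reaches
#' `floor`.
#'
#' @param obs_abund vector of observed abundances (one entry per
#'   species-niche observation).
#' @param expected_fun function of `n` (vectorized, `n >= 1`) giving the
#'   expected number of species with abundance `n`.
#' @param expected_tail_fun function of `M` giving the expected species
#'   count with abundance `> M`.
#' @param floor minimum expected count per pooled class.
#' @return data.frame with `lower`, `upper`, `O`, `E` per pooled class,
#'   or `NULL` when fewer than 2 classes remain.
#' @export
bin_sad <- function(obs_abund, expected_fun, expected_tail_fun,
                    floor = 1.0) {
  maxn <- max(obs_abund)
  n_oct <- base::floor(log2(maxn)) + 1L
  lower <- 2^(seq_len(n_oct) - 1L)
  upper <- pmin(2^seq_len(n_oct) - 1L, maxn)
  En <- expected_fun(seq_len(maxn))
  oct_of <- base::floor(log2(seq_len(maxn))) + 1L
  E <- as.numeric(tapply(En, oct_of, sum))
  E[n_oct] <- E[n_oct] + expected_tail_fun(maxn)
  O <- as.numeric(tapply(tabulate(obs_abund, maxn), oct_of, sum))

  # pool offending classes (rightmost first) into their left neighbour
  while (length(E) > 1L && any(E < floor)) {
    i <- max(which(E < floor))
    j <- if (i == 1L) 2L else i - 1L
    a <- min(i, j); b <- max(i, j)
    E[a] <- E[a] + E[b]; O[a] <- O[a] + O[b]; upper[a] <- upper[b]
    E <- E[-b]; O <- O[-b]; lower <- lower[-b]; upper <- upper[-b]
  }
  if (length(E) < 2L) return(NULL)
  data.frame(lower = lower, upper = upper, O = O, E = E)
}

# chi-squared GOF + R^2 on pooled classes
sad_gof <- function(binned) {
  if (is.null(binned)) {
    return(list(chi2 = NA_real_, df = NA_integer_, P = NA_real_,
                R2 = NA_real_, valid = FALSE))
  }
  chi2 <- sum((binned$O - binned$E)^2 / binned$E)
  df <- nrow(binned) - 1L
  sstot <- sum((binned$O - mean(binned$O))^2)
  R2 <- if (sstot > 0) 1 - sum((binned$O - binned$E)^2) / sstot else
    ifelse(chi2 == 0, 1, NA_real_)
  list(chi2 = chi2, df = df, P = pchisq(chi2, df, lower.tail = FALSE),
       R2 = R2, valid = TRUE)
}

#' Fit the niche-neutral hybrid model to a metacommunity
#'
#' Treats each of the `K` local communities (time points) as a niche
#' with its own neutral species abundance distribution: per niche the
#' zero-truncated negative-binomial model is fitted by maximum
#' likelihood ([fit_niche()]), the metacommunity expected SAD is the sum
#' across niches, \eqn{\langle\phi_{n;K}\rangle = \sum_i
#' \langle\phi_{n,i}\rangle}, and goodness of fit is assessed by the
#' chi-squared statistic \eqn{\chi^2 = \sum_n (E_n - O_n)^2 / E_n} over
#' pooled Preston octaves, together with `R^2` on the same classes.
#' Each niche is additionally tested against its own fit (local
#' neutrality test); per-niche P-values are stored so pass counts can be
#' re-evaluated at any threshold via [nnh_local_pass()].
#'
#' Niches with flagged fits (degenerate SADs or boundary optima) are
#' excluded from the averages, the pooled expected SAD and the local
#' pass denominator.
#'
#' The per-niche migration coefficient is the concentration-to-
#' probability convention `m_i = gamma_i / (gamma_i + J_i - 1)`,
#' mirroring the relation between immigration rate and migration
#' probability in the multi-site neutral model.
#'
#' @param x an [abundance_matrix()] (or bare count matrix).
#' @param P_t P-value threshold used for the reported local pass counts.
#' @param bin_floor minimum expected species count per pooled class.
#' @param n_starts optimizer starts per niche.
#' @return object of class `nnh_fit`: `per_niche` data.frame (`J`, `S`,
#'   `theta`, `x`, `gamma`, `m`, `flagged`, `P_local`), `K`, `K_valid`,
#'   `binned`, `chi2`, `df`, `P`, `R2`, `N_pass`, `pct_pass`, `P_t`, and
#'   the averaged reporting `row` (see [nnh_result_row()]).
#' @examples
#' \donttest{
#' m <- gen_hybrid(K = 6, theta = rep(8, 6), x = rep(0.7, 6),
#'                 gamma = rep(1, 6), S = rep(30, 6), seed = 1)
#' fit <- nnh_fit(m)
#' coef(fit)
#' }
#' @export
nnh_fit <- function(x, P_t = 0.05, bin_floor = 1.0, n_starts = 3L) {
  if (!inherits(x, "abundance_matrix")) x <- abundance_matrix(x)
  counts <- unclass(x)
  K <- ncol(counts)

  fits <- vector("list", K)
  P_local <- rep(NA_real_, K)
  for (i in seq_len(K)) {
    ab <- counts[, i][counts[, i] > 0]
    fits[[i]] <- fit_niche(ab, n_starts = n_starts)
    f <- fits[[i]]
    if (!f$flagged) {
      b <- bin_sad(ab,
                   function(n) expected_sad(n, f$theta, f$x, f$gamma),
                   function(M) expected_sad_tail(M, f$theta, f$x, f$gamma),
                   floor = bin_floor)
      P_local[i] <- sad_gof(b)$P
    }
  }

  per_niche <- data.frame(
    niche = colnames(counts) %||% seq_len(K),
    J = vapply(fits, `[[`, 0, "J"),
    S = vapply(fits, `[[`, 0, "S"),
    theta = vapply(fits, `[[`, 0, "theta"),
    x = vapply(fits, `[[`, 0, "x"),
    gamma = vapply(fits, `[[`, 0, "gamma"),
    flagged = vapply(fits, `[[`, TRUE, "flagged"),
    P_local = P_local,
    stringsAsFactors = FALSE)
  per_niche$m <- with(per_niche,
                      ifelse(flagged, NA_real_, gamma / (gamma + J - 1)))

  valid <- !per_niche$flagged
  K_valid <- sum(valid)

  if (K_valid > 0L) {
    vf <- fits[valid]
    obs <- counts[, valid, drop = FALSE]
    obs_abund <- obs[obs > 0]
    efun <- function(n) {
      Reduce(`+`, lapply(vf, function(f)
        expected_sad(n, f$theta, f$x, f$gamma)))
    }
    tfun <- function(M) {
      sum(vapply(vf, function(f)
        expected_sad_tail(M, f$theta, f$x, f$gamma), 0))
    }
    binned <- bin_sad(obs_abund, efun, tfun, floor = bin_floor)
    gof <- sad_gof(binned)
  } else {
    binned <- NULL
    gof <- sad_gof(NULL)
  }

  N_pass <- sum(P_local[valid] > P_t, na.rm = TRUE)
  pct_pass <- if (K_valid > 0L) 100 * N_pass / K_valid else NA_real_

  avg <- function(v) mean(v[valid])
  row <- if (K_valid > 0L && gof$valid) {
    nnh_result_row(attr(x, "subject_id"),
                   J = avg(per_niche$J), S = avg(per_niche$S),
                   theta = avg(per_niche$theta), m = avg(per_niche$m),
                   x = avg(per_niche$x), gamma = avg(per_niche$gamma),
                   R2 = gof$R2, chi2 = gof$chi2, P = gof$P,
                   N_pass = N_pass, pct_pass = pct_pass)
  } else NULL

  structure(list(counts = x, per_niche = per_niche, K = K,
                 K_valid = K_valid, binned = binned,
                 chi2 = gof$chi2, df = gof$df, P = gof$P, R2 = gof$R2,
                 N_pass = N_pass, pct_pass = pct_pass, P_t = P_t,
                 row = row, call = match.call()),
            class = "nnh_fit")
}

#' Local neutrality pass counts at an arbitrary threshold
#'
#' Re-evaluates the per-niche local neutrality tests of an [nnh_fit()]
#' at threshold `P_t`: a niche passes iff its local P-value exceeds
#' `P_t`. Only niches with valid fits count toward the denominator.
#'
#' @param fit an `nnh_fit`.
#' @param P_t threshold in (0, 1).
#' @return list with `N_pass` and `pct_pass`.
#' @export
nnh_local_pass <- function(fit, P_t = 0.05) {
  if (P_t <= 0 || P_t >= 1) stop("P_t must lie in (0, 1)")
  valid <- !fit$per_niche$flagged
  n <- sum(fit$per_niche$P_local[valid] > P_t, na.rm = TRUE)
  k <- sum(valid)
  list(N_pass = n, pct_pass = if (k > 0) 100 * n / k else NA_real_)
}

#' @export
print.nnh_fit <- function(x, ...) {
  cat("Niche-neutral hybrid model fit\n")
  cat(sprintf("  subject: %s, %d niches (%d with valid fits)\n",
              attr(x$counts, "subject_id"), x$K, x$K_valid))
  if (!is.na(x$chi2))
    cat(sprintf("  metacommunity chi2 = %.3f (df %d), P = %.3f, R2 = %.3f\n",
                x$chi2, x$df, x$P, x$R2))
  else cat("  metacommunity test undefined (too few pooled classes)\n")
  cat(sprintf("  local tests: %d/%d niches pass at P_t = %.2f (%.1f%%)\n",
              x$N_pass, x$K_valid, x$P_t, x$pct_pass))
  invisible(x)
}

#' @export
coef.nnh_fit <- function(object, ...) {
  v <- !object$per_niche$flagged
  if (!any(v)) return(c(theta = NA, x = NA, gamma = NA, m = NA))
  with(object$per_niche[v, ],
       c(theta = mean(theta), x = mean(x), gamma = mean(gamma),
         m = mean(m)))
}

#' @export
summary.nnh_fit <- function(object, ...) {
  structure(list(per_niche = object$per_niche, row = object$row,
                 K = object$K, K_valid = object$K_valid),
            class = "summary.nnh_fit")
}

#' @export
print.summary.nnh_fit <- function(x, ...) {
  cat(sprintf("Per-niche fits (%d/%d valid):\n", x$K_valid, x$K))
  print(x$per_niche, digits = 4)
  if (!is.null(x$row)) {
    cat("\nMetacommunity summary row:\n")
    print(x$row, digits = 4)
  }
  invisible(x)
}

#' Expected metacommunity species abundance distribution
#'
#' @param object an [nnh_fit()].
#' @param n abundances at which to evaluate the pooled expectation.
#' @param ... unused.
#' @return expected species counts `E_n` summed over valid niches.
#' @export
predict.nnh_fit <- function(object, n = NULL, ...) {
  if (is.null(n)) n <- seq_len(max(unclass(object$counts)))
  valid <- which(!object$per_niche$flagged)
  if (!length(valid)) return(rep(NA_real_, length(n)))
  out <- rep(0, length(n))
  for (i in valid) {
    p <- object$per_niche[i, ]
    out <- out + expected_sad(n, p$theta, p$x, p$gamma)
  }
  out
}

#' Observed-vs-predicted SAD plot for a niche-neutral hybrid fit
#'
#' Plots the pooled observed and expected species counts per abundance
#' octave.
#'
#' @param x an [nnh_fit()].
#' @param ... passed to [graphics::barplot()].
#' @export
plot.nnh_fit <- function(x, ...) {
  if (is.null(x$binned)) stop("no pooled classes to plot")
  b <- x$binned
  lab <- ifelse(b$lower == b$upper, b$lower,
                paste0(b$lower, "-", b$upper))
  h <- rbind(observed = b$O, predicted = b$E)
  barplot(h, beside = TRUE, names.arg = lab,
          xlab = "abundance class", ylab = "number of species",
          legend.text = rownames(h),
          main = sprintf("subject %s: observed vs predicted SAD",
                         attr(x$counts, "subject_id")), ...)
  invisible(x)
}
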