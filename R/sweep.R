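#' Classify a subject's metacommunity at one P-value threshold
#'
#' A model "passes" when its metacommunity pseudo P-value strictly
#' exceeds the threshold `P_t`. The four exhaustive, mutually exclusive
#' categories are `MSN-only`, `NNH-only`, `both`, and `neither`.
#'
#' @param P_msn metacommunity pseudo P-value(s) of the multi-site
#'   neutral test.
#' @param P_nnh chi-squared P-value(s) of the niche-neutral hybrid
#'   metacommunity test.
#' @param P_t threshold in (0, 1).
#' @return factor with levels `MSN-only`, `NNH-only`, `both`, `neither`.
#' @examples
#' classify_assembly(0.975, 0.000, 0.05) # MSN-only
#' classify_assembly(0.686, 0.996, 0.05) # both
#' @export
classify_assembly <- function(P_msn, P_nnh, P_t = 0.05) {
  if (P_t <= 0 || P_t >= 1) stop("P_t must lie in (0, 1)")
  if (any(P_msn < 0 | P_msn > 1, na.rm = TRUE) ||
      any(P_nnh < 0 | P_nnh > 1, na.rm = TRUE))
    stop("P-values must lie in [0, 1]")
  msn <- P_msn > P_t
  nnh <- P_nnh > P_t
  lv <- c("MSN-only", "NNH-only", "both", "neither")
  factor(ifelse(msn & nnh, "both",
         ifelse(msn, "MSN-only",
         ifelse(nnh, "NNH-only", "neither"))), levels = lv)
}

#' Collate per-subject test results for sweeping and reporting
#'
#' @param subject_id,group character vectors.
#' @param P_M,P_L multi-site neutral metacommunity / local pseudo
#'   P-values.
#' @param P_nnh niche-neutral hybrid metacommunity P-values.
#' @param local_P list of per-niche local P-value vectors from the
#'   hybrid fits (one element per subject).
#' @return data.frame of class `mn_results` with a `local_P` list
#'   column.
#' @export
collate_results <- function(subject_id, group, P_M, P_L, P_nnh,
                            local_P) {
  df <- data.frame(subject_id = subject_id, group = group,
                   P_M = P_M, P_L = P_L, P_nnh = P_nnh,
                   stringsAsFactors = FALSE)
  df$local_P <- local_P
  class(df) <- c("mn_results", "data.frame")
  df
}

# mean over valid niches of 100 * 1{P_local > P_t}
nnh_local_rate <- function(local_P, P_t) {
  p <- local_P[!is.na(local_P)]
  if (!length(p)) return(NA_real_)
  100 * mean(p > P_t)
}

#' Passing-rate and category tables under a P-value threshold sweep
#'
#' For each group and overall, at each threshold: the percentage of
#' subjects whose metacommunity passes the multi-site neutral (MSN) and
#' niche-neutral hybrid (NNH) tests, the local-community passing rates
#' (for MSN the percentage of subjects with `P_L > P_t`; for NNH the
#' mean over subjects of the percentage of niches passing), and the
#' four-way category breakdown of [classify_assembly()].
#'
#' @param results an `mn_results` table from [collate_results()].
#' @param thresholds P-value thresholds, default `c(0.05, 0.5, 0.9,
#'   0.95)`.
#' @return list with `passing` (long data.frame: `group`, `n`, `model`,
#'   `level`, `threshold`, `pct`) and `categories` (data.frame:
#'   `threshold`, `group`, `n`, counts and percentages of the four
#'   categories). Percentages are rounded to 1 decimal.
#' @export
sweep_tables <- function(results, thresholds = c(0.05, 0.5, 0.9, 0.95)) {
  groups_all <- if (is.factor(results$group)) levels(results$group)
                else unique(as.character(results$group))
  present <- intersect(groups_all, as.character(results$group))
  empty <- setdiff(groups_all, present)
  if (length(empty)) warning("omitting empty group(s): ",
                             paste(empty, collapse = ", "))
  blocks <- c(as.list(present), list(NULL)) # NULL = overall

  passing <- list(); cats <- list()
  for (b in blocks) {
    sub <- if (is.null(b)) results else results[results$group == b, ]
    gname <- if (is.null(b)) "Overall" else b
    n <- nrow(sub)
    if (n == 0L) next
    for (t in thresholds) {
      passing[[length(passing) + 1L]] <- data.frame(
        group = gname, n = n,
        model = c("MSN", "MSN", "NNH", "NNH"),
        level = c("metacommunity", "local", "metacommunity", "local"),
        threshold = t,
        pct = round(c(100 * mean(sub$P_M > t),
                      100 * mean(sub$P_L > t),
                      100 * mean(sub$P_nnh > t, na.rm = TRUE),
                      mean(vapply(sub$local_P, nnh_local_rate, 0,
                                  P_t = t), na.rm = TRUE)), 1),
        stringsAsFactors = FALSE)
      cl <- classify_assembly(sub$P_M, sub$P_nnh, t)
      cnt <- table(cl)
      cats[[length(cats) + 1L]] <- data.frame(
        threshold = t, group = gname, n = n,
        msn_only = unname(cnt["MSN-only"]),
        msn_only_pct = round(100 * cnt[["MSN-only"]] / n, 1),
        nnh_only = unname(cnt["NNH-only"]),
        nnh_only_pct = round(100 * cnt[["NNH-only"]] / n, 1),
        both = unname(cnt["both"]),
        both_pct = round(100 * cnt[["both"]] / n, 1),
        neither = unname(cnt["neither"]),
        neither_pct = round(100 * cnt[["neither"]] / n, 1),
        stringsAsFactors = FALSE)
    }
  }
  list(passing = do.call(rbind, passing),
       categories = do.call(rbind, cats))
}

#' Compare host-status groups: Fisher's exact and Student's t-tests
#'
#' At each threshold and for each model, group pairs are compared with
#' a two-sided Fisher exact test on the 2x2 metacommunity pass/fail
#' counts and a two-sided two-sample Student's t-test (pooled variance
#' by default) on the per-subject local passing rates (for NNH the
#' percentage of niches passing; for MSN `100 * 1{P_L > P_t}`).
#'
#' @param results an `mn_results` table.
#' @param thresholds P-value thresholds.
#' @param merges named list of merged group labels, e.g.
#'   `list(BV = c("ABV", "SBV"), HEA = c("HEA-1", "HEA-2", "PREG"))`;
#'   merged labels are added to the comparison set.
#' @param pairs optional 2-column matrix/list of label pairs; default
#'   all pairs of base plus merged labels.
#' @param welch use Welch's t-test instead of pooled variance.
#' @return data.frame: `threshold`, `model`, `group1`, `group2`, `n1`,
#'   `n2`, `fisher_P`, `t_P` (`NA` with a note when a group has < 2
#'   subjects).
#' @export
group_compare <- function(results, thresholds = c(0.05, 0.5, 0.9, 0.95),
                          merges = list(BV = c("ABV", "SBV"),
                                        HEA = c("HEA-1", "HEA-2")),
                          pairs = NULL, welch = FALSE) {
  base <- unique(as.character(results$group))
  labels <- c(base, names(merges))
  members <- c(setNames(as.list(base), base), merges)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(labels, 2L))
  }
  out <- list()
  for (t in thresholds) {
    for (r in seq_len(nrow(pairs))) {
      g1 <- pairs[r, 1L]; g2 <- pairs[r, 2L]
      if (any(members[[g1]] %in% members[[g2]])) next # overlapping merge
      s1 <- results[results$group %in% members[[g1]], ]
      s2 <- results[results$group %in% members[[g2]], ]
      for (model in c("MSN", "NNH")) {
        meta_p <- function(s) if (model == "MSN") s$P_M else s$P_nnh
        pass1 <- sum(meta_p(s1) > t, na.rm = TRUE)
        pass2 <- sum(meta_p(s2) > t, na.rm = TRUE)
        tab <- matrix(c(pass1, nrow(s1) - pass1,
                        pass2, nrow(s2) - pass2), 2L, byrow = TRUE)
        fp <- fisher.test(tab)$p.value
        rate <- function(s) {
          if (model == "MSN") 100 * (s$P_L > t)
          else vapply(s$local_P, nnh_local_rate, 0, P_t = t)
        }
        r1 <- rate(s1); r2 <- rate(s2)
        tp <- if (length(r1) < 2L || length(r2) < 2L) NA_real_ else {
          v <- tryCatch(t.test(r1, r2, var.equal = !welch)$p.value,
                        error = function(e) NA_real_) # zero variance etc.
          v
        }
        out[[length(out) + 1L]] <- data.frame(
          threshold = t, model = model, group1 = g1, group2 = g2,
          n1 = nrow(s1), n2 = nrow(s2), fisher_P = fp, t_P = tp,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
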