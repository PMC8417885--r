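#' Write the full set of report artifacts for a pipeline run
#'
#' Emits, under `out_dir`: the per-subject MSN and NNH result tables
#' (TSV, fixed reporting schemas), the threshold-sweep passing and
#' category tables, the group-comparison table, bar charts of passing
#' percentages per group at each threshold, observed-vs-predicted SAD
#' plots for requested subjects, and a JSON run manifest (seed,
#' iteration counts, thresholds, package version).
#'
#' @param msn_rows data.frame of [msn_result_row()] rows.
#' @param nnh_rows data.frame of [nnh_result_row()] rows.
#' @param results an `mn_results` table from [collate_results()].
#' @param nnh_fits named list of [nnh_fit()] objects (for SAD plots).
#' @param out_dir output directory (created if absent).
#' @param thresholds P-value thresholds for the sweep.
#' @param sad_subjects subject ids to plot; default the first subject.
#' @param run_config list recorded verbatim in the manifest.
#' @return invisible character vector of files written.
#' @export
make_report <- function(msn_rows, nnh_rows, results, nnh_fits,
                        out_dir, thresholds = c(0.05, 0.5, 0.9, 0.95),
                        sad_subjects = NULL, run_config = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  p <- function(f) file.path(out_dir, f)

  write_result_table(msn_rows, p("msn_results.tsv"), schema = "msn")
  write_result_table(nnh_rows, p("nnh_results.tsv"), schema = "nnh")
  files <- c(files, p("msn_results.tsv"), p("nnh_results.tsv"))

  sw <- sweep_tables(results, thresholds)
  write.table(sw$passing, p("passing_rates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sw$categories, p("category_breakdown.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c(files, p("passing_rates.tsv"), p("category_breakdown.tsv"))

  gc_tab <- group_compare(results, thresholds)
  write.table(gc_tab, p("group_comparisons.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c(files, p("group_comparisons.tsv"))

  for (t in thresholds) {
    f <- p(sprintf("passing_barchart_Pt%s.pdf", format(t)))
    pdf(f, width = 8, height = 5)
    pb <- sw$passing[sw$passing$threshold == t &
                       sw$passing$group != "Overall", ]
    h <- tapply(pb$pct, list(paste(pb$model, pb$level), pb$group), identity)
    barplot(h, beside = TRUE, ylim = c(0, 100),
            ylab = "% passing", xlab = "group",
            main = sprintf("Passing percentages at P_t = %s", format(t)),
            legend.text = rownames(h),
            args.legend = list(x = "topright", cex = 0.7, bty = "n"))
    dev.off()
    files <- c(files, f)
  }

  if (is.null(sad_subjects) && length(nnh_fits))
    sad_subjects <- names(nnh_fits)[1L]
  for (s in sad_subjects) {
    fit <- nnh_fits[[s]]
    if (is.null(fit) || is.null(fit$binned)) next
    f <- p(sprintf("sad_%s.pdf", s))
    pdf(f, width = 6, height = 5)
    plot(fit)
    dev.off()
    files <- c(files, f)
  }

  manifest <- c(run_config,
                list(thresholds = thresholds,
                     n_subjects = nrow(results),
                     package_version =
                       as.character(utils::packageVersion("metaneutral")),
                     files = basename(files)))
  jsonlite::write_json(manifest, p("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, p("run_manifest.json"))
  invisible(files)
}

#' Run the full assembly analysis on a synthetic cohort
#'
#' End-to-end pipeline: generate the cohort, fit the multi-site neutral
#' model and run both neutrality tests per subject, fit the
#' niche-neutral hybrid model per subject, classify subjects under the
#' threshold sweep, compare groups, and write all report artifacts.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory for [make_report()]; `NULL` to skip
#'   writing artifacts.
#' @param n_iter,n_burn,thin Gibbs sampler settings per subject
#'   (desk-scale defaults; see [msn_fit()] for the reference protocol).
#' @param thresholds P-value sweep.
#' @param seed master seed; every random stage derives from it.
#' @param verbose print per-subject progress lines.
#' @return invisible list: `cohort`, `msn_rows`, `nnh_rows`, `results`,
#'   `sweep`, `comparisons`, `files`.
#' @export
run_all <- function(spec = cohort_spec(subjects_per_group = c(1, 3, 1, 4, 3),
                                       T_range = c(5, 10),
                                       depth_range = c(800, 1200)),
                    out_dir = NULL,
                    n_iter = 2000L, n_burn = 1000L, thin = 10L,
                    thresholds = c(0.05, 0.5, 0.9, 0.95),
                    seed = 1L, verbose = FALSE) {
  spec$seed <- as.integer(seed)
  cohort <- gen_cohort(spec)
  set.seed(seed + 1L)

  msn_rows <- list(); nnh_rows <- list(); nnh_fits <- list()
  res <- list()
  for (sid in names(cohort$matrices)) {
    m <- cohort$matrices[[sid]]
    if (verbose) message(sprintf("[%s] %d species x %d communities",
                                 sid, nrow(m), ncol(m)))
    ms <- msn_analyze(m, n_iter = n_iter, n_burn = n_burn, thin = thin)
    nf <- nnh_fit(m)
    msn_rows[[sid]] <- ms$row
    if (!is.null(nf$row)) nnh_rows[[sid]] <- nf$row
    nnh_fits[[sid]] <- nf
    res[[sid]] <- list(group = cohort$manifest[[sid]]$group,
                       P_M = ms$meta$P, P_L = ms$local$P,
                       P_nnh = nf$P,
                       local_P = nf$per_niche$P_local)
  }

  results <- collate_results(
    subject_id = names(res),
    group = vapply(res, `[[`, "", "group"),
    P_M = vapply(res, `[[`, 0, "P_M"),
    P_L = vapply(res, `[[`, 0, "P_L"),
    P_nnh = vapply(res, function(r) ifelse(is.na(r$P_nnh), 0, r$P_nnh), 0),
    local_P = lapply(res, `[[`, "local_P"))

  msn_rows <- do.call(rbind, msn_rows)
  nnh_rows <- if (length(nnh_rows)) do.call(rbind, nnh_rows) else
    nnh_result_row("none", 0, 0, 1, 0, 0.5, 1, 1, 0, 1, 0, 0)[0L, ]

  sw <- sweep_tables(results, thresholds)
  gc_tab <- group_compare(results, thresholds)

  files <- character(0)
  if (!is.null(out_dir)) {
    files <- make_report(msn_rows, nnh_rows, results, nnh_fits, out_dir,
                         thresholds = thresholds,
                         run_config = list(seed = seed, n_iter = n_iter,
                                           n_burn = n_burn, thin = thin))
  }
  invisible(list(cohort = cohort, msn_rows = msn_rows,
                 nnh_rows = nnh_rows, results = results, sweep = sw,
                 comparisons = gc_tab, files = files))
}
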