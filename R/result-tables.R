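#' Assemble one row of the multi-site neutral result table
#'
#' Collects the per-subject quantities reported for the multi-site
#' neutral (MSN) fit: the observed log-likelihood `L_0`, the posterior
#' median biodiversity number `theta`, the M-value (mean over local
#' communities of the chain-median migration probabilities), and the
#' metacommunity- and local-level Monte-Carlo test summaries.
#'
#' @param subject_id subject label.
#' @param L_0 median observed log-likelihood (nats).
#' @param theta posterior median fundamental biodiversity number.
#' @param M_value mean of per-community median migration probabilities.
#' @param L_M,N_M,P_M metacommunity-level simulated-likelihood median,
#'   pass count and pseudo P-value.
#' @param L_L,N_L,P_L same at the local-community level.
#' @param N number of simulated parameter sets.
#' @return one-row data.frame in the fixed reporting column order.
#' @export
msn_result_row <- function(subject_id, L_0, theta, M_value,
                           L_M, N_M, N, P_M, L_L, N_L, P_L) {
  stopifnot(N_M <= N, N_L <= N, P_M >= 0, P_M <= 1, P_L >= 0, P_L <= 1)
  data.frame(subject_id = as.character(subject_id),
             L_0 = L_0, theta = theta, M_value = M_value,
             L_M = L_M, N_M = as.integer(N_M), N = as.integer(N), P_M = P_M,
             L_L = L_L, N_L = as.integer(N_L), P_L = P_L,
             stringsAsFactors = FALSE)
}

#' Assemble one row of the niche-neutral hybrid result table
#'
#' @param subject_id subject label.
#' @param J,S,theta,m,x,gamma per-niche averages: individuals, species,
#'   biodiversity parameter, migration coefficient, birth/death ratio,
#'   immigration parameter.
#' @param R2 coefficient of determination of the binned observed vs
#'   expected species abundance distribution.
#' @param chi2,P chi-squared statistic and upper-tail P-value of the
#'   metacommunity goodness-of-fit test.
#' @param N_pass,pct_pass count and percentage of niches passing the
#'   local neutrality test.
#' @return one-row data.frame in the fixed reporting column order.
#' @export
nnh_result_row <- function(subject_id, J, S, theta, m, x, gamma,
                           R2, chi2, P, N_pass, pct_pass) {
  stopifnot(P >= 0, P <= 1, pct_pass >= 0, pct_pass <= 100, chi2 >= 0)
  data.frame(subject_id = as.character(subject_id),
             J = J, S = S, theta = theta, m = m, x = x, gamma = gamma,
             R2 = R2, chi2 = chi2, P = P,
             N_pass = as.integer(N_pass), pct_pass = pct_pass,
             stringsAsFactors = FALSE)
}

.msn_real_cols <- c("L_0", "theta", "M_value", "L_M", "P_M", "L_L", "P_L")
.nnh_real_cols <- c("J", "S", "theta", "m", "x", "gamma", "R2", "chi2", "P")

#' Write MSN or NNH result rows to a TSV file
#'
#' Columns follow the fixed reporting order of the per-subject summary
#' tables; real-valued columns (including log-likelihoods) are rendered
#' to 3 decimals, percentages to 1 decimal, counts as integers. An empty
#' row list produces a header-only file.
#'
#' @param rows data.frame of rows from [msn_result_row()] or
#'   [nnh_result_row()] (possibly `rbind`-ed), or an empty data.frame
#'   with the right columns.
#' @param path output TSV path.
#' @param schema `"msn"` or `"nnh"`; inferred from columns when `NULL`.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(rows, path, schema = NULL) {
  if (is.null(schema)) {
    schema <- if ("P_M" %in% names(rows)) "msn"
              else if ("pct_pass" %in% names(rows)) "nnh"
              else stop("cannot infer result-table schema from columns")
  }
  cols <- switch(schema,
    msn = c("subject_id", .msn_real_cols[1:4], "N_M", "N", "P_M",
            "L_L", "N_L", "P_L"),
    nnh = c("subject_id", .nnh_real_cols, "N_pass", "pct_pass"),
    stop("unknown schema: ", schema))
  # fixed order even for empty input
  out <- rows[, cols, drop = FALSE]
  real <- intersect(switch(schema, msn = .msn_real_cols,
                           nnh = .nnh_real_cols), cols)
  for (cl in real) out[[cl]] <- sprintf("%.3f", out[[cl]])
  if (schema == "nnh") out$pct_pass <- sprintf("%.1f", rows$pct_pass)
  if (nrow(rows) == 0L) out <- out[0L, , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_result_table()]
#'
#' @param path TSV path.
#' @return data.frame with numeric columns restored.
#' @export
read_result_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
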