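#' Construct an abundance matrix for one subject (metacommunity)
#'
#' An `abundance_matrix` holds the non-negative integer counts of each
#' species (rows) in each local community (columns) of one subject's
#' metacommunity. In a longitudinal design each column is one time-point
#' sample; the multi-site neutral model treats it as a local community
#' coupled to the subject's metacommunity, the niche-neutral hybrid model
#' treats it as a niche.
#'
#' Rows that are zero everywhere are dropped with a warning: a species
#' never observed in the subject carries no information for either model.
#'
#' @param counts integer matrix, species x local community; all entries
#'   `>= 0`, every column sum `>= 1`.
#' @param species_ids,sample_ids character labels for rows / columns;
#'   default taken from `dimnames(counts)` or generated.
#' @param subject_id single character label for the subject.
#' @return An object of class `abundance_matrix`: the validated integer
#'   matrix with `subject_id` attribute.
#' @examples
#' m <- abundance_matrix(matrix(c(5, 1, 0, 0, 2, 3), nrow = 3),
#'                       subject_id = "S1")
#' colSums(m)
#' @export
abundance_matrix <- function(counts, species_ids = NULL, sample_ids = NULL,
                             subject_id = "subject") {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("empty abundance table")
  if (any(!is.finite(counts))) stop("non-finite entries in abundance table")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at row %d, column %d", bad[1L], bad[2L]))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at row %d, column %d", bad[1L], bad[2L]))
  }
  storage.mode(counts) <- "integer"
  if (is.null(species_ids))
    species_ids <- rownames(counts) %||% sprintf("sp%03d", seq_len(nrow(counts)))
  if (is.null(sample_ids))
    sample_ids <- colnames(counts) %||% sprintf("t%03d", seq_len(ncol(counts)))
  dimnames(counts) <- list(species_ids, sample_ids)

  zero_rows <- rowSums(counts) == 0L
  if (any(zero_rows)) {
    warning(sprintf("dropping %d all-zero species row(s): %s",
                    sum(zero_rows),
                    paste(head(species_ids[zero_rows], 5L), collapse = ", ")))
    counts <- counts[!zero_rows, , drop = FALSE]
  }
  if (nrow(counts) == 0L) stop("no species with positive counts")
  if (any(colSums(counts) < 1L)) stop("every local community needs >= 1 read")

  structure(counts, subject_id = as.character(subject_id)[1L],
            class = c("abundance_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: subject '%s', %d species x %d local communities\n",
              attr(x, "subject_id"), nrow(x), ncol(x)))
  cat(sprintf("  per-sample depth: %s\n",
              paste(range(colSums(unclass(x))), collapse = "-")))
  invisible(x)
}

#' @export
`[.abundance_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out))
    attr(out, "subject_id") <- attr(x, "subject_id")
  out
}

#' Read a species-by-sample abundance table
#'
#' Reads a TSV/CSV count table with a header row into an
#' [abundance_matrix()]. By default species are rows (taxa-as-rows
#' convention); set `orientation = "samples_as_rows"` for the transpose.
#'
#' @param path file path; tab-separated unless the extension is `.csv`.
#' @param orientation `"species_as_rows"` (default) or `"samples_as_rows"`.
#' @param subject_id subject label; defaults to the file stem.
#' @return An [abundance_matrix()].
#' @export
read_abundance_table <- function(path,
                                 orientation = c("species_as_rows",
                                                 "samples_as_rows"),
                                 subject_id = NULL) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, row.names = 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty abundance table: ", path)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))),
                 arr.ind = TRUE)
    if (length(bad)) {
      stop(sprintf("non-numeric entry at row '%s', column '%s' in %s",
                   rownames(df)[bad[1L, 1L]], colnames(df)[bad[1L, 2L]], path))
    }
    storage.mode(m) <- "numeric"
  }
  if (orientation == "samples_as_rows") m <- t(m)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  abundance_matrix(m, subject_id = subject_id)
}

#' Write an abundance matrix to a TSV file
#'
#' @param x an [abundance_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  df <- data.frame(species_id = rownames(x), unclass(x),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects columns `subject_id`, `sample_id`, `group`, `time_index`.
#' Within each subject the time indices must be strictly increasing in
#' file order.
#'
#' @param path TSV path.
#' @param groups allowed group labels; defaults to the study's five
#'   cohorts and is extensible.
#' @return data.frame with the four columns, `group` as factor.
#' @export
read_metadata <- function(path,
                          groups = c("ABV", "SBV", "HEA-1", "HEA-2", "PREG")) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("subject_id", "sample_id", "group", "time_index")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(df$group %in% groups))
    stop("unknown group label(s): ",
         paste(unique(setdiff(df$group, groups)), collapse = ", "))
  for (s in unique(df$subject_id)) {
    ti <- df$time_index[df$subject_id == s]
    if (any(diff(ti) <= 0))
      stop("sample_times not strictly increasing for subject ", s)
  }
  df$group <- factor(df$group, levels = groups)
  df
}
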