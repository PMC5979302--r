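#' Read a per-sample per-amplicon count table
#'
#' Accepts either a wide table (rows = samples, first column `sample`,
#' remaining columns = amplicon ids) or a tidy long table with columns
#' `sample`, `amplicon`, `count`.  Columns are checked against the
#' panel: the matrix must contain exactly the panel's amplicons.
#'
#' @param path Tab- or comma-delimited input file.
#' @param panel A [panel_design()].
#' @return Integer matrix, samples x amplicons (dimnames set).
#' @export
read_counts <- function(path, panel) {
  if (!file.exists(path)) stop("count file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (all(c("sample", "amplicon", "count") %in% names(df))) {
    wide <- stats::xtabs(count ~ sample + amplicon, data = df)
    m <- matrix(as.numeric(wide), nrow = nrow(wide),
                dimnames = unname(dimnames(wide)))
  } else if ("sample" %in% names(df)) {
    m <- as.matrix(df[, setdiff(names(df), "sample"), drop = FALSE])
    rownames(m) <- df$sample
  } else {
    stop("count file must be wide (sample + amplicon columns) or long ",
         "(sample, amplicon, count)", call. = FALSE)
  }
  as_count_matrix(m, panel)
}

#' Validate and order a count matrix against a panel
#'
#' @param m Numeric matrix, samples x amplicons, with amplicon ids as
#'   column names.
#' @param panel A [panel_design()].
#' @return The matrix with columns reordered to panel order.
#' @export
as_count_matrix <- function(m, panel) {
  validate_panel(panel)
  ids <- panel$amplicons$id
  missing <- setdiff(ids, colnames(m))
  if (length(missing) > 0L) {
    stop("count matrix lacks panel amplicon(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(colnames(m), ids)
  if (length(extra) > 0L) {
    stop("count matrix has unknown amplicon column(s): ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  m <- m[, ids, drop = FALSE]
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  m
}

#' Write a count matrix as a wide TSV
#'
#' @param m Count matrix (samples x amplicons).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path) {
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Within-plex read-count frequencies
#'
#' The read-count "frequency" of an amplicon is its count divided by
#' the total count of all amplicons of the *same plex* in the same
#' sample, so frequencies within a plex sum to 1 for every sample.
#' Normalizing within the plex removes sample- and plex-level loading
#' differences, leaving only the relative amplification stoichiometry
#' in which copy-number changes are visible.
#'
#' @param m Count matrix (samples x amplicons, panel order).
#' @param panel A [panel_design()].
#' @return Matrix of frequencies, same shape as `m`.
#' @export
rc_frequency <- function(m, panel) {
  m <- as_count_matrix(m, panel)
  plex_of <- panel$amplicons$plex_id[match(colnames(m), panel$amplicons$id)]
  freq <- m
  for (px in panel$plexes) {
    cols <- plex_of == px
    tot <- rowSums(m[, cols, drop = FALSE])
    zero <- tot == 0
    if (any(zero)) {
      stop("zero total count in plex ", px, " for sample(s): ",
           paste(rownames(m)[zero], collapse = ", "), call. = FALSE)
    }
    freq[, cols] <- m[, cols, drop = FALSE] / tot
  }
  freq
}

#' Run-level per-amplicon frequency statistics with CI99 bounds
#'
#' For every amplicon, the mean and standard deviation of its
#' within-plex frequency across the run's samples, and the normal-
#' approximation 99% confidence interval `mean +/- 2.576 * sd`.  These
#' bounds are the data-filtering gate applied to each sample after
#' sequencing; a sample under scrutiny can be excluded from its own
#' baseline (leave-one-out).
#'
#' @param m Count matrix for the run.
#' @param panel A [panel_design()].
#' @param exclude_sample Optional sample name(s) excluded from the
#'   baseline.
#' @param z Quantile multiplier (default 2.576, the two-sided 99%
#'   normal quantile).
#' @return An object of class `amplicon_run_stats`: data.frame with
#'   columns `amplicon_id`, `gene`, `plex_id`, `mean_freq`, `sd_freq`,
#'   `ci99_low`, `ci99_high`; attribute `n_samples`.
#' @export
run_ci99 <- function(m, panel, exclude_sample = NULL, z = 2.576) {
  freq <- rc_frequency(m, panel)
  if (!is.null(exclude_sample)) {
    keep <- !rownames(freq) %in% exclude_sample
    freq <- freq[keep, , drop = FALSE]
  }
  if (nrow(freq) < 3L) {
    stop("CI99 baseline needs >= 3 samples (have ", nrow(freq), ")",
         call. = FALSE)
  }
  mu <- colMeans(freq)
  sdv <- apply(freq, 2, stats::sd)
  idx <- match(colnames(freq), panel$amplicons$id)
  out <- data.frame(amplicon_id = colnames(freq),
                    gene = panel$amplicons$gene[idx],
                    plex_id = panel$amplicons$plex_id[idx],
                    mean_freq = unname(mu),
                    sd_freq = unname(sdv),
                    ci99_low = unname(mu - z * sdv),
                    ci99_high = unname(mu + z * sdv),
                    stringsAsFactors = FALSE)
  attr(out, "n_samples") <- nrow(freq)
  attr(out, "z") <- z
  class(out) <- c("amplicon_run_stats", "data.frame")
  out
}

#' Flag a sample's frequencies against run CI99 bounds
#'
#' Closed-interval comparison: values strictly below `ci99_low` are
#' `LOW`, strictly above `ci99_high` are `HIGH`, boundary values are
#' `IN_CI`.
#'
#' @param freqs Named numeric vector of one sample's within-plex
#'   frequencies (names = amplicon ids), e.g. one row of
#'   [rc_frequency()].
#' @param stats An [run_ci99()] result.
#' @return Named character vector over the amplicons of `freqs`.
#' @export
flag_rc_outliers <- function(freqs, stats) {
  stopifnot(inherits(stats, "amplicon_run_stats"))
  idx <- match(names(freqs), stats$amplicon_id)
  if (any(is.na(idx))) {
    stop("amplicon(s) absent from run statistics: ",
         paste(names(freqs)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  lo <- stats$ci99_low[idx]
  hi <- stats$ci99_high[idx]
  flags <- ifelse(freqs < lo, "LOW", ifelse(freqs > hi, "HIGH", "IN_CI"))
  names(flags) <- names(freqs)
  flags
}

#' Global gene-1/gene-2 read-count ratio
#'
#' Per plex, the ratio of summed gene-1 counts to summed gene-2
#' counts; the global ratio of a sample is the unweighted mean of its
#' per-plex ratios.  Each sample's global ratio is compared against
#' the cohort (all other samples): samples outside
#' `cohort mean +/- flag_multiplier * sd` are flagged.  A whole-gene
#' event roughly doubles or halves the global ratio, the signature
#' that separates it from the cohort's normal spread.
#'
#' @param m Count matrix for the run.
#' @param panel A [panel_design()].
#' @param flag_multiplier SD multiplier for the cohort gate (default 2).
#' @return An object of class `gene_ratio_result`: list with
#'   `per_plex` (samples x plexes ratio matrix), `global` (named
#'   vector), `cohort` (per-sample leave-one-out mean/sd) and `flagged`
#'   (named logical).
#' @export
global_gene_ratio <- function(m, panel, flag_multiplier = 2) {
  m <- as_count_matrix(m, panel)
  g1 <- panel$gene_labels[1]
  amp <- panel$amplicons
  per_plex <- sapply(panel$plexes, function(px) {
    c1 <- amp$id[amp$plex_id == px & amp$gene == g1]
    c2 <- amp$id[amp$plex_id == px & amp$gene != g1]
    s1 <- rowSums(m[, c1, drop = FALSE])
    s2 <- rowSums(m[, c2, drop = FALSE])
    if (any(s1 == 0) || any(s2 == 0)) {
      stop("zero gene count sum in plex ", px, call. = FALSE)
    }
    s1 / s2
  })
  per_plex <- matrix(per_plex, nrow = nrow(m),
                     dimnames = list(rownames(m), panel$plexes))
  glob <- rowMeans(per_plex)
  n <- length(glob)
  cohort <- data.frame(sample = names(glob),
                       cohort_mean = NA_real_, cohort_sd = NA_real_)
  flagged <- stats::setNames(rep(FALSE, n), names(glob))
  if (n >= 3L) {
    for (i in seq_len(n)) {
      others <- glob[-i]
      cohort$cohort_mean[i] <- mean(others)
      cohort$cohort_sd[i] <- stats::sd(others)
      flagged[i] <- abs(glob[i] - cohort$cohort_mean[i]) >
        flag_multiplier * cohort$cohort_sd[i]
    }
  }
  structure(list(per_plex = per_plex, global = glob, cohort = cohort,
                 flagged = flagged, flag_multiplier = flag_multiplier,
                 gene_labels = panel$gene_labels),
            class = "gene_ratio_result")
}

#' @export
print.gene_ratio_result <- function(x, ...) {
  cat(sprintf("gene_ratio_result: %s/%s, %d sample(s)\n",
              x$gene_labels[1], x$gene_labels[2], length(x$global)))
  df <- data.frame(global = round(x$global, 4),
                   flagged = x$flagged)
  print(df)
  invisible(x)
}
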