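#' Bundle confirmed-normal reference peak sets
#'
#' A reference profile holds one calibrated peak set per plex from a
#' sample (or pool of samples) previously confirmed copy-number-normal
#' by an orthogonal dosage assay (a "true negative CNV" reference).
#' Every amplicon of every covered plex must have been detected: a
#' reference with dropouts cannot anchor normalization.
#'
#' @param peaksets List of [assign_amplicons()] results, one per plex.
#' @param note Free-text provenance (which samples, which assay
#'   confirmed them).
#' @return An object of class `reference_profile`.
#' @export
reference_profile <- function(peaksets, note = "") {
  if (inherits(peaksets, "calibrated_peakset")) peaksets <- list(peaksets)
  ok <- vapply(peaksets, inherits, logical(1), "calibrated_peakset")
  if (!all(ok)) stop("`peaksets` must be calibrated_peakset objects",
                     call. = FALSE)
  plex_ids <- vapply(peaksets, function(p) p$plex_id, character(1))
  if (anyDuplicated(plex_ids) > 0L) {
    stop("duplicate plex in reference profile", call. = FALSE)
  }
  for (ps in peaksets) {
    miss <- ps$assignments$amplicon_id[ps$assignments$status == "MISSING"]
    if (length(miss) > 0L) {
      stop("reference profile has MISSING amplicon(s) in plex ",
           ps$plex_id, ": ", paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  names(peaksets) <- plex_ids
  structure(list(peaksets = peaksets, note = note),
            class = "reference_profile")
}

#' Pool several confirmed-normal peak sets into one reference
#'
#' Per-amplicon median peak height across the supplied peak sets of one
#' plex; positions are averaged.  Pooling several negatives damps
#' sample-specific amplification wobble in the baseline.
#'
#' @param peaksets List of [assign_amplicons()] results for the *same*
#'   plex.
#' @return A single pooled `calibrated_peakset`.
#' @export
pool_reference_peaksets <- function(peaksets) {
  stopifnot(length(peaksets) >= 1L)
  plex <- unique(vapply(peaksets, function(p) p$plex_id, character(1)))
  if (length(plex) != 1L) {
    stop("all peak sets must come from the same plex", call. = FALSE)
  }
  base <- peaksets[[1]]$assignments
  hmat <- vapply(peaksets, function(p) {
    p$assignments$height[match(base$amplicon_id, p$assignments$amplicon_id)]
  }, numeric(nrow(base)))
  bmat <- vapply(peaksets, function(p) {
    p$assignments$bp[match(base$amplicon_id, p$assignments$amplicon_id)]
  }, numeric(nrow(base)))
  hmat <- matrix(hmat, nrow = nrow(base))
  bmat <- matrix(bmat, nrow = nrow(base))
  out <- base
  out$height <- apply(hmat, 1, stats::median, na.rm = TRUE)
  out$bp <- rowMeans(bmat, na.rm = TRUE)
  out$status <- ifelse(is.finite(out$height), "OK", "MISSING")
  structure(list(sample_id = "pooled_reference", plex_id = plex,
                 assignments = out,
                 unexpected_peaks = peaksets[[1]]$unexpected_peaks[0, ]),
            class = "calibrated_peakset")
}

#' Cross-gene peak-height normalization against the reference
#'
#' The core fragment-analysis comparison.  One gene is chosen as the
#' normalization anchor: the scaling factor is the *median* over the
#' anchor gene's amplicons of (reference height / sample height), and
#' every amplicon's ratio is then
#' `scale * sample_height / reference_height`.  Anchor-gene amplicons
#' therefore center on 1.0 by construction, and a true copy-number
#' change in the *other* gene shows up directly in its ratios.  The
#' median anchor is robust to a minority of CNV-affected amplicons
#' within the anchor gene itself.
#'
#' Because the anchor is internal to the sample, a whole-gene event is
#' fundamentally ambiguous at this stage: halving of every GENE2 ratio
#' under a GENE1 anchor is algebraically indistinguishable from a
#' doubling of GENE1 against a GENE2 anchor.  See [detect_ambiguity()].
#'
#' @param sample A [assign_amplicons()] peak set for one plex.
#' @param reference A [reference_profile()] covering that plex (or a
#'   single `calibrated_peakset`).
#' @param panel The [panel_design()].
#' @param ref_gene Which of the two gene labels anchors the scaling.
#' @return An object of class `normalized_profile` with fields
#'   `sample_id`, `plex_id`, `ref_gene`, `scale`, `ratios` (named
#'   numeric, `NA` for MISSING amplicons) and `flags` (filled by
#'   [collect_out_of_range()], initially `NULL`).
#' @export
normalize_by_reference_gene <- function(sample, reference, panel, ref_gene) {
  validate_panel(panel)
  stopifnot(inherits(sample, "calibrated_peakset"))
  if (inherits(reference, "calibrated_peakset")) {
    reference <- reference_profile(list(reference))
  }
  stopifnot(inherits(reference, "reference_profile"))
  if (!ref_gene %in% panel$gene_labels) {
    stop("`ref_gene` must be one of: ",
         paste(panel$gene_labels, collapse = ", "), call. = FALSE)
  }
  ref_ps <- reference$peaksets[[sample$plex_id]]
  if (is.null(ref_ps)) {
    stop("reference profile does not cover plex ", sample$plex_id,
         call. = FALSE)
  }
  s <- sample$assignments
  r <- ref_ps$assignments
  r <- r[match(s$amplicon_id, r$amplicon_id), ]
  ok <- s$status == "OK"
  anchor <- ok & s$gene == ref_gene
  if (!any(anchor)) {
    stop("no normalization anchor: every ", ref_gene,
         " amplicon is MISSING in sample ", sample$sample_id,
         call. = FALSE)
  }
  scale <- stats::median(r$height[anchor] / s$height[anchor])
  ratios <- rep(NA_real_, nrow(s))
  ratios[ok] <- scale * s$height[ok] / r$height[ok]
  names(ratios) <- s$amplicon_id
  structure(list(sample_id = sample$sample_id, plex_id = sample$plex_id,
                 ref_gene = ref_gene, scale = scale, ratios = ratios,
                 genes = stats::setNames(s$gene, s$amplicon_id),
                 flags = NULL),
            class = "normalized_profile")
}

#' Flag out-of-range amplicon ratios
#'
#' Classifies each ratio against a closed normal range: `ratio < low`
#' is `LOW`, `ratio > high` is `HIGH`, boundary values are `IN_RANGE`;
#' amplicons missing from the sample are `MISSING`.  The default
#' 0.7-1.3 gate is the normal range used for MLPA relative peak
#' ratios, reused here for peak-height ratios.
#'
#' @param profile A [normalize_by_reference_gene()] result.
#' @param low,high Normal-range bounds, `0 < low < high`.
#' @return The profile with its `flags` field set (named character
#'   vector over amplicon ids).
#' @export
collect_out_of_range <- function(profile, low = 0.7, high = 1.3) {
  stopifnot(inherits(profile, "normalized_profile"))
  if (!(low > 0 && low < high)) {
    stop("need 0 < low < high", call. = FALSE)
  }
  r <- profile$ratios
  flags <- ifelse(is.na(r), "MISSING",
                  ifelse(r < low, "LOW",
                         ifelse(r > high, "HIGH", "IN_RANGE")))
  names(flags) <- names(r)
  profile$flags <- flags
  profile$range <- c(low = low, high = high)
  profile
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf(
    "normalized_profile: sample %s, plex %s, anchor %s (scale %.4g)\n",
    x$sample_id, x$plex_id, x$ref_gene, x$scale))
  if (!is.null(x$flags)) {
    oor <- names(x$flags)[!x$flags %in% "IN_RANGE"]
    if (length(oor)) cat("  out-of-range/missing:",
                         paste(oor, collapse = ", "), "\n")
    else cat("  all amplicons in range\n")
  }
  invisible(x)
}

#' Full fragment-analysis report over both normalizations
#'
#' Runs [normalize_by_reference_gene()] under *both* anchor-gene
#' choices for every supplied plex, gates the ratios, and assembles a
#' combined flag table.  Column naming: `ratio_g1norm`/`flag_g1norm`
#' refer to normalization anchored on the panel's first gene label,
#' `*_g2norm` on the second.
#'
#' @param sample_peaksets List of [assign_amplicons()] results (one per
#'   plex) for the test sample.
#' @param reference A [reference_profile()] covering those plexes.
#' @param panel The [panel_design()].
#' @param low,high Ratio gate (defaults 0.7 / 1.3).
#' @return An object of class `fa_report`: list with `table` (one row
#'   per amplicon) and `profiles` (the underlying normalized profiles).
#' @export
fa_report <- function(sample_peaksets, reference, panel,
                      low = 0.7, high = 1.3) {
  validate_panel(panel)
  if (inherits(sample_peaksets, "calibrated_peakset")) {
    sample_peaksets <- list(sample_peaksets)
  }
  g1 <- panel$gene_labels[1]
  g2 <- panel$gene_labels[2]
  profiles <- list()
  rows <- lapply(sample_peaksets, function(ps) {
    p1 <- collect_out_of_range(
      normalize_by_reference_gene(ps, reference, panel, g1), low, high)
    p2 <- collect_out_of_range(
      normalize_by_reference_gene(ps, reference, panel, g2), low, high)
    profiles[[ps$plex_id]] <<- list(g1norm = p1, g2norm = p2)
    data.frame(sample_id = ps$sample_id,
               plex_id = ps$plex_id,
               amplicon_id = names(p1$ratios),
               gene = unname(p1$genes),
               ratio_g1norm = unname(p1$ratios),
               flag_g1norm = unname(p1$flags),
               ratio_g2norm = unname(p2$ratios),
               flag_g2norm = unname(p2$flags),
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows), profiles = profiles,
                 range = c(low = low, high = high),
                 gene_labels = panel$gene_labels),
            class = "fa_report")
}

#' Write an FA report as TSV + JSON summary
#'
#' @param report An [fa_report()].
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_fa_report <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "fa_report"))
  if (!is.null(tsv_path)) {
    utils::write.table(report$table, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    tab <- report$table
    oor <- tab[tab$flag_g1norm != "IN_RANGE" | tab$flag_g2norm != "IN_RANGE",
               c("plex_id", "amplicon_id", "gene", "ratio_g1norm",
                 "flag_g1norm", "ratio_g2norm", "flag_g2norm")]
    jsonlite::write_json(
      list(range = as.list(report$range),
           gene_labels = report$gene_labels,
           n_amplicons = nrow(tab),
           out_of_range = oor),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' Overlay sample and reference electropherograms on a bp axis
#'
#' Converts both traces to base pairs through their calibrations,
#' resamples them on a common bp grid, and draws the sample (red) over
#' the reference (blue) with amplicon labels; out-of-range amplicons
#' are starred.  Returns the aligned curve table alongside the plot.
#'
#' @param sample_trace,reference_trace [raw_trace()] objects.
#' @param sample_fit,reference_fit Their [fit_size_standard()]
#'   calibrations.
#' @param panel A [panel_design()].
#' @param plex_id Plex shown.
#' @param channel Sample channel name in both traces.
#' @param flagged Character vector of amplicon ids to star (e.g. the
#'   out-of-range set from [collect_out_of_range()]).
#' @param file Optional output image path (png/pdf by extension).
#' @param grid_step bp spacing of the resampling grid.
#' @return List with `plot` (a ggplot) and `curves` (data.frame `bp`,
#'   `sample`, `reference`).
#' @export
overlay_curves <- function(sample_trace, reference_trace,
                           sample_fit, reference_fit,
                           panel, plex_id, channel = "sample",
                           flagged = character(0), file = NULL,
                           grid_step = 0.25) {
  stopifnot(inherits(sample_trace, "raw_trace"),
            inherits(reference_trace, "raw_trace"))
  if (!inherits(sample_fit, "calibration_fit") ||
      !inherits(reference_fit, "calibration_fit")) {
    stop("both traces must come with a valid scan-to-bp calibration",
         call. = FALSE)
  }
  bp_axis <- function(trace, fit) {
    y <- trace$channels[[channel]]
    fit$slope * seq_along(y) + fit$intercept
  }
  sx <- bp_axis(sample_trace, sample_fit)
  rx <- bp_axis(reference_trace, reference_fit)
  sy <- sample_trace$channels[[channel]]
  ry <- reference_trace$channels[[channel]]
  lo <- max(min(sx), min(rx))
  hi <- min(max(sx), max(rx))
  grid <- seq(lo, hi, by = grid_step)
  curves <- data.frame(
    bp = grid,
    sample = stats::approx(sx, sy, xout = grid)$y,
    reference = stats::approx(rx, ry, xout = grid)$y)
  amp <- plex_amplicons(panel, plex_id)
  amp$label <- ifelse(amp$id %in% flagged, paste0(amp$id, " *"), amp$id)
  label_y <- max(curves$sample, curves$reference, na.rm = TRUE) * 1.05
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = bp)) +
    ggplot2::geom_line(ggplot2::aes(y = reference),
                       colour = "blue", linewidth = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = sample),
                       colour = "red", linewidth = 0.4) +
    ggplot2::annotate("text", x = amp$expected_length_bp, y = label_y,
                      label = amp$label, angle = 90, size = 2.2,
                      hjust = 0) +
    ggplot2::labs(x = "fragment size (bp)", y = "fluorescence",
                  title = sprintf("plex %s: sample (red) vs reference (blue)",
                                  plex_id)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 10, height = 4, dpi = 150)
  }
  list(plot = p, curves = curves)
}
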