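#' Construct a dosage probe panel
#'
#' A probe panel for an MLPA- or MAQ-style dosage assay: TARGET probes
#' interrogate exons of the two genes, REFERENCE probes lie outside
#' both genes and anchor the intra-sample normalization.  At least two
#' REFERENCE probes are required.
#'
#' @param probes Data.frame with columns `id`, `role`
#'   (`TARGET`/`REFERENCE`), `gene` (`NA` for REFERENCE), `exon_label`,
#'   `expected_length_bp`.
#' @return An object of class `probe_panel`.
#' @export
probe_panel <- function(probes) {
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  need <- c("id", "role", "gene", "exon_label", "expected_length_bp")
  for (col in setdiff(need, names(probes))) probes[[col]] <- NA
  probes <- probes[, need]
  if (anyDuplicated(probes$id) > 0L) {
    stop("duplicate probe id(s)", call. = FALSE)
  }
  if (!all(probes$role %in% c("TARGET", "REFERENCE"))) {
    stop("probe role must be TARGET or REFERENCE", call. = FALSE)
  }
  if (sum(probes$role == "REFERENCE") < 2L) {
    stop("probe panel needs >= 2 REFERENCE probes", call. = FALSE)
  }
  if (any(probes$role == "TARGET" & is.na(probes$gene))) {
    stop("every TARGET probe must carry a gene label", call. = FALSE)
  }
  structure(probes, class = c("probe_panel", "data.frame"))
}

#' Bundled default dosage probe panels
#'
#' Two synthetic probe layouts mirroring the two orthogonal dosage
#' assays used to confirm CNV screening results:
#' * `"maq"` -- a multiplex-amplicon-quantification style panel: 10
#'   target amplicons per gene plus 6 reference amplicons;
#' * `"mlpa"` -- an MLPA-style panel with one probe per exon (24 for
#'   gene 1, 27 for gene 2, the BRCA1/BRCA2 exon counts) plus 12
#'   reference probes.
#'
#' Probe ids and stuffer lengths are synthetic placeholders (commercial
#' kit layouts are proprietary); lengths ascend in steps of 9 bp within
#' the 130-600 bp capillary-electrophoresis window.
#'
#' @param style `"maq"` or `"mlpa"`.
#' @param gene_labels Two gene labels (defaults BRCA1/BRCA2).
#' @return A [probe_panel()].
#' @export
default_probe_panel <- function(style = c("maq", "mlpa"),
                                gene_labels = c("BRCA1", "BRCA2")) {
  style <- match.arg(style)
  n <- switch(style, maq = c(10L, 10L, 6L), mlpa = c(24L, 27L, 12L))
  mk <- function(prefix, count, role, gene) {
    data.frame(id = paste0(prefix, "_", seq_len(count)),
               role = role, gene = gene,
               exon_label = if (role == "TARGET") {
                 paste0(gene, " exon ", seq_len(count))
               } else NA_character_,
               stringsAsFactors = FALSE)
  }
  tag <- toupper(style)
  df <- rbind(
    mk(paste0(tag, "_", gene_labels[1]), n[1], "TARGET", gene_labels[1]),
    mk(paste0(tag, "_", gene_labels[2]), n[2], "TARGET", gene_labels[2]),
    mk(paste0(tag, "_REF"), n[3], "REFERENCE", NA_character_))
  df$expected_length_bp <- 130 + 9 * (seq_len(nrow(df)) - 1)
  probe_panel(df)
}

#' Assemble a dosage run
#'
#' One test sample and at least three control samples, all measured
#' over the same probe set.  Control heights must be strictly
#' positive; a zero/missing TARGET height in the *test* sample is
#' legitimate (homozygous deletion) and propagates to a dosage
#' quotient of 0, but zero REFERENCE heights are an error.
#'
#' @param probes A [probe_panel()].
#' @param test Named numeric vector of the test sample's peak heights
#'   (names = probe ids).
#' @param controls Numeric matrix, controls x probes (column names =
#'   probe ids), `>= 3` rows.
#' @param test_id,control_ids Sample identifiers.
#' @return An object of class `dosage_run`.
#' @export
dosage_run <- function(probes, test, controls, test_id = "test",
                       control_ids = rownames(controls)) {
  stopifnot(inherits(probes, "probe_panel"))
  ids <- probes$id
  if (!all(ids %in% names(test))) {
    stop("test sample does not cover every probe", call. = FALSE)
  }
  if (!all(ids %in% colnames(controls))) {
    stop("control samples do not cover every probe", call. = FALSE)
  }
  if (nrow(controls) < 3L) {
    stop("dosage run needs >= 3 control samples", call. = FALSE)
  }
  test <- test[ids]
  controls <- controls[, ids, drop = FALSE]
  if (is.null(control_ids)) control_ids <- paste0("control_", seq_len(nrow(controls)))
  rownames(controls) <- control_ids
  ref <- ids[probes$role == "REFERENCE"]
  bad_ctrl <- apply(controls <= 0 | !is.finite(controls), 1, any)
  if (any(bad_ctrl)) {
    stop("zero or missing peak height in control sample(s): ",
         paste(control_ids[bad_ctrl], collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(test[ref]) | test[ref] <= 0)) {
    stop("zero or missing REFERENCE-probe height in test sample ", test_id,
         call. = FALSE)
  }
  test[!is.finite(test)] <- 0
  structure(list(probes = probes, test = test, controls = controls,
                 test_id = test_id),
            class = "dosage_run")
}

#' Read a dosage run from a long peak table
#'
#' Expects columns `sample`, `probe`, `height`; the test sample is
#' named via `test_id`, all other samples are controls.
#'
#' @param path Delimited text file.
#' @param probes A [probe_panel()].
#' @param test_id Which `sample` value is the test sample.
#' @return A [dosage_run()].
#' @export
read_dosage_peaks <- function(path, probes, test_id) {
  if (!file.exists(path)) stop("peak file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "probe", "height") %in% names(df))) {
    stop("dosage peak file must have columns sample, probe, height",
         call. = FALSE)
  }
  if (!test_id %in% df$sample) {
    stop("test sample ", test_id, " not present in peak table",
         call. = FALSE)
  }
  wide <- stats::xtabs(height ~ sample + probe, data = df)
  m <- matrix(as.numeric(wide), nrow = nrow(wide),
              dimnames = unname(dimnames(wide)))
  test <- m[test_id, ]
  ctrl <- m[setdiff(rownames(m), test_id), , drop = FALSE]
  dosage_run(probes, test, ctrl, test_id = test_id)
}

#' Write a dosage run as a long peak table
#'
#' @param run A [dosage_run()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dosage_peaks <- function(run, path) {
  stopifnot(inherits(run, "dosage_run"))
  long <- rbind(
    data.frame(sample = run$test_id, probe = names(run$test),
               height = unname(run$test)),
    do.call(rbind, lapply(rownames(run$controls), function(cid) {
      data.frame(sample = cid, probe = colnames(run$controls),
                 height = unname(run$controls[cid, ]))
    })))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Dosage quotients (DQ / relative peak ratios)
#'
#' The standard double normalization shared by MAQ dosage quotients
#' and MLPA relative peak ratios.  Within each sample s, every probe
#' height is divided by the aggregate (median by default) of that
#' sample's REFERENCE-probe heights, giving v(s, p); the dosage
#' quotient of probe p is then v(test, p) divided by the aggregate of
#' v(c, p) over the control samples c.  Under the proportional copy-
#' number model, dq = CN/2 against diploid controls: 1.0 for two
#' copies, 0.5 for a heterozygous deletion, 1.5 for a three-copy
#' duplication, 0 for a homozygous deletion (absent test peak).
#'
#' @param run A [dosage_run()].
#' @param aggregate `"median"` (default, robust to an aberrant
#'   reference probe or control) or `"mean"` (for comparison with
#'   software that averages).
#' @return An object of class `dosage_result`: data.frame rows for
#'   TARGET probes (`probe_id`, `gene`, `exon_label`, `dq`), fields
#'   accessible via `$table`; classification added by [classify_dq()].
#' @export
compute_dq <- function(run, aggregate = c("median", "mean")) {
  stopifnot(inherits(run, "dosage_run"))
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "median") stats::median else mean
  probes <- run$probes
  ref <- probes$id[probes$role == "REFERENCE"]
  v_test <- run$test / agg(run$test[ref])
  ref_ctrl <- apply(run$controls[, ref, drop = FALSE], 1, agg)
  v_ctrl <- sweep(run$controls, 1, ref_ctrl, "/")
  baseline <- apply(v_ctrl, 2, agg)
  dq <- v_test / baseline
  tgt <- probes[probes$role == "TARGET", , drop = FALSE]
  table <- data.frame(probe_id = tgt$id, gene = tgt$gene,
                      exon_label = tgt$exon_label,
                      dq = unname(dq[tgt$id]),
                      stringsAsFactors = FALSE)
  structure(list(table = table, test_id = run$test_id,
                 n_controls = nrow(run$controls), aggregate = aggregate,
                 range = NULL, gene_summary = NULL),
            class = "dosage_result")
}

#' Classify dosage quotients against the normal range
#'
#' Closed-interval gate, default 0.7-1.3 (the MLPA normal range):
#' `dq < low` is `DELETED`, `dq > high` is `DUPLICATED`, boundary
#' values are `NORMAL`.  The per-gene summary is `WHOLE_LOSS` when
#' every probe of a gene is `DELETED`, `WHOLE_GAIN` when every probe
#' is `DUPLICATED`, `NORMAL` when all are `NORMAL`, otherwise
#' `PARTIAL_LOSS`/`PARTIAL_GAIN`/`MIXED` by which aberrations occur.
#'
#' @param result A [compute_dq()] result.
#' @param low,high Normal-range bounds, `0 < low < high`.
#' @return The `dosage_result` with `classification` column, `range`,
#'   and `gene_summary` filled in.
#' @export
classify_dq <- function(result, low = 0.7, high = 1.3) {
  stopifnot(inherits(result, "dosage_result"))
  if (!(low > 0 && low < high)) stop("need 0 < low < high", call. = FALSE)
  tab <- result$table
  tab$classification <- ifelse(tab$dq < low, "DELETED",
                               ifelse(tab$dq > high, "DUPLICATED",
                                      "NORMAL"))
  genes <- unique(tab$gene)
  gene_summary <- stats::setNames(vapply(genes, function(g) {
    cls <- tab$classification[tab$gene == g]
    if (all(cls == "DELETED")) "WHOLE_LOSS"
    else if (all(cls == "DUPLICATED")) "WHOLE_GAIN"
    else if (all(cls == "NORMAL")) "NORMAL"
    else if (any(cls == "DELETED") && !any(cls == "DUPLICATED")) "PARTIAL_LOSS"
    else if (any(cls == "DUPLICATED") && !any(cls == "DELETED")) "PARTIAL_GAIN"
    else "MIXED"
  }, character(1)), genes)
  result$table <- tab
  result$range <- c(low = low, high = high)
  result$gene_summary <- gene_summary
  result
}

#' @export
print.dosage_result <- function(x, ...) {
  cat(sprintf("dosage_result: test %s vs %d controls (%s aggregation)\n",
              x$test_id, x$n_controls, x$aggregate))
  if (!is.null(x$gene_summary)) {
    for (g in names(x$gene_summary)) {
      cat(sprintf("  %s: %s\n", g, x$gene_summary[g]))
    }
  }
  invisible(x)
}

#' Write a dosage result as TSV + JSON
#'
#' @param result A (classified) `dosage_result`.
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the result.
#' @export
write_dosage_result <- function(result, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "dosage_result"))
  if (!is.null(tsv_path)) {
    utils::write.table(result$table, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(test_id = result$test_id, n_controls = result$n_controls,
           aggregate = result$aggregate,
           range = if (is.null(result$range)) NULL else as.list(result$range),
           gene_summary = if (is.null(result$gene_summary)) NULL else
             as.list(result$gene_summary),
           probes = result$table),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}

#' Per-probe dosage plot with normal-range band
#'
#' Dot plot of dosage quotients in probe order with the normal range
#' shaded, the visual layout of MLPA/MAQ dosage reports.
#'
#' @param result A classified `dosage_result`.
#' @param file Optional output image path.
#' @return A ggplot object, invisibly if written to `file`.
#' @export
plot_dosage <- function(result, file = NULL) {
  stopifnot(inherits(result, "dosage_result"))
  tab <- result$table
  if (is.null(tab$classification)) {
    stop("classify the result first (classify_dq)", call. = FALSE)
  }
  tab$probe_id <- factor(tab$probe_id, levels = tab$probe_id)
  rng <- result$range
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = probe_id, y = dq,
                                         colour = gene)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = rng["low"], ymax = rng["high"],
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = "dosage quotient",
                  title = sprintf("Dosage quotients: %s (normal range %.1f-%.1f)",
                                  result$test_id, rng["low"], rng["high"])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 9, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}
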