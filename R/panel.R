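#' Genomic interval
#'
#' A 1-based genomic interval.  Throughout the package the length of an
#' interval is computed as `end - start` (see [genomic_span()]), the
#' convention used by diagnostic reports that quote a deletion of
#' 2664 bp spanning chr17:41256109-41258773.
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 1-based start position.
#' @param end 1-based end position, `end >= start`.
#' @return An object of class `genomic_interval`.
#' @examples
#' iv <- genomic_interval("chr17", 41256109, 41258773)
#' genomic_span(iv)  # 2664
#' @export
genomic_interval <- function(chrom, start, end) {
  if (!is.character(chrom) || length(chrom) != 1L || is.na(chrom) ||
      !nzchar(chrom)) {
    stop("`chrom` must be a non-empty string", call. = FALSE)
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end)) {
    stop("`start` and `end` must be single positions", call. = FALSE)
  }
  if (end < start) {
    stop("`end` must be >= `start`", call. = FALSE)
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' Span of a genomic interval in base pairs
#'
#' Returns `end - start`.  Note that this is the difference of the two
#' coordinates, *not* the 1-based inclusive length `end - start + 1`:
#' the deletion chr17:41256109-41258773 has span 2664 under this
#' convention.
#'
#' @param iv A [genomic_interval()].
#' @return Integer span in bp.
#' @export
genomic_span <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  as.numeric(iv$end - iv$start)
}

#' Construct a panel design
#'
#' A panel design describes a dual-gene multiplex amplicon panel: two
#' gene labels, an ordered set of multiplex reactions ("plexes"), and
#' one row per amplicon.  Cross-gene normalization requires every plex
#' to carry at least one amplicon of each gene; this is enforced here.
#'
#' @param gene_labels Character vector of exactly two gene labels
#'   (order matters: ratios are reported as gene1/gene2).
#' @param plexes Character vector of plex labels.
#' @param amplicons A data.frame with columns `id`, `plex_id`, `gene`,
#'   `expected_length_bp` and optionally `chrom`, `start`, `end`,
#'   `exon_label`.
#' @return An object of class `panel_design`.
#' @export
panel_design <- function(gene_labels, plexes, amplicons) {
  amplicons <- as.data.frame(amplicons, stringsAsFactors = FALSE)
  optional <- c("chrom", "start", "end", "exon_label")
  for (col in optional) {
    if (is.null(amplicons[[col]])) amplicons[[col]] <- NA
  }
  amplicons$expected_length_bp <- as.numeric(amplicons$expected_length_bp)
  amplicons$start <- as.numeric(amplicons$start)
  amplicons$end <- as.numeric(amplicons$end)
  amplicons <- amplicons[, c("id", "plex_id", "gene", "expected_length_bp",
                             "chrom", "start", "end", "exon_label")]
  panel <- structure(
    list(gene_labels = as.character(gene_labels),
         plexes = as.character(plexes),
         amplicons = amplicons),
    class = "panel_design")
  validate_panel(panel)
  panel
}

#' Validate a panel design
#'
#' Checks all structural invariants of a [panel_design()]: exactly two
#' gene labels, unique amplicon ids, known plex and gene labels,
#' positive expected lengths, and both genes represented in every plex.
#'
#' @param panel A `panel_design` object.
#' @return The panel, invisibly, if valid; otherwise an error.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "panel_design"))
  amp <- panel$amplicons
  if (length(panel$gene_labels) != 2L ||
      anyDuplicated(panel$gene_labels) > 0L) {
    stop("panel must define exactly two distinct gene labels", call. = FALSE)
  }
  if (nrow(amp) == 0L) {
    stop("panel defines zero amplicons", call. = FALSE)
  }
  if (anyDuplicated(amp$id) > 0L) {
    dup <- unique(amp$id[duplicated(amp$id)])
    stop("duplicate amplicon id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_gene <- setdiff(unique(amp$gene), panel$gene_labels)
  if (length(bad_gene) > 0L) {
    stop("unknown gene label(s): ", paste(bad_gene, collapse = ", "),
         call. = FALSE)
  }
  bad_plex <- setdiff(unique(amp$plex_id), panel$plexes)
  if (length(bad_plex) > 0L) {
    stop("amplicon assigned to undeclared plex: ",
         paste(bad_plex, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(amp$expected_length_bp)) ||
      any(amp$expected_length_bp <= 0)) {
    stop("expected_length_bp must be positive for every amplicon",
         call. = FALSE)
  }
  for (px in panel$plexes) {
    genes_here <- unique(amp$gene[amp$plex_id == px])
    missing <- setdiff(panel$gene_labels, genes_here)
    if (length(missing) > 0L) {
      stop("plex ", px, " lacks any amplicon of gene ",
           paste(missing, collapse = ", "),
           " (both genes are required in every plex for cross-gene ",
           "normalization)", call. = FALSE)
    }
  }
  has_iv <- !is.na(amp$chrom)
  if (any(has_iv)) {
    iv <- amp[has_iv, ]
    if (any(is.na(iv$start)) || any(is.na(iv$end)) || any(iv$end < iv$start)) {
      stop("amplicon genomic intervals must have end >= start", call. = FALSE)
    }
  }
  invisible(panel)
}

#' @export
print.panel_design <- function(x, ...) {
  cat("panel_design:", paste(x$gene_labels, collapse = " / "), "\n")
  tab <- table(factor(x$amplicons$plex_id, levels = x$plexes))
  cat(" ", nrow(x$amplicons), "amplicons in", length(x$plexes), "plexes (",
      paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Load a panel design from a YAML config file
#'
#' The config schema is a YAML mapping with keys `gene_labels` (list of
#' two), `plexes` (list), and `amplicons` (list of records with fields
#' `id`, `plex`, `gene`, `expected_length_bp` and optional `chrom`,
#' `start`, `end`, `exon`).  The bundled default panel file is at
#' `system.file("extdata", "default_panel_synthetic.yaml",
#' package = "ampliCNV")`.
#'
#' @param path Path to the YAML panel file.
#' @return A validated [panel_design()].
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (key in c("gene_labels", "plexes", "amplicons")) {
    if (is.null(cfg[[key]])) {
      stop("panel config is missing required key `", key, "`", call. = FALSE)
    }
  }
  grab <- function(rec, field, default = NA) {
    if (is.null(rec[[field]])) default else rec[[field]]
  }
  amp <- do.call(rbind, lapply(cfg$amplicons, function(rec) {
    data.frame(id = as.character(grab(rec, "id")),
               plex_id = as.character(grab(rec, "plex")),
               gene = as.character(grab(rec, "gene")),
               expected_length_bp = as.numeric(grab(rec, "expected_length_bp")),
               chrom = as.character(grab(rec, "chrom")),
               start = as.numeric(grab(rec, "start")),
               end = as.numeric(grab(rec, "end")),
               exon_label = as.character(grab(rec, "exon")),
               stringsAsFactors = FALSE)
  }))
  if (is.null(amp)) stop("panel defines zero amplicons", call. = FALSE)
  panel_design(gene_labels = unlist(cfg$gene_labels),
               plexes = unlist(cfg$plexes),
               amplicons = amp)
}

#' Serialize a panel design to YAML
#'
#' Writes the schema consumed by [load_panel()]; `load_panel(write_panel(p))`
#' is the identity on valid panels.
#'
#' @param panel A [panel_design()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  amp <- panel$amplicons
  as_plain <- function(x) {
    # keep whole numbers integral so YAML never switches to scientific
    if (is.finite(x) && x == round(x) && abs(x) < .Machine$integer.max) {
      as.integer(x)
    } else {
      x
    }
  }
  recs <- lapply(seq_len(nrow(amp)), function(i) {
    rec <- list(id = amp$id[i], plex = amp$plex_id[i], gene = amp$gene[i],
                expected_length_bp = as_plain(amp$expected_length_bp[i]))
    if (!is.na(amp$chrom[i])) {
      rec$chrom <- amp$chrom[i]
      rec$start <- as_plain(amp$start[i])
      rec$end <- as_plain(amp$end[i])
    }
    if (!is.na(amp$exon_label[i])) rec$exon <- amp$exon_label[i]
    rec
  })
  yaml::write_yaml(list(gene_labels = as.list(panel$gene_labels),
                        plexes = as.list(panel$plexes),
                        amplicons = recs), path)
  invisible(path)
}

#' Export amplicon intervals as BED
#'
#' Amplicons carrying a genomic interval are written in BED format.
#' The panel stores 1-based coordinates; BED is 0-based half-open, so
#' `chromStart = start - 1` and `chromEnd = end` on export.
#'
#' @param panel A [panel_design()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  validate_panel(panel)
  amp <- panel$amplicons
  amp <- amp[!is.na(amp$chrom), , drop = FALSE]
  if (nrow(amp) == 0L) stop("no amplicon carries a genomic interval",
                            call. = FALSE)
  bed <- data.frame(chrom = amp$chrom,
                    start = format(amp$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(amp$end, scientific = FALSE, trim = TRUE),
                    name = amp$id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' The bundled default dual-gene panel
#'
#' A BRCA1/BRCA2 panel of 93 amplicons over five plexes
#' (A: 17, B: 20, C: 19, D: 18, E: 19), the layout of a commercial
#' dual-gene amplicon screening kit.  Exact fragment sizes and primer
#' coordinates of commercial kits are proprietary, so the bundled sizes
#' and intervals are synthetic placeholders: sizes are spaced >= 6 bp
#' within each plex (comfortably above the 2 bp match tolerance) and
#' intervals tile the GRCh37 BRCA1 (chr17) and BRCA2 (chr13) loci.
#' Amplicons referenced in published normalized-profile figures
#' (D_9, D_10, C_6 on BRCA1; A_2, A_3, A_6a BRCA1 and A_4, A_5, A_6b
#' BRCA2) keep those ids and gene assignments.
#'
#' @return A [panel_design()].
#' @export
default_panel <- function() {
  path <- system.file("extdata", "default_panel_synthetic.yaml",
                      package = "ampliCNV")
  if (!nzchar(path)) stop("bundled panel file not found", call. = FALSE)
  load_panel(path)
}

#' Amplicons of one plex, in panel order
#'
#' @param panel A [panel_design()].
#' @param plex_id A plex label of the panel.
#' @return The amplicon data.frame subset to `plex_id`.
#' @export
plex_amplicons <- function(panel, plex_id) {
  stopifnot(inherits(panel, "panel_design"))
  if (!plex_id %in% panel$plexes) {
    stop("unknown plex: ", plex_id, call. = FALSE)
  }
  panel$amplicons[panel$amplicons$plex_id == plex_id, , drop = FALSE]
}
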