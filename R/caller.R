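FA_FLAGS <- c("LOW", "IN_RANGE", "HIGH", "MISSING")
RC_FLAGS <- c("LOW", "IN_CI", "HIGH", "MISSING")

#' The default evidence-integration truth table
#'
#' Explicit, versioned mapping from the three evidence flags of an
#' amplicon to its CNV state.  For an amplicon of gene g, `cross` is
#' its FA flag under the *other* gene's normalization (where a real
#' copy-number change in g is visible), `own` its flag under g's own
#' normalization (which centers g on 1.0 and so should stay in range
#' for whole-gene events, or agree for partial ones), and `rc` the
#' read-count CI99 flag.
#'
#' Default (conservative) rules:
#' * `cross == LOW`  and `own` in (LOW, IN_RANGE) and `rc` in
#'   (LOW, MISSING)  -> `LOSS`
#' * `cross == HIGH` and `own` in (HIGH, IN_RANGE) and `rc` in
#'   (HIGH, MISSING) -> `GAIN`
#' * all of `cross`, `own` in range and `rc` in (IN_CI, MISSING)
#'   -> `NEUTRAL`
#' * any FA flag `MISSING`, or any contradictory combination
#'   -> `NO_CALL`
#'
#' Laboratories can tune the table: it is plain data with one row per
#' (cross, own, rc) combination and may be edited and passed back into
#' [classify_amplicon()].
#'
#' @return Data.frame with columns `cross`, `own`, `rc`, `state` and
#'   attribute `version`.
#' @export
default_truth_table <- function() {
  grid <- expand.grid(cross = FA_FLAGS, own = FA_FLAGS, rc = RC_FLAGS,
                      stringsAsFactors = FALSE)
  state <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cr <- grid$cross[i]; ow <- grid$own[i]; rc <- grid$rc[i]
    state[i] <-
      if (cr == "MISSING" || ow == "MISSING") "NO_CALL"
      else if (cr == "LOW" && ow %in% c("LOW", "IN_RANGE") &&
               rc %in% c("LOW", "MISSING")) "LOSS"
      else if (cr == "HIGH" && ow %in% c("HIGH", "IN_RANGE") &&
               rc %in% c("HIGH", "MISSING")) "GAIN"
      else if (cr == "IN_RANGE" && ow == "IN_RANGE" &&
               rc %in% c("IN_CI", "MISSING")) "NEUTRAL"
      else "NO_CALL"
  }
  grid$state <- state
  attr(grid, "version") <- "default-1"
  grid
}

#' Classify one amplicon from its evidence flags
#'
#' @param fa_flag_g1norm,fa_flag_g2norm FA flags of this amplicon under
#'   the gene-1-anchored and gene-2-anchored normalizations
#'   (`LOW`/`IN_RANGE`/`HIGH`/`MISSING`).
#' @param rc_flag Read-count flag (`LOW`/`IN_CI`/`HIGH`), or `MISSING`
#'   when no read-count evidence is available.
#' @param gene The amplicon's gene.
#' @param gene_labels The panel's two gene labels (ordered).
#' @param truth_table Integration table, see [default_truth_table()].
#' @return One of `LOSS`, `NEUTRAL`, `GAIN`, `NO_CALL`.
#' @export
classify_amplicon <- function(fa_flag_g1norm, fa_flag_g2norm,
                              rc_flag = "MISSING", gene, gene_labels,
                              truth_table = default_truth_table()) {
  if (!fa_flag_g1norm %in% FA_FLAGS || !fa_flag_g2norm %in% FA_FLAGS) {
    stop("unknown FA flag: ",
         paste(setdiff(c(fa_flag_g1norm, fa_flag_g2norm), FA_FLAGS),
               collapse = ", "), call. = FALSE)
  }
  if (!rc_flag %in% RC_FLAGS) {
    stop("unknown RC flag: ", rc_flag, call. = FALSE)
  }
  if (!gene %in% gene_labels) stop("unknown gene: ", gene, call. = FALSE)
  if (gene == gene_labels[1]) {
    cross <- fa_flag_g2norm; own <- fa_flag_g1norm
  } else {
    cross <- fa_flag_g1norm; own <- fa_flag_g2norm
  }
  hit <- truth_table$state[truth_table$cross == cross &
                           truth_table$own == own &
                           truth_table$rc == rc_flag]
  if (length(hit) != 1L) {
    stop("truth table has no unique entry for (", cross, ", ", own, ", ",
         rc_flag, ")", call. = FALSE)
  }
  hit
}

#' Classify every amplicon of an FA report, with optional RC flags
#'
#' @param fa An [fa_report()].
#' @param rc_flags Optional named character vector of read-count flags
#'   from [flag_rc_outliers()]; amplicons absent from it get `MISSING`
#'   RC evidence.
#' @param panel The [panel_design()].
#' @param truth_table See [default_truth_table()].
#' @return Data.frame of per-amplicon calls with the evidence columns
#'   retained (`flag_g1norm`, `flag_g2norm`, `rc_flag`, `state`).
#' @export
classify_calls <- function(fa, rc_flags = NULL, panel,
                           truth_table = default_truth_table()) {
  stopifnot(inherits(fa, "fa_report"))
  tab <- fa$table
  tab$rc_flag <- if (is.null(rc_flags)) "MISSING" else {
    f <- unname(rc_flags[tab$amplicon_id])
    ifelse(is.na(f), "MISSING", f)
  }
  tab$state <- vapply(seq_len(nrow(tab)), function(i) {
    classify_amplicon(tab$flag_g1norm[i], tab$flag_g2norm[i],
                      tab$rc_flag[i], tab$gene[i], panel$gene_labels,
                      truth_table)
  }, character(1))
  tab
}

whole_pattern <- function(states, target, no_call_tol) {
  n <- length(states)
  if (n == 0L) return(FALSE)
  nc <- sum(states == "NO_CALL")
  callable <- states[states != "NO_CALL"]
  length(callable) > 0L && all(callable == target) && nc / n <= no_call_tol
}

#' Gene-level verdict and whole-gene ambiguity detection
#'
#' Aggregates per-amplicon calls into gene-level states.  If every
#' callable amplicon of one gene is `LOSS` while every callable
#' amplicon of the other is `GAIN` (or the mirrored pattern), the two
#' readings are algebraically equivalent under intra-sample cross-gene
#' normalization -- a whole-gene deletion of one gene and a whole-gene
#' duplication of the other predict identical ratio profiles -- so the
#' verdict carries a `WHOLE_GENE_AMBIGUITY` with both rival hypotheses
#' and a recommendation for orthogonal dosage testing (MLPA/MAQ).  A
#' proper subset of one gene's amplicons flagged consistently under
#' both normalizations is an unambiguous `PARTIAL_LOSS`/`PARTIAL_GAIN`.
#'
#' @param calls Per-amplicon call table from [classify_calls()].
#' @param panel The [panel_design()].
#' @param no_call_tol Fraction of `NO_CALL` amplicons tolerated inside
#'   a whole-gene pattern (default 0.1), so isolated dropouts do not
#'   break the rule.
#' @return An object of class `cnv_verdict`: list with `calls`,
#'   `gene_level` (named character), `ambiguity` (`"NONE"` or
#'   `"WHOLE_GENE_AMBIGUITY"`), `hypotheses` (list of rival gene-state
#'   pairs, empty when unambiguous) and `recommendation`.
#' @export
detect_ambiguity <- function(calls, panel, no_call_tol = 0.1) {
  validate_panel(panel)
  ids <- panel$amplicons$id
  if (!all(ids %in% calls$amplicon_id)) {
    stop("calls must cover every panel amplicon", call. = FALSE)
  }
  g1 <- panel$gene_labels[1]
  g2 <- panel$gene_labels[2]
  st <- function(g) calls$state[calls$gene == g]
  gene_level <- stats::setNames(c("NEUTRAL", "NEUTRAL"), c(g1, g2))
  hypotheses <- list()
  ambiguity <- "NONE"
  recommendation <- "No copy-number change detected."

  loss1 <- whole_pattern(st(g1), "LOSS", no_call_tol)
  loss2 <- whole_pattern(st(g2), "LOSS", no_call_tol)
  gain1 <- whole_pattern(st(g1), "GAIN", no_call_tol)
  gain2 <- whole_pattern(st(g2), "GAIN", no_call_tol)

  if ((loss2 && gain1) || (loss1 && gain2)) {
    if (loss2 && gain1) {
      lost <- g2; gained <- g1
    } else {
      lost <- g1; gained <- g2
    }
    gene_level[lost] <- "WHOLE_LOSS"
    gene_level[gained] <- "WHOLE_GAIN"
    ambiguity <- "WHOLE_GENE_AMBIGUITY"
    hypotheses <- list(list(gene = lost, state = "WHOLE_LOSS"),
                       list(gene = gained, state = "WHOLE_GAIN"))
    recommendation <- paste0(
      "Intra-panel evidence cannot distinguish a whole-gene deletion of ",
      lost, " from a whole-gene duplication of ", gained,
      ": the two hypotheses predict identical normalized profiles. ",
      "Orthogonal dosage testing (MLPA/MAQ) is REQUIRED before any ",
      "whole-gene call is reported.")
  } else {
    for (g in c(g1, g2)) {
      sub <- calls[calls$gene == g, , drop = FALSE]
      consistent_loss <- sub$state == "LOSS" &
        sub$flag_g1norm == "LOW" & sub$flag_g2norm == "LOW"
      consistent_gain <- sub$state == "GAIN" &
        sub$flag_g1norm == "HIGH" & sub$flag_g2norm == "HIGH"
      one_sided_loss <- whole_pattern(sub$state, "LOSS", no_call_tol)
      one_sided_gain <- whole_pattern(sub$state, "GAIN", no_call_tol)
      if (any(consistent_loss) || one_sided_loss) {
        gene_level[g] <- "PARTIAL_LOSS"
      } else if (any(consistent_gain) || one_sided_gain) {
        gene_level[g] <- "PARTIAL_GAIN"
      }
    }
    if (any(gene_level != "NEUTRAL")) {
      ev <- gene_level[gene_level != "NEUTRAL"]
      recommendation <- paste0(
        "Partial copy-number event(s) detected (",
        paste(names(ev), ev, sep = ": ", collapse = "; "),
        "); confirmation by an orthogonal dosage assay is recommended.")
    }
  }
  structure(list(calls = calls, gene_level = gene_level,
                 ambiguity = ambiguity, hypotheses = hypotheses,
                 no_call_tol = no_call_tol,
                 recommendation = recommendation),
            class = "cnv_verdict")
}

#' @export
print.cnv_verdict <- function(x, ...) {
  cat("cnv_verdict:\n")
  for (g in names(x$gene_level)) {
    cat(sprintf("  %s: %s\n", g, x$gene_level[g]))
  }
  cat("  ambiguity:", x$ambiguity, "\n")
  cat("  ", x$recommendation, "\n", sep = "")
  invisible(x)
}

#' Resolve a whole-gene ambiguity with dosage evidence
#'
#' The only route to a final whole-gene call.  The rival hypothesis
#' whose prediction matches the per-gene dosage summary (e.g. all
#' gene-2 probes DELETED, gene-1 probes NORMAL selects the gene-2
#' whole-deletion reading) is chosen; if the dosage result contradicts
#' both hypotheses the call stays `UNRESOLVED` with both retained.
#' Intra-panel evidence is never re-weighted to break the tie.
#'
#' @param verdict A [detect_ambiguity()] result.
#' @param dosage A classified [compute_dq()]/[classify_dq()] result.
#' @return An object of class `final_call`: list with `verdict`,
#'   `dosage`, `gene_level` (resolved), `resolution` (one of
#'   `DOSAGE_RESOLVED`, `UNRESOLVED`, `NO_AMBIGUITY`) and `provenance`.
#' @export
resolve_with_dosage <- function(verdict, dosage) {
  stopifnot(inherits(verdict, "cnv_verdict"))
  stopifnot(inherits(dosage, "dosage_result"))
  if (is.null(dosage$gene_summary)) {
    stop("dosage result must be classified first (see classify_dq)",
         call. = FALSE)
  }
  genes <- names(verdict$gene_level)
  covered <- intersect(genes, names(dosage$gene_summary))
  if (verdict$ambiguity == "WHOLE_GENE_AMBIGUITY") {
    hyp_genes <- vapply(verdict$hypotheses, function(h) h$gene, character(1))
    if (!any(hyp_genes %in% covered)) {
      stop("dosage result covers neither gene of the ambiguity",
           call. = FALSE)
    }
    supported <- vapply(verdict$hypotheses, function(h) {
      other <- setdiff(genes, h$gene)
      ok_self <- h$gene %in% covered &&
        dosage$gene_summary[[h$gene]] == h$state
      ok_other <- !(other %in% covered) ||
        dosage$gene_summary[[other]] == "NORMAL"
      ok_self && ok_other
    }, logical(1))
    if (sum(supported) == 1L) {
      h <- verdict$hypotheses[[which(supported)]]
      gene_level <- stats::setNames(rep("NEUTRAL", length(genes)), genes)
      gene_level[h$gene] <- h$state
      resolution <- "DOSAGE_RESOLVED"
      provenance <- sprintf(
        "%s %s selected: dosage assay classified %s probes as %s.",
        h$gene, h$state, h$gene, dosage$gene_summary[[h$gene]])
    } else {
      gene_level <- verdict$gene_level
      resolution <- "UNRESOLVED"
      provenance <- paste(
        "Dosage evidence supports",
        if (sum(supported) == 0L) "neither" else "both",
        "rival hypotheses; whole-gene status remains unresolved.")
    }
  } else {
    gene_level <- verdict$gene_level
    resolution <- "NO_AMBIGUITY"
    agree <- vapply(covered, function(g) {
      ds <- dosage$gene_summary[[g]]
      vl <- verdict$gene_level[[g]]
      (vl == "NEUTRAL" && ds == "NORMAL") ||
        (vl %in% c("PARTIAL_LOSS", "WHOLE_LOSS") &&
           ds %in% c("PARTIAL_LOSS", "WHOLE_LOSS")) ||
        (vl %in% c("PARTIAL_GAIN", "WHOLE_GAIN") &&
           ds %in% c("PARTIAL_GAIN", "WHOLE_GAIN"))
    }, logical(1))
    provenance <- if (length(covered) == 0L) {
      "No dosage evidence supplied; verdict carried forward unchanged."
    } else if (all(agree)) {
      "Dosage assay corroborates the intra-panel verdict."
    } else {
      paste("Dosage assay disagrees with the intra-panel verdict for:",
            paste(covered[!agree], collapse = ", "))
    }
  }
  structure(list(verdict = verdict, dosage = dosage,
                 gene_level = gene_level, resolution = resolution,
                 provenance = provenance),
            class = "final_call")
}

#' @export
print.final_call <- function(x, ...) {
  cat("final_call (", x$resolution, ")\n", sep = "")
  for (g in names(x$gene_level)) {
    cat(sprintf("  %s: %s\n", g, x$gene_level[g]))
  }
  cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Export a verdict or final call as JSON
#'
#' @param x A `cnv_verdict` or `final_call`.
#' @param path Output JSON path.
#' @param extra Named list merged into the document (e.g. seeds,
#'   config echo).
#' @return `path`, invisibly.
#' @export
write_call_json <- function(x, path, extra = list()) {
  doc <- if (inherits(x, "final_call")) {
    list(kind = "final_call",
         resolution = x$resolution,
         gene_level = as.list(x$gene_level),
         provenance = x$provenance,
         ambiguity = x$verdict$ambiguity,
         hypotheses = x$verdict$hypotheses,
         dosage_gene_summary = as.list(x$dosage$gene_summary))
  } else if (inherits(x, "cnv_verdict")) {
    list(kind = "cnv_verdict",
         gene_level = as.list(x$gene_level),
         ambiguity = x$ambiguity,
         hypotheses = x$hypotheses,
         recommendation = x$recommendation,
         calls = x$calls)
  } else {
    stop("`x` must be a cnv_verdict or final_call", call. = FALSE)
  }
  doc$tool_version <- as.character(utils::packageVersion("ampliCNV"))
  doc <- c(doc, extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
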