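# Independent restatement of the documented integration rules, used as
# the enumeration oracle for the default truth table.
oracle_state <- function(cross, own, rc) {
  if (cross == "MISSING" || own == "MISSING") return("NO_CALL")
  if (cross == "LOW" && own != "HIGH" && rc %in% c("LOW", "MISSING")) {
    return("LOSS")
  }
  if (cross == "HIGH" && own != "LOW" && rc %in% c("HIGH", "MISSING")) {
    return("GAIN")
  }
  if (cross == "IN_RANGE" && own == "IN_RANGE" &&
      rc %in% c("IN_CI", "MISSING")) {
    return("NEUTRAL")
  }
  "NO_CALL"
}

test_that("classify_amplicon reproduces the documented examples", {
  gl <- c("G1", "G2")
  expect_equal(classify_amplicon("LOW", "LOW", "LOW", "G1", gl), "LOSS")
  expect_equal(classify_amplicon("LOW", "LOW", "LOW", "G2", gl), "LOSS")
  expect_equal(classify_amplicon("IN_RANGE", "IN_RANGE", "IN_CI", "G1", gl),
               "NEUTRAL")
  expect_equal(classify_amplicon("LOW", "HIGH", "IN_CI", "G1", gl),
               "NO_CALL")
  expect_equal(classify_amplicon("LOW", "HIGH", "IN_CI", "G2", gl),
               "NO_CALL")
  expect_error(classify_amplicon("WAT", "LOW", "LOW", "G1", gl),
               "unknown FA flag")
  expect_error(classify_amplicon("LOW", "LOW", "SIDEWAYS", "G1", gl),
               "unknown RC flag")
})

test_that("the default truth table matches the rule oracle on all combos", {
  gl <- c("G1", "G2")
  fa <- c("LOW", "IN_RANGE", "HIGH")
  rc <- c("LOW", "IN_CI", "HIGH", "MISSING")
  n_checked <- 0L
  for (f1 in fa) for (f2 in fa) for (r in rc) for (g in gl) {
    cross <- if (g == "G1") f2 else f1
    own <- if (g == "G1") f1 else f2
    expect_equal(classify_amplicon(f1, f2, r, g, gl),
                 oracle_state(cross, own, r),
                 info = paste(f1, f2, r, g))
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 72L)  # 36 flag combos x 2 genes
  # FA dropouts are never called
  for (r in rc) {
    expect_equal(classify_amplicon("MISSING", "LOW", r, "G1", gl), "NO_CALL")
    expect_equal(classify_amplicon("LOW", "MISSING", r, "G1", gl), "NO_CALL")
  }
})

test_that("a whole-gene-2 event is reported as the two rival hypotheses", {
  panel <- default_panel()
  cnv <- cnv_whole_gene(panel, "BRCA2", 1L)
  calls <- classify_calls(fa_report_for_cnv(panel, cnv), NULL, panel)
  v <- detect_ambiguity(calls, panel)
  expect_equal(v$ambiguity, "WHOLE_GENE_AMBIGUITY")
  expect_equal(unname(v$gene_level["BRCA2"]), "WHOLE_LOSS")
  expect_equal(unname(v$gene_level["BRCA1"]), "WHOLE_GAIN")
  hyp <- lapply(v$hypotheses, function(h) paste(h$gene, h$state))
  expect_setequal(unlist(hyp), c("BRCA2 WHOLE_LOSS", "BRCA1 WHOLE_GAIN"))
  expect_match(v$recommendation, "MLPA/MAQ")
})

test_that("the exon 5-7 partial deletion is unambiguous", {
  panel <- default_panel()
  cnv <- cnv_spec(panel, c("D_9", "D_10", "C_6"), 1L)
  calls <- classify_calls(fa_report_for_cnv(panel, cnv), NULL, panel)
  expect_setequal(calls$amplicon_id[calls$state == "LOSS"],
                  c("D_9", "D_10", "C_6"))
  v <- detect_ambiguity(calls, panel)
  expect_equal(v$ambiguity, "NONE")
  expect_equal(unname(v$gene_level["BRCA1"]), "PARTIAL_LOSS")
  expect_equal(unname(v$gene_level["BRCA2"]), "NEUTRAL")
})

test_that("an all-neutral panel yields a neutral verdict", {
  panel <- default_panel()
  calls <- classify_calls(fa_report_for_cnv(panel), NULL, panel)
  v <- detect_ambiguity(calls, panel)
  expect_equal(v$ambiguity, "NONE")
  expect_true(all(v$gene_level == "NEUTRAL"))
})

test_that("ambiguity detection is symmetric under gene exchange", {
  panel <- default_panel()
  # gene-2 halved vs gene-1 doubled produce mirrored verdicts
  v_del <- detect_ambiguity(classify_calls(
    fa_report_for_cnv(panel, cnv_whole_gene(panel, "BRCA2", 1L)),
    NULL, panel), panel)
  v_dup <- detect_ambiguity(classify_calls(
    fa_report_for_cnv(panel, cnv_whole_gene(panel, "BRCA1", 4L)),
    NULL, panel), panel)
  expect_equal(v_del$ambiguity, "WHOLE_GENE_AMBIGUITY")
  expect_equal(v_dup$ambiguity, "WHOLE_GENE_AMBIGUITY")
  # both verdicts carry one loss and one gain hypothesis
  for (v in list(v_del, v_dup)) {
    expect_setequal(vapply(v$hypotheses, function(h) h$state, character(1)),
                    c("WHOLE_LOSS", "WHOLE_GAIN"))
  }
})

test_that("the whole-gene rule tolerates a bounded NO_CALL fraction", {
  panel <- default_panel()
  cnv <- cnv_whole_gene(panel, "BRCA2", 1L)
  calls <- classify_calls(fa_report_for_cnv(panel, cnv), NULL, panel)
  # knock 4 of 48 gene-2 amplicons (~8%) down to NO_CALL
  g2 <- which(calls$gene == "BRCA2")
  calls$state[g2[1:4]] <- "NO_CALL"
  v <- detect_ambiguity(calls, panel)
  expect_equal(v$ambiguity, "WHOLE_GENE_AMBIGUITY")
  # above the tolerance the pattern no longer counts as whole-gene
  calls$state[g2[1:8]] <- "NO_CALL"  # ~17%
  v2 <- detect_ambiguity(calls, panel, no_call_tol = 0.1)
  expect_equal(v2$ambiguity, "NONE")
})

test_that("dosage evidence resolves the ambiguity in either direction", {
  panel <- default_panel()
  probes <- default_probe_panel("maq", panel$gene_labels)
  verdict <- detect_ambiguity(classify_calls(
    fa_report_for_cnv(panel, cnv_whole_gene(panel, "BRCA2", 1L)),
    NULL, panel), panel)

  del2 <- classify_dq(compute_dq(gen_dosage_run(
    probes, cnv_whole_gene(probes, "BRCA2", 1L), n_controls = 4,
    seed = 1)))
  final <- resolve_with_dosage(verdict, del2)
  expect_equal(final$resolution, "DOSAGE_RESOLVED")
  expect_equal(unname(final$gene_level["BRCA2"]), "WHOLE_LOSS")
  expect_equal(unname(final$gene_level["BRCA1"]), "NEUTRAL")

  dup1 <- classify_dq(compute_dq(gen_dosage_run(
    probes, cnv_whole_gene(probes, "BRCA1", 3L), n_controls = 4,
    seed = 2)))
  final2 <- resolve_with_dosage(verdict, dup1)
  expect_equal(final2$resolution, "DOSAGE_RESOLVED")
  expect_equal(unname(final2$gene_level["BRCA1"]), "WHOLE_GAIN")
  expect_equal(unname(final2$gene_level["BRCA2"]), "NEUTRAL")

  normal <- classify_dq(compute_dq(gen_dosage_run(
    probes, n_controls = 4, seed = 3)))
  final3 <- resolve_with_dosage(verdict, normal)
  expect_equal(final3$resolution, "UNRESOLVED")
  expect_setequal(unname(final3$gene_level), c("WHOLE_LOSS", "WHOLE_GAIN"))

  # dosage covering neither gene
  alien <- normal
  names(alien$gene_summary) <- c("X1", "X2")
  expect_error(resolve_with_dosage(verdict, alien), "neither gene")
})

test_that("no whole-gene call exists without dosage evidence", {
  panel <- default_panel()
  # exhaustively: single-gene whole patterns never produce a final
  # whole-gene state from intra-panel evidence alone
  for (g in panel$gene_labels) for (cn in c(1L, 3L)) {
    calls <- classify_calls(
      fa_report_for_cnv(panel, cnv_whole_gene(panel, g, cn)), NULL, panel)
    v <- detect_ambiguity(calls, panel)
    expect_s3_class(v, "cnv_verdict")
    expect_false(inherits(v, "final_call"))
    expect_equal(v$ambiguity, "WHOLE_GENE_AMBIGUITY")
    expect_match(v$recommendation, "REQUIRED")
  }
  # and a contradictory dosage result leaves the call unresolved rather
  # than falling back to intra-panel evidence
  probes <- default_probe_panel("maq", panel$gene_labels)
  verdict <- detect_ambiguity(classify_calls(
    fa_report_for_cnv(panel, cnv_whole_gene(panel, "BRCA2", 1L)),
    NULL, panel), panel)
  contradictory <- classify_dq(compute_dq(gen_dosage_run(
    probes, cnv_spec(probes, probes$id[probes$role == "TARGET"][1], 1L),
    n_controls = 4, seed = 4)))
  expect_equal(resolve_with_dosage(verdict, contradictory)$resolution,
               "UNRESOLVED")
})

test_that("partial events below half a gene stay unambiguous", {
  panel <- default_panel()
  set.seed(13)
  for (rep in 1:6) {
    g <- sample(panel$gene_labels, 1)
    cn <- sample(c(1L, 3L), 1)
    # strictly less than half of the gene's amplicons in every plex
    # (the median anchor is per-plex)
    hit <- unlist(lapply(panel$plexes, function(px) {
      ids_px <- with(panel$amplicons, id[gene == g & plex_id == px])
      kmax <- ceiling(length(ids_px) / 2) - 1
      sample(ids_px, sample(0:kmax, 1))
    }))
    if (length(hit) == 0) {
      hit <- sample(panel$amplicons$id[panel$amplicons$gene == g], 1)
    }
    calls <- classify_calls(
      fa_report_for_cnv(panel, cnv_spec(panel, hit, cn)), NULL, panel)
    v <- detect_ambiguity(calls, panel)
    expect_equal(v$ambiguity, "NONE")
    expect_equal(unname(v$gene_level[g]),
                 if (cn == 1L) "PARTIAL_LOSS" else "PARTIAL_GAIN")
    got <- calls$amplicon_id[calls$state != "NEUTRAL"]
    expect_setequal(got, hit)
  }
})
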