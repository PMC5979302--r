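counts_matrix <- function(panel, values) {
  m <- matrix(values, nrow = 1,
              dimnames = list("s1", panel$amplicons$id))
  m
}

test_that("rc_frequency normalizes within each plex", {
  panel <- tiny_panel()
  m <- counts_matrix(panel, c(300, 100, 200, 200, 10, 10, 10, 10))
  f <- rc_frequency(m, panel)
  expect_equal(unname(f[1, c("P_1", "P_2")]),
               c(300, 100) / 800)
  expect_equal(unname(f[1, paste0("Q_", 1:4)]), rep(0.25, 4))

  # uniform counts over the default 17-amplicon plex A give 1/17
  dp <- default_panel()
  u <- matrix(100, nrow = 1, ncol = 93,
              dimnames = list("u", dp$amplicons$id))
  fu <- rc_frequency(u, dp)
  a_ids <- plex_amplicons(dp, "A")$id
  expect_equal(unname(fu[1, a_ids]), rep(1 / 17, 17))

  # frequencies sum to 1 per plex on random matrices
  set.seed(8)
  r <- matrix(rpois(5 * 93, 500), nrow = 5,
              dimnames = list(paste0("s", 1:5), dp$amplicons$id))
  fr <- rc_frequency(r, dp)
  for (px in dp$plexes) {
    ids <- plex_amplicons(dp, px)$id
    expect_equal(unname(rowSums(fr[, ids])), rep(1, 5), tolerance = 1e-12)
  }
})

test_that("rc_frequency errors on a zero plex total and rejects bad input", {
  panel <- tiny_panel()
  m <- counts_matrix(panel, c(0, 0, 0, 0, 10, 10, 10, 10))
  expect_error(rc_frequency(m, panel), "zero total count in plex P")
  bad <- counts_matrix(panel, rep(1, 8))
  colnames(bad)[1] <- "nope"
  expect_error(rc_frequency(bad, panel), "lacks|unknown")
})

test_that("frequencies are invariant to library-size scaling", {
  panel <- tiny_panel()
  set.seed(4)
  m <- matrix(rpois(3 * 8, 400), nrow = 3,
              dimnames = list(paste0("s", 1:3), panel$amplicons$id))
  f0 <- rc_frequency(m, panel)
  m2 <- m
  m2[2, ] <- m2[2, ] * 13
  expect_equal(rc_frequency(m2, panel), f0, tolerance = 1e-12)
})

test_that("run_ci99 matches the closed-form mean +/- 2.576 sd", {
  panel <- tiny_panel()
  m <- matrix(rep(c(100, 100, 100, 100, 25, 25, 25, 25), each = 4),
              nrow = 4, dimnames = list(paste0("s", 1:4),
                                        panel$amplicons$id))
  st <- run_ci99(m, panel)
  expect_equal(st$sd_freq, rep(0, 8))
  expect_equal(st$ci99_low, st$mean_freq)
  expect_equal(st$ci99_high, st$mean_freq)

  # constructed 5-sample frequencies with a hand-computed oracle
  set.seed(5)
  m5 <- matrix(rpois(5 * 8, 300), nrow = 5,
               dimnames = list(paste0("s", 1:5), panel$amplicons$id))
  st5 <- run_ci99(m5, panel)
  f5 <- rc_frequency(m5, panel)
  for (a in c("P_1", "Q_3")) {
    mu <- mean(f5[, a])
    sdv <- sqrt(sum((f5[, a] - mu)^2) / (5 - 1))
    i <- which(st5$amplicon_id == a)
    expect_equal(st5$mean_freq[i], mu, tolerance = 1e-12)
    expect_equal(st5$ci99_low[i], mu - 2.576 * sdv, tolerance = 1e-12)
    expect_equal(st5$ci99_high[i], mu + 2.576 * sdv, tolerance = 1e-12)
  }

  expect_error(run_ci99(m5[1:2, ], panel), ">= 3")
  expect_error(run_ci99(m5[1:3, ], panel, exclude_sample = "s1"), ">= 3")
})

test_that("CI99 bounds cover ~99% of held-out normal samples", {
  panel <- default_panel()
  nm <- noise_model(efficiency_spread = 0.3, sample_noise_sd = 0.05)
  cohort <- gen_counts(panel, n_samples = 50, depth = 5000, noise = nm,
                       seed = 101)
  held <- gen_counts(panel, n_samples = 20, depth = 5000, noise = nm,
                     seed = 202,
                     efficiencies = attr(cohort, "efficiencies"))
  st <- run_ci99(cohort, panel)
  f <- rc_frequency(held, panel)
  inside <- 0L
  for (i in seq_len(nrow(f))) {
    flags <- flag_rc_outliers(f[i, ], st)
    inside <- inside + sum(flags == "IN_CI")
  }
  coverage <- inside / (nrow(f) * ncol(f))
  expect_gte(coverage, 0.97)
  expect_lte(coverage, 1.0)
})

test_that("outlier flags use closed CI bounds and catch gene-2 halving", {
  panel <- tiny_panel()
  st <- structure(
    data.frame(amplicon_id = panel$amplicons$id,
               gene = panel$amplicons$gene,
               plex_id = panel$amplicons$plex_id,
               mean_freq = 0.25, sd_freq = 0.02,
               ci99_low = 0.25 - 2.576 * 0.02,
               ci99_high = 0.25 + 2.576 * 0.02),
    class = c("amplicon_run_stats", "data.frame"))
  f <- stats::setNames(rep(0.25, 8), panel$amplicons$id)
  expect_true(all(flag_rc_outliers(f, st) == "IN_CI"))
  f["P_1"] <- 0.25 + 2.576 * 0.02  # exactly at the upper bound
  f["P_2"] <- 0.4
  f["P_3"] <- 0.1
  fl <- flag_rc_outliers(f, st)
  expect_equal(unname(fl[c("P_1", "P_2", "P_3")]),
               c("IN_CI", "HIGH", "LOW"))
  expect_error(flag_rc_outliers(c(ZZ = 0.2), st), "absent")

  # whole-gene-2 halving against a normal cohort: gene-2 LOW, gene-1 HIGH
  dp <- default_panel()
  nm <- noise_model(efficiency_spread = 0.2, sample_noise_sd = 0.03)
  cohort <- gen_counts(dp, n_samples = 12, depth = 20000, noise = nm,
                       seed = 31)
  case <- gen_counts(dp, cnv = cnv_whole_gene(dp, "BRCA2", 1L),
                     n_samples = 1, depth = 20000,
                     noise = noise_model(0, 0), seed = 32,
                     efficiencies = attr(cohort, "efficiencies"))
  stc <- run_ci99(cohort, dp)
  flc <- flag_rc_outliers(rc_frequency(case, dp)[1, ], stc)
  g2 <- dp$amplicons$id[dp$amplicons$gene == "BRCA2"]
  g1 <- dp$amplicons$id[dp$amplicons$gene == "BRCA1"]
  expect_true(all(flc[g2] == "LOW"))
  expect_true(all(flc[g1] == "HIGH"))
})

test_that("about 1% of cohort amplicon-sample pairs fall outside CI99", {
  panel <- default_panel()
  nm <- noise_model(efficiency_spread = 0.25, sample_noise_sd = 0.05)
  cohort <- gen_counts(panel, n_samples = 50, depth = 5000, noise = nm,
                       seed = 77)
  f <- rc_frequency(cohort, panel)
  outliers <- 0L
  for (s in rownames(cohort)) {
    st <- run_ci99(cohort, panel, exclude_sample = s)
    outliers <- outliers + sum(flag_rc_outliers(f[s, ], st) != "IN_CI")
  }
  rate <- outliers / (nrow(f) * ncol(f))
  expect_gt(rate, 0.001)
  expect_lt(rate, 0.03)
})

test_that("global gene ratio reproduces 0.7, doubles on gene-2 halving", {
  panel <- tiny_panel()
  # engineered counts: gene-1 sum / gene-2 sum = 0.7 in both plexes
  m <- counts_matrix(panel, c(400, 300, 500, 500, 350, 350, 600, 400))
  gr <- global_gene_ratio(m, panel)
  expect_equal(unname(gr$per_plex[1, ]), c(0.7, 0.7))
  expect_equal(unname(gr$global), 0.7)

  halved <- m
  g2 <- panel$amplicons$id[panel$amplicons$gene == "G2"]
  halved[, g2] <- halved[, g2] / 2
  gr2 <- global_gene_ratio(halved, panel)
  expect_equal(unname(gr2$global), 1.4)
  expect_equal(unname(gr2$per_plex[1, ]), unname(gr$per_plex[1, ]) * 2)

  equal <- counts_matrix(panel, rep(100, 8))
  expect_equal(unname(global_gene_ratio(equal, panel)$global), 1)

  zero <- counts_matrix(panel, c(0, 0, 1, 1, 1, 1, 1, 1))
  expect_error(global_gene_ratio(zero, panel), "zero gene count")
})

test_that("a whole-gene-2 case is flagged against its cohort", {
  panel <- default_panel()
  nm <- noise_model(efficiency_spread = 0.2, sample_noise_sd = 0.03)
  cohort <- gen_counts(panel, n_samples = 8, depth = 20000, noise = nm,
                       seed = 51, calibrate_gene_ratio = 0.7)
  case <- gen_counts(panel, cnv = cnv_whole_gene(panel, "BRCA2", 1L),
                     n_samples = 1, depth = 20000, noise = nm, seed = 52,
                     efficiencies = attr(cohort, "efficiencies"),
                     sample_prefix = "case")
  m <- rbind(cohort, case)
  gr <- global_gene_ratio(m, panel)
  expect_false(any(gr$flagged[rownames(cohort)]))
  expect_true(gr$flagged["case1"])
  expect_gt(gr$global["case1"], 1.3)
})

test_that("count tables round-trip through wide and long dialects", {
  panel <- tiny_panel()
  set.seed(6)
  m <- matrix(rpois(2 * 8, 300), nrow = 2,
              dimnames = list(c("a", "b"), panel$amplicons$id))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts(m, f)
  expect_equal(read_counts(f, panel), m)
  # long dialect
  long <- data.frame(sample = rep(rownames(m), each = 8),
                     amplicon = rep(colnames(m), 2),
                     count = as.vector(t(m)))
  fl <- withr::local_tempfile(fileext = ".tsv")
  write.table(long, fl, sep = "\t", quote = FALSE, row.names = FALSE)
  m2 <- read_counts(fl, panel)
  expect_equal(m2[rownames(m), ], m)
})
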