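spec_ids <- function(x) {
  if (inherits(x, "panel_design")) x$amplicons$id
  else if (inherits(x, "probe_panel")) x$id
  else if (is.character(x)) x
  else stop("expected a panel_design, probe_panel or character ids",
            call. = FALSE)
}

#' Copy-number specification
#'
#' A named integer vector mapping every amplicon (or probe) id of a
#' panel to a copy number; the diploid default is 2 everywhere.
#'
#' @param x A [panel_design()], [probe_panel()] or character vector of
#'   ids.
#' @param ids Ids whose copy number differs from the default.
#' @param cn Copy number (single non-negative integer) for `ids`.
#' @param default Background copy number (default 2).
#' @return Named integer vector of class `cnv_spec`.
#' @export
cnv_spec <- function(x, ids = character(0), cn = 2L, default = 2L) {
  all_ids <- spec_ids(x)
  if (!all(ids %in% all_ids)) {
    stop("unknown id(s) in cnv spec: ",
         paste(setdiff(ids, all_ids), collapse = ", "), call. = FALSE)
  }
  if (length(cn) != 1L || cn < 0 || cn != round(cn)) {
    stop("`cn` must be a single non-negative integer", call. = FALSE)
  }
  out <- stats::setNames(rep(as.integer(default), length(all_ids)), all_ids)
  out[ids] <- as.integer(cn)
  class(out) <- "cnv_spec"
  out
}

#' Whole-gene copy-number event
#'
#' Convenience constructor: every amplicon (or TARGET probe) of `gene`
#' at copy number `cn`, everything else diploid.
#'
#' @param x A [panel_design()] or [probe_panel()].
#' @param gene Gene label.
#' @param cn Copy number for the gene.
#' @return A [cnv_spec()].
#' @export
cnv_whole_gene <- function(x, gene, cn) {
  ids <- if (inherits(x, "panel_design")) {
    if (!gene %in% x$gene_labels) stop("unknown gene: ", gene, call. = FALSE)
    x$amplicons$id[x$amplicons$gene == gene]
  } else if (inherits(x, "probe_panel")) {
    if (!gene %in% x$gene[x$role == "TARGET"]) {
      stop("unknown gene: ", gene, call. = FALSE)
    }
    x$id[x$role == "TARGET" & x$gene %in% gene]
  } else {
    stop("expected a panel_design or probe_panel", call. = FALSE)
  }
  cnv_spec(x, ids, cn)
}

#' Multiplicative noise model for the generators
#'
#' Both knobs are lognormal standard deviations on the log scale:
#' `efficiency_spread` is the per-amplicon (or per-probe) spread of
#' amplification efficiency, drawn once per cohort so that run-level
#' statistics behave like a real sequencing run; `sample_noise_sd` is
#' the per-observation multiplicative noise.
#'
#' @param efficiency_spread Lognormal sd of per-amplicon efficiency
#'   (>= 0, default 0).
#' @param sample_noise_sd Lognormal sd per observation (>= 0, default 0).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(efficiency_spread = 0, sample_noise_sd = 0) {
  if (efficiency_spread < 0 || sample_noise_sd < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(efficiency_spread = efficiency_spread,
                 sample_noise_sd = sample_noise_sd),
            class = "noise_model")
}

align_cnv <- function(cnv, ids) {
  if (is.null(cnv)) return(stats::setNames(rep(2L, length(ids)), ids))
  if (!all(ids %in% names(cnv))) {
    stop("cnv spec does not cover every id", call. = FALSE)
  }
  unclass(cnv)[ids]
}

draw_efficiencies <- function(ids, spread) {
  stats::setNames(exp(stats::rnorm(length(ids), 0, spread)), ids)
}

#' Generate a synthetic read-count matrix
#'
#' Expected count of amplicon a is
#' `depth * efficiency(a) * CN(a)/2`, perturbed by multiplicative
#' lognormal noise and rounded.  Efficiencies are drawn once (before
#' any per-sample noise) and returned in the `efficiencies` attribute,
#' so a cohort and a separately generated case sample can share them.
#' With `calibrate_gene_ratio`, gene-1 efficiencies are rescaled per
#' plex so that the noiseless diploid gene-1/gene-2 count ratio equals
#' the requested value in every plex (hence globally).
#'
#' @param panel A [panel_design()].
#' @param cnv A [cnv_spec()] applied to every generated sample
#'   (default: diploid).
#' @param n_samples Number of samples.
#' @param depth Expected diploid per-amplicon count at efficiency 1.
#' @param noise A [noise_model()].
#' @param seed Required RNG seed; recorded in the output attributes.
#' @param calibrate_gene_ratio Optional target for the diploid per-plex
#'   gene-1/gene-2 count ratio (e.g. 0.7).
#' @param efficiencies Optional named vector reusing a previous draw
#'   (bypasses `efficiency_spread` and calibration).
#' @param sample_prefix Prefix for generated sample names.
#' @return Count matrix (samples x amplicons) with attributes `seed`,
#'   `efficiencies`, `cnv`.
#' @export
gen_counts <- function(panel, cnv = NULL, n_samples = 1L, depth = 1000,
                       noise = noise_model(), seed,
                       calibrate_gene_ratio = NULL, efficiencies = NULL,
                       sample_prefix = "S") {
  validate_panel(panel)
  stopifnot(inherits(noise, "noise_model"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (depth <= 0) stop("`depth` must be > 0", call. = FALSE)
  set.seed(seed)
  amp <- panel$amplicons
  ids <- amp$id
  if (is.null(efficiencies)) {
    eff <- draw_efficiencies(ids, noise$efficiency_spread)
    if (!is.null(calibrate_gene_ratio)) {
      g1 <- panel$gene_labels[1]
      for (px in panel$plexes) {
        in_px <- amp$plex_id == px
        i1 <- in_px & amp$gene == g1
        i2 <- in_px & amp$gene != g1
        f <- calibrate_gene_ratio * sum(eff[ids[i2]]) / sum(eff[ids[i1]])
        eff[ids[i1]] <- eff[ids[i1]] * f
      }
    }
  } else {
    if (!all(ids %in% names(efficiencies))) {
      stop("`efficiencies` must cover every amplicon", call. = FALSE)
    }
    eff <- efficiencies[ids]
  }
  cn <- align_cnv(cnv, ids)
  expected <- depth * eff * cn / 2
  m <- t(vapply(seq_len(n_samples), function(i) {
    round(expected * exp(stats::rnorm(length(ids), 0,
                                      noise$sample_noise_sd)))
  }, numeric(length(ids))))
  dimnames(m) <- list(paste0(sample_prefix, seq_len(n_samples)), ids)
  attr(m, "seed") <- seed
  attr(m, "efficiencies") <- eff
  attr(m, "cnv") <- cn
  m
}

#' Generate a synthetic fragment-analysis trace
#'
#' Emits one Gaussian peak per amplicon of the plex at the scan
#' position implied by a known affine scan model
#' (`bp = slope * scan + intercept`), with height proportional to
#' `efficiency * CN/2`; amplicons at copy number 0 produce no peak.  A
#' second channel carries the size-standard ladder.  The ground-truth
#' scan model and planted heights are attached for oracle testing.
#'
#' @param panel A [panel_design()].
#' @param plex_id Plex to simulate.
#' @param cnv A [cnv_spec()] (default diploid).
#' @param noise A [noise_model()].
#' @param seed Required RNG seed.
#' @param sample_id Sample name embedded in the trace.
#' @param slope,intercept True affine scan model, bp per scan and bp.
#' @param base_height Diploid peak height at efficiency 1.
#' @param peak_sd_scans Gaussian peak width (sd) in scans.
#' @param ladder_height Ladder peak height.
#' @param standard A [size_standard()].
#' @param efficiencies Optional named vector reusing a previous draw.
#' @return A [raw_trace()] with channels `sample` and `ladder` and
#'   attribute `truth` (scan model, planted heights, efficiencies,
#'   seed).
#' @export
gen_trace <- function(panel, plex_id, cnv = NULL, noise = noise_model(),
                      seed, sample_id = "synthetic",
                      slope = 0.25, intercept = 0, base_height = 2000,
                      peak_sd_scans = 3, ladder_height = 1200,
                      standard = liz600(), efficiencies = NULL) {
  validate_panel(panel)
  stopifnot(inherits(noise, "noise_model"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(seed)
  amp <- plex_amplicons(panel, plex_id)
  ids <- amp$id
  eff <- if (is.null(efficiencies)) {
    draw_efficiencies(ids, noise$efficiency_spread)
  } else {
    efficiencies[ids]
  }
  cn <- align_cnv(cnv, ids)
  heights <- base_height * eff * cn / 2 *
    exp(stats::rnorm(length(ids), 0, noise$sample_noise_sd))
  heights[cn == 0] <- 0
  scan_of <- function(bp) round((bp - intercept) / slope)
  max_bp <- max(amp$expected_length_bp, standard$fragment_sizes_bp) + 20
  n_scans <- scan_of(max_bp)
  x <- seq_len(n_scans)
  bump <- function(center, h) h * exp(-(x - center)^2 / (2 * peak_sd_scans^2))
  sample_ch <- rep(0, n_scans)
  for (i in seq_along(ids)) {
    if (heights[i] > 0) {
      sample_ch <- sample_ch + bump(scan_of(amp$expected_length_bp[i]),
                                    heights[i])
    }
  }
  ladder_ch <- rep(0, n_scans)
  for (bp in standard$fragment_sizes_bp) {
    ladder_ch <- ladder_ch + bump(scan_of(bp), ladder_height)
  }
  trace <- raw_trace(sample_id, plex_id,
                     list(sample = sample_ch, ladder = ladder_ch))
  attr(trace, "truth") <- list(
    scan_model = list(slope = slope, intercept = intercept),
    heights = stats::setNames(heights, ids),
    efficiencies = eff, cnv = cn, seed = seed)
  trace
}

#' Generate a synthetic dosage run
#'
#' Control samples are diploid; the test sample's probe heights are
#' proportional to `CN/2`.  Per-probe efficiencies are shared by all
#' samples (they model probe-specific amplification), while
#' `sample_noise_sd` perturbs every observation independently.
#'
#' @param probes A [probe_panel()].
#' @param cnv A [cnv_spec()] over the probes (default diploid).
#' @param n_controls Number of diploid controls (>= 3).
#' @param noise A [noise_model()].
#' @param seed Required RNG seed.
#' @param base_height Diploid peak height at efficiency 1.
#' @return A [dosage_run()] with attribute `truth`.
#' @export
gen_dosage_run <- function(probes, cnv = NULL, n_controls = 4L,
                           noise = noise_model(), seed,
                           base_height = 1000) {
  stopifnot(inherits(probes, "probe_panel"))
  stopifnot(inherits(noise, "noise_model"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_controls < 3L) stop("`n_controls` must be >= 3", call. = FALSE)
  set.seed(seed)
  ids <- probes$id
  eff <- draw_efficiencies(ids, noise$efficiency_spread)
  cn <- align_cnv(cnv, ids)
  draw <- function(cn_vec) {
    base_height * eff * cn_vec / 2 *
      exp(stats::rnorm(length(ids), 0, noise$sample_noise_sd))
  }
  controls <- t(vapply(seq_len(n_controls), function(i) draw(rep(2L, length(ids))),
                       numeric(length(ids))))
  dimnames(controls) <- list(paste0("control_", seq_len(n_controls)), ids)
  test <- stats::setNames(draw(cn), ids)
  run <- dosage_run(probes, test, controls, test_id = "test")
  attr(run, "truth") <- list(cnv = cn, efficiencies = eff, seed = seed)
  run
}
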