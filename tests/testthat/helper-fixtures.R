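# Fixtures and independent oracles shared across the test files.

# A minimal two-plex dual-gene panel for fast unit tests.
tiny_panel <- function() {
  amp <- data.frame(
    id = c("P_1", "P_2", "P_3", "P_4", "Q_1", "Q_2", "Q_3", "Q_4"),
    plex_id = rep(c("P", "Q"), each = 4),
    gene = rep(c("G1", "G1", "G2", "G2"), 2),
    expected_length_bp = c(150, 160, 170, 180, 200, 210, 220, 230),
    stringsAsFactors = FALSE)
  panel_design(c("G1", "G2"), c("P", "Q"), amp)
}

# Build a calibrated peak set directly from per-amplicon heights,
# bypassing the trace chain (peaks exactly at expected sizes).
# Amplicons absent from `heights` come out MISSING.
peakset_from_heights <- function(panel, plex_id, heights,
                                 sample_id = "s") {
  amp <- plex_amplicons(panel, plex_id)
  ids <- intersect(amp$id, names(heights))
  peaks <- data.frame(
    position = amp$expected_length_bp[match(ids, amp$id)],
    height = unname(heights[ids]))
  attr(peaks, "units") <- "bp"
  assign_amplicons(peaks, panel, plex_id, sample_id = sample_id)
}

# Diploid reference profile with unit heights for every amplicon.
flat_reference <- function(panel) {
  sets <- lapply(panel$plexes, function(px) {
    amp <- plex_amplicons(panel, px)
    h <- stats::setNames(rep(1000, nrow(amp)), amp$id)
    peakset_from_heights(panel, px, h, sample_id = "reference")
  })
  reference_profile(sets, note = "synthetic flat reference")
}

# FA report for a sample whose heights are 1000 * cn/2 per amplicon.
fa_report_for_cnv <- function(panel, cnv = NULL, low = 0.7, high = 1.3) {
  cn <- if (is.null(cnv)) {
    stats::setNames(rep(2, nrow(panel$amplicons)), panel$amplicons$id)
  } else {
    unclass(cnv)
  }
  sets <- lapply(panel$plexes, function(px) {
    amp <- plex_amplicons(panel, px)
    h <- stats::setNames(1000 * cn[amp$id] / 2, amp$id)
    h <- h[h > 0]
    peakset_from_heights(panel, px, h, sample_id = "case")
  })
  fa_report(sets, flat_reference(panel), panel, low, high)
}

# Closed-form ordinary-least-squares oracle (normal equations).
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# Independent brute-force peak->amplicon matcher: repeatedly take the
# globally closest unassigned (amplicon, peak) pair within tolerance,
# breaking exact ties by smaller expected size.
brute_force_assign <- function(expected, peaks, tolerance) {
  assigned <- stats::setNames(rep(NA_integer_, length(expected)),
                              names(expected))
  used <- rep(FALSE, length(peaks))
  repeat {
    best <- NULL
    for (a in seq_along(expected)) {
      if (!is.na(assigned[a])) next
      for (p in seq_along(peaks)) {
        if (used[p]) next
        d <- abs(expected[a] - peaks[p])
        if (d > tolerance) next
        if (is.null(best) || d < best$d ||
            (d == best$d && expected[a] < expected[best$a])) {
          best <- list(a = a, p = p, d = d)
        }
      }
    }
    if (is.null(best)) break
    assigned[best$a] <- best$p
    used[best$p] <- TRUE
  }
  assigned
}

# Gaussian bump helper for hand-built traces.
gauss_bump <- function(n, center, height, sd = 3) {
  height * exp(-((seq_len(n) - center)^2) / (2 * sd^2))
}
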