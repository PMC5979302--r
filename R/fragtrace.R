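#' Size standard definition
#'
#' @param name Standard name.
#' @param fragment_sizes_bp Strictly increasing fragment lengths (>= 2).
#' @return An object of class `size_standard`.
#' @export
size_standard <- function(name, fragment_sizes_bp) {
  fragment_sizes_bp <- as.numeric(fragment_sizes_bp)
  if (length(fragment_sizes_bp) < 2L ||
      any(diff(fragment_sizes_bp) <= 0)) {
    stop("size standard needs >= 2 strictly increasing fragment sizes",
         call. = FALSE)
  }
  structure(list(name = name, fragment_sizes_bp = fragment_sizes_bp),
            class = "size_standard")
}

#' The GeneScan 600 LIZ size standard
#'
#' The 36-fragment LIZ-600 ladder (20-600 bp) co-electrophoresed with
#' every sample and used to map scan positions to base pairs.
#'
#' @return A [size_standard()].
#' @export
liz600 <- function() {
  size_standard("LIZ-600", c(
    20, 40, 60, 80, 100, 114, 120, 140, 160, 180,
    200, 214, 220, 240, 250, 260, 280, 300, 314, 320,
    340, 360, 380, 400, 414, 420, 440, 460, 480, 500,
    514, 520, 540, 560, 580, 600))
}

#' Construct a raw fragment-analysis trace
#'
#' A trace holds one or more fluorescence channels (typically the
#' sample dye channel and the size-standard channel) sampled on a
#' common scan axis.
#'
#' @param sample_id Sample identifier.
#' @param plex_id Plex label of the multiplex reaction loaded in this well.
#' @param channels Named list of equal-length finite numeric vectors,
#'   indexed by scan number (1-based).
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(sample_id, plex_id, channels) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("`channels` must be a named list of intensity vectors",
         call. = FALSE)
  }
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all channels must have the same length", call. = FALSE)
  }
  if (any(!vapply(channels, function(x) all(is.finite(x)), logical(1)))) {
    stop("channel intensities must be finite", call. = FALSE)
  }
  structure(list(sample_id = sample_id, plex_id = plex_id,
                 channels = lapply(channels, as.numeric)),
            class = "raw_trace")
}

#' Read a trace from a delimited text export
#'
#' Expects a tab- or comma-delimited file with header columns
#' `scan`, `channel`, `intensity` (long format, one row per scan per
#' channel), the dialect produced by fragment-analysis software table
#' exports and by [write_trace()].
#'
#' @param path Input file.
#' @param sample_id,plex_id Identifiers to attach; default from filename.
#' @return A [raw_trace()].
#' @export
read_trace <- function(path, sample_id = NULL, plex_id = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("scan", "channel", "intensity")
  if (!all(need %in% names(df))) {
    stop("trace file must have columns scan, channel, intensity",
         call. = FALSE)
  }
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(plex_id)) plex_id <- NA_character_
  chans <- split(df[, c("scan", "intensity")], df$channel)
  channels <- lapply(chans, function(d) d$intensity[order(d$scan)])
  raw_trace(sample_id, plex_id, channels)
}

#' Write a trace as delimited text
#'
#' @param trace A [raw_trace()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "raw_trace"))
  long <- do.call(rbind, lapply(names(trace$channels), function(ch) {
    y <- trace$channels[[ch]]
    data.frame(scan = seq_along(y), channel = ch, intensity = y)
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Detect peaks in a trace channel
#'
#' The channel is smoothed with a centered moving average and strict
#' local maxima of the smoothed signal above `min_height` are returned.
#' A plateau (run of equal smoothed values higher than both neighbours)
#' is reported once, at its leftmost scan.  Reported heights are the
#' raw (unsmoothed) intensities at the peak scan, since smoothing
#' attenuates amplitude.
#'
#' @param trace A [raw_trace()].
#' @param channel Channel name to analyse.
#' @param min_height Minimum smoothed height for a peak to be kept.
#' @param smooth_window Odd moving-average window in scans (>= 1;
#'   1 disables smoothing).
#' @return A data.frame with columns `position` (scan), `height` (raw
#'   intensity) and `smoothed_height`, ordered by position, with
#'   attribute `units = "scan"`.
#' @export
detect_peaks <- function(trace, channel, min_height = 50,
                         smooth_window = 5) {
  stopifnot(inherits(trace, "raw_trace"))
  if (!channel %in% names(trace$channels)) {
    stop("no such channel: ", channel, call. = FALSE)
  }
  if (min_height <= 0) stop("`min_height` must be > 0", call. = FALSE)
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    stop("`smooth_window` must be odd and >= 1", call. = FALSE)
  }
  y <- trace$channels[[channel]]
  empty <- data.frame(position = numeric(0), height = numeric(0),
                      smoothed_height = numeric(0))
  attr(empty, "units") <- "scan"
  if (length(y) < 3L) return(empty)
  s <- if (smooth_window > 1) {
    as.numeric(stats::filter(y, rep(1 / smooth_window, smooth_window),
                             sides = 2))
  } else {
    y
  }
  s[is.na(s)] <- 0
  # collapse runs of equal value so plateaus count once (leftmost scan)
  r <- rle(s)
  v <- r$values
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  k <- length(v)
  if (k < 3L) return(empty)
  is_max <- c(FALSE, v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k],
              FALSE)
  pos <- starts[is_max & v >= min_height]
  out <- data.frame(position = as.numeric(pos), height = y[pos],
                    smoothed_height = s[pos])
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "units") <- "scan"
  out
}

#' Pair detected ladder peaks with the known standard sizes
#'
#' Selects the n tallest detected peaks (n = number of standard
#' fragments), orders them by scan position and pairs them 1:1 with
#' the ascending known fragment sizes.  Spurious low peaks are thereby
#' discarded; the quality of the pairing is subsequently gated by the
#' r-squared check in [fit_size_standard()].
#'
#' @param peaks Peak table from [detect_peaks()] (scan units).
#' @param standard A [size_standard()].
#' @return Data.frame with columns `position`, `height`, `known_bp`.
#' @export
identify_standard_peaks <- function(peaks, standard = liz600()) {
  stopifnot(inherits(standard, "size_standard"))
  sizes <- standard$fragment_sizes_bp
  n <- length(sizes)
  if (nrow(peaks) < n) {
    stop("insufficient ladder peaks: detected ", nrow(peaks),
         ", size standard ", standard$name, " has ", n, " fragments",
         call. = FALSE)
  }
  keep <- order(peaks$height, decreasing = TRUE)[seq_len(n)]
  sel <- peaks[sort(keep), , drop = FALSE]
  sel <- sel[order(sel$position), , drop = FALSE]
  out <- data.frame(position = sel$position, height = sel$height,
                    known_bp = sizes)
  rownames(out) <- NULL
  out
}

#' Fit the linear scan-to-bp calibration
#'
#' Ordinary least-squares fit of `bp = slope * scan + intercept` to the
#' identified size-standard peaks.  The fit is rejected when r-squared
#' falls below `min_r_squared`, the guard against mis-identified
#' ladders.
#'
#' @param pairs Data.frame from [identify_standard_peaks()] with
#'   columns `position` and `known_bp`.
#' @param min_r_squared Minimum acceptable r-squared (default 0.99).
#' @return An object of class `calibration_fit` with fields `slope`
#'   (bp/scan), `intercept` (bp), `r_squared`, `residuals_bp`, `n`.
#' @export
fit_size_standard <- function(pairs, min_r_squared = 0.99) {
  if (length(unique(pairs$position)) < 2L) {
    stop("calibration needs >= 2 ladder peaks at distinct scan positions",
         call. = FALSE)
  }
  fit <- stats::lm(known_bp ~ position, data = pairs)
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((pairs$known_bp - mean(pairs$known_bp))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  if (r2 < min_r_squared) {
    stop(sprintf(
      "size-standard fit rejected: r-squared %.6f below threshold %.6f",
      r2, min_r_squared), call. = FALSE)
  }
  slope <- unname(co["position"])
  if (slope <= 0) {
    stop("size-standard fit has non-positive slope; ladder mis-identified?",
         call. = FALSE)
  }
  structure(list(slope = slope, intercept = unname(co["(Intercept)"]),
                 r_squared = r2,
                 residuals_bp = unname(stats::residuals(fit)),
                 n = nrow(pairs)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("calibration_fit: bp = %.6g * scan + %.6g (r2 = %.6f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Convert peak positions from scan units to base pairs
#'
#' @param peaks Peak table in scan units.
#' @param fit A [fit_size_standard()] calibration.
#' @return The peak table with `position` in bp (attribute
#'   `units = "bp"`); heights unchanged.
#' @export
scan_to_bp <- function(peaks, fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  out <- peaks
  out$position <- fit$slope * peaks$position + fit$intercept
  attr(out, "units") <- "bp"
  out
}

#' Assign calibrated peaks to panel amplicons
#'
#' Greedy nearest-distance matching: all (amplicon, peak) pairs within
#' `tolerance_bp` of the amplicon's expected size are ranked by
#' ascending absolute distance and assigned greedily, so no peak serves
#' two amplicons.  Exact distance ties are broken in favour of the
#' amplicon with the smaller expected size.  Amplicons left unmatched
#' are flagged `MISSING`; detected peaks matching no amplicon are
#' returned as `unexpected_peaks`.
#'
#' @param peaks_bp Calibrated peak table (bp units).
#' @param panel A [panel_design()].
#' @param plex_id Which plex was loaded in this well.
#' @param tolerance_bp Maximum |observed - expected| distance (default 2).
#' @param sample_id Sample identifier recorded in the result.
#' @return An object of class `calibrated_peakset` with fields
#'   `sample_id`, `plex_id`, `assignments` (data.frame `amplicon_id`,
#'   `gene`, `expected_bp`, `bp`, `height`, `status`), and
#'   `unexpected_peaks`.
#' @export
assign_amplicons <- function(peaks_bp, panel, plex_id, tolerance_bp = 2.0,
                             sample_id = NA_character_) {
  validate_panel(panel)
  if (!identical(attr(peaks_bp, "units"), "bp")) {
    stop("peaks must be calibrated to bp units (see scan_to_bp)",
         call. = FALSE)
  }
  if (tolerance_bp <= 0) stop("`tolerance_bp` must be > 0", call. = FALSE)
  amp <- plex_amplicons(panel, plex_id)
  sizes <- sort(amp$expected_length_bp)
  if (any(diff(sizes) < 2 * tolerance_bp)) {
    warning("plex ", plex_id, " has amplicons with expected sizes closer ",
            "than 2 * tolerance_bp; assignment may be ambiguous",
            call. = FALSE)
  }
  n_a <- nrow(amp)
  n_p <- nrow(peaks_bp)
  cand <- NULL
  if (n_p > 0L) {
    d <- abs(outer(amp$expected_length_bp, peaks_bp$position, "-"))
    idx <- which(d <= tolerance_bp, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      cand <- data.frame(a = idx[, 1], p = idx[, 2],
                         dist = d[idx],
                         expected = amp$expected_length_bp[idx[, 1]])
      cand <- cand[order(cand$dist, cand$expected), , drop = FALSE]
    }
  }
  match_of <- rep(NA_integer_, n_a)
  peak_used <- rep(FALSE, n_p)
  if (!is.null(cand)) {
    for (i in seq_len(nrow(cand))) {
      a <- cand$a[i]; p <- cand$p[i]
      if (is.na(match_of[a]) && !peak_used[p]) {
        match_of[a] <- p
        peak_used[p] <- TRUE
      }
    }
  }
  assignments <- data.frame(
    amplicon_id = amp$id,
    gene = amp$gene,
    expected_bp = amp$expected_length_bp,
    bp = ifelse(is.na(match_of), NA_real_, peaks_bp$position[match_of]),
    height = ifelse(is.na(match_of), NA_real_, peaks_bp$height[match_of]),
    status = ifelse(is.na(match_of), "MISSING", "OK"),
    stringsAsFactors = FALSE)
  structure(list(sample_id = sample_id, plex_id = plex_id,
                 assignments = assignments,
                 unexpected_peaks = peaks_bp[!peak_used, , drop = FALSE]),
            class = "calibrated_peakset")
}

#' @export
print.calibrated_peakset <- function(x, ...) {
  n_ok <- sum(x$assignments$status == "OK")
  cat(sprintf(
    "calibrated_peakset: sample %s, plex %s, %d/%d amplicons matched, %d unexpected peak(s)\n",
    x$sample_id, x$plex_id, n_ok, nrow(x$assignments),
    nrow(x$unexpected_peaks)))
  invisible(x)
}

#' Write a calibrated peak set as tab-separated text
#'
#' @param peakset A [assign_amplicons()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peakset <- function(peakset, path) {
  stopifnot(inherits(peakset, "calibrated_peakset"))
  df <- peakset$assignments
  df$sample_id <- peakset$sample_id
  df$plex_id <- peakset$plex_id
  utils::write.table(
    df[, c("sample_id", "plex_id", "amplicon_id", "gene", "expected_bp",
           "bp", "height", "status")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full trace-to-peakset calibration chain
#'
#' Convenience wrapper: detect sample and ladder peaks, identify the
#' size standard, fit the scan-to-bp line, convert, and assign to the
#' panel's amplicons.
#'
#' @param trace A [raw_trace()] with a sample and a ladder channel.
#' @param panel A [panel_design()].
#' @param plex_id Plex loaded in this well (defaults to the trace's).
#' @param sample_channel,ladder_channel Channel names.
#' @param standard A [size_standard()].
#' @param min_height,smooth_window Peak-detection parameters.
#' @param tolerance_bp Amplicon match tolerance.
#' @param min_r_squared Calibration quality gate.
#' @return A list with `peakset` ([assign_amplicons()] result) and
#'   `fit` (the [fit_size_standard()] calibration).
#' @export
calibrate_trace <- function(trace, panel, plex_id = trace$plex_id,
                            sample_channel = "sample",
                            ladder_channel = "ladder",
                            standard = liz600(),
                            min_height = 50, smooth_window = 5,
                            tolerance_bp = 2.0, min_r_squared = 0.99) {
  ladder_peaks <- detect_peaks(trace, ladder_channel, min_height,
                               smooth_window)
  pairs <- identify_standard_peaks(ladder_peaks, standard)
  fit <- fit_size_standard(pairs, min_r_squared)
  sample_peaks <- detect_peaks(trace, sample_channel, min_height,
                               smooth_window)
  peaks_bp <- scan_to_bp(sample_peaks, fit)
  peakset <- assign_amplicons(peaks_bp, panel, plex_id, tolerance_bp,
                              sample_id = trace$sample_id)
  list(peakset = peakset, fit = fit)
}
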