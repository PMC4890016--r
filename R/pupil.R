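#' Pupil trace container
#'
#' Fixed-rate pupil samples with blink annotations and block onsets. Blinks
#' arrive as half-open `[start_s, end_s)` intervals from the tracker's
#' detector; detection itself is out of scope.
#'
#' @param samples numeric pupil samples (a.u.).
#' @param fs sampling rate in Hz (default 500).
#' @param blinks two-column matrix / data frame of blink intervals
#'   `(start_s, end_s)`, or NULL.
#' @param blocks optional tibble with `onset_s` and `condition` per block.
#' @param session_id identifier carried in metadata.
#' @return a `pupil_trace` object.
#' @export
pupil_trace <- function(samples, fs = 500, blinks = NULL, blocks = NULL,
                        session_id = "session") {
  if (fs <= 0) abort("fs must be positive", class = "facedcm_config_error")
  dur <- length(samples) / fs
  if (!is.null(blinks)) {
    blinks <- as.matrix(blinks)
    if (ncol(blinks) != 2L) abort("blinks must have two columns")
    if (any(blinks[, 1] < 0) || any(blinks[, 2] > dur + 1e-9) ||
        any(blinks[, 2] <= blinks[, 1])) {
      abort("blink intervals outside the trace", class = "facedcm_config_error")
    }
  }
  structure(list(samples = as.numeric(samples), fs = fs, blinks = blinks,
                 blocks = blocks, session_id = session_id,
                 preprocessing = character(0)),
            class = "pupil_trace")
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat("<pupil_trace> ", x$session_id, ": ", length(x$samples), " samples @ ",
      x$fs, " Hz (", format(length(x$samples) / x$fs, digits = 4), " s), ",
      if (is.null(x$blinks)) 0L else nrow(x$blinks), " blinks",
      if (length(x$preprocessing)) paste0("; ", paste(x$preprocessing, collapse = " > ")),
      "\n", sep = "")
  invisible(x)
}

sample_times <- function(trace) (seq_along(trace$samples) - 1L) / trace$fs

blink_mask <- function(trace) {
  t <- sample_times(trace)
  bad <- rep(FALSE, length(t))
  if (!is.null(trace$blinks)) {
    for (i in seq_len(nrow(trace$blinks))) {
      bad <- bad | (t >= trace$blinks[i, 1] & t < trace$blinks[i, 2])
    }
  }
  bad
}

#' Preprocess a pupil trace
#'
#' Fixed pipeline: (1) blink spans are replaced by cubic-spline
#' interpolation over the neighbouring valid samples (edge blinks are first
#' filled by nearest-valid-value extension, since spline extrapolation is
#' unstable); (2) the trace is z-normalised using the mean and standard
#' deviation of all (interpolated) samples; (3) high-frequency noise is
#' suppressed with a centred moving-average window of `smooth_ms`
#' milliseconds (edge-replicated). The order is recorded in the trace's
#' `preprocessing` metadata.
#'
#' @param trace a [pupil_trace()].
#' @param smooth_ms smoothing window width in milliseconds (default 50).
#' @return the cleaned `pupil_trace`.
#' @export
preprocess <- function(trace, smooth_ms = 50) {
  stopifnot(inherits(trace, "pupil_trace"))
  x <- trace$samples
  bad <- blink_mask(trace)
  if (all(bad)) abort("no non-blink samples", class = "facedcm_config_error")
  good <- which(!bad)
  # edge blinks: extend nearest valid value before spline fitting
  if (bad[1]) x[seq_len(good[1] - 1L)] <- x[good[1]]
  nlast <- good[length(good)]
  if (bad[length(x)]) x[(nlast + 1L):length(x)] <- x[nlast]
  bad[seq_len(good[1])] <- FALSE
  bad[nlast:length(x)] <- FALSE
  if (any(bad)) {
    idx <- seq_along(x)
    sp <- splinefun(idx[!bad], x[!bad], method = "fmm")
    x[bad] <- sp(idx[bad])
  }
  s <- sd(x)
  if (s == 0) abort("constant trace: sd is zero", class = "facedcm_config_error")
  x <- (x - mean(x)) / s
  w <- max(1L, round(smooth_ms / 1000 * trace$fs))
  x <- box_smooth(x, w)
  out <- trace
  out$samples <- x
  out$blinks <- NULL
  out$preprocessing <- c(trace$preprocessing,
                         "interpolate", "z-normalize", paste0("smooth[", w, "]"))
  out
}

# centred moving average with edge replication
box_smooth <- function(x, w) {
  if (w <= 1L) return(x)
  half <- (w - 1L) %/% 2L
  pad <- c(rep(x[1], half), x, rep(x[length(x)], w - 1L - half))
  as.numeric(stats::filter(pad, rep(1 / w, w), sides = 1))[(w - 1L + 1L):(w - 1L + length(x))]
}

#' Per-block slow pupil-change metric
#'
#' Mean pupil size over the late window `[onset + 9 s, onset + 11 s)` minus
#' the baseline mean over `[onset, onset + 50 ms)`. Windows are half-open
#' and left-aligned at the stated times; the block must extend at least
#' 11 s beyond its onset.
#'
#' @param trace a (cleaned) [pupil_trace()].
#' @param onset_s block onset in seconds from trace start.
#' @param baseline_s,late_from_s,late_to_s window definition (defaults
#'   0.05, 9 and 11 s).
#' @return scalar change value.
#' @export
block_metric <- function(trace, onset_s, baseline_s = 0.05,
                         late_from_s = 9, late_to_s = 11) {
  t <- sample_times(trace)
  if (onset_s + late_to_s > length(trace$samples) / trace$fs + 1e-9) {
    abort("block truncated before the late window", class = "facedcm_config_error")
  }
  win <- function(a, b) trace$samples[t >= a - 1e-12 & t < b - 1e-12]
  mean(win(onset_s + late_from_s, onset_s + late_to_s)) -
    mean(win(onset_s, onset_s + baseline_s))
}

#' Condition-averaged pupil block metrics
#'
#' Computes the per-block slow-change metric for every stimulus block of a
#' design and averages within condition, returning the 3 stimulus x 2
#' hemifield table that enters the group-level mixed ANOVA.
#'
#' @param trace a cleaned [pupil_trace()].
#' @param design a [build_block_design()] giving onsets and conditions, or
#'   NULL to use the trace's own `blocks`.
#' @return tibble with columns `stimulus` (F/O/S), `hemifield` (LVF/RVF),
#'   `value` (mean metric) and `n_blocks`.
#' @export
condition_averages <- function(trace, design = NULL) {
  blocks <- if (!is.null(design)) stim_blocks(design) else trace$blocks
  if (is.null(blocks)) abort("no block annotations")
  blocks <- as_tibble(blocks[blocks$condition %in% .conditions, ])
  if (!all(.conditions %in% blocks$condition)) {
    abort("missing condition in the design", class = "facedcm_config_error")
  }
  blocks$metric <- vapply(blocks$onset_s, function(o) block_metric(trace, o), 0)
  dplyr::summarise(
    dplyr::group_by(blocks,
                    stimulus = substr(.data$condition, 1, 1),
                    hemifield = sub("^[FOS]_", "", .data$condition)),
    value = mean(.data$metric), n_blocks = dplyr::n(),
    .groups = "drop")
}
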