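#' Build the pseudo-randomised block design
#'
#' Generates the lateralised face/object/scrambled block paradigm: six
#' conditions (faces, objects, scrambled images, each in the left or right
#' visual field), each repeated `n_reps` times in a pseudo-random order in
#' which no condition occurs three times in a row. Every stimulus block is
#' followed by a fixation block of the same duration; runs are separated by
#' rest breaks during which the scanner keeps acquiring.
#'
#' @param n_reps repetitions per condition (default 7).
#' @param block_scans scans per block (default 10; 14.5 s at the default TR).
#' @param tr_s repetition time in seconds (default 1.45).
#' @param n_runs number of runs; `6 * n_reps` must be divisible by `n_runs`.
#' @param break_scans rest scans between consecutive runs (default 42).
#' @param seed integer seed for the pseudo-randomisation.
#' @param lead_in_scans,lead_out_scans extra rest scans before the first and
#'   after the last block (default 0).
#'
#' @return A `block_design`: a tibble with columns `onset_s`, `duration_s`,
#'   `condition` and `run` (stimulus and fixation blocks only), carrying
#'   attributes `tr_s`, `n_scans`, `run_boundaries` (run start times, s) and
#'   `seed`.
#' @export
#' @examples
#' d <- build_block_design(n_reps = 1, n_runs = 1, seed = 1)
#' table(d$condition)
build_block_design <- function(n_reps = 7, block_scans = 10, tr_s = 1.45,
                               n_runs = 3, break_scans = 42, seed = 1,
                               lead_in_scans = 0, lead_out_scans = 0) {
  if (n_reps < 1 || block_scans < 1 || tr_s <= 0 || n_runs < 1 ||
      break_scans < 0 || lead_in_scans < 0 || lead_out_scans < 0) {
    abort("non-positive design arguments", class = "facedcm_config_error")
  }
  n_stim <- 6L * as.integer(n_reps)
  if (n_stim %% n_runs != 0) {
    abort("6 * n_reps must be divisible by n_runs", class = "facedcm_config_error")
  }
  order <- withr_seed(seed, shuffle_no_triples(rep(.conditions, n_reps)))

  block_dur <- block_scans * tr_s
  per_run <- n_stim %/% n_runs
  onset <- lead_in_scans * tr_s
  rows <- vector("list", 2L * n_stim)
  run_boundaries <- numeric(n_runs)
  k <- 0L
  for (r in seq_len(n_runs)) {
    run_boundaries[r] <- onset
    for (b in seq_len(per_run)) {
      cond <- order[(r - 1L) * per_run + b]
      rows[[k <- k + 1L]] <- list(onset_s = onset, duration_s = block_dur,
                                  condition = cond, run = r)
      onset <- onset + block_dur
      rows[[k <- k + 1L]] <- list(onset_s = onset, duration_s = block_dur,
                                  condition = "FIXATION", run = r)
      onset <- onset + block_dur
    }
    if (r < n_runs) onset <- onset + break_scans * tr_s
  }
  blocks <- dplyr::bind_rows(rows)
  n_scans <- lead_in_scans + n_runs * 2L * per_run * block_scans +
    (n_runs - 1L) * break_scans + lead_out_scans
  structure(blocks,
            class = c("block_design", class(blocks)),
            tr_s = tr_s, n_scans = as.integer(n_scans),
            run_boundaries = run_boundaries, seed = seed)
}

# constrained shuffle: no condition three times consecutively
shuffle_no_triples <- function(labels) {
  repeat {
    x <- sample(labels)
    r <- rle(x)
    if (all(r$lengths < 3L)) return(x)
  }
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

design_tr <- function(design) attr(design, "tr_s")
design_n_scans <- function(design) attr(design, "n_scans")

stim_blocks <- function(design) {
  design[design$condition %in% .conditions, , drop = FALSE]
}

#' Canonical haemodynamic response function
#'
#' Double-gamma HRF (response peak 6 s, undershoot peak 16 s,
#' peak-to-undershoot ratio 6), sampled at `dt` and truncated at `length_s`,
#' scaled to unit sum.
#'
#' @param dt sampling interval (s).
#' @param length_s support length (s, default 32).
#' @param peak,undershoot,ratio shape parameters of the two gamma densities.
#' @return numeric vector of HRF samples.
#' @export
canonical_hrf <- function(dt, length_s = 32, peak = 6, undershoot = 16, ratio = 6) {
  t <- seq(0, length_s, by = dt)
  h <- dgamma(t, shape = peak, scale = 1) - dgamma(t, shape = undershoot, scale = 1) / ratio
  h / sum(h)
}

#' Build DCM input functions and GLM condition regressors
#'
#' From a block design, constructs (a) the five binary microtime input
#' functions driving the dynamic causal model -- `RVF`, `LVF`, `faces`,
#' `faces|RVF`, `faces|LVF` -- and (b) the six condition regressors of the
#' region-level GLM (condition boxcars convolved with the canonical HRF,
#' sampled at scan times).
#'
#' @param design a [build_block_design()] object.
#' @param microtime_dt_s microtime bin width (s); must divide the TR. Default
#'   `tr_s / 16`.
#' @return A `dcm_inputs` list: `u` (microtime bins x 5, in {0,1}), `dt`,
#'   `bins_per_tr`, `tr_s`, `n_scans`, and `glm_regressors` (scans x 6).
#' @export
build_inputs <- function(design, microtime_dt_s = NULL) {
  tr <- design_tr(design)
  if (is.null(microtime_dt_s)) microtime_dt_s <- tr / 16
  bins_per_tr <- round(tr / microtime_dt_s)
  if (abs(bins_per_tr * microtime_dt_s - tr) > 1e-9 || bins_per_tr < 1) {
    abort("microtime_dt_s must divide tr_s", class = "facedcm_config_error")
  }
  sb <- stim_blocks(design)
  o <- order(sb$onset_s)
  if (any(sb$onset_s[o][-1] < (sb$onset_s + sb$duration_s)[o][-nrow(sb)] - 1e-9)) {
    abort("design has overlapping blocks", class = "facedcm_config_error")
  }
  n_scans <- design_n_scans(design)
  n_micro <- n_scans * bins_per_tr
  dt <- microtime_dt_s

  u <- matrix(0, n_micro, 5L, dimnames = list(NULL, .inputs))
  boxcars <- matrix(0, n_micro, 6L, dimnames = list(NULL, .conditions))
  for (i in seq_len(nrow(sb))) {
    from <- round(sb$onset_s[i] / dt) + 1L
    to <- round((sb$onset_s[i] + sb$duration_s[i]) / dt)
    to <- min(to, n_micro)
    if (from > to) next
    idx <- from:to
    cond <- sb$condition[i]
    boxcars[idx, cond] <- 1
    field <- if (grepl("_RVF$", cond)) "RVF" else "LVF"
    u[idx, field] <- 1
    if (grepl("^F_", cond)) {
      u[idx, "faces"] <- 1
      u[idx, paste0("faces|", field)] <- 1
    }
  }

  h <- canonical_hrf(dt)
  conv <- apply(boxcars, 2L, function(x) {
    y <- stats::convolve(x, rev(h), type = "open")
    y[seq_len(n_micro)]
  })
  scan_bins <- (seq_len(n_scans) - 1L) * bins_per_tr + 1L
  glm_regressors <- conv[scan_bins, , drop = FALSE]

  structure(list(u = u, dt = dt, bins_per_tr = bins_per_tr, tr_s = tr,
                 n_scans = n_scans, glm_regressors = glm_regressors),
            class = "dcm_inputs")
}

# discrete-cosine high-pass basis: components with period > 1/cutoff_hz
dct_basis <- function(n, tr_s, cutoff_hz) {
  r_max <- floor(2 * n * tr_s * cutoff_hz)
  if (r_max < 1) return(matrix(0, n, 0))
  t <- seq_len(n) - 1L
  sapply(seq_len(r_max), function(r) cos(pi * (2 * t + 1) * r / (2 * n)))
}

#' Fit the region-level GLM
#'
#' Ordinary least squares of region time series on the six condition
#' regressors (plus optional nuisance regressors), after removing low
#' frequencies from both data and design with a discrete-cosine high-pass
#' filter, and evaluation of linear contrasts.
#'
#' @param series scans x regions matrix (or data frame) of time series.
#' @param inputs a [build_inputs()] object supplying the regressors.
#' @param highpass_cutoff_hz high-pass cut-off frequency (default 1/128 Hz).
#' @param nuisance optional scans x k matrix of nuisance regressors.
#' @param contrasts named list of length-6 contrast weight vectors over the
#'   condition regressors. The default face-sensitivity contrast
#'   `"[2*F]-[O+S]"` uses weights (1, 1, -1/2, -1/2, -1/2, -1/2) over
#'   (F_LVF, F_RVF, O_LVF, O_RVF, S_LVF, S_RVF).
#' @return A `glm_fit` list: `betas` (regressor x region), `contrast_values`
#'   (contrast x region), `residual_variance` per region, `df_residual`.
#' @export
fit_glm <- function(series, inputs, highpass_cutoff_hz = 1 / 128,
                    nuisance = NULL,
                    contrasts = list(`[2*F]-[O+S]` = c(1, 1, -0.5, -0.5, -0.5, -0.5))) {
  Y <- as.matrix(series)
  X <- inputs$glm_regressors
  if (nrow(Y) != nrow(X)) {
    abort("series length does not match regressor length", class = "facedcm_config_error")
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    X <- cbind(X, nuisance)
  }
  n <- nrow(Y)
  K <- cbind(1, dct_basis(n, inputs$tr_s, highpass_cutoff_hz))
  resid_k <- function(M) M - K %*% qr.solve(K, M)
  Yf <- resid_k(Y)
  Xf <- resid_k(X)

  qx <- qr(Xf)
  if (qx$rank < ncol(Xf)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(Xf)), qx$pivot[seq_len(qx$rank)])]
    abort(paste0("rank-deficient design; offending columns: ",
                 paste(bad, collapse = ", ")),
          class = "facedcm_rank_error")
  }
  betas <- qr.coef(qx, Yf)
  rownames(betas) <- colnames(X)
  res <- Yf - Xf %*% betas
  df <- n - ncol(Xf) - ncol(K)
  rv <- colSums(res^2) / max(df, 1L)

  cw <- do.call(rbind, contrasts)
  cv <- cw %*% betas[seq_len(6L), , drop = FALSE]
  rownames(cv) <- names(contrasts)

  structure(list(betas = betas, contrast_values = cv,
                 residual_variance = rv, df_residual = df,
                 contrast_weights = contrasts),
            class = "glm_fit")
}

#' @export
tidy.glm_fit <- function(x, ...) {
  b <- as_tibble(x$betas, rownames = "term")
  tidyr::pivot_longer(b, -"term", names_to = "region", values_to = "estimate")
}

#' First eigenvariate of a voxel time-series matrix
#'
#' Summary time series of a region of interest: the first left singular
#' vector of the voxel matrix, scaled to the data's amplitude
#' (`d1 / sqrt(n_voxels)`), with its sign chosen to correlate positively
#' with the mean voxel series.
#'
#' @param voxel_series time x voxel matrix.
#' @return numeric time series of length `nrow(voxel_series)`.
#' @export
first_eigenvariate <- function(voxel_series) {
  Y <- as.matrix(voxel_series)
  if (ncol(Y) < 1L || all(Y == 0)) {
    abort("voxel matrix is empty or all zero", class = "facedcm_config_error")
  }
  sv <- svd(Y, nu = 1L, nv = 0L)
  y <- sv$u[, 1L] * sv$d[1L] / sqrt(ncol(Y))
  m <- rowMeans(Y)
  s <- sum(y * m)
  if (s < 0) y <- -y
  y
}
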