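#' Synthetic cohort configuration
#'
#' Bundles everything the cohort generator needs: group sizes, the master
#' seed, the signal-to-noise ratio of the BOLD simulation, the block-design
#' parameters, the generating model per group, the group parameter tables
#' (means and between-subject standard deviations per connection), pupil
#' effect sizes per condition and group, and lateralization effect sizes.
#'
#' The generating models default to the two winning families -- family B
#' (context combination S/F) for right-handers and family F (S/F) for
#' left-handers -- so that family recovery is meaningful. Pupil amplitudes
#' default to a faces-only group difference (stronger pupil decrease over
#' face blocks in right-handers); lateralization defaults make the FFA
#' right-dominant in the right-handed group only, with the OFA
#' right-dominant in both.
#'
#' @param n_per_group subjects per group (default 20).
#' @param seed master seed; all per-subject seeds derive from it.
#' @param snr ratio of noiseless BOLD signal sd to observation noise sd
#'   (default 1).
#' @param design named list of [build_block_design()] arguments.
#' @param generating named list per group: `family` (A-F), `combo`
#'   (`"inter/intra"`).
#' @param param_table as [group_connectivity_table()].
#' @param a_diag_mean,a_diag_sd generative moments of the self-connections
#'   (Hz); draws are truncated to stay negative.
#' @param pupil named list: `fs`, `amplitude` (3 x 2 group matrix of block
#'   response amplitudes for F/O/S rows), `noise_sd`, `blink_rate_hz`,
#'   `blink_dur_s`.
#' @param li named list: `n_voxels`, `target` (region x group LI targets).
#' @param antithetic use antithetic (mirror-image) parameter draws for
#'   consecutive subject pairs, so the cohort-mean generative parameters
#'   equal the table means exactly with an even `n_per_group`; a
#'   variance-reduction device for recovery experiments (default FALSE).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 20, seed = 1, snr = 1,
                          design = list(n_reps = 7, block_scans = 10,
                                        tr_s = 1.45, n_runs = 3,
                                        break_scans = 42),
                          generating = list(RH = list(family = "B", combo = "S/F"),
                                            LH = list(family = "F", combo = "S/F")),
                          param_table = group_connectivity_table(),
                          a_diag_mean = -0.5, a_diag_sd = 0.05,
                          pupil = NULL, li = NULL, antithetic = FALSE) {
  if (n_per_group < 1) abort("n_per_group must be at least 1",
                             class = "facedcm_config_error")
  if (any(param_table$rh_sd < 0, na.rm = TRUE) ||
      any(param_table$lh_sd < 0, na.rm = TRUE)) {
    abort("standard deviations must be non-negative", class = "facedcm_config_error")
  }
  if (is.null(pupil)) {
    pupil <- list(fs = 500,
                  amplitude = matrix(c(-0.30, -0.15,   # faces  RH, LH
                                       -0.20, -0.20,   # objects
                                       -0.10, -0.10),  # scrambled
                                     nrow = 3, byrow = TRUE,
                                     dimnames = list(c("F", "O", "S"), c("RH", "LH"))),
                  noise_sd = 0.4, blink_rate_hz = 0.25, blink_dur_s = 0.2)
  }
  if (is.null(li)) {
    li <- list(n_voxels = 40,
               target = matrix(c(-0.31, -0.04,   # FFA  RH, LH
                                 -0.30, -0.30),  # OFA
                               nrow = 2, byrow = TRUE,
                               dimnames = list(c("FFA", "OFA"), c("RH", "LH"))))
  }
  cfg <- list(n_per_group = n_per_group, seed = seed, snr = snr,
              design = design, generating = generating,
              param_table = param_table,
              a_diag_mean = a_diag_mean, a_diag_sd = a_diag_sd,
              pupil = pupil, li = li, antithetic = antithetic)
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "cohort_config")
}

generating_spec <- function(config, group) {
  g <- config$generating[[group]]
  parts <- strsplit(g$combo, "/", fixed = TRUE)[[1]]
  skel <- build_endogenous_skeleton()
  b <- expand_context(intra_context = parts[2], inter_context = parts[1],
                      family_sites = default_families()[[g$family]])
  dcm_spec(.regions, skel$a_mask, b, skel$c_mask,
           family_id = g$family, combo = g$combo)
}

table_lookup <- function(tab, group, class, connection) {
  row <- tab[tab$class == class & tab$connection == connection, ]
  if (nrow(row) != 1L) {
    abort(paste0("missing table entry for ", class, " ", connection),
          class = "facedcm_config_error")
  }
  if (group == "RH") c(row$rh_mean, row$rh_sd) else c(row$lh_mean, row$lh_sd)
}

#' Sample one subject's generative parameters
#'
#' Draws every free parameter of the group's generating model from a
#' Gaussian around its group mean with the group's between-subject standard
#' deviation; self-connections are truncated to stay strictly negative.
#' With all standard deviations zero the subject equals the group mean
#' exactly.
#'
#' @param config a [cohort_config()].
#' @param group `"RH"` or `"LH"`.
#' @param seed integer seed for this subject's draw.
#' @param flip negate the Gaussian deviations around the group means
#'   (antithetic partner draw; the marginal distribution is unchanged).
#' @return a [dcm_params()] for the generating spec.
#' @export
sample_subject_params <- function(config, group, seed, flip = FALSE) {
  spec <- generating_spec(config, group)
  tab <- config$param_table
  sgn <- if (flip) -1 else 1
  withr_seed(seed, {
    n <- length(spec$regions)
    A <- matrix(0, n, n, dimnames = list(spec$regions, spec$regions))
    for (i in seq_len(n)) {
      repeat {
        d <- config$a_diag_mean + sgn * rnorm(1, 0, config$a_diag_sd)
        if (d < -1e-3) break
      }
      A[i, i] <- d
    }
    for (j in seq_len(n)) for (i in seq_len(n)) {
      if (i != j && spec$a_mask[i, j] == 1L) {
        conn <- paste0(spec$regions[j], "->", spec$regions[i])
        ms <- table_lookup(tab, group, "endogenous", conn)
        A[i, j] <- ms[1] + sgn * rnorm(1, 0, ms[2])
      }
    }
    B <- list()
    for (nm in spec$input_labels) {
      bm <- spec$b_masks[[nm]]
      if (!any(bm == 1L)) next
      Bm <- matrix(0, n, n)
      for (j in seq_len(n)) for (i in seq_len(n)) {
        if (bm[i, j] == 1L) {
          conn <- paste0(spec$regions[j], "->", spec$regions[i])
          ms <- table_lookup(tab, group, nm, conn)
          if (anyNA(ms)) ms[is.na(ms)] <- 0
          Bm[i, j] <- ms[1] + sgn * rnorm(1, 0, ms[2])
        }
      }
      B[[nm]] <- Bm
    }
    C <- matrix(0, n, length(spec$input_labels),
                dimnames = list(spec$regions, spec$input_labels))
    for (j in seq_along(spec$input_labels)) for (i in seq_len(n)) {
      if (spec$c_mask[i, j] == 1L) {
        conn <- paste0(spec$input_labels[j], "->", spec$regions[i])
        ms <- table_lookup(tab, group, "driving", conn)
        C[i, j] <- ms[1] + sgn * rnorm(1, 0, ms[2])
      }
    }
    dcm_params(spec, A, B, C)
  })
}

# half-cosine onset ramp block response at sampling rate fs
pupil_block_response <- function(n_samples, onset_idx, dur_samples, amplitude,
                                 fs, ramp_s = 0.5) {
  r <- numeric(n_samples)
  ramp_n <- round(ramp_s * fs)
  prof <- c((1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2,
            rep(1, max(dur_samples - ramp_n, 0)))
  idx <- onset_idx + seq_along(prof) - 1L
  keep <- idx <= n_samples
  r[idx[keep]] <- amplitude * prof[keep]
  r
}

# pink (1/f) noise via spectral shaping, unit sd
pink_noise <- function(n) {
  w <- rnorm(n)
  f <- stats::fft(w)
  freq <- c(1, seq_len(n - 1))
  f <- f / sqrt(pmin(freq, n - freq + 1))
  x <- Re(stats::fft(f, inverse = TRUE)) / n
  (x - mean(x)) / sd(x)
}

simulate_pupil_trace <- function(design, group, pupil_cfg, seed, session_id) {
  fs <- pupil_cfg$fs
  sb <- stim_blocks(design)
  total_s <- design_n_scans(design) * design_tr(design)
  n <- round(total_s * fs)
  withr_seed(seed, {
    x <- pupil_cfg$noise_sd * pink_noise(n)
    for (i in seq_len(nrow(sb))) {
      stim <- substr(sb$condition[i], 1, 1)
      amp <- pupil_cfg$amplitude[stim, group]
      x <- x + pupil_block_response(n, round(sb$onset_s[i] * fs) + 1L,
                                    round(sb$duration_s[i] * fs), amp, fs)
    }
    x <- x + 5  # arbitrary raw pupil baseline (a.u.); removed by z-normalisation
    n_blinks <- stats::rpois(1, pupil_cfg$blink_rate_hz * total_s)
    blinks <- NULL
    if (n_blinks > 0) {
      starts <- sort(runif(n_blinks, 0, total_s - 2 * pupil_cfg$blink_dur_s))
      durs <- runif(n_blinks, 0.5, 1.5) * pupil_cfg$blink_dur_s
      blinks <- cbind(starts, pmin(starts + durs, total_s))
      keep <- c(TRUE, diff(starts) > 2 * pupil_cfg$blink_dur_s)
      blinks <- blinks[keep, , drop = FALSE]
      for (i in seq_len(nrow(blinks))) {
        idx <- (round(blinks[i, 1] * fs) + 1L):min(round(blinks[i, 2] * fs), n)
        x[idx] <- 0  # occluded samples; replaced during preprocessing
      }
    }
    pupil_trace(x, fs = fs, blinks = blinks,
                blocks = stim_blocks(design)[, c("onset_s", "condition")],
                session_id = session_id)
  })
}

simulate_li_voxels <- function(li_cfg, group, seed) {
  withr_seed(seed, {
    out <- list()
    for (region in rownames(li_cfg$target)) {
      liv <- li_cfg$target[region, group]
      mu_l <- 1 + liv
      mu_r <- 1 - liv
      out[[region]] <- list(
        left = rgamma(li_cfg$n_voxels, shape = 6, rate = 6 / mu_l),
        right = rgamma(li_cfg$n_voxels, shape = 6, rate = 6 / mu_r))
    }
    out
  })
}

#' Generate a complete synthetic cohort
#'
#' For every subject of both groups: a fresh pseudo-randomised block design,
#' generative DCM parameters drawn around the group means, a BOLD dataset
#' simulated at the configured SNR, a pupil trace (condition-dependent block
#' responses plus pink noise and blink annotations), and suprathreshold
#' voxel-value sets for lateralization-index computation. Everything is
#' deterministically derived from the config's master seed.
#'
#' @param config a [cohort_config()].
#' @param groups which groups to generate (default both).
#' @return A `cohort` list: `subjects` (each with `subject_id`, `group`,
#'   `design`, `inputs`, `params`, `bold`, `pupil`, `li`), `config`.
#' @export
generate_cohort <- function(config, groups = c("RH", "LH")) {
  subjects <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    goff <- match(g, c("RH", "LH")) * 100000L
    for (s in seq_len(config$n_per_group)) {
      # antithetic pairs share a seed; the even member mirrors the draws
      flip <- isTRUE(config$antithetic) && s %% 2L == 0L
      pseed <- if (flip) config$seed + goff + s - 1L else config$seed + goff + s
      sseed <- config$seed + goff + s
      sid <- sprintf("%s%02d", g, s)
      dargs <- config$design
      microtime <- dargs$microtime_dt_s
      dargs$microtime_dt_s <- NULL
      design <- do.call(build_block_design, c(dargs, list(seed = sseed)))
      inputs <- build_inputs(design, microtime_dt_s = microtime)
      params <- sample_subject_params(config, g, seed = pseed + 1L, flip = flip)
      bold <- simulate_bold(params, inputs, snr = config$snr, seed = sseed + 2L,
                            subject_id = sid, group = g)
      pupil <- simulate_pupil_trace(design, g, config$pupil, seed = sseed + 3L,
                                    session_id = sid)
      li <- simulate_li_voxels(config$li, g, seed = sseed + 4L)
      subjects[[sid]] <- list(subject_id = sid, group = g, design = design,
                              inputs = inputs, params = params, bold = bold,
                              pupil = pupil, li = li, seed = sseed)
    }
  }
  structure(list(subjects = subjects, config = config), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  gr <- table(vapply(x$subjects, function(s) s$group, character(1)))
  cat("<cohort> ", paste(names(gr), gr, sep = " = ", collapse = ", "),
      "; seed ", x$config$seed, ", snr ", x$config$snr,
      ", hash ", substr(x$config$hash, 1, 8), "\n", sep = "")
  invisible(x)
}
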