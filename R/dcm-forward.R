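#' Default haemodynamic parameters
#'
#' Classical balloon-windkessel constants: vasodilatory signal decay
#' `kappa` = 0.64 /s, flow feedback `gamma` = 0.32 /s, mean transit time
#' `tau` = 2.0 s, vessel stiffness `alpha` = 0.32, resting oxygen extraction
#' `E0` = 0.4, resting venous volume fraction `V0` = 0.04.
#'
#' @param regions region labels (one parameter row each).
#' @return regions x 6 matrix with columns `kappa`, `gamma`, `tau`, `alpha`,
#'   `E0`, `V0`.
#' @export
default_hemo <- function(regions = .regions) {
  h <- matrix(rep(c(0.64, 0.32, 2.0, 0.32, 0.4, 0.04), each = length(regions)),
              nrow = length(regions),
              dimnames = list(regions, c("kappa", "gamma", "tau", "alpha", "E0", "V0")))
  h
}

#' DCM parameter set
#'
#' Real-valued connection strengths (Hz) respecting a structure spec, plus
#' per-region haemodynamic parameters. Entries outside the spec's masks must
#' be exactly zero and the diagonal of `A` strictly negative.
#'
#' @param spec a [dcm_spec()].
#' @param A endogenous rate matrix (Hz).
#' @param B named list of modulatory rate matrices, one per input (missing
#'   inputs default to zero).
#' @param C driving-input rate matrix (Hz).
#' @param hemo per-region haemodynamic parameters as from [default_hemo()].
#' @return a `dcm_params` object.
#' @export
dcm_params <- function(spec, A, B = NULL, C = NULL, hemo = default_hemo(spec$regions)) {
  n <- length(spec$regions)
  m <- length(spec$input_labels)
  A <- as.matrix(A)
  if (is.null(C)) C <- matrix(0, n, m)
  C <- as.matrix(C)
  Bfull <- setNames(rep(list(matrix(0, n, n)), m), spec$input_labels)
  if (!is.null(B)) for (nm in names(B)) Bfull[[nm]] <- as.matrix(B[[nm]])
  if (any(A[spec$a_mask == 0L] != 0)) abort("A has entries outside the mask")
  if (any(diag(A) >= 0)) abort("A diagonal must be strictly negative")
  if (any(C[spec$c_mask == 0L] != 0)) abort("C has entries outside the mask")
  for (nm in spec$input_labels) {
    if (any(Bfull[[nm]][spec$b_masks[[nm]] == 0L] != 0)) {
      abort(paste0("B[", nm, "] has entries outside the mask"))
    }
  }
  hemo <- as.matrix(hemo)
  if (any(hemo <= 0) || any(hemo[, "E0"] >= 1) || any(hemo[, "alpha"] >= 1)) {
    abort("invalid haemodynamic parameters")
  }
  dimnames(A) <- list(spec$regions, spec$regions)
  dimnames(C) <- list(spec$regions, spec$input_labels)
  Bfull <- lapply(Bfull, function(b) {
    dimnames(b) <- list(spec$regions, spec$regions)
    b
  })
  structure(list(A = A, B = Bfull, C = C, hemo = hemo, spec = spec),
            class = "dcm_params")
}

#' Bilinear neural state derivative
#'
#' `dz/dt = (A + sum_j u_j B_j) z + C u`: endogenous coupling `A`, input-
#' dependent modulation `B_j`, driving inputs `C`.
#'
#' @param z neural state vector (one element per region).
#' @param u input vector (one element per input).
#' @param params a [dcm_params()].
#' @return derivative vector `dz/dt` (Hz scale).
#' @export
neural_derivative <- function(z, u, params) {
  n <- nrow(params$A)
  if (length(z) != n || length(u) != length(params$B)) {
    abort("dimension mismatch", class = "facedcm_config_error")
  }
  J <- params$A
  for (j in seq_along(u)) if (u[j] != 0) J <- J + u[j] * params$B[[j]]
  unname(drop(J %*% z + params$C %*% u))
}

#' Balloon-windkessel state derivative for one region
#'
#' States: vasodilatory signal `s`, blood inflow `f`, venous volume `v`,
#' deoxyhaemoglobin content `q`. At rest (`s = 0`, `f = v = q = 1`) and zero
#' neural input the derivative vanishes.
#'
#' @param h numeric state vector `c(s, f, v, q)`.
#' @param z scalar neural activity of the region.
#' @param hemo named vector or single-row matrix with `kappa`, `gamma`,
#'   `tau`, `alpha`, `E0` (and optionally `V0`, unused here).
#' @return derivative vector `c(ds, df, dv, dq)`.
#' @export
hemodynamic_derivative <- function(h, z, hemo) {
  hemo <- drop(as.matrix(hemo))
  s <- h[1]; f <- h[2]; v <- h[3]; q <- h[4]
  if (f <= 0 || v <= 0 || q <= 0) {
    abort("non-positive flow/volume state", class = "facedcm_config_error")
  }
  fv <- v^(1 / hemo["alpha"])
  E <- 1 - (1 - hemo["E0"])^(1 / f)
  unname(c(z - hemo["kappa"] * s - hemo["gamma"] * (f - 1),
           s,
           (f - fv) / hemo["tau"],
           (f * E / hemo["E0"] - fv * q / v) / hemo["tau"]))
}

#' BOLD readout from haemodynamic states
#'
#' Percent signal change `100 V0 [k1 (1-q) + k2 (1-q/v) + k3 (1-v)]` with
#' `k1 = 7 E0`, `k2 = 2`, `k3 = 2 E0 - 0.2`.
#'
#' @param v,q venous volume and deoxyhaemoglobin states.
#' @param E0,V0 resting extraction fraction and venous volume fraction.
#' @return BOLD signal (percent).
#' @export
bold_signal <- function(v, q, E0 = 0.4, V0 = 0.04) {
  100 * V0 * (7 * E0 * (1 - q) + 2 * (1 - q / v) + (2 * E0 - 0.2) * (1 - v))
}

# noiseless BOLD prediction at scan times (scans x regions matrix)
dcm_predict <- function(params, inputs, n_scans = inputs$n_scans) {
  U <- inputs$u
  need <- n_scans * inputs$bins_per_tr
  if (nrow(U) < need) abort("inputs shorter than requested scan count")
  U <- U[seq_len(need), , drop = FALSE]
  Barr <- unlist(params$B, use.names = FALSE)
  scan_idx <- as.integer((seq_len(n_scans) - 1L) * inputs$bins_per_tr)
  Y <- .dcm_integrate_cpp(params$A, Barr, params$C, U, params$hemo,
                          inputs$dt, scan_idx)
  colnames(Y) <- rownames(params$A)
  Y
}

#' Simulate a BOLD dataset from a DCM
#'
#' Integrates the joint neural and haemodynamic system at microtime
#' resolution (fixed-step 4th-order Runge-Kutta, one step per microtime
#' bin), reads the BOLD signal at scan times, and adds i.i.d. Gaussian
#' observation noise per region.
#'
#' @param params a [dcm_params()].
#' @param inputs a [build_inputs()] object.
#' @param n_scans number of scans (default: all scans covered by `inputs`).
#' @param noise_sd observation noise standard deviation, or `"snr"` scaling
#'   via the `snr` argument.
#' @param snr if given (and `noise_sd` is NULL), noise_sd is set per region
#'   to `sd(noiseless series) / snr`.
#' @param seed integer seed for the observation noise.
#' @param subject_id,group metadata carried in the result.
#' @return A `bold_dataset`: list with `series` (scans x regions), `tr_s`,
#'   `subject_id`, `group`, `noise_sd`, `snr`, `seed`.
#' @export
simulate_bold <- function(params, inputs, n_scans = inputs$n_scans,
                          noise_sd = NULL, snr = NULL, seed = 1,
                          subject_id = "sim", group = NA_character_) {
  Y <- dcm_predict(params, inputs, n_scans)
  if (is.null(noise_sd)) {
    noise_sd <- if (is.null(snr)) 0 else apply(Y, 2L, sd) / snr
  }
  noise_sd <- rep_len(noise_sd, ncol(Y))
  if (any(noise_sd > 0)) {
    E <- withr_seed(seed, matrix(rnorm(length(Y)), nrow(Y), ncol(Y)))
    Y <- Y + sweep(E, 2L, noise_sd, `*`)
  }
  structure(list(series = Y, tr_s = inputs$tr_s, subject_id = subject_id,
                 group = group, noise_sd = noise_sd, snr = snr, seed = seed),
            class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat("<bold_dataset> ", x$subject_id, ": ", nrow(x$series), " scans x ",
      ncol(x$series), " regions, TR ", x$tr_s, " s\n", sep = "")
  invisible(x)
}
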