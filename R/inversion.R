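#' Parameter map of a DCM spec
#'
#' Enumerates the free parameters implied by a structure spec in a fixed
#' order: A diagonal (self-connections), A off-diagonal, modulatory B per
#' input, driving C, then (optionally) per-region haemodynamic parameters
#' as log-deviations `ltau` (transit time) and `lE0` (resting extraction)
#' from their defaults.
#'
#' @param spec a [dcm_spec()].
#' @param hemo_free include `ltau`/`lE0` per region (default TRUE).
#' @return tibble with columns `name`, `type`, `row`, `col`, `input`.
#' @export
param_map <- function(spec, hemo_free = TRUE) {
  rg <- spec$regions
  n <- length(rg)
  rows <- list()
  add <- function(name, type, row = NA_integer_, col = NA_integer_,
                  input = NA_character_) {
    rows[[length(rows) + 1L]] <<- list(name = name, type = type,
                                       row = row, col = col, input = input)
  }
  for (i in seq_len(n)) add(paste0("A:", rg[i], "->", rg[i]), "A_diag", i, i)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (i != j && spec$a_mask[i, j] == 1L) {
      add(paste0("A:", rg[j], "->", rg[i]), "A_off", i, j)
    }
  }
  for (nm in spec$input_labels) {
    bm <- spec$b_masks[[nm]]
    for (j in seq_len(n)) for (i in seq_len(n)) {
      if (bm[i, j] == 1L) add(paste0("B:", nm, ":", rg[j], "->", rg[i]), "B", i, j, nm)
    }
  }
  for (j in seq_along(spec$input_labels)) for (i in seq_len(n)) {
    if (spec$c_mask[i, j] == 1L) {
      add(paste0("C:", spec$input_labels[j], "->", rg[i]), "C", i, j,
          spec$input_labels[j])
    }
  }
  if (hemo_free) {
    for (i in seq_len(n)) add(paste0("ltau:", rg[i]), "ltau", i)
    for (i in seq_len(n)) add(paste0("lE0:", rg[i]), "lE0", i)
  }
  dplyr::bind_rows(rows)
}

#' Default shrinkage priors
#'
#' Zero-mean Gaussian shrinkage priors on masked parameters: variance 1/16
#' for endogenous off-diagonal and modulatory parameters, 1 for driving
#' inputs, and 1/256 for deviations of the self-connections around their
#' prior mean of -0.5 Hz. Haemodynamic log-deviations get variance 1/16.
#' Observation noise is parameterised as a per-region log-precision with a
#' Gaussian (log-normal) hyperprior.
#'
#' @param spec a [dcm_spec()].
#' @param a_off_var,b_var,c_var,a_diag_var prior variances per class.
#' @param a_diag_mean prior mean of self-connections (Hz).
#' @param hemo_free estimate `ltau`/`lE0` (default TRUE); other haemodynamic
#'   constants stay fixed.
#' @param hemo_var prior variance of the haemodynamic log-deviations.
#' @param lambda_mean,lambda_var hyperprior moments of the log noise
#'   precision. `lambda_mean = NULL` (default) makes the mean data-adaptive:
#'   `log(1 / var(y_r)) + lambda_offset` per region, a deliberately
#'   optimistic (tight) noise hyperprior that keeps the likelihood
#'   informative during early ascent.
#' @param lambda_offset log-precision offset above the total data variance
#'   used by the adaptive hyperprior (default 2).
#' @return a `dcm_priors` list: `map` (with `prior_mean`, `prior_var`
#'   columns), `lambda_mean`, `lambda_var`.
#' @export
default_priors <- function(spec, a_off_var = 1 / 16, b_var = 1 / 16,
                           c_var = 1, a_diag_mean = -0.5, a_diag_var = 1 / 256,
                           hemo_free = TRUE, hemo_var = 1 / 16,
                           lambda_mean = NULL, lambda_var = 1,
                           lambda_offset = 2) {
  map <- param_map(spec, hemo_free = hemo_free)
  map$prior_mean <- dplyr::case_match(map$type,
                                      "A_diag" ~ a_diag_mean,
                                      .default = 0)
  map$prior_var <- dplyr::case_match(map$type,
                                     "A_diag" ~ a_diag_var,
                                     "A_off" ~ a_off_var,
                                     "B" ~ b_var,
                                     "C" ~ c_var,
                                     c("ltau", "lE0") ~ hemo_var)
  structure(list(map = map, lambda_mean = lambda_mean, lambda_var = lambda_var,
                 lambda_offset = lambda_offset, spec = spec),
            class = "dcm_priors")
}

# fast theta -> (A, B, C, hemo) builder; returns closures bound to the spec
make_theta_builder <- function(spec, map, hemo0 = default_hemo(spec$regions)) {
  n <- length(spec$regions)
  m <- length(spec$input_labels)
  a_rows <- map$type %in% c("A_diag", "A_off")
  a_idx <- map$row[a_rows] + n * (map$col[a_rows] - 1L)
  b_rows <- map$type == "B"
  b_input <- match(map$input[b_rows], spec$input_labels)
  b_idx <- map$row[b_rows] + n * (map$col[b_rows] - 1L) + n * n * (b_input - 1L)
  c_rows <- map$type == "C"
  c_idx <- map$row[c_rows] + n * (map$col[c_rows] - 1L)
  ltau_rows <- map$type == "ltau"
  lE0_rows <- map$type == "lE0"
  ltau_reg <- map$row[ltau_rows]
  lE0_reg <- map$row[lE0_rows]
  function(theta) {
    A <- matrix(0, n, n)
    A[a_idx] <- theta[a_rows]
    Barr <- numeric(n * n * m)
    Barr[b_idx] <- theta[b_rows]
    C <- matrix(0, n, m)
    C[c_idx] <- theta[c_rows]
    hemo <- hemo0
    if (any(ltau_rows)) hemo[ltau_reg, "tau"] <- hemo0[ltau_reg, "tau"] * exp(theta[ltau_rows])
    if (any(lE0_rows)) hemo[lE0_reg, "E0"] <- pmin(hemo0[lE0_reg, "E0"] * exp(theta[lE0_rows]), 0.95)
    list(A = A, Barr = Barr, C = C, hemo = hemo)
  }
}

#' Variational Laplace inversion of a DCM
#'
#' Estimates the posterior density over DCM parameters under the Laplace
#' (Gaussian) approximation by Gauss-Newton ascent on the negative free
#' energy with Levenberg-Marquardt regularisation. Gradients of the forward
#' model are obtained by central finite differences; per-region noise
#' log-precisions are optimised jointly under a Gaussian hyperprior. Data
#' and predictions are mean-centred per region, so the fit is invariant to
#' baseline offsets.
#'
#' @param spec a [dcm_spec()] defining the model structure.
#' @param data a `bold_dataset` (or scans x regions matrix).
#' @param inputs a [build_inputs()] object aligned to the same scan grid.
#' @param priors a [default_priors()] object.
#' @param max_iter iteration cap (default 128).
#' @param tol convergence tolerance on the free-energy increase (nats,
#'   default 1e-4), required on two consecutive accepted iterations.
#' @param fd_step finite-difference step on the parameter scale.
#' @param init optional named vector of starting values for (a subset of)
#'   the free parameters; defaults to the prior means.
#' @param restarts number of additional seeded restarts from Gaussian
#'   perturbations of the starting point (sd `restart_sd`); the restart with
#'   the highest free energy is returned.
#' @param restart_sd,restart_seed perturbation scale and seed for restarts.
#' @return A `dcm_posterior`: named posterior `mean`, covariance `cov`,
#'   negative free energy `F`, accepted-iteration `trace`, `converged` flag,
#'   per-region `lambda` (log noise precisions), and the prior `map`.
#' @export
variational_laplace <- function(spec, data, inputs, priors = default_priors(spec),
                                max_iter = 128, tol = 1e-4, fd_step = 1e-4,
                                init = NULL, restarts = 0, restart_sd = 0.1,
                                restart_seed = 1, warmup = 4L,
                                tau_init = 0.5, tau_down = 2, tau_up = 4) {
  if (restarts > 0) {
    base_init <- init
    fits <- lapply(0:restarts, function(k) {
      fr <- priors$map$prior_var > 0
      start <- setNames(priors$map$prior_mean[fr], priors$map$name[fr])
      if (!is.null(base_init)) {
        common <- intersect(names(base_init), names(start))
        start[common] <- base_init[common]
      }
      ik <- base_init
      if (k > 0) {
        # perturbations scale with each parameter's prior sd
        noise <- withr_seed(restart_seed + k,
                            rnorm(sum(fr), 0, restart_sd * sqrt(priors$map$prior_var[fr])))
        ik <- start + noise
      }
      variational_laplace(spec, data, inputs, priors, max_iter = max_iter,
                          tol = tol, fd_step = fd_step, init = ik)
    })
    Fs <- vapply(fits, function(f) f$F, 0)
    return(fits[[which.max(Fs)]])
  }
  Y <- if (inherits(data, "bold_dataset")) data$series else as.matrix(data)
  n_scans <- nrow(Y)
  nreg <- ncol(Y)
  if (nreg != length(spec$regions)) abort("data/spec region mismatch")
  need <- n_scans * inputs$bins_per_tr
  if (nrow(inputs$u) < need) abort("inputs do not cover the data's scan grid")
  U <- inputs$u[seq_len(need), , drop = FALSE]
  scan_idx <- as.integer((seq_len(n_scans) - 1L) * inputs$bins_per_tr)
  dt <- inputs$dt

  Yc <- sweep(Y, 2L, colMeans(Y))
  y <- as.vector(Yc)
  reg_of <- rep(seq_len(nreg), each = n_scans)
  N <- length(y)

  map <- priors$map
  free <- which(map$prior_var > 0)
  fixed_theta <- map$prior_mean
  p <- length(free)
  mu0 <- map$prior_mean[free]
  v0 <- map$prior_var[free]
  iS0 <- diag(1 / v0, p)
  ldS0 <- sum(log(v0))

  build <- make_theta_builder(spec, map)
  predict_theta <- function(th_free) {
    th <- fixed_theta
    th[free] <- th_free
    pb <- build(th)
    Yp <- .dcm_integrate_cpp(pb$A, pb$Barr, pb$C, U, pb$hemo, dt, scan_idx)
    as.vector(sweep(Yp, 2L, colMeans(Yp)))
  }
  # divergence of a trial point is treated as a rejected step, not an error
  safe_predict <- function(th_free) {
    tryCatch(predict_theta(th_free), error = function(e) NULL)
  }

  jacobian <- function(th_free) {
    J <- matrix(0, N, p)
    for (k in seq_len(p)) {
      tp <- th_free; tp[k] <- tp[k] + fd_step
      tm <- th_free; tm[k] <- tm[k] - fd_step
      gp <- safe_predict(tp)
      gm <- safe_predict(tm)
      if (is.null(gp) || is.null(gm)) abort("divergence in finite-difference step")
      J[, k] <- (gp - gm) / (2 * fd_step)
    }
    J
  }

  vl <- priors$lambda_var
  l0 <- if (is.null(priors$lambda_mean)) {
    vy <- pmax(apply(Yc, 2L, var), 1e-12)
    -log(vy) + (priors$lambda_offset %||% 2)
  } else {
    rep_len(priors$lambda_mean, nreg)
  }
  n_r <- tabulate(reg_of, nreg)

  # free energy and lambda/Sigma coordinate ascent at a given (e, J)
  fe_at <- function(e, J, d, lambda, update_lambda = TRUE) {
    n_rep <- if (update_lambda) 4L else 1L
    for (rep in seq_len(n_rep)) {
      Pi <- exp(lambda)[reg_of]
      P <- crossprod(J * Pi, J) + iS0
      R <- tryCatch(chol(P), error = function(err) NULL)
      if (is.null(R)) return(NULL)
      Sigma <- chol2inv(R)
      if (!update_lambda) break
      G <- vapply(seq_len(nreg), function(r) {
        idx <- reg_of == r
        sum(e[idx]^2) + sum((J[idx, , drop = FALSE] %*% Sigma) * J[idx, , drop = FALSE])
      }, 0)
      if (any(!is.finite(G))) return(NULL)
      for (it in 1:8) {
        g1 <- 0.5 * n_r - 0.5 * exp(lambda) * G - (lambda - l0) / vl
        g2 <- -0.5 * exp(lambda) * G - 1 / vl
        step <- g1 / g2
        lambda <- lambda - pmax(pmin(step, 4), -4)
        if (max(abs(step)) < 1e-8) break
      }
    }
    Pi <- exp(lambda)[reg_of]
    P <- crossprod(J * Pi, J) + iS0
    R <- tryCatch(chol(P), error = function(err) NULL)
    if (is.null(R)) return(NULL)
    Sigma <- chol2inv(R)
    G <- vapply(seq_len(nreg), function(r) {
      idx <- reg_of == r
      sum(e[idx]^2) + sum((J[idx, , drop = FALSE] %*% Sigma) * J[idx, , drop = FALSE])
    }, 0)
    if (any(!is.finite(G))) return(NULL)
    s_l <- 1 / (0.5 * exp(lambda) * G + 1 / vl)
    Fv <- -0.5 * sum(exp(lambda) * G) + 0.5 * sum(n_r * lambda) -
      0.5 * N * log(2 * pi) -
      0.5 * sum(d^2 / v0) - 0.5 * sum(diag(Sigma) / v0) -
      0.5 * ldS0 - sum(log(diag(R))) + 0.5 * p +
      -0.5 * sum((lambda - l0)^2) / vl - 0.5 * sum(s_l) / vl +
      0.5 * sum(log(s_l / vl)) + 0.5 * nreg
    list(F = Fv, Sigma = Sigma, lambda = lambda, P = P)
  }

  mu <- mu0
  if (!is.null(init)) {
    nm <- intersect(names(init), map$name[free])
    mu[match(nm, map$name[free])] <- init[nm]
  }
  lambda <- l0

  best <- NULL
  trace <- numeric(0)
  tau <- tau_init
  mu_try <- mu
  converged <- FALSE
  small_steps <- 0L
  iter <- 0L
  n_accepted <- 0L
  warmup <- as.integer(warmup)

  while (iter < max_iter) {
    iter <- iter + 1L
    g <- safe_predict(mu_try)
    if (is.null(g) || any(!is.finite(g)) || max(abs(g)) > 1e6) {
      if (is.null(best)) {
        # unstable starting point: contract towards the prior mean
        mu_try <- (mu_try + mu0) / 2
        if (max(abs(mu_try - mu0)) < 1e-10) {
          abort(sprintf("divergent prediction at iteration %d", iter))
        }
        next
      }
      tau <- tau * 4
      mu_try <- lm_step(best, iS0, mu0, tau)
      next
    }
    e <- y - g
    J <- tryCatch(jacobian(mu_try), error = function(err) NULL)
    if (is.null(J)) {
      if (is.null(best)) { mu_try <- (mu_try + mu0) / 2; next }
      tau <- tau * tau_up
      mu_try <- lm_step(best, iS0, mu0, tau)
      next
    }
    d <- mu_try - mu0
    st <- fe_at(e, J, d, lambda, update_lambda = n_accepted >= warmup)
    if (is.null(st) || !is.finite(st$F)) {
      if (is.null(best)) { mu_try <- (mu_try + mu0) / 2; next }
      tau <- tau * 4
      mu_try <- lm_step(best, iS0, mu0, tau)
      next
    }
    if (is.null(best) || st$F > best$F) {
      dF <- if (is.null(best)) Inf else st$F - best$F
      best <- list(mu = mu_try, F = st$F, Sigma = st$Sigma, lambda = st$lambda,
                   J = J, e = e, P = st$P)
      lambda <- st$lambda
      trace <- c(trace, st$F)
      tau <- max(tau / tau_down, 1e-6)
      n_accepted <- n_accepted + 1L
      small_steps <- if (dF < tol && n_accepted > warmup) small_steps + 1L else 0L
      if (small_steps >= 2L) { converged <- TRUE; break }
    } else {
      tau <- tau * tau_up
      if (tau > 1e6) { converged <- small_steps >= 1L; break }
    }
    mu_try <- lm_step(best, iS0, mu0, tau)
  }

  if (is.null(best)) {
    abort("no iteration produced a finite free energy", class = "facedcm_config_error")
  }
  mean_full <- fixed_theta
  mean_full[free] <- best$mu
  names(mean_full) <- map$name
  cov <- best$Sigma
  dimnames(cov) <- list(map$name[free], map$name[free])
  structure(list(mean = mean_full, free = map$name[free], cov = cov,
                 F = best$F, trace = trace, converged = converged,
                 iterations = iter, lambda = setNames(best$lambda, spec$regions),
                 map = map, family_id = spec$family_id, combo = spec$combo,
                 settings = list(max_iter = max_iter, tol = tol, fd_step = fd_step)),
            class = "dcm_posterior")
}

# Levenberg-Marquardt step from the best accepted state
lm_step <- function(best, iS0, mu0, tau) {
  Pi <- exp(best$lambda)
  # rebuild J'PiJ from stored P (already includes iS0)
  P <- best$P
  rhs <- crossprod(best$J, best$e * rep(Pi, each = nrow(best$J) / length(Pi))) -
    iS0 %*% (best$mu - mu0)
  D <- diag(pmax(diag(P), 1e-8), nrow(P))
  step <- tryCatch(solve(P + tau * D, rhs), error = function(e) NULL)
  if (is.null(step)) step <- rhs / (diag(P) * (1 + tau))
  drop(best$mu + step)
}

#' Log model evidence approximation
#'
#' Returns the negative free energy of a converged (or flagged) posterior,
#' the variational lower bound on the log model evidence used for model
#' comparison.
#'
#' @param posterior a [variational_laplace()] result.
#' @return scalar (nats).
#' @export
log_evidence <- function(posterior) {
  stopifnot(inherits(posterior, "dcm_posterior"))
  posterior$F
}

#' @export
print.dcm_posterior <- function(x, ...) {
  cat("<dcm_posterior> ", length(x$free), " free parameters, F = ",
      format(x$F, digits = 6), ", ",
      if (x$converged) "converged" else "not converged",
      " in ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' @export
tidy.dcm_posterior <- function(x, ...) {
  sdv <- setNames(rep(0, length(x$mean)), names(x$mean))
  sdv[x$free] <- sqrt(pmax(diag(x$cov), 0))
  tibble(term = names(x$mean), estimate = unname(x$mean),
         std.error = unname(sdv), type = x$map$type)
}

#' @export
glance.dcm_posterior <- function(x, ...) {
  tibble(logLik = x$F, n_free = length(x$free),
         iterations = x$iterations, converged = x$converged)
}
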