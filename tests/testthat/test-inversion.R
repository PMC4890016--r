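test_that("default priors implement tight shrinkage over the masked structure", {
  spec <- build_endogenous_skeleton()
  pr <- default_priors(spec)
  m <- pr$map
  expect_equal(m$prior_mean[m$type == "A_diag"], rep(-0.5, 6))
  expect_equal(m$prior_var[m$type == "A_diag"], rep(1 / 256, 6))
  expect_equal(m$prior_var[m$type == "A_off"], rep(1 / 16, 16))
  expect_equal(m$prior_var[m$type == "C"], rep(1, 2))
  # dimensionality: mask ones plus haemodynamic free parameters
  expect_equal(nrow(m), 6 + 16 + 0 + 2 + 12)
  spec_b <- facedcm:::generating_spec(
    cohort_config(n_per_group = 1, seed = 1), "RH")
  mb <- default_priors(spec_b)$map
  n_b <- sum(vapply(spec_b$b_masks, sum, 0L))
  expect_equal(nrow(mb), 6 + 16 + n_b + 2 + 12)
  expect_equal(sum(mb$type == "B"), 8L)
  # parameters outside the masks are absent entirely
  expect_false(any(grepl("^B:faces\\|", mb$name)))
})

test_that("uninformative data leaves the posterior at the prior", {
  spec <- toy_spec()
  inputs <- toy_inputs(n_scans = 50)
  # data simulated noiselessly from the prior mean (C = 0: flat response)
  p0 <- dcm_params(spec, diag(-0.5, 2), NULL, matrix(0, 2, 1))
  flat <- simulate_bold(p0, inputs, noise_sd = 0.05, seed = 1)
  pr <- default_priors(spec, hemo_free = FALSE)
  post <- variational_laplace(spec, flat, inputs, pr, max_iter = 32)
  m <- pr$map
  prior_sd <- sqrt(m$prior_var)
  dev <- abs(post$mean - m$prior_mean)
  expect_true(all(dev <= prior_sd + 1e-9))
})

test_that("linearised regime matches the conjugate Bayesian regression posterior", {
  # tiny inputs, only C free: the forward map is linear in C up to O(C^2)
  spec <- toy_spec()
  inputs <- toy_inputs(n_scans = 60)
  # freeze everything except C (haemodynamics and A at their true values)
  pr <- default_priors(spec, a_off_var = 0, a_diag_var = 0, hemo_free = FALSE)
  c_true <- 0.005
  truth <- toy_params(spec, a21 = 0, c1 = c_true)
  noise <- 1e-4
  dat <- simulate_bold(truth, inputs, noise_sd = noise, seed = 3)
  # pin the noise hyperparameter so both routes use the same precision
  pr$lambda_mean <- -2 * log(noise)
  pr$lambda_var <- 1e-10
  post <- variational_laplace(spec, dat, inputs, pr, max_iter = 32)
  # oracle: ridge regression of the centred data on the unit-C response
  unit <- simulate_bold(toy_params(spec, a21 = 0, c1 = 1e-4), inputs,
                        noise_sd = 0)$series / 1e-4
  x <- unit[, 1] - mean(unit[, 1])
  y <- dat$series[, 1] - mean(dat$series[, 1])
  v0 <- 1                                    # prior variance of C
  prec <- 1 / noise^2
  post_var <- 1 / (prec * sum(x^2) + 1 / v0)
  post_mean <- post_var * prec * sum(x * y)
  expect_lt(abs(unname(post$mean["C:u1->r1"]) - post_mean), 1e-3)
  expect_equal(unname(sqrt(post$cov["C:u1->r1", "C:u1->r1"])),
               sqrt(post_var), tolerance = 1e-2)
})

test_that("free energy trace is monotone over accepted iterations", {
  spec <- toy_spec(b_on = TRUE)
  inputs <- toy_inputs(n_scans = 40)
  for (s in 1:20) {
    p <- toy_params(spec, a21 = runif(1, 0.1, 0.4), b21 = runif(1, -0.2, 0.2),
                    c1 = runif(1, 0.3, 0.9))
    dat <- simulate_bold(p, inputs, snr = 1, seed = s)
    post <- variational_laplace(spec, dat, inputs,
                                default_priors(spec, hemo_free = FALSE),
                                max_iter = 24)
    expect_false(is.unsorted(post$trace))
    expect_true(is.finite(post$F))
    ev <- eigen(post$cov, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("identical data and settings give identical evidence", {
  spec <- toy_spec()
  inputs <- toy_inputs(n_scans = 40)
  dat <- simulate_bold(toy_params(spec), inputs, snr = 2, seed = 7)
  pr <- default_priors(spec, hemo_free = FALSE)
  f1 <- log_evidence(variational_laplace(spec, dat, inputs, pr, max_iter = 16))
  f2 <- log_evidence(variational_laplace(spec, dat, inputs, pr, max_iter = 16))
  expect_identical(f1, f2)
})

test_that("evidence penalises superfluous parameters and rewards true structure", {
  spec_min <- toy_spec(b_on = FALSE)
  spec_b <- toy_spec(b_on = TRUE)
  inputs <- toy_inputs(n_scans = 60)
  pr_min <- default_priors(spec_min, hemo_free = FALSE)
  pr_b <- default_priors(spec_b, hemo_free = FALSE)
  # (a) irrelevant extra parameter (true B = 0) lowers F on average
  dF_extra <- vapply(1:6, function(s) {
    dat <- simulate_bold(toy_params(spec_min, a21 = 0.35, c1 = 0.7), inputs,
                         snr = 2, seed = s)
    f_min <- log_evidence(variational_laplace(spec_min, dat, inputs, pr_min, max_iter = 24))
    f_b <- log_evidence(variational_laplace(spec_b, dat, inputs, pr_b, max_iter = 24))
    f_b - f_min
  }, 0)
  expect_lt(mean(dF_extra), 0)
  # (b) the generating model beats a model missing a strong true modulation
  wins <- vapply(1:10, function(s) {
    dat <- simulate_bold(toy_params(spec_b, a21 = 0.2, b21 = 0.35, c1 = 0.7),
                         inputs, snr = 2, seed = 100 + s)
    f_b <- log_evidence(variational_laplace(spec_b, dat, inputs, pr_b, max_iter = 24))
    f_min <- log_evidence(variational_laplace(spec_min, dat, inputs, pr_min, max_iter = 24))
    f_b >= f_min
  }, TRUE)
  expect_gte(sum(wins), 8L)
})

test_that("posterior shrinks to the prior as prior variance vanishes", {
  spec <- toy_spec()
  inputs <- toy_inputs(n_scans = 40)
  dat <- simulate_bold(toy_params(spec, a21 = 0.35), inputs, snr = 2, seed = 5)
  devs <- vapply(c(1 / 4, 1 / 64, 1 / 1024), function(v) {
    pr <- default_priors(spec, a_off_var = v, hemo_free = FALSE)
    post <- variational_laplace(spec, dat, inputs, pr, max_iter = 24)
    abs(post$mean["A:r1->r2"])
  }, 0)
  expect_true(all(diff(devs) < 0))
})
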