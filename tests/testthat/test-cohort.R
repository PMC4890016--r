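test_that("group tables carry the expected structure and anchor values", {
  tab <- group_connectivity_table()
  expect_equal(sum(tab$class == "endogenous"), 16L)
  expect_equal(sum(tab$class == "driving"), 2L)
  # anchor: right-hander endogenous left-to-right FFA coupling
  row <- tab[tab$class == "endogenous" & tab$connection == "FFA_L->FFA_R", ]
  expect_equal(row$rh_mean, 0.228)
  expect_equal(row$rh_sd, 0.147)
  # anchor: driving input onto right EVC (left-visual-field stimulation)
  drv <- tab[tab$class == "driving" & tab$connection == "LVF->EVC_R", ]
  expect_equal(drv$rh_mean, 0.794)
  expect_equal(drv$lh_mean, 0.663)
})

test_that("zero-variance configs reproduce the group means exactly", {
  tab0 <- dplyr::mutate(group_connectivity_table(), rh_sd = 0, lh_sd = 0)
  cfg <- cohort_config(n_per_group = 2, seed = 1, param_table = tab0, a_diag_sd = 0)
  p1 <- sample_subject_params(cfg, "RH", seed = 10)
  p2 <- sample_subject_params(cfg, "RH", seed = 77)
  expect_equal(p1$A, p2$A)
  expect_equal(p1$A["FFA_R", "FFA_L"], 0.228)
  expect_equal(p1$C["EVC_R", "LVF"], 0.794)
  expect_equal(p1$B$faces["OFA_L", "EVC_L"], 0.137)
  expect_true(all(diag(p1$A) == -0.5))
  # left-handers use the other column and the family-F structure
  pl <- sample_subject_params(cfg, "LH", seed = 10)
  expect_equal(pl$C["EVC_R", "LVF"], 0.663)
  expect_equal(pl$B$faces["FFA_L", "EVC_L"], 0.165)  # EVC_L->FFA_L modulated in family F
  expect_equal(p1$B$faces["FFA_L", "EVC_L"], 0)      # but not in family B
  # the configured LH face modulation exceeds the RH one by construction
  expect_gt(pl$B$faces["FFA_L", "EVC_L"], p1$B$faces["FFA_L", "EVC_L"])
})

test_that("sampled parameters follow the configured moments", {
  cfg <- cohort_config(n_per_group = 1, seed = 2)
  n <- 2000
  draws <- vapply(seq_len(n), function(i) {
    sample_subject_params(cfg, "RH", seed = 20000 + i)$A["FFA_R", "FFA_L"]
  }, 0)
  expect_lt(abs(mean(draws) - 0.228), 3 * 0.147 / sqrt(n))
  expect_equal(sd(draws), 0.147, tolerance = 0.1)
  # self connections never cross zero
  diags <- vapply(1:200, function(i) {
    min(diag(sample_subject_params(cfg, "RH", seed = 3000 + i)$A))
  }, 0)
  expect_true(all(diags < 0))
})

test_that("cohort generation is reproducible and internally consistent", {
  cfg <- cohort_config(n_per_group = 2, seed = 42, snr = 1,
                       design = list(n_reps = 1, block_scans = 10, tr_s = 1.45,
                                     n_runs = 1, break_scans = 0))
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$subjects$RH01$bold$series, c2$subjects$RH01$bold$series)
  expect_identical(c1$subjects$LH02$pupil$samples, c2$subjects$LH02$pupil$samples)
  expect_identical(c1$subjects$RH02$li, c2$subjects$RH02$li)
  expect_equal(length(c1$subjects), 4L)
  # provenance metadata
  expect_true(nzchar(cfg$hash))
  # different seeds give different cohorts
  c3 <- generate_cohort(cohort_config(n_per_group = 2, seed = 43, snr = 1,
                                      design = cfg$design))
  expect_false(identical(c1$subjects$RH01$bold$series, c3$subjects$RH01$bold$series))
})

test_that("every generated artifact feeds its downstream stage", {
  cfg <- cohort_config(n_per_group = 1, seed = 8, snr = 1,
                       design = list(n_reps = 1, block_scans = 10, tr_s = 1.45,
                                     n_runs = 1, break_scans = 0),
                       pupil = list(fs = 60,
                                    amplitude = matrix(c(-0.3, -0.15, -0.2, -0.2, -0.1, -0.1),
                                                       3, 2, byrow = TRUE,
                                                       dimnames = list(c("F", "O", "S"),
                                                                       c("RH", "LH"))),
                                    noise_sd = 0.2, blink_rate_hz = 0.2,
                                    blink_dur_s = 0.2))
  co <- generate_cohort(cfg)
  s <- co$subjects[[1]]
  # BOLD -> GLM -> contrast
  fit <- fit_glm(s$bold$series, s$inputs)
  expect_equal(dim(fit$betas), c(6L, 6L))
  expect_true(all(is.finite(fit$contrast_values)))
  # BOLD -> inversion (few iterations: smoke integration, not recovery)
  post <- variational_laplace(s$params$spec, s$bold, s$inputs,
                              default_priors(s$params$spec), max_iter = 3)
  expect_true(is.finite(post$F))
  # pupil -> preprocess -> condition table -> ANOVA input shape
  tab <- condition_averages(preprocess(s$pupil), s$design)
  expect_equal(nrow(tab), 6L)
  expect_true(all(is.finite(tab$value)))
  # LI voxel sets -> bootstrap LI
  li <- bootstrap_li(s$li$FFA$left, s$li$FFA$right, n_boot = 500, seed = 1)
  expect_true(is.finite(li$li) && abs(li$li) <= 1)
})

test_that("null group differences yield calibrated two-sample tests", {
  # equalise the groups: left-hander columns copied from right-handers,
  # identical pupil and LI effects
  tab <- group_connectivity_table()
  tab$lh_mean <- tab$rh_mean
  tab$lh_sd <- tab$rh_sd
  fp <- 0L
  n_sim <- 100
  for (s in seq_len(n_sim)) {
    set.seed(s)
    # two-sample t-test on simulated per-subject parameter draws (the DCM
    # estimates' sampling layer), 10 vs 10
    X <- matrix(rnorm(20 * 6, mean = rep(tab$rh_mean[1:6], each = 20),
                      sd = rep(tab$rh_sd[1:6], each = 20)), 20, 6,
                dimnames = list(NULL, paste0("p", 1:6)))
    r <- ttest_and_fdr(X, mode = "two-sample", group = rep(c("RH", "LH"), each = 10))
    fp <- fp + any(r$significant)
  }
  expect_lt(fp / n_sim, 0.15)
})
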