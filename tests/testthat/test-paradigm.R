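test_that("default block design reproduces the paradigm structure", {
  d <- build_block_design(seed = 7)
  stim <- d[d$condition %in% c("F_LVF", "F_RVF", "O_LVF", "O_RVF", "S_LVF", "S_RVF"), ]
  expect_equal(nrow(d), 84L)
  expect_equal(nrow(stim), 42L)
  expect_true(all(d$duration_s == 14.5))
  expect_equal(unname(table(stim$condition)[sort(unique(stim$condition))]),
               rep(7L, 6L), ignore_attr = TRUE)
  # every stimulus block followed by an equally long fixation block
  idx <- which(d$condition != "FIXATION")
  expect_true(all(d$condition[idx + 1L] == "FIXATION"))
  expect_true(all(d$duration_s[idx + 1L] == d$duration_s[idx]))
  # non-overlapping and ordered
  expect_true(all(diff(d$onset_s) > 0))
  expect_true(all(d$onset_s[-1] >= (d$onset_s + d$duration_s)[-nrow(d)] - 1e-9))
})

test_that("design is deterministic in the seed and respects repetition counts", {
  d1 <- build_block_design(n_reps = 2, n_runs = 2, seed = 3)
  d2 <- build_block_design(n_reps = 2, n_runs = 2, seed = 3)
  d3 <- build_block_design(n_reps = 2, n_runs = 2, seed = 4)
  expect_identical(d1, d2)
  expect_false(identical(d1$condition, d3$condition))
  dmin <- build_block_design(n_reps = 1, n_runs = 1, seed = 1)
  stim <- dmin[dmin$condition != "FIXATION", ]
  expect_equal(nrow(stim), 6L)
  expect_setequal(stim$condition, c("F_LVF", "F_RVF", "O_LVF", "O_RVF", "S_LVF", "S_RVF"))
  # pseudo-randomisation: never three identical conditions in a row
  big <- build_block_design(n_reps = 12, n_runs = 1, seed = 2)
  r <- rle(big$condition[big$condition != "FIXATION"])
  expect_true(all(r$lengths < 3))
})

test_that("invalid design arguments are rejected", {
  expect_error(build_block_design(n_reps = 0), class = "facedcm_config_error")
  expect_error(build_block_design(tr_s = -1), class = "facedcm_config_error")
  expect_error(build_block_design(n_reps = 1, n_runs = 4), class = "facedcm_config_error")
})

test_that("input functions implement the five-regressor coding", {
  d <- build_block_design(seed = 1)
  inp <- build_inputs(d)
  u <- inp$u
  dt <- inp$dt
  # conditional regressors bounded by their parents, hemifields disjoint
  expect_true(all(u[, "faces|RVF"] <= pmin(u[, "faces"], u[, "RVF"])))
  expect_true(all(u[, "faces|LVF"] <= pmin(u[, "faces"], u[, "LVF"])))
  expect_true(all(u[, "RVF"] + u[, "LVF"] <= 1))
  # every face bin is in exactly one hemifield
  expect_equal(u[, "faces"], u[, "faces|RVF"] + u[, "faces|LVF"])
  # total RVF on-time: 21 RVF blocks of 14.5 s (brute-force over the design)
  stim <- d[grepl("_RVF$", d$condition), ]
  expect_equal(sum(u[, "RVF"]) * dt, sum(stim$duration_s))
  expect_equal(sum(u[, "RVF"]) * dt, 304.5)
  # during one face-RVF block only RVF/faces/faces|RVF are on
  fb <- d[d$condition == "F_RVF", ][1, ]
  bin <- round(fb$onset_s / dt) + 5L
  expect_equal(unname(u[bin, ]), c(1, 0, 1, 1, 0))
  ob <- d[d$condition == "O_LVF", ][1, ]
  bin <- round(ob$onset_s / dt) + 5L
  expect_equal(unname(u[bin, ]), c(0, 1, 0, 0, 0))
})

test_that("GLM recovers noiseless betas and filters slow drift", {
  d <- build_block_design(n_reps = 2, n_runs = 1, break_scans = 0, seed = 5)
  inp <- build_inputs(d)
  X <- inp$glm_regressors
  betas <- c(1, 1, 0, 0, 0, 0)
  y <- X %*% betas
  fit <- fit_glm(cbind(roi = y), inp)
  expect_lt(max(abs(fit$betas[1:6, 1] - betas)), 1e-8)
  # face contrast of betas (1,1,0,0,0,0) under (1,1,-1/2...) weights is 2
  expect_equal(unname(fit$contrast_values["[2*F]-[O+S]", 1]), 2, tolerance = 1e-8)
  # drift slower than the cut-off leaves ~ zero contrast after filtering
  n <- nrow(X)
  drift <- sin(2 * pi * seq_len(n) * 1.45 / 400)  # 400 s period > 128 s
  fit_d <- fit_glm(cbind(roi = drift), inp)
  expect_lt(abs(fit_d$contrast_values[1, 1]), 0.05)
  # same drift without filtering leaks into the regressors
  fit_n <- fit_glm(cbind(roi = drift), inp, highpass_cutoff_hz = 1e-6)
  expect_gt(abs(fit_n$contrast_values[1, 1]), abs(fit_d$contrast_values[1, 1]))
})

test_that("GLM rejects mismatched and rank-deficient designs", {
  d <- build_block_design(n_reps = 1, n_runs = 1, seed = 1)
  inp <- build_inputs(d)
  expect_error(fit_glm(matrix(0, 10, 1), inp), class = "facedcm_config_error")
  dup <- inp$glm_regressors[, 1]
  expect_error(fit_glm(matrix(rnorm(inp$n_scans), ncol = 1), inp, nuisance = cbind(dup, dup)),
               class = "facedcm_rank_error")
})

test_that("first eigenvariate matches the dominant singular direction", {
  set.seed(11)
  y <- sin(seq(0, 6 * pi, length.out = 100))
  expect_equal(abs(cor(first_eigenvariate(cbind(y)), y)), 1, tolerance = 1e-12)
  expect_equal(first_eigenvariate(cbind(y, y)),
               first_eigenvariate(cbind(y)) * sqrt(2) / sqrt(2), tolerance = 1e-10)
  # rank-1 matrix u v': output proportional to u (checked against svd oracle)
  u <- rnorm(80); v <- runif(12, 0.5, 2)
  M <- outer(u, v)
  ev <- first_eigenvariate(M)
  expect_equal(abs(cor(ev, u)), 1, tolerance = 1e-10)
  # permutation invariance up to sign
  M2 <- M[, sample(ncol(M))] + 0
  expect_equal(abs(ev), abs(first_eigenvariate(M2)), tolerance = 1e-10)
  # positive correlation with the mean voxel series by convention
  expect_gt(cor(ev, rowMeans(M)), 0)
  expect_error(first_eigenvariate(matrix(0, 5, 2)), class = "facedcm_config_error")
})

test_that("design and series round-trip through TSV with sidecars", {
  d <- build_block_design(n_reps = 1, n_runs = 1, seed = 9)
  tmp <- tempfile(fileext = ".tsv")
  write_design_tsv(d, tmp)
  d2 <- read_design_tsv(tmp)
  expect_equal(as.data.frame(d), as.data.frame(d2))
  expect_equal(attr(d2, "tr_s"), 1.45)
  expect_equal(attr(d2, "n_scans"), attr(d, "n_scans"))
  M <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("EVC_L", "EVC_R")))
  tmp2 <- tempfile(fileext = ".tsv")
  write_series_tsv(M, tmp2, tr_s = 1.45)
  b <- read_series_tsv(tmp2)
  expect_equal(unname(b$series), unname(M), tolerance = 1e-12)
  expect_equal(b$tr_s, 1.45)
})
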