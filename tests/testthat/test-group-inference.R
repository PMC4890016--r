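test_that("BH correction within class matches the brute-force definition", {
  # equal p-values all pass
  vals <- matrix(rnorm(50), 5, 10)
  set.seed(1)
  # step-up rule at m = 4: thresholds k/m * alpha = .0125, .025, .0375, .05;
  # p_(3) = 0.04 > 0.0375, so exactly the two smallest are rejected
  p <- c(0.01, 0.02, 0.04, 0.2)
  expect_equal(bh_reject_oracle(p), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(p.adjust(p, "BH") < 0.05), bh_reject_oracle(p))
  # randomised agreement between the package path and the oracle
  for (rep in 1:25) {
    m <- sample(3:12, 1)
    n <- 8
    X <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("par", 1:m)))
    X[, 1] <- X[, 1] + 2  # one real effect
    res <- ttest_and_fdr(X, mode = "one-sample")
    p_raw <- res$p
    expect_equal(res$significant, bh_reject_oracle(p_raw, 0.05))
  }
})

test_that("t-tests respect classes, modes and zero-variance flags", {
  set.seed(42)
  X <- cbind(a1 = rnorm(10) + 1, a2 = rnorm(10), b1 = rnorm(10), flat = rep(2, 10))
  classes <- list(A = c("a1", "a2"), B = c("b1", "flat"))
  res <- ttest_and_fdr(X, classes, mode = "one-sample")
  expect_equal(res$class, c("A", "A", "B", "B"))
  expect_false(res$tested[res$parameter == "flat"])
  expect_true(is.na(res$p_adj[res$parameter == "flat"]))
  # correction within class: a1's adjusted p only involves class A
  pa <- res$p[res$class == "A" & res$tested]
  expect_equal(res$p_adj[res$class == "A" & res$tested], p.adjust(pa, "BH"))
  # single-member classes reduce to uncorrected testing
  res1 <- ttest_and_fdr(X[, 1:2], classes = list(c1 = "a1", c2 = "a2"))
  expect_equal(res1$p_adj, res1$p)
  # two-sample null calibration: false-positive families are rare
  fp <- 0L
  for (s in 1:200) {
    set.seed(s)
    Y <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, paste0("q", 1:5)))
    r <- ttest_and_fdr(Y, mode = "two-sample", group = rep(c("g1", "g2"), each = 6))
    fp <- fp + any(r$significant)
  }
  expect_lte(fp / 200, 0.1)  # FDR controls the family-wise null near alpha
})

test_that("2x2 mixed ANOVA matches the sums-of-squares oracle", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 4
    df <- expand.grid(subject = paste0("s", 1:(2 * n)), within = c("w1", "w2"))
    df$group <- ifelse(as.integer(sub("s", "", df$subject)) <= n, "g1", "g2")
    df$value <- rnorm(nrow(df))
    out <- mixed_anova_2x2(df)
    orc <- mixed_anova_oracle(df)
    expect_equal(out$statistic[out$effect == "group"], orc$F_group, tolerance = 1e-10)
    expect_equal(out$statistic[out$effect == "within"], orc$F_within, tolerance = 1e-10)
    expect_equal(out$statistic[out$effect == "group:within"], orc$F_interaction,
                 tolerance = 1e-10)
  }
  # adding a group-mean difference equally to both within levels changes
  # only the group effect, not the interaction
  df <- expand.grid(subject = paste0("s", 1:8), within = c("w1", "w2"))
  df$group <- rep(rep(c("g1", "g2"), each = 4), 2)
  df$value <- rnorm(nrow(df))
  out0 <- mixed_anova_2x2(df)
  df$value <- df$value + ifelse(df$group == "g1", 5, 0)
  out <- mixed_anova_2x2(df)
  expect_equal(out$statistic[out$effect == "group:within"],
               out0$statistic[out0$effect == "group:within"], tolerance = 1e-8)
  expect_equal(out$statistic[out$effect == "within"],
               out0$statistic[out0$effect == "within"], tolerance = 1e-8)
  expect_gt(out$statistic[out$effect == "group"],
            out0$statistic[out0$effect == "group"])
  # group relabelling leaves F unchanged
  df2 <- df; df2$group <- ifelse(df$group == "g1", "g2", "g1")
  expect_equal(mixed_anova_2x2(df2)$statistic, out$statistic, tolerance = 1e-10)
  # interaction degrees of freedom are (1, N - 2)
  expect_equal(out$df1[out$effect == "group:within"], 1)
  expect_equal(out$df2[out$effect == "group:within"], 8 - 2)
})

test_that("3-way mixed ANOVA is calibrated and location invariant", {
  sim_df <- function(seed, delta = 0) {
    set.seed(seed)
    df <- expand.grid(subject = paste0("s", 1:12), stimulus = c("F", "O", "S"),
                      hemifield = c("LVF", "RVF"))
    df$group <- ifelse(as.integer(sub("s", "", df$subject)) <= 6, "RH", "LH")
    df$value <- rnorm(nrow(df)) +
      delta * (df$group == "LH") * (df$stimulus == "F")
    df
  }
  out <- mixed_anova_3way(sim_df(1))
  expect_setequal(out$effect,
                  c("group", "stimulus", "hemifield", "group:stimulus",
                    "group:hemifield", "stimulus:hemifield",
                    "group:stimulus:hemifield"))
  # adding a constant changes no F statistic
  df <- sim_df(2)
  df2 <- df; df2$value <- df$value + 100
  expect_equal(mixed_anova_3way(df2)$statistic, mixed_anova_3way(df)$statistic,
               tolerance = 1e-8)
  # null calibration of every effect's type-I rate at alpha = 0.05
  n_sim <- 500
  rej <- matrix(0, n_sim, 7)
  for (s in seq_len(n_sim)) {
    rej[s, ] <- mixed_anova_3way(sim_df(1000 + s))$p.value < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(abs(rates - 0.05) <= 0.03))
  # an injected group x stimulus effect is detected more often than a
  # hemifield main effect under the same noise
  n_pow <- 60
  hit_int <- hit_hemi <- 0
  for (s in seq_len(n_pow)) {
    o <- mixed_anova_3way(sim_df(5000 + s, delta = 1.2))
    hit_int <- hit_int + (o$p.value[o$effect == "group:stimulus"] < 0.05)
    hit_hemi <- hit_hemi + (o$p.value[o$effect == "hemifield"] < 0.05)
  }
  expect_gt(hit_int, hit_hemi)
  expect_gt(hit_int / n_pow, 0.5)
  # incomplete designs are rejected
  expect_error(mixed_anova_3way(sim_df(1)[-1, ]), class = "facedcm_config_error")
})

test_that("bootstrap LI matches closed forms and is antisymmetric", {
  # degenerate constant values with sum(L) = 3 sum(R): LI = 0.5 exactly
  L <- rep(3, 30); R <- rep(1, 30)
  r <- bootstrap_li(L, R, n_boot = 2000, threshold_frac = 0, seed = 1)
  expect_equal(r$li, 0.5, tolerance = 1e-12)
  # identical sides: LI ~ 0
  set.seed(5)
  v <- runif(40, 0.5, 2)
  r0 <- bootstrap_li(v, v, n_boot = 5000, threshold_frac = 0, seed = 2)
  expect_lt(abs(r0$li), 0.01)
  # full right dominance when the left side is entirely subthreshold
  r1 <- bootstrap_li(rep(0.1, 20), rep(1, 20), threshold_frac = 0.5,
                     n_boot = 500, seed = 3)
  expect_equal(r1$li, -1)
  # antisymmetry within bootstrap tolerance
  set.seed(9)
  a <- rgamma(25, 4); b <- rgamma(35, 2)
  rab <- bootstrap_li(a, b, n_boot = 5000, threshold_frac = 0, seed = 4)
  rba <- bootstrap_li(b, a, n_boot = 5000, threshold_frac = 0, seed = 4)
  expect_equal(rab$li, -rba$li, tolerance = 0.02)
  expect_true(abs(rab$li) <= 1)
  # a side with no values at all: undefined
  rna <- bootstrap_li(numeric(0), b)
  expect_true(is.na(rna$li))
})
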