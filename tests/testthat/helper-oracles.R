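# Independent oracles used across the suite. These are deliberately written
# from first principles (brute force / closed form) and never call the
# package functions they are used to check.

# Benjamini-Hochberg by its definition: largest k with p_(k) <= k/m * alpha
bh_reject_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- max(c(0L, which(ps <= seq_len(m) / m * alpha)))
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# classical mixed-ANOVA sums of squares for one between (a levels) and one
# within (b levels) factor, balanced, n subjects per group
mixed_anova_oracle <- function(df) {
  # df: subject, group, within, value
  mu <- mean(df$value)
  n_s <- length(unique(df$subject))
  a <- length(unique(df$group))
  b <- length(unique(df$within))
  n <- n_s / a
  gm <- tapply(df$value, df$group, mean)
  wm <- tapply(df$value, df$within, mean)
  sm <- tapply(df$value, df$subject, mean)
  cellm <- tapply(df$value, list(df$group, df$within), mean)
  grp_of_subj <- tapply(as.character(df$group), df$subject, `[`, 1)
  ss_group <- b * n * sum((gm - mu)^2)
  ss_subj <- b * sum((sm - mu)^2)
  ss_subj_within_grp <- ss_subj - ss_group
  ss_within <- a * n * sum((wm - mu)^2)
  ss_cells <- n * sum((cellm - mu)^2)
  ss_int <- ss_cells - ss_group - ss_within
  ss_tot <- sum((df$value - mu)^2)
  ss_err <- ss_tot - ss_subj - ss_within - ss_int
  df_g <- a - 1; df_sw <- a * (n - 1)
  df_w <- b - 1; df_i <- df_g * df_w; df_e <- df_sw * df_w
  list(
    F_group = (ss_group / df_g) / (ss_subj_within_grp / df_sw),
    F_within = (ss_within / df_w) / (ss_err / df_e),
    F_interaction = (ss_int / df_i) / (ss_err / df_e))
}

# 2-region toy DCM used by inversion tests: region 2 driven by region 1
toy_spec <- function(b_on = FALSE) {
  a <- matrix(c(1, 1, 0, 1), 2, 2)   # 1 -> 2 forward only
  b <- if (b_on) list(u1 = matrix(c(0, 1, 0, 0), 2, 2)) else NULL
  cm <- matrix(c(1, 0), 2, 1)
  dcm_spec(c("r1", "r2"), a, b, cm, input_labels = "u1")
}

toy_inputs <- function(n_scans = 80, tr = 1.45, bins = 16, period = 20) {
  U <- matrix(0, n_scans * bins, 1)
  on <- rep(rep(c(1, 0), each = period / 2 * bins), length.out = nrow(U))
  U[, 1] <- on
  structure(list(u = U, dt = tr / bins, bins_per_tr = bins, tr_s = tr,
                 n_scans = n_scans, glm_regressors = NULL),
            class = "dcm_inputs")
}

toy_params <- function(spec, a21 = 0.3, b21 = 0, c1 = 0.6) {
  A <- matrix(c(-0.5, a21, 0, -0.5), 2, 2)
  B <- if (b21 != 0) list(u1 = matrix(c(0, b21, 0, 0), 2, 2)) else NULL
  dcm_params(spec, A, B, matrix(c(c1, 0), 2, 1))
}

# look up a named parameter's generative value in a dcm_params object
true_param <- function(params, name) {
  p <- strsplit(name, ":", fixed = TRUE)[[1]]
  rg <- rownames(params$A)
  if (p[1] == "A") {
    e <- strsplit(p[2], "->", fixed = TRUE)[[1]]
    params$A[e[2], e[1]]
  } else if (p[1] == "B") {
    e <- strsplit(p[3], "->", fixed = TRUE)[[1]]
    params$B[[p[2]]][match(e[2], rg), match(e[1], rg)]
  } else if (p[1] == "C") {
    e <- strsplit(p[2], "->", fixed = TRUE)[[1]]
    params$C[e[2], e[1]]
  } else {
    0
  }
}
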