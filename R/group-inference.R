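#' Parameter-class t-tests with FDR correction within class
#'
#' One- or two-sample t-tests per parameter with Benjamini-Hochberg
#' false-discovery-rate correction applied independently within each
#' parameter class (the endogenous, per-input modulatory, and driving-input
#' blocks by default). Zero-variance parameters are flagged and excluded
#' from testing.
#'
#' @param values subjects x parameters matrix (column names = parameter
#'   ids), or a tidy tibble with columns `subject`, `parameter`, `value`
#'   (and `group` for two-sample mode).
#' @param classes named list mapping class label to parameter ids; defaults
#'   to a single class containing every parameter.
#' @param mode `"one-sample"` (mean different from zero) or `"two-sample"`
#'   (difference between groups).
#' @param group character/factor vector per subject (two-sample mode).
#' @param alpha significance level after correction (default 0.05).
#' @return tibble with columns `parameter`, `class`, `estimate`, `t`, `df`,
#'   `p`, `p_adj`, `significant`, `tested`.
#' @export
ttest_and_fdr <- function(values, classes = NULL,
                          mode = c("one-sample", "two-sample"),
                          group = NULL, alpha = 0.05) {
  mode <- match.arg(mode)
  if (is.data.frame(values) && all(c("subject", "parameter", "value") %in% names(values))) {
    wide <- tidyr::pivot_wider(values, id_cols = dplyr::any_of(c("subject", "group")),
                               names_from = "parameter", values_from = "value")
    if (is.null(group) && "group" %in% names(wide)) group <- wide$group
    values <- as.matrix(wide[, setdiff(names(wide), c("subject", "group"))])
  }
  values <- as.matrix(values)
  params <- colnames(values)
  if (is.null(params)) params <- paste0("p", seq_len(ncol(values)))
  if (mode == "two-sample") {
    if (is.null(group)) abort("two-sample mode needs group labels")
    gl <- unique(group)
    if (length(gl) != 2L) abort("two-sample mode needs exactly two groups")
    if (min(table(group)) < 3L) abort("need at least 3 subjects per group")
  } else if (nrow(values) < 3L) {
    abort("need at least 3 subjects")
  }
  if (is.null(classes)) classes <- list(all = params)

  res <- purrr::map_dfr(params, function(pn) {
    x <- values[, pn]
    cls <- names(classes)[vapply(classes, function(cc) pn %in% cc, TRUE)]
    cls <- if (length(cls)) cls[1] else NA_character_
    if (mode == "one-sample") {
      if (sd(x) == 0) {
        return(tibble(parameter = pn, class = cls, estimate = mean(x),
                      t = NA_real_, df = NA_real_, p = NA_real_, tested = FALSE))
      }
      tt <- t.test(x)
      tibble(parameter = pn, class = cls, estimate = mean(x),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, tested = TRUE)
    } else {
      x1 <- x[group == gl[1]]; x2 <- x[group == gl[2]]
      if (sd(x1) == 0 && sd(x2) == 0) {
        return(tibble(parameter = pn, class = cls, estimate = mean(x1) - mean(x2),
                      t = NA_real_, df = NA_real_, p = NA_real_, tested = FALSE))
      }
      tt <- t.test(x1, x2, var.equal = TRUE)
      tibble(parameter = pn, class = cls, estimate = mean(x1) - mean(x2),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, tested = TRUE)
    }
  })
  res <- dplyr::group_by(res, .data$class)
  res <- dplyr::mutate(res, p_adj = {
    pa <- rep(NA_real_, dplyr::n())
    pa[.data$tested] <- p.adjust(.data$p[.data$tested], method = "BH")
    pa
  })
  res <- dplyr::ungroup(res)
  dplyr::mutate(res, significant = !is.na(.data$p_adj) & .data$p_adj < alpha)
}

check_balanced <- function(tab) {
  if (any(tab == 0L)) abort("incomplete design: empty cells", class = "facedcm_config_error")
  if (length(unique(as.vector(tab))) != 1L) {
    abort("unbalanced within-subject design", class = "facedcm_config_error")
  }
}

extract_aov <- function(fit) {
  s <- summary(fit)
  purrr::map_dfr(s, function(stratum) {
    tt <- if (is.list(stratum)) stratum[[1]] else stratum
    tt <- as.data.frame(tt)
    tt$effect <- trimws(rownames(tt))
    tt <- tt[tt$effect != "Residuals", , drop = FALSE]
    if (!nrow(tt)) return(NULL)
    resid_df <- as.data.frame(if (is.list(stratum)) stratum[[1]] else stratum)
    rdf <- resid_df["Residuals", "Df"]
    tibble(effect = tt$effect, df1 = tt$Df, df2 = rdf,
           statistic = tt$`F value`, p.value = tt$`Pr(>F)`)
  })
}

#' 2 x 2 mixed-effects ANOVA
#'
#' Classical mixed ANOVA with one between-subject factor (e.g. handedness)
#' and one two-level within-subject factor (e.g. region or hemisphere),
#' computed from the standard sums-of-squares decomposition (between stratum
#' for the group effect; subject-by-within stratum for the within effect and
#' the interaction, F with (1, N-2) df).
#'
#' @param data tidy tibble with columns `subject`, `group`, `within`,
#'   `value` (one row per subject x within level).
#' @return tibble with columns `effect`, `df1`, `df2`, `statistic`,
#'   `p.value`.
#' @export
mixed_anova_2x2 <- function(data) {
  d <- dplyr::mutate(data, subject = factor(.data$subject),
                     group = factor(.data$group), within = factor(.data$within))
  check_balanced(table(d$subject, d$within))
  fit <- aov(value ~ group * within + Error(subject / within), data = d)
  extract_aov(fit)
}

#' 3-way mixed ANOVA (group x stimulus x hemifield)
#'
#' Mixed ANOVA with a between-subject group factor and two within-subject
#' factors (three-level stimulus, two-level hemifield), all main effects and
#' interactions through the three-way term. Uncorrected degrees of freedom
#' by default; Greenhouse-Geisser correction is applied to effects involving
#' the three-level factor when `gg = TRUE`.
#'
#' @param data tidy tibble with columns `subject`, `group`, `stimulus`,
#'   `hemifield`, `value` (one row per subject x stimulus x hemifield).
#' @param gg apply Greenhouse-Geisser df correction to stimulus effects.
#' @return tibble with columns `effect`, `df1`, `df2`, `statistic`,
#'   `p.value`.
#' @export
mixed_anova_3way <- function(data, gg = FALSE) {
  d <- dplyr::mutate(data, subject = factor(.data$subject),
                     group = factor(.data$group),
                     stimulus = factor(.data$stimulus),
                     hemifield = factor(.data$hemifield))
  check_balanced(table(d$subject, d$stimulus, d$hemifield))
  fit <- aov(value ~ group * stimulus * hemifield +
               Error(subject / (stimulus * hemifield)), data = d)
  out <- extract_aov(fit)
  if (gg) out <- gg_correct(out, d)
  out
}

# Greenhouse-Geisser epsilon for the stimulus factor, applied to the
# stimulus-stratum effects' df and p-values
gg_correct <- function(out, d) {
  wide <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(d, .data$subject, .data$stimulus),
                     value = mean(.data$value), .groups = "drop"),
    names_from = "stimulus", values_from = "value")
  M <- as.matrix(wide[, -1])
  S <- stats::cov(M)
  k <- ncol(M)
  Cc <- diag(k) - 1 / k
  Sc <- Cc %*% S %*% Cc
  eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  eps <- min(max(eps, 1 / (k - 1)), 1)
  stim <- grepl("stimulus", out$effect)
  out$df1[stim] <- out$df1[stim] * eps
  out$df2[stim] <- out$df2[stim] * eps
  out$p.value[stim] <- stats::pf(out$statistic[stim], out$df1[stim],
                                 out$df2[stim], lower.tail = FALSE)
  out
}

#' Bootstrap lateralization index
#'
#' Hemispheric dominance of suprathreshold activation:
#' `LI = (sum(L) - sum(R)) / (sum(L) + sum(R))` over bootstrap resamples of
#' the left- and right-hemisphere voxel values; the reported value is the
#' symmetric trimmed mean of the bootstrap LI distribution. Positive values
#' mean left dominance. Values are thresholded per side at a configurable
#' fraction of the side-wise maximum before resampling.
#'
#' @param left_values,right_values suprathreshold voxel values per side.
#' @param n_boot bootstrap resamples (default 10000).
#' @param trim symmetric trim fraction of the bootstrap distribution
#'   (default 0.25).
#' @param threshold_frac threshold as a fraction of the overall maximum
#'   across both sides (default 0.5); set 0 to keep all values. A side left
#'   empty by thresholding (while the other survives) contributes a zero
#'   sum, giving full dominance of the surviving side.
#' @param seed RNG seed.
#' @return An `li_result`: tibble with `li`, `ci_lower`, `ci_upper`,
#'   `n_left`, `n_right`, `n_boot`, `trim`, `seed`. `li` is `NA` when a side
#'   has no values at all.
#' @export
bootstrap_li <- function(left_values, right_values, n_boot = 10000,
                         trim = 0.25, threshold_frac = 0.5, seed = 1) {
  L0 <- left_values[is.finite(left_values)]
  R0 <- right_values[is.finite(right_values)]
  if (!length(L0) || !length(R0)) {
    return(structure(tibble(li = NA_real_, ci_lower = NA_real_,
                            ci_upper = NA_real_, n_left = length(L0),
                            n_right = length(R0), n_boot = n_boot,
                            trim = trim, seed = seed),
                     class = c("li_result", "tbl_df", "tbl", "data.frame")))
  }
  cut <- threshold_frac * max(c(L0, R0))
  L <- L0[L0 >= cut]
  R <- R0[R0 >= cut]
  if (!length(L) && !length(R)) {
    abort("no suprathreshold values on either side", class = "facedcm_config_error")
  }
  boot_sum <- function(x) {
    if (!length(x)) return(rep(0, n_boot))
    rowSums(matrix(sample(x, n_boot * length(x), replace = TRUE), n_boot))
  }
  lis <- withr_seed(seed, {
    sl <- boot_sum(L)
    sr <- boot_sum(R)
    (sl - sr) / (sl + sr)
  })
  structure(tibble(li = mean(lis, trim = trim),
                   ci_lower = unname(quantile(lis, 0.025)),
                   ci_upper = unname(quantile(lis, 0.975)),
                   n_left = length(L), n_right = length(R),
                   n_boot = n_boot, trim = trim, seed = seed),
            class = c("li_result", "tbl_df", "tbl", "data.frame"))
}
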