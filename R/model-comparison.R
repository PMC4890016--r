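#' Evidence matrix
#'
#' Subjects x models matrix of negative free energies with model tags and
#' optional per-subject group labels.
#'
#' @param F subjects x models numeric matrix.
#' @param tags optional tibble from [model_space_tags()] (columns
#'   `family_id`, `combo`), one row per model.
#' @param groups optional character vector of group labels per subject.
#' @return an `evidence_matrix` object.
#' @export
evidence_matrix <- function(F, tags = NULL, groups = NULL) {
  F <- as.matrix(F)
  if (!all(is.finite(F))) abort("evidence matrix must be finite")
  if (!is.null(tags) && nrow(tags) != ncol(F)) abort("tags/model mismatch")
  if (!is.null(groups) && length(groups) != nrow(F)) abort("groups/subject mismatch")
  structure(list(F = F, tags = tags, groups = groups), class = "evidence_matrix")
}

ev_F <- function(x) if (inherits(x, "evidence_matrix")) x$F else as.matrix(x)

# variational update of the Dirichlet over model frequencies
# (hierarchical Dirichlet-multinomial; alpha0 is the per-model prior count)
rfx_alpha <- function(F, alpha0) {
  K <- ncol(F)
  alpha <- alpha0 + colSums(matrix(1 / K, nrow(F), K))
  lme <- sweep(F, 1L, apply(F, 1L, max))
  for (it in 1:256) {
    w <- sweep(lme, 2L, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- exp(sweep(w, 1L, apply(w, 1L, max)))
    g <- w / rowSums(w)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < 1e-8) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  list(alpha = alpha, g = g)
}

# free energy (evidence bound) of the Dirichlet-multinomial RFX model
rfx_free_energy <- function(F, alpha0) {
  fit <- rfx_alpha(F, alpha0)
  alpha <- fit$alpha
  g <- fit$g
  elr <- digamma(alpha) - digamma(sum(alpha))
  gl <- g * log(pmax(g, 1e-300))
  sum(g * F) + sum(sweep(g, 2L, elr, `*`)) - sum(gl) +
    lgamma(sum(alpha0)) - sum(lgamma(alpha0)) +
    sum(lgamma(alpha)) - lgamma(sum(alpha)) +
    sum((alpha0 - alpha) * elr)
}

dirichlet_sample <- function(n, alpha) {
  K <- length(alpha)
  x <- matrix(rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  x / rowSums(x)
}

#' Random-effects Bayesian model selection
#'
#' Hierarchical Dirichlet-multinomial inference on model frequencies in the
#' population: a variational update of the Dirichlet concentrations from the
#' subjects' log evidences, expected probabilities as normalised
#' concentrations, and exceedance probabilities (probability of being the
#' most frequent model) by seeded Monte-Carlo sampling of the posterior
#' Dirichlet.
#'
#' @param F an [evidence_matrix()] or subjects x models matrix.
#' @param alpha0 per-model prior concentration (default 1).
#' @param n_samples Monte-Carlo draws for exceedance probabilities.
#' @param seed RNG seed for the sampler.
#' @return A `bms_result` tibble with columns `model`, `alpha`,
#'   `expected_prob`, `exceedance_prob` (plus tag columns when available),
#'   carrying `n_samples` and `seed` attributes.
#' @export
rfx_bms <- function(F, alpha0 = 1, n_samples = 1e5, seed = 1) {
  Fm <- ev_F(F)
  if (ncol(Fm) < 2L) abort("need at least two models", class = "facedcm_config_error")
  if (nrow(Fm) < 1L) abort("need at least one subject", class = "facedcm_config_error")
  alpha0 <- rep_len(alpha0, ncol(Fm))
  fit <- rfx_alpha(Fm, alpha0)
  alpha <- fit$alpha
  r <- withr_seed(seed, dirichlet_sample(n_samples, alpha))
  win <- max.col(r, ties.method = "random")
  xp <- tabulate(win, ncol(Fm)) / n_samples
  out <- tibble(model = seq_len(ncol(Fm)), alpha = alpha,
                expected_prob = alpha / sum(alpha), exceedance_prob = xp)
  if (inherits(F, "evidence_matrix") && !is.null(F$tags)) {
    out <- dplyr::bind_cols(out, F$tags[, setdiff(names(F$tags), "model"), drop = FALSE])
  }
  structure(out, class = c("bms_result", class(out)),
            n_samples = n_samples, seed = seed)
}

#' Family-level Bayesian model selection
#'
#' Random-effects BMS over a partition of the model space into families,
#' with a prior uniform over families (per-model prior concentration
#' proportional to 1 / family size). Family frequencies are obtained by
#' aggregating sampled model frequencies within families; exceedance
#' probabilities count the family with the largest summed frequency.
#'
#' @param F an [evidence_matrix()] or subjects x models matrix.
#' @param families factor/character vector of family ids per model, or NULL
#'   to take `family_id` from the evidence tags.
#' @param n_samples,seed Monte-Carlo settings as in [rfx_bms()].
#' @return a `bms_result` tibble over families.
#' @export
family_bms <- function(F, families = NULL, n_samples = 1e5, seed = 1) {
  Fm <- ev_F(F)
  if (is.null(families)) {
    if (!inherits(F, "evidence_matrix") || is.null(F$tags)) {
      abort("families must be given or present as tags")
    }
    families <- F$tags$family_id
  }
  if (length(families) != ncol(Fm) || anyNA(families)) {
    abort("family partition does not cover all models", class = "facedcm_config_error")
  }
  fam <- factor(families)
  sizes <- table(fam)
  alpha0 <- 1 / as.numeric(sizes)[as.integer(fam)]
  fit <- rfx_alpha(Fm, alpha0)
  alpha <- fit$alpha
  famsum <- function(x) tapply(x, fam, sum)
  fam_alpha <- as.numeric(famsum(alpha))
  r <- withr_seed(seed, dirichlet_sample(n_samples, alpha))
  rf <- t(apply(r, 1L, famsum))
  win <- max.col(rf, ties.method = "random")
  xp <- tabulate(win, nlevels(fam)) / n_samples
  out <- tibble(family_id = levels(fam),
                alpha = fam_alpha,
                expected_prob = fam_alpha / sum(alpha),
                exceedance_prob = xp)
  structure(out, class = c("bms_result", class(out)),
            n_samples = n_samples, seed = seed)
}

#' Between-group comparison of model frequencies
#'
#' Asks whether two groups share one population profile of model
#' frequencies: compares the evidence (variational bound) of a pooled
#' single-Dirichlet random-effects model against independent per-group
#' Dirichlets, at equal prior odds, and returns the posterior probability
#' that the frequencies are equal.
#'
#' @param F_g1,F_g2 evidence matrices (same model set, same column order).
#' @param alpha0 per-model prior concentration (default 1).
#' @return scalar posterior probability `p(equal | data)`.
#' @export
compare_group_frequencies <- function(F_g1, F_g2, alpha0 = 1) {
  F1 <- ev_F(F_g1); F2 <- ev_F(F_g2)
  if (ncol(F1) != ncol(F2)) abort("groups must share one model set")
  if (nrow(F1) < 1L || nrow(F2) < 1L) abort("empty group", class = "facedcm_config_error")
  a0 <- rep_len(alpha0, ncol(F1))
  f_pooled <- rfx_free_energy(rbind(F1, F2), a0)
  f_sep <- rfx_free_energy(F1, a0) + rfx_free_energy(F2, a0)
  1 / (1 + exp(f_sep - f_pooled))
}

#' Occam's window over a subject's models
#'
#' Retains the models whose posterior odds ratio relative to the subject's
#' best model exceeds the threshold: `exp(F_i - F_best) > odds_threshold`.
#' The best model is always retained.
#'
#' @param F_subject numeric vector of negative free energies over models.
#' @param odds_threshold posterior odds cut-off (default 0.05).
#' @return integer indices of the retained models.
#' @export
occams_window <- function(F_subject, odds_threshold = 0.05) {
  if (!all(is.finite(F_subject))) abort("non-finite evidence")
  which(exp(F_subject - max(F_subject)) > odds_threshold)
}

#' Subject-level Bayesian model averaging
#'
#' Averages per-model posterior means with weights proportional to
#' `exp(F_i - F_best)` over the subject's Occam's window. Parameters absent
#' from a model's structure contribute zero with that model's weight (a
#' model without a connection asserts its strength is 0).
#'
#' @param posteriors list of [variational_laplace()] results (or named
#'   numeric vectors of posterior means), one per model.
#' @param F_subject numeric vector of evidences aligned with `posteriors`.
#' @param odds_threshold Occam's-window threshold (default 0.05).
#' @return A `bma_result`: tibble with columns `term` and `estimate`,
#'   carrying attributes `retained` (model indices) and `weights`.
#' @export
bma_subject <- function(posteriors, F_subject, odds_threshold = 0.05) {
  if (length(posteriors) != length(F_subject)) abort("posteriors/evidence mismatch")
  keep <- occams_window(F_subject, odds_threshold)
  w <- exp(F_subject[keep] - max(F_subject[keep]))
  w <- w / sum(w)
  means <- lapply(posteriors[keep], function(p) {
    if (inherits(p, "dcm_posterior")) p$mean else p
  })
  terms <- unique(unlist(lapply(means, names)))
  est <- setNames(numeric(length(terms)), terms)
  for (k in seq_along(means)) {
    m <- means[[k]]
    est[names(m)] <- est[names(m)] + w[k] * m
  }
  out <- tibble(term = terms, estimate = unname(est))
  structure(out, class = c("bma_result", class(out)),
            retained = keep, weights = w, odds_threshold = odds_threshold)
}
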