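#' Write / read a block design as TSV
#'
#' Tab-separated columns `onset_s`, `duration_s`, `condition`, `run`, with a
#' JSON sidecar (`<path>.json`) holding `tr_s`, `n_scans`, `run_boundaries`
#' and the randomisation seed.
#'
#' @param design a [build_block_design()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- list(tr_s = design_tr(design), n_scans = design_n_scans(design),
               run_boundaries = attr(design, "run_boundaries"),
               seed = attr(design, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  d <- as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(d, class = c("block_design", class(d)),
            tr_s = meta$tr_s, n_scans = as.integer(meta$n_scans),
            run_boundaries = meta$run_boundaries, seed = meta$seed)
}

#' Write / read region time series as TSV
#'
#' One column per region, one row per scan, with a JSON sidecar recording
#' the repetition time and units.
#'
#' @param dataset a `bold_dataset` (or scans x regions matrix).
#' @param path output TSV path.
#' @param tr_s repetition time when `dataset` is a bare matrix.
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(dataset, path, tr_s = NULL) {
  if (inherits(dataset, "bold_dataset")) {
    M <- dataset$series
    tr_s <- dataset$tr_s
  } else {
    M <- as.matrix(dataset)
    if (is.null(tr_s)) abort("tr_s required for a bare matrix")
  }
  utils::write.table(as.data.frame(M), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(tr_s = tr_s, units = "percent signal change"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  M <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(series = M, tr_s = meta$tr_s, subject_id = basename(path),
                 group = NA_character_, noise_sd = NA_real_, snr = NA_real_,
                 seed = NA_integer_),
            class = "bold_dataset")
}

#' Serialise a DCM spec or evidence matrix to JSON lines
#'
#' One spec per line, masks as 0/1 arrays, for audit of the enumerated
#' model space.
#'
#' @param space list of [dcm_spec()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_space_jsonl <- function(space, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in space) {
    rec <- list(family_id = s$family_id, combo = s$combo, regions = s$regions,
                a_mask = s$a_mask, b_masks = s$b_masks, c_mask = s$c_mask,
                input_labels = s$input_labels)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Write / read an evidence matrix as TSV with a JSON tag sidecar
#'
#' Subjects x models negative free energies; model tags and group labels go
#' to `<path>.json`.
#'
#' @param ev an [evidence_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_evidence_tsv <- function(ev, path) {
  stopifnot(inherits(ev, "evidence_matrix"))
  utils::write.table(as.data.frame(ev$F), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(tags = ev$tags, groups = ev$groups),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_evidence_tsv
#' @export
read_evidence_tsv <- function(path) {
  F <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(F) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tags <- if (is.null(meta$tags) || length(meta$tags) == 0) NULL else as_tibble(meta$tags)
  groups <- if (is.null(meta$groups) || length(meta$groups) == 0) NULL else unlist(meta$groups)
  evidence_matrix(F, tags = tags, groups = groups)
}

#' Serialise a posterior to JSON
#'
#' Means, the lower triangle of the covariance, the negative free energy,
#' the convergence trace and the settings, for audit and downstream model
#' averaging outside R.
#'
#' @param posterior a [variational_laplace()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_posterior_json <- function(posterior, path) {
  stopifnot(inherits(posterior, "dcm_posterior"))
  cov_lt <- posterior$cov[lower.tri(posterior$cov, diag = TRUE)]
  rec <- list(mean = as.list(posterior$mean), free = posterior$free,
              cov_lower_triangle = cov_lt, F = posterior$F,
              trace = posterior$trace, converged = posterior$converged,
              lambda = as.list(posterior$lambda),
              family_id = posterior$family_id, combo = posterior$combo,
              settings = posterior$settings)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
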