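#' DCM structure specification
#'
#' Binary structure masks over an ordered set of regions: endogenous
#' connections `a_mask` (diagonal always present), per-input modulatory masks
#' `b_masks` (nonzero only where `a_mask` is), and driving-input mask
#' `c_mask`.
#'
#' @param regions character vector of region labels.
#' @param a_mask regions x regions binary matrix.
#' @param b_masks named list (one per input) of regions x regions binary
#'   matrices; missing inputs default to all-zero masks.
#' @param c_mask regions x inputs binary matrix.
#' @param input_labels character vector of input labels.
#' @param family_id,combo optional tags identifying the spec's place in a
#'   model space.
#' @return a `dcm_spec` object.
#' @export
dcm_spec <- function(regions, a_mask, b_masks = NULL, c_mask,
                     input_labels = .inputs, family_id = NA_character_,
                     combo = NA_character_) {
  n <- length(regions)
  m <- length(input_labels)
  a_mask <- as_mask(a_mask, n, n)
  diag(a_mask) <- 1L
  c_mask <- as_mask(c_mask, n, m)
  full <- setNames(rep(list(matrix(0L, n, n)), m), input_labels)
  if (!is.null(b_masks)) {
    for (nm in names(b_masks)) {
      if (!nm %in% input_labels) abort(paste0("unknown input: ", nm))
      full[[nm]] <- as_mask(b_masks[[nm]], n, n)
    }
  }
  for (nm in input_labels) {
    if (any(full[[nm]] & !a_mask)) {
      abort("modulatory mask outside the endogenous mask",
            class = "facedcm_config_error")
    }
  }
  dimnames(a_mask) <- list(regions, regions)
  dimnames(c_mask) <- list(regions, input_labels)
  full <- lapply(full, function(b) { dimnames(b) <- list(regions, regions); b })
  structure(list(regions = regions, a_mask = a_mask, b_masks = full,
                 c_mask = c_mask, input_labels = input_labels,
                 family_id = family_id, combo = combo),
            class = "dcm_spec")
}

as_mask <- function(x, nr, nc) {
  x <- as.matrix(x)
  if (nrow(x) != nr || ncol(x) != nc) abort("mask has wrong dimensions")
  storage.mode(x) <- "integer"
  (x != 0L) * 1L
}

#' @export
print.dcm_spec <- function(x, ...) {
  cat("<dcm_spec> ", length(x$regions), " regions",
      if (!is.na(x$family_id)) paste0(", family ", x$family_id, " [", x$combo, "]"),
      "\n", sep = "")
  cat("  endogenous connections:", sum(x$a_mask) - length(x$regions),
      "+ self; modulated:", sum(vapply(x$b_masks, sum, 0L)),
      "; driving:", sum(x$c_mask), "\n")
  invisible(x)
}

#' Endogenous skeleton of the bilateral face network
#'
#' The fixed endogenous and driving-input structure shared by every model in
#' the space: within each hemisphere, reciprocal connections among EVC, OFA
#' and FFA (including the direct EVC-FFA route); between hemispheres,
#' reciprocal links between homotopic OFA and homotopic FFA only (no
#' EVC-EVC and no heterotopic links). Driving inputs target contralateral
#' early visual cortex: RVF drives left EVC, LVF drives right EVC.
#'
#' @return a [dcm_spec()] with `a_mask` and `c_mask` set, all `b_masks` zero.
#' @export
build_endogenous_skeleton <- function() {
  n <- 6L
  A <- matrix(0L, n, n, dimnames = list(.regions, .regions))
  diag(A) <- 1L
  for (h in c("L", "R")) {
    r <- function(x) paste0(x, "_", h)
    for (pair in list(c("EVC", "OFA"), c("OFA", "FFA"), c("EVC", "FFA"))) {
      A[r(pair[2]), r(pair[1])] <- 1L   # forward, row = target
      A[r(pair[1]), r(pair[2])] <- 1L   # backward
    }
  }
  for (reg in c("OFA", "FFA")) {
    A[paste0(reg, "_R"), paste0(reg, "_L")] <- 1L
    A[paste0(reg, "_L"), paste0(reg, "_R")] <- 1L
  }
  C <- matrix(0L, n, 5L, dimnames = list(.regions, .inputs))
  C["EVC_L", "RVF"] <- 1L
  C["EVC_R", "LVF"] <- 1L
  dcm_spec(.regions, A, NULL, C)
}

#' Family definitions for the model space
#'
#' Each family fixes the set of intrahemispheric forward connections
#' (applied bilaterally) that experimental inputs may modulate. Families B
#' (EVC to OFA and OFA to FFA) and F (all three forward connections) are the
#' two anchored compositions; A, C, D, E default to single- and double-site
#' alternatives and can be overridden.
#'
#' @return named list mapping family id to a character vector of forward
#'   sites among `"EVC->OFA"`, `"OFA->FFA"`, `"EVC->FFA"`.
#' @export
default_families <- function() {
  list(A = "EVC->OFA",
       B = c("EVC->OFA", "OFA->FFA"),
       C = "OFA->FFA",
       D = "EVC->FFA",
       E = c("EVC->OFA", "EVC->FFA"),
       F = c("EVC->OFA", "OFA->FFA", "EVC->FFA"))
}

.contexts <- c("S", "F", "F+S", "FxS")

# modulatory placements for one context on a set of directed connections,
# split into left-hemisphere-origin and right-hemisphere-origin groups
context_placement <- function(context, left_edges, right_edges) {
  out <- list()
  add <- function(lst, input, edges) {
    lst[[input]] <- c(lst[[input]], edges)
    lst
  }
  if (context %in% c("S", "F+S")) {
    out <- add(out, "RVF", left_edges)
    out <- add(out, "LVF", right_edges)
  }
  if (context %in% c("F", "F+S")) {
    out <- add(out, "faces", c(left_edges, right_edges))
  }
  if (context == "FxS") {
    out <- add(out, "faces|RVF", left_edges)
    out <- add(out, "faces|LVF", right_edges)
  }
  out
}

site_edges <- function(sites, hemi) {
  vapply(strsplit(sites, "->", fixed = TRUE), function(p) {
    paste0(p[1], "_", hemi, "->", p[2], "_", hemi)
  }, character(1))
}

#' Expand a context combination into modulatory masks
#'
#' Builds the five per-input modulatory masks for one model: the
#' intrahemispheric context decides how the family's forward sites are
#' modulated, the interhemispheric context does the same for the four
#' homotopic links. Context `S` places the RVF input on left-hemisphere
#' (respectively left-to-right) connections and LVF on their mirror images;
#' `F` places the faces input on all connections of the group bilaterally;
#' `F+S` is the union; `FxS` substitutes the conditional `faces|RVF` /
#' `faces|LVF` inputs with the lateralised placement of `S`.
#'
#' @param intra_context,inter_context one of `"S"`, `"F"`, `"F+S"`, `"FxS"`.
#' @param family_sites character vector of intrahemispheric forward sites,
#'   e.g. `c("EVC->OFA", "OFA->FFA")`.
#' @return named list of 6 x 6 binary masks, one per input.
#' @export
expand_context <- function(intra_context, inter_context, family_sites) {
  stopifnot(intra_context %in% .contexts, inter_context %in% .contexts)
  intra <- context_placement(intra_context,
                             site_edges(family_sites, "L"),
                             site_edges(family_sites, "R"))
  inter <- context_placement(inter_context,
                             c("OFA_L->OFA_R", "FFA_L->FFA_R"),
                             c("OFA_R->OFA_L", "FFA_R->FFA_L"))
  masks <- setNames(rep(list(matrix(0L, 6L, 6L,
                                    dimnames = list(.regions, .regions))), 5L),
                    .inputs)
  for (src in list(intra, inter)) {
    for (input in names(src)) {
      for (edge in src[[input]]) {
        p <- strsplit(edge, "->", fixed = TRUE)[[1]]
        masks[[input]][p[2], p[1]] <- 1L
      }
    }
  }
  masks
}

#' Enumerate the 96-model space
#'
#' Crosses the six families with the sixteen context combinations (four
#' intrahemispheric x four interhemispheric modulatory contexts), attaching
#' the shared endogenous skeleton to each. Models are tagged
#' `family_id` and `combo` (`"inter/intra"`, interhemispheric context first)
#' in a deterministic order: families alphabetically, then inter context,
#' then intra context, each in the order S, F, F+S, FxS.
#'
#' @param families named list as returned by [default_families()].
#' @return list of 96 [dcm_spec()] objects.
#' @export
enumerate_model_space <- function(families = default_families()) {
  if (anyDuplicated(names(families)) ||
      anyDuplicated(vapply(families, function(s) paste(sort(s), collapse = "+"),
                           character(1)))) {
    abort("duplicate family definitions", class = "facedcm_config_error")
  }
  skel <- build_endogenous_skeleton()
  out <- list()
  for (fam in names(families)) {
    for (inter in .contexts) {
      for (intra in .contexts) {
        b <- expand_context(intra, inter, families[[fam]])
        spec <- dcm_spec(.regions, skel$a_mask, b, skel$c_mask,
                         family_id = fam,
                         combo = paste0(inter, "/", intra))
        out[[length(out) + 1L]] <- spec
      }
    }
  }
  names(out) <- vapply(out, function(s) paste0(s$family_id, ":", s$combo),
                       character(1))
  out
}

#' Model-space tags as a tibble
#'
#' @param space list of specs from [enumerate_model_space()].
#' @return tibble with columns `model`, `family_id`, `combo`.
#' @export
model_space_tags <- function(space) {
  tibble(model = seq_along(space),
         family_id = vapply(space, function(s) s$family_id, character(1)),
         combo = vapply(space, function(s) s$combo, character(1)))
}
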