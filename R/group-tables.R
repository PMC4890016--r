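#' Group-level connectivity estimates for the bilateral face network
#'
#' Default generative parameter tables for the synthetic cohort: group-level
#' means and between-subject standard deviations (Hz) of the endogenous
#' connections, the modulatory influences per input class, and the driving
#' inputs, separately for right-handed (RH) and left-handed (LH) cohorts.
#' Parameters reported without an estimate in a class (connections that were
#' never part of that class's modulated set) are absent from the table.
#'
#' @return tibble with columns `class` (`endogenous`, `RVF`, `LVF`,
#'   `faces`, `faces|RVF`, `faces|LVF`, `driving`), `connection`
#'   (`"SRC->TGT"`, or the target region for driving inputs), `rh_mean`,
#'   `rh_sd`, `lh_mean`, `lh_sd`.
#' @export
group_connectivity_table <- function() {
  tribble <- function(...) tibble::tribble(...)
  endo <- tribble(
    ~connection,       ~rh_mean, ~rh_sd, ~lh_mean, ~lh_sd,
    "FFA_L->FFA_R",  0.228, 0.147,  0.253, 0.087,
    "FFA_L->OFA_L",  0.106, 0.096,  0.147, 0.095,
    "FFA_L->EVC_L", -0.111, 0.222, -0.141, 0.206,
    "FFA_R->FFA_L",  0.216, 0.133,  0.235, 0.123,
    "FFA_R->OFA_R",  0.124, 0.147,  0.197, 0.141,
    "FFA_R->EVC_R", -0.005, 0.158, -0.061, 0.213,
    "OFA_L->OFA_R",  0.214, 0.125,  0.185, 0.154,
    "OFA_L->FFA_L",  0.155, 0.127,  0.051, 0.092,
    "OFA_L->EVC_L", -0.233, 0.140, -0.126, 0.272,
    "OFA_R->OFA_L",  0.209, 0.093,  0.217, 0.165,
    "OFA_R->FFA_R",  0.149, 0.117,  0.125, 0.084,
    "OFA_R->EVC_R", -0.177, 0.222, -0.099, 0.225,
    "EVC_L->FFA_L",  0.110, 0.078,  0.155, 0.069,
    "EVC_L->OFA_L",  0.220, 0.119,  0.213, 0.106,
    "EVC_R->FFA_R",  0.121, 0.073,  0.180, 0.105,
    "EVC_R->OFA_R",  0.194, 0.069,  0.182, 0.090)
  rvf <- tribble(
    ~connection,       ~rh_mean, ~rh_sd, ~lh_mean, ~lh_sd,
    "FFA_L->FFA_R",  0.061, 0.104,  0.180, 0.065,
    "OFA_L->OFA_R",  0.110, 0.176,  0.016, 0.114,
    "OFA_L->FFA_L", -0.063, 0.106, -0.068, 0.144,
    "EVC_L->FFA_L",  0.018, 0.055,  0.091, 0.089,
    "EVC_L->OFA_L",  0.119, 0.095,  0.106, 0.119)
  lvf <- tribble(
    ~connection,       ~rh_mean, ~rh_sd, ~lh_mean, ~lh_sd,
    "FFA_R->FFA_L",  0.100, 0.105,  0.149, 0.101,
    "OFA_R->OFA_L",  0.108, 0.118,  0.077, 0.133,
    "OFA_R->FFA_R", -0.116, 0.105, -0.068, 0.093,
    "EVC_R->FFA_R", -0.005, 0.044,  0.013, 0.101,
    "EVC_R->OFA_R",  0.113, 0.100,  0.057, 0.144)
  faces <- tribble(
    ~connection,       ~rh_mean, ~rh_sd, ~lh_mean, ~lh_sd,
    "FFA_L->FFA_R",  0.169, 0.105,  0.176, 0.070,
    "FFA_R->FFA_L",  0.060, 0.063,  0.128, 0.081,
    "OFA_L->OFA_R",  0.154, 0.100,  0.149, 0.113,
    "OFA_L->FFA_L",  0.094, 0.071,  0.064, 0.075,
    "OFA_R->OFA_L",  0.087, 0.050,  0.075, 0.072,
    "OFA_R->FFA_R",  0.120, 0.077,  0.076, 0.085,
    "EVC_L->FFA_L",  0.070, 0.090,  0.165, 0.083,
    "EVC_L->OFA_L",  0.137, 0.105,  0.128, 0.087,
    "EVC_R->FFA_R",  0.065, 0.092,  0.105, 0.077,
    "EVC_R->OFA_R",  0.129, 0.068,  0.136, 0.111)
  faces_rvf <- tribble(
    ~connection,       ~rh_mean, ~rh_sd, ~lh_mean, ~lh_sd,
    "FFA_L->FFA_R",  0.003, 0.008,  NA,    NA,
    "OFA_L->OFA_R",  0.001, 0.003,  NA,    NA,
    "OFA_L->FFA_L",  0.000, 0.001,  0.000, 0.001,
    "EVC_L->FFA_L",  0.002, 0.005,  0.001, 0.003,
    "EVC_L->OFA_L",  NA,    NA,     0.000, 0.001)
  faces_lvf <- tribble(
    ~connection,       ~rh_mean, ~rh_sd, ~lh_mean, ~lh_sd,
    "FFA_R->FFA_L",  0.001, 0.005,  NA,    NA,
    "OFA_R->OFA_L",  0.002, 0.008,  NA,    NA,
    "OFA_R->FFA_R",  0.000, 0.001,  0.000, 0.002,
    "EVC_R->FFA_R",  0.002, 0.005,  0.001, 0.004,
    "EVC_R->OFA_R",  NA,    NA,     0.001, 0.002)
  driving <- tribble(
    ~connection,       ~rh_mean, ~rh_sd, ~lh_mean, ~lh_sd,
    "RVF->EVC_L",    0.895, 0.450,  0.731, 0.334,
    "LVF->EVC_R",    0.794, 0.537,  0.663, 0.278)
  dplyr::bind_rows(
    dplyr::mutate(endo, class = "endogenous", .before = 1),
    dplyr::mutate(rvf, class = "RVF", .before = 1),
    dplyr::mutate(lvf, class = "LVF", .before = 1),
    dplyr::mutate(faces, class = "faces", .before = 1),
    dplyr::mutate(faces_rvf, class = "faces|RVF", .before = 1),
    dplyr::mutate(faces_lvf, class = "faces|LVF", .before = 1),
    dplyr::mutate(driving, class = "driving", .before = 1))
}

#' Parameter classes for FDR correction
#'
#' The default partition of tested parameters into classes within which the
#' Benjamini-Hochberg correction is applied: one endogenous block, one block
#' per modulatory input, and the driving inputs.
#'
#' @param parameters character vector of parameter names in the package's
#'   `A:...` / `B:input:...` / `C:...` naming.
#' @return named list of parameter-name vectors.
#' @export
parameter_classes <- function(parameters) {
  cls <- dplyr::case_when(
    grepl("^A:", parameters) ~ "endogenous",
    grepl("^B:RVF:", parameters) ~ "modulatory-RVF",
    grepl("^B:LVF:", parameters) ~ "modulatory-LVF",
    grepl("^B:faces:", parameters) ~ "modulatory-faces",
    grepl("^B:faces\\|RVF:", parameters) ~ "modulatory-faces|RVF",
    grepl("^B:faces\\|LVF:", parameters) ~ "modulatory-faces|LVF",
    grepl("^C:", parameters) ~ "driving",
    TRUE ~ "other")
  split(parameters, cls)
}
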