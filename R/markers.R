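#' Marker panel
#'
#' The four first-trimester screening markers handled by the package, with
#' the cohort CSV column that stores each raw concentration.
#'
#' @format Named character vector: names are marker identifiers
#'   (`dd`, `papp_a`, `free_b_hcg`, `nt`), values are cohort column names.
#' @export
hdp_markers <- c(
  dd         = "dd_ng_ml",
  papp_a     = "papp_a_mu_l",
  free_b_hcg = "free_b_hcg_ng_ml",
  nt         = "nt_cm"
)

#' Case-group labels
#'
#' Group labels of the case-control design: healthy controls plus the three
#' grades of hypertensive disorders of pregnancy (gestational hypertension,
#' preeclampsia, severe preeclampsia).  `"HDP"` denotes the pooled case
#' group (GH + PE + SPE).
#'
#' @format Character vector of the four generated labels.
#' @export
hdp_groups <- c("control", "GH", "PE", "SPE")

# columns every cohort table must carry
cohort_columns <- c(
  "subject_id", "group", "maternal_age", "maternal_weight",
  "gestational_age_days", unname(hdp_markers)
)

# first-trimester screening window, days (9w0d .. 13w6d)
ga_window_days <- c(63, 97)

# 97.5th standard-normal quantile used to invert median/percentile summaries
z975 <- 1.959964

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}
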