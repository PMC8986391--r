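#' Lognormal parameters from a median and 2.5/97.5 percentiles
#'
#' Screening markers are conventionally summarised as a median with a
#' 2.5--97.5 percentile range.  Assuming the marker is lognormal, the
#' summary inverts in closed form: the log10 median is the Gaussian mean
#' and the percentile span divided by `2 * 1.959964` is the Gaussian SD.
#' The printed percentile pairs of real cohorts are usually slightly
#' asymmetric about the median in log space; this symmetric inversion is
#' the standard compromise and the asymmetry is irreducible from the
#' three numbers alone.
#'
#' @param median Median on the raw concentration scale (> 0).
#' @param p2_5,p97_5 The 2.5th and 97.5th percentiles (raw scale).
#' @return Named numeric vector `c(mu, sigma)` in log10 units.
#' @examples
#' derive_lognormal_params(0.84, 0.33, 1.36)
#' @export
derive_lognormal_params <- function(median, p2_5, p97_5) {
  stop_if_not(is.numeric(median) && is.numeric(p2_5) && is.numeric(p97_5),
              "median and percentiles must be numeric")
  stop_if_not(p2_5 > 0 && p2_5 < median && median < p97_5,
              "ordering violation: need 0 < p2.5 (%g) < median (%g) < p97.5 (%g)",
              p2_5, median, p97_5)
  c(mu = log10(median),
    sigma = (log10(p97_5) - log10(p2_5)) / (2 * z975))
}

#' Group specification for the synthetic cohort generator
#'
#' Bundles everything the generator needs for one study group: the group
#' size, the median and 2.5/97.5 percentile of each marker on the raw
#' concentration scale, the same three-number summaries for maternal age,
#' maternal weight and gestational age at testing, and a between-marker
#' correlation matrix on the log10 scale.
#'
#' @param name Group label, one of `"control"`, `"GH"`, `"PE"`, `"SPE"`.
#' @param n Number of subjects to generate (> 0).
#' @param markers Numeric matrix with rows `dd`, `papp_a`, `free_b_hcg`,
#'   `nt` and columns `median`, `p2_5`, `p97_5` (marker units: ng/mL,
#'   mU/L, ng/mL, cm respectively).
#' @param age,weight,ga Numeric vectors `c(median, p2_5, p97_5)` for
#'   maternal age (years), maternal weight (kg) and gestational age at
#'   testing (days).
#' @param correlation Symmetric positive semi-definite 4x4 matrix with
#'   unit diagonal: correlation of the log10 markers.  Defaults to the
#'   identity (independent markers).
#' @return An object of class `"group_spec"`.
#' @seealso [default_group_specs()] for the built-in study groups.
#' @export
group_spec <- function(name, n, markers, age, weight, ga,
                       correlation = diag(4)) {
  stop_if_not(name %in% hdp_groups, "unknown group label '%s'", name)
  stop_if_not(length(n) == 1 && n > 0 && n == round(n),
              "n must be a positive integer")
  stop_if_not(is.matrix(markers) && nrow(markers) == 4 && ncol(markers) == 3,
              "markers must be a 4x3 matrix (marker x median/p2_5/p97_5)")
  rownames(markers) <- names(hdp_markers)
  colnames(markers) <- c("median", "p2_5", "p97_5")
  for (m in names(hdp_markers)) {
    row <- markers[m, ]
    stop_if_not(row["p2_5"] > 0 && row["p2_5"] < row["median"] &&
                  row["median"] < row["p97_5"],
                "group '%s', marker '%s': need 0 < p2.5 < median < p97.5",
                name, m)
  }
  for (v in list(age = age, weight = weight, ga = ga)) {
    stop_if_not(length(v) == 3 && v[2] < v[1] && v[1] < v[3] && v[2] > 0,
                "group '%s': demographic summaries must satisfy 0 < p2.5 < median < p97.5",
                name)
  }
  stop_if_not(is.matrix(correlation) && all(dim(correlation) == 4),
              "correlation must be a 4x4 matrix")
  stop_if_not(isTRUE(all.equal(correlation, t(correlation))) &&
                isTRUE(all.equal(unname(diag(correlation)), rep(1, 4))),
              "correlation must be symmetric with unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  stop_if_not(min(ev) > -1e-8, "correlation matrix is not positive semi-definite")
  structure(
    list(name = name, n = as.integer(n), markers = markers,
         age = unname(age), weight = unname(weight), ga = unname(ga),
         correlation = unname(correlation)),
    class = "group_spec"
  )
}

#' Built-in study group specifications
#'
#' The four groups of the reference case-control study of first-trimester
#' HDP screening: 150 healthy controls, 126 gestational hypertension (GH),
#' 53 preeclampsia (PE) and 41 severe preeclampsia (SPE) pregnancies.
#' Marker summaries are the published group-wise medians and 2.5--97.5
#' percentile ranges of raw D-dimer (ng/mL), PAPP-A (mU/L), free
#' beta-hCG (ng/mL) and NT (cm); demographics are the published maternal
#' age, weight and gestational-age summaries.  Between-marker correlations
#' were not published; the default is independence (identity matrix),
#' overridable via `correlation`.
#'
#' @param correlation Optional 4x4 log-scale marker correlation matrix
#'   applied to every group.
#' @return Named list of four [group_spec()] objects.
#' @export
default_group_specs <- function(correlation = diag(4)) {
  mk <- function(...) matrix(c(...), nrow = 4, byrow = TRUE,
                             dimnames = list(names(hdp_markers),
                                             c("median", "p2_5", "p97_5")))
  list(
    control = group_spec(
      "control", 150,
      mk(226.60,  89.41,  367.32,
         4495,   1650,   13545,
         52.65,  16.87,  156.23,
         1.40,   0.73,   2.34),
      age = c(28.23, 23.11, 34.61), weight = c(51.00, 43.00, 65.23),
      ga = c(91, 81, 97), correlation = correlation),
    GH = group_spec(
      "GH", 126,
      mk(269.52, 198.42, 335.38,
         3420,   837,    10430,
         42.4,   12.70,  121.65,
         1.40,   0.70,   2.30),
      age = c(29.26, 21.46, 34.48), weight = c(59.55, 44.51, 91.30),
      ga = c(89, 80, 97), correlation = correlation),
    PE = group_spec(
      "PE", 53,
      mk(304.67, 193.88, 361.89,
         3720,   842,    12120,
         43.80,  10.61,  315.00,
         1.30,   0.56,   2.71),
      age = c(29.26, 22.05, 34.17), weight = c(57.00, 37.67, 95.36),
      ga = c(90, 81, 97), correlation = correlation),
    SPE = group_spec(
      "SPE", 41,
      mk(329.23, 256.03, 397.95,
         3320,   450,    11495,
         37.80,  15.10,  168.05,
         1.20,   0.70,   1.95),
      age = c(28.52, 23.20, 35.10), weight = c(56.40, 40.15, 74.28),
      ga = c(90, 76, 97), correlation = correlation)
  )
}

#' Cohort generator configuration
#'
#' @param groups List of [group_spec()] objects with unique names; defaults
#'   to the built-in study groups.
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   seed.
#' @param separation_scale Multiplier in \[0, 1\] applied to each case
#'   group's log-scale marker offset (both the log-median shift and the
#'   log-SD difference) relative to control.  `1` reproduces the published
#'   separation, `0` makes every group's marker distribution identical to
#'   control -- the null configuration used for calibration checks.
#'   Demographics are never scaled.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(groups = default_group_specs(), seed = 1L,
                          separation_scale = 1) {
  nms <- vapply(groups, function(g) g$name, "")
  stop_if_not(!anyDuplicated(nms), "group names must be unique")
  stop_if_not("control" %in% nms, "a 'control' group is required")
  stop_if_not(length(separation_scale) == 1 && separation_scale >= 0 &&
                separation_scale <= 1,
              "separation_scale must be a single value in [0, 1]")
  names(groups) <- nms
  structure(list(groups = groups, seed = as.integer(seed),
                 separation_scale = separation_scale),
            class = "cohort_config")
}

# (mu, sigma) per marker for one group, log10 scale, after interpolating
# the case-vs-control offset by separation_scale
group_marker_params <- function(spec, control_spec, separation_scale) {
  p <- vapply(names(hdp_markers), function(m) {
    derive_lognormal_params(spec$markers[m, "median"],
                            spec$markers[m, "p2_5"],
                            spec$markers[m, "p97_5"])
  }, numeric(2))
  if (spec$name != "control" && separation_scale != 1) {
    p0 <- vapply(names(hdp_markers), function(m) {
      derive_lognormal_params(control_spec$markers[m, "median"],
                              control_spec$markers[m, "p2_5"],
                              control_spec$markers[m, "p97_5"])
    }, numeric(2))
    p <- p0 + separation_scale * (p - p0)
  }
  p  # 2 x 4 matrix: rows mu, sigma
}

#' Simulate a synthetic screening cohort
#'
#' Draws one subject table with the statistical structure the downstream
#' analysis assumes.  Within each group the vector of log10 marker
#' concentrations is multivariate normal with per-marker means and SDs
#' obtained by [derive_lognormal_params()] from the group's median /
#' percentile summaries and the group's correlation matrix; maternal age
#' and weight are univariate lognormal fitted the same way; gestational
#' age is discrete uniform over the 63--97 day screening window, clipped
#' to the group's published percentile envelope.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` with one row per subject and columns
#'   `subject_id`, `group`, `maternal_age` (years), `maternal_weight`
#'   (kg), `gestational_age_days`, `dd_ng_ml`, `papp_a_mu_l`,
#'   `free_b_hcg_ng_ml`, `nt_cm`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 42))
#' table(cohort$group)
#' @export
simulate_cohort <- function(config) {
  stop_if_not(inherits(config, "cohort_config"),
              "config must be a cohort_config object")
  set.seed(config$seed)
  control_spec <- config$groups[["control"]]
  out <- lapply(config$groups, function(spec) {
    p <- group_marker_params(spec, control_spec, config$separation_scale)
    sigma <- p["sigma", ]
    cov <- diag(sigma, 4) %*% spec$correlation %*% diag(sigma, 4)
    logx <- MASS::mvrnorm(spec$n, mu = p["mu", ], Sigma = cov)
    if (spec$n == 1) logx <- matrix(logx, nrow = 1)
    markers <- 10^logx
    colnames(markers) <- unname(hdp_markers)

    age_p <- derive_lognormal_params(spec$age[1], spec$age[2], spec$age[3])
    wt_p <- derive_lognormal_params(spec$weight[1], spec$weight[2], spec$weight[3])
    age <- 10^stats::rnorm(spec$n, age_p["mu"], age_p["sigma"])
    weight <- 10^stats::rnorm(spec$n, wt_p["mu"], wt_p["sigma"])
    ga <- sample(ga_window_days[1]:ga_window_days[2], spec$n, replace = TRUE)
    ga <- pmin(pmax(ga, spec$ga[2]), spec$ga[3])

    data.frame(subject_id = NA_character_, group = spec$name,
               maternal_age = age, maternal_weight = weight,
               gestational_age_days = as.numeric(ga), markers,
               stringsAsFactors = FALSE)
  })
  cohort <- do.call(rbind, out)
  rownames(cohort) <- NULL
  cohort$subject_id <- sprintf("S%05d", seq_len(nrow(cohort)))
  cohort
}

#' Write / read a cohort CSV
#'
#' The CSV schema is fixed: `subject_id, group, maternal_age,
#' maternal_weight, gestational_age_days, dd_ng_ml, papp_a_mu_l,
#' free_b_hcg_ng_ml, nt_cm`.  Numeric fields are written with 17
#' significant digits so a write/read round trip reproduces every double
#' exactly.
#'
#' @param cohort Cohort `data.frame` as produced by [simulate_cohort()].
#' @param path File path.
#' @return `read_cohort` returns the cohort `data.frame`; `write_cohort`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stop_if_not(all(cohort_columns %in% names(cohort)),
              "cohort is missing columns: %s",
              paste(setdiff(cohort_columns, names(cohort)), collapse = ", "))
  out <- cohort[, cohort_columns]
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  stop_if_not(file.exists(path), "no such file: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0) stop("cohort file is empty: ", path, call. = FALSE)
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- setdiff(cohort_columns, c("subject_id", "group"))
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   raw[[col]][bad[1]], bad[1], col), call. = FALSE)
    }
    if (anyNA(vals)) {
      stop(sprintf("missing value at row %d, column '%s'",
                   which(is.na(vals))[1], col), call. = FALSE)
    }
    raw[[col]] <- vals
  }
  raw[, cohort_columns]
}
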