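#' Median model for one marker
#'
#' A median model converts a raw marker concentration into a multiple of
#' the median (MoM).  The gestational-age-specific median follows a
#' log10-quartic:
#' \deqn{GA_{Med} = 10^{c_0 + c_1 GA + c_2 GA^2 + c_3 GA^3 + c_4 GA^4}}
#' with `GA` in completed weeks, and the maternal-weight correction factor
#' is log-linear,
#' \deqn{f(w) = 10^{w_0 + w_1 w},}
#' normalised so that `f` equals 1 at the reference cohort's mean weight.
#' Raw MoM is concentration divided by the gestational-age median; the
#' adjusted MoM additionally divides by the weight correction factor, so
#' MoM and adjusted MoM coincide at the reference mean weight.
#'
#' @param marker Marker identifier (one of `names(hdp_markers)`).
#' @param ga_coefficients Numeric `c(c0, c1, c2, c3, c4)` of the log10
#'   quartic in gestational weeks.
#' @param weight_coefficients Numeric `c(w0, w1)` of the log10-linear
#'   weight correction; `c(0, 0)` disables weight adjustment.
#' @param ref_mean_weight Mean maternal weight (kg) of the reference
#'   cohort at which the correction factor is 1; `NA` when no weight
#'   correction is fitted.
#' @param ga_range Gestational-age support of the model in days; when a
#'   model is fitted from data, [ga_median()] clamps its argument into
#'   this range so the quartic is never extrapolated beyond the
#'   reference observations (polynomials diverge quickly outside their
#'   fitting support).  Defaults to the full screening window.
#' @return An object of class `"median_model"`.
#' @export
median_model <- function(marker, ga_coefficients,
                         weight_coefficients = c(0, 0),
                         ref_mean_weight = NA_real_,
                         ga_range = ga_window_days) {
  stop_if_not(marker %in% names(hdp_markers), "unknown marker '%s'", marker)
  stop_if_not(length(ga_coefficients) == 5,
              "ga_coefficients must have length 5 (c0..c4)")
  stop_if_not(length(weight_coefficients) == 2,
              "weight_coefficients must have length 2 (w0, w1)")
  stop_if_not(length(ga_range) == 2 && ga_range[1] < ga_range[2],
              "ga_range must be an increasing pair of days")
  structure(
    list(marker = marker,
         ga_coefficients = as.numeric(ga_coefficients),
         weight_coefficients = as.numeric(weight_coefficients),
         ref_mean_weight = as.numeric(ref_mean_weight),
         ga_range = as.numeric(ga_range)),
    class = "median_model"
  )
}

#' Built-in D-dimer gestational-age median model
#'
#' The published D-dimer median equation for the 9--13+6 week screening
#' window, with coefficients
#' `(-108.6, 35.5, -4.253, 0.2262, -0.004508)` on gestational age in
#' weeks.  It carries no weight correction; refit one from a reference
#' cohort with [fit_median_model()] when weight adjustment is wanted.
#'
#' @return A [median_model()] for `dd`.
#' @examples
#' ga_median(dd_median_model(), 84)  # ~231 ng/mL at 12 weeks
#' @export
dd_median_model <- function() {
  median_model("dd", c(-108.6, 35.5, -4.253, 0.2262, -0.004508))
}

#' Gestational-age-specific median concentration
#'
#' Evaluates a median model's log10 quartic at a gestational age given in
#' days (converted internally to weeks).  Ages outside the 63--97 day
#' screening window are a domain error: the quartic is a within-window
#' interpolation and is not extrapolated.
#'
#' @param model A [median_model()].
#' @param gestational_age Gestational age in days, in \[63, 97\].
#' @return Median concentration in the marker's units (vectorised).
#' @export
ga_median <- function(model, gestational_age) {
  stop_if_not(inherits(model, "median_model"), "model must be a median_model")
  if (any(gestational_age < ga_window_days[1] |
            gestational_age > ga_window_days[2])) {
    stop(sprintf("gestational age outside the %d-%d day screening window",
                 ga_window_days[1], ga_window_days[2]), call. = FALSE)
  }
  # evaluate within the model's fitted support only
  gestational_age <- pmin(pmax(gestational_age, model$ga_range[1]),
                          model$ga_range[2])
  w <- gestational_age / 7
  cf <- model$ga_coefficients
  10^(cf[1] + cf[2] * w + cf[3] * w^2 + cf[4] * w^3 + cf[5] * w^4)
}

#' Maternal-weight correction factor
#'
#' @param model A [median_model()].
#' @param weight Maternal weight in kg (vectorised).
#' @return Dimensionless factor, 1 at the reference mean weight.
#' @export
weight_correction <- function(model, weight) {
  stop_if_not(inherits(model, "median_model"), "model must be a median_model")
  cf <- model$weight_coefficients
  10^(cf[1] + cf[2] * weight)
}

#' Fit a median model from a reference cohort
#'
#' Regresses log10 concentration on a quartic in gestational weeks over
#' the control records of `reference` (ordinary least squares), then
#' regresses the resulting log10 MoM residuals on maternal weight and
#' re-centres the weight term so the correction factor is exactly 1 at
#' the controls' mean weight.  The median raw MoM of the reference is
#' therefore approximately 1 by construction.
#'
#' @param reference Cohort `data.frame`; only rows with
#'   `group == "control"` are used when a `group` column is present.
#' @param marker Marker identifier.
#' @param weight_degree Polynomial degree of the log10 weight correction
#'   (default 1, log-linear).
#' @return A [median_model()] with fitted coefficients.
#' @export
fit_median_model <- function(reference, marker, weight_degree = 1) {
  stop_if_not(marker %in% names(hdp_markers), "unknown marker '%s'", marker)
  ref <- reference
  if ("group" %in% names(ref) && any(ref$group == "control")) {
    ref <- ref[ref$group == "control", , drop = FALSE]
  }
  stop_if_not(nrow(ref) >= 50,
              "median-model fit needs >= 50 control records, got %d", nrow(ref))
  conc <- ref[[hdp_markers[[marker]]]]
  stop_if_not(!is.null(conc) && all(conc > 0),
              "marker column '%s' missing or non-positive", hdp_markers[[marker]])
  w <- ref$gestational_age_days / 7
  stop_if_not(length(unique(floor(w))) >= 3,
              "median-model fit needs records spanning >= 3 distinct gestational weeks")
  y <- log10(conc)
  fit <- stats::lm(y ~ poly(w, 4, raw = TRUE))
  ga_cf <- unname(stats::coef(fit))
  ga_cf[is.na(ga_cf)] <- 0

  resid_log_mom <- y - stats::fitted(fit)
  wt <- ref$maternal_weight
  mean_wt <- mean(wt)
  if (weight_degree >= 1 && stats::sd(wt) > 0) {
    wfit <- stats::lm(resid_log_mom ~ poly(wt, weight_degree, raw = TRUE))
    wcf <- unname(stats::coef(wfit))
    wcf[is.na(wcf)] <- 0
    # keep the linear term; re-centre so the factor is 1 at the mean weight
    slope <- wcf[2]
    wt_cf <- c(-slope * mean_wt, slope)
    if (weight_degree > 1) {
      # higher-degree corrections: evaluate the full fitted polynomial,
      # recentred at the mean weight, and refit a line through it for the
      # (w0, w1) storage contract
      grid <- seq(min(wt), max(wt), length.out = 64)
      fx <- vapply(grid, function(g) sum(wcf * g^(seq_along(wcf) - 1)), 0)
      fx <- fx - sum(wcf * mean_wt^(seq_along(wcf) - 1))
      lf <- stats::lm(fx ~ grid)
      wt_cf <- c(unname(stats::coef(lf)[1]), unname(stats::coef(lf)[2]))
      wt_cf[1] <- -wt_cf[2] * mean_wt
    }
  } else {
    wt_cf <- c(0, 0)
  }
  median_model(marker, ga_cf, wt_cf, mean_wt,
               ga_range = range(ref$gestational_age_days))
}

#' Compute MoM profiles for a cohort
#'
#' Applies one median model per marker: raw MoM is the concentration
#' divided by the gestational-age median, and the adjusted MoM further
#' divides by the maternal-weight correction factor.
#'
#' @param cohort Cohort `data.frame` (one or more rows).
#' @param models Named list of [median_model()] objects, one per marker to
#'   convert; names must be marker identifiers.
#' @return A `data.frame` with `subject_id`, `group` (if present),
#'   `maternal_age`, and a `<marker>_mom` and `<marker>_adj_mom` column
#'   per supplied model.
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 1))
#' models <- fit_all_median_models(cohort)
#' mom <- compute_mom(cohort, models)
#' head(mom)
#' @export
compute_mom <- function(cohort, models) {
  stop_if_not(is.list(models) && length(models) > 0,
              "models must be a non-empty named list of median_model objects")
  stop_if_not(!is.null(names(models)) && all(names(models) %in% names(hdp_markers)),
              "models must be named by marker identifier")
  out <- data.frame(subject_id = cohort$subject_id, stringsAsFactors = FALSE)
  if ("group" %in% names(cohort)) out$group <- cohort$group
  if ("maternal_age" %in% names(cohort)) out$maternal_age <- cohort$maternal_age
  for (m in names(models)) {
    model <- models[[m]]
    stop_if_not(inherits(model, "median_model"),
                "models[['%s']] is not a median_model", m)
    col <- hdp_markers[[m]]
    stop_if_not(col %in% names(cohort), "cohort lacks marker column '%s'", col)
    med <- ga_median(model, cohort$gestational_age_days)
    mom <- cohort[[col]] / med
    adj <- mom / weight_correction(model, cohort$maternal_weight)
    out[[paste0(m, "_mom")]] <- mom
    out[[paste0(m, "_adj_mom")]] <- adj
  }
  out
}

#' Fit median models for the whole panel
#'
#' Convenience wrapper fitting [fit_median_model()] for each of the four
#' markers from the same reference cohort.
#'
#' @inheritParams fit_median_model
#' @param markers Marker identifiers to fit (default: all four).
#' @return Named list of [median_model()] objects.
#' @export
fit_all_median_models <- function(reference, markers = names(hdp_markers),
                                  weight_degree = 1) {
  stats::setNames(
    lapply(markers, function(m) fit_median_model(reference, m, weight_degree)),
    markers
  )
}

#' Serialize / deserialize median models
#'
#' Median models round-trip through a small JSON document carrying the
#' marker name, both coefficient vectors and the reference mean weight.
#'
#' @param models Named list of [median_model()] objects.
#' @param path JSON file path.
#' @return `read_median_models` returns the named list;
#'   `write_median_models` returns `path` invisibly.
#' @export
write_median_models <- function(models, path) {
  payload <- lapply(models, function(m) {
    list(marker = m$marker,
         ga_coefficients = m$ga_coefficients,
         weight_coefficients = m$weight_coefficients,
         ref_mean_weight = m$ref_mean_weight,
         ga_range = m$ga_range)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_median_models
#' @export
read_median_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  stats::setNames(
    lapply(payload, function(p) {
      median_model(p$marker, p$ga_coefficients, p$weight_coefficients,
                   if (is.null(p$ref_mean_weight)) NA_real_ else p$ref_mean_weight,
                   if (is.null(p$ga_range)) ga_window_days else p$ga_range)
    }),
    names(payload)
  )
}
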