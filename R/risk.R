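#' The ten built-in risk model specifications
#'
#' The screening study builds ten likelihood-ratio models from the
#' four-marker panel: the four single markers, four D-dimer combinations
#' and two aneuploidy-panel combinations.
#'
#' @return Named list (`"1"` .. `"10"`) of character vectors of marker
#'   identifiers.
#' @export
risk_model_markers <- function() {
  list(
    "1"  = "dd",
    "2"  = "papp_a",
    "3"  = "free_b_hcg",
    "4"  = "nt",
    "5"  = c("dd", "papp_a"),
    "6"  = c("dd", "free_b_hcg"),
    "7"  = c("papp_a", "free_b_hcg"),
    "8"  = c("dd", "papp_a", "free_b_hcg"),
    "9"  = c("papp_a", "free_b_hcg", "nt"),
    "10" = c("dd", "papp_a", "free_b_hcg", "nt")
  )
}

#' Risk model specification
#'
#' @param model_id Integer 1--10 selecting a built-in marker subset, or
#'   `NULL` when `markers` is given explicitly.
#' @param markers Ordered subset of `names(hdp_markers)`; overrides
#'   `model_id`.
#' @param case_group `"GH"`, `"PE"`, `"SPE"` or `"HDP"` (the pooled
#'   GH + PE + SPE case group).
#' @param log_transform Fit the group Gaussians on log10 adjusted MoM
#'   (default `TRUE`, the screening convention) or on raw adjusted MoM.
#' @param risk_convention `"as_printed"` reports the HDP risk as the
#'   reciprocal likelihood ratio times the maternal-age prior, exactly as
#'   the source formula is printed; `"direct"` reports likelihood ratio
#'   times prior.  Ranking always uses the log likelihood-ratio score, so
#'   the convention affects only the reported risk value.
#' @return An object of class `"risk_model_spec"`.
#' @export
risk_model_spec <- function(model_id = NULL, markers = NULL,
                            case_group = "HDP", log_transform = TRUE,
                            risk_convention = c("as_printed", "direct")) {
  risk_convention <- match.arg(risk_convention)
  if (is.null(markers)) {
    stop_if_not(!is.null(model_id) && as.character(model_id) %in%
                  names(risk_model_markers()),
                "model_id must be 1..10 when markers is not given")
    markers <- risk_model_markers()[[as.character(model_id)]]
  } else {
    stop_if_not(all(markers %in% names(hdp_markers)) && !anyDuplicated(markers),
                "markers must be a subset of the four panel markers")
  }
  stop_if_not(case_group %in% c("GH", "PE", "SPE", "HDP"),
              "case_group must be GH, PE, SPE or HDP")
  structure(
    list(model_id = if (is.null(model_id)) NA_integer_ else as.integer(model_id),
         markers = markers, case_group = case_group,
         log_transform = log_transform, risk_convention = risk_convention),
    class = "risk_model_spec"
  )
}

adj_mom_matrix <- function(profiles, markers, log_transform) {
  cols <- paste0(markers, "_adj_mom")
  missing_cols <- setdiff(cols, names(profiles))
  stop_if_not(length(missing_cols) == 0,
              "profiles lack adjusted-MoM columns: %s",
              paste(missing_cols, collapse = ", "))
  x <- as.matrix(profiles[, cols, drop = FALSE])
  colnames(x) <- markers
  if (log_transform) x <- log10(x)
  x
}

#' Fit a per-group Gaussian density over marker MoM values
#'
#' Computes the sample mean vector and unbiased sample covariance of the
#' (optionally log10) adjusted MoM values of one study group, the
#' density parameters of the likelihood-ratio risk models.  A
#' near-singular covariance (condition number above 1e12) is ridged by
#' adding `1e-8 * trace / dim` to the diagonal.
#'
#' @param profiles MoM profile `data.frame` from [compute_mom()], with a
#'   `group` column.
#' @param spec A [risk_model_spec()] naming the marker subset and scale.
#' @param group Group label to fit (`"HDP"` pools GH, PE and SPE).
#' @return An object of class `"gaussian_group_model"` with fields
#'   `group`, `markers`, `mean`, `covariance`, `n`, `log_transform`.
#' @export
fit_group_density <- function(profiles, spec, group) {
  stop_if_not(inherits(spec, "risk_model_spec"), "spec must be a risk_model_spec")
  stop_if_not("group" %in% names(profiles), "profiles need a 'group' column")
  keep <- if (group == "HDP") profiles$group %in% c("GH", "PE", "SPE")
          else profiles$group == group
  stop_if_not(sum(keep) >= 10,
              "density fit for group '%s' needs >= 10 records, got %d",
              group, sum(keep))
  x <- adj_mom_matrix(profiles[keep, , drop = FALSE], spec$markers,
                      spec$log_transform)
  mu <- colMeans(x)
  sigma <- stats::cov(x)
  d <- length(spec$markers)
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) > 1e12) {
    sigma <- sigma + diag(1e-8 * sum(diag(sigma)) / d, d)
  }
  zero_var <- diag(sigma) <= 0
  if (any(zero_var)) {
    stop("zero variance after regularization for marker(s): ",
         paste(spec$markers[zero_var], collapse = ", "), call. = FALSE)
  }
  structure(
    list(group = group, markers = spec$markers, mean = mu,
         covariance = sigma, n = sum(keep), log_transform = spec$log_transform),
    class = "gaussian_group_model"
  )
}

# log multivariate-normal density, rows of x are observations
mvn_logdensity <- function(model, x) {
  x <- as.matrix(x)
  d <- length(model$markers)
  stop_if_not(ncol(x) == d,
              "dimension mismatch: model has %d markers, x has %d columns",
              d, ncol(x))
  ch <- chol(model$covariance)
  centred <- sweep(x, 2, model$mean)
  z <- backsolve(ch, t(centred), transpose = TRUE)
  logdet <- 2 * sum(log(diag(ch)))
  -0.5 * (d * log(2 * pi) + logdet + colSums(z^2))
}

#' Multivariate normal density of a group model
#'
#' Evaluates the fitted Gaussian density at one or more marker vectors
#' (computed in log space internally and exponentiated on return).
#'
#' @param model A `gaussian_group_model`.
#' @param x Numeric vector (one observation) or matrix (one row per
#'   observation) on the model's fitting scale.
#' @return Positive density value(s).
#' @export
likelihood <- function(model, x) {
  stop_if_not(inherits(model, "gaussian_group_model"),
              "model must be a gaussian_group_model")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stop_if_not(all(is.finite(x)), "x must be finite")
  exp(mvn_logdensity(model, x))
}

#' Case-vs-control likelihood ratio
#'
#' The screening risk factor: the ratio of the case-group to the
#' control-group Gaussian density at a subject's marker vector, computed
#' as the exponential of the log-density difference so it does not
#' overflow for |log LR| up to ~700.
#'
#' @param case_model,control_model `gaussian_group_model`s over the same
#'   ordered marker subset and scale.
#' @param x Marker vector or matrix as in [likelihood()].
#' @return Positive likelihood ratio(s).
#' @export
likelihood_ratio <- function(case_model, control_model, x) {
  stop_if_not(inherits(case_model, "gaussian_group_model") &&
                inherits(control_model, "gaussian_group_model"),
              "both models must be gaussian_group_model objects")
  stop_if_not(identical(case_model$markers, control_model$markers),
              "case and control models cover different marker sets")
  stop_if_not(identical(case_model$log_transform, control_model$log_transform),
              "case and control models use different scales")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  exp(mvn_logdensity(case_model, x) - mvn_logdensity(control_model, x))
}

#' Maternal-age prior risk
#'
#' The background age-related risk used as the prior multiplied into the
#' likelihood ratio.  The printed source formula,
#' `0.000627 + exp(-16.2395 + 0.286 * maternal age - 0.5)`, is
#' typographically ambiguous about the trailing `-0.5`, so three parses
#' are offered:
#' \describe{
#'   \item{`canonical`}{`0.000627 + exp(-16.2395 + 0.286 * age)` -- the
#'     classical aneuploidy age-risk form (default).}
#'   \item{`half_year`}{the `-0.5` shifts the age by half a year inside
#'     the product: `exp(-16.2395 + 0.286 * (age - 0.5))`.}
#'   \item{`trailing_term`}{the `-0.5` is a free term in the exponent:
#'     `exp(-16.2395 + 0.286 * age - 0.5)`.}
#' }
#' All three are strictly increasing in age and differ only by a constant
#' factor on the exponential component, so they never change within-age
#' ranking.
#'
#' @param maternal_age Age in years, in (10, 60); vectorised.
#' @param parse_variant One of `"canonical"`, `"half_year"`,
#'   `"trailing_term"`.
#' @return Prior risk on the probability scale.
#' @examples
#' maternal_age_prior(30)  # ~1.1e-3
#' @export
maternal_age_prior <- function(maternal_age,
                               parse_variant = c("canonical", "half_year",
                                                 "trailing_term")) {
  parse_variant <- match.arg(parse_variant)
  stop_if_not(all(maternal_age > 10 & maternal_age < 60),
              "maternal_age must be in (10, 60) years")
  expo <- switch(parse_variant,
    canonical     = -16.2395 + 0.286 * maternal_age,
    half_year     = -16.2395 + 0.286 * (maternal_age - 0.5),
    trailing_term = -16.2395 + 0.286 * maternal_age - 0.5
  )
  0.000627 + exp(expo)
}

#' Score subjects under one risk model
#'
#' For each profile row, evaluates the case-vs-control likelihood ratio
#' on the spec's marker subvector, the maternal-age prior, and the HDP
#' risk under the requested convention.  The ranking score is always
#' `log10(LR)` (larger = more case-like), independent of the risk
#' reporting convention.
#'
#' @param spec A [risk_model_spec()].
#' @param case_model,control_model Fitted `gaussian_group_model`s.
#' @param profiles MoM profile `data.frame` with a `maternal_age` column.
#' @param parse_variant Age-prior parse passed to [maternal_age_prior()].
#' @return A `data.frame`: `subject_id`, `group` (if present), `lr`,
#'   `risk_age`, `risk_hdp`, `score`.
#' @export
compute_risk <- function(spec, case_model, control_model, profiles,
                         parse_variant = "canonical") {
  stop_if_not(inherits(spec, "risk_model_spec"), "spec must be a risk_model_spec")
  x <- adj_mom_matrix(profiles, spec$markers, spec$log_transform)
  lr <- likelihood_ratio(case_model, control_model, x)
  risk_age <- maternal_age_prior(profiles$maternal_age, parse_variant)
  risk_hdp <- if (spec$risk_convention == "as_printed") (1 / lr) * risk_age
              else lr * risk_age
  out <- data.frame(subject_id = profiles$subject_id, stringsAsFactors = FALSE)
  if ("group" %in% names(profiles)) out$group <- profiles$group
  out$lr <- lr
  out$risk_age <- risk_age
  out$risk_hdp <- risk_hdp
  out$score <- log10(lr)
  out
}

#' Run all ten risk models for one case definition
#'
#' Fits the case-group and control-group Gaussians for each built-in
#' marker subset and scores every subject of the case group and the
#' control group.  `case_group = "HDP"` pools GH, PE and SPE into one
#' case arm (220 cases at the default group sizes).
#'
#' @param profiles MoM profile `data.frame` from [compute_mom()].
#' @param case_group `"GH"`, `"PE"`, `"SPE"` or `"HDP"`.
#' @param log_transform,risk_convention,parse_variant Passed through to
#'   [risk_model_spec()] and [compute_risk()].
#' @return Named list (`"1"` .. `"10"`); each element is the scored
#'   `data.frame` of [compute_risk()] restricted to case + control
#'   subjects, plus a logical `is_case` column.
#' @export
run_all_models <- function(profiles, case_group,
                           log_transform = TRUE,
                           risk_convention = "as_printed",
                           parse_variant = "canonical") {
  case_labels <- if (case_group == "HDP") c("GH", "PE", "SPE") else case_group
  n_case <- sum(profiles$group %in% case_labels)
  stop_if_not(n_case > 0, "case group '%s' is empty", case_group)
  stop_if_not(sum(profiles$group == "control") > 0, "control group is empty")
  keep <- profiles$group %in% c(case_labels, "control")
  sub <- profiles[keep, , drop = FALSE]
  out <- lapply(names(risk_model_markers()), function(id) {
    spec <- risk_model_spec(model_id = id, case_group = case_group,
                            log_transform = log_transform,
                            risk_convention = risk_convention)
    case_m <- fit_group_density(sub, spec, case_group)
    ctrl_m <- fit_group_density(sub, spec, "control")
    res <- compute_risk(spec, case_m, ctrl_m, sub, parse_variant)
    res$is_case <- sub$group %in% case_labels
    attr(res, "spec") <- spec
    attr(res, "case_model") <- case_m
    attr(res, "control_model") <- ctrl_m
    res
  })
  stats::setNames(out, names(risk_model_markers()))
}

#' Serialize / deserialize fitted group models
#'
#' @param models Named list of `gaussian_group_model` objects.
#' @param path JSON file path.
#' @return `read_group_models` returns the named list;
#'   `write_group_models` returns `path` invisibly.
#' @export
write_group_models <- function(models, path) {
  payload <- lapply(models, function(m) {
    list(group = m$group, markers = m$markers, mean = unname(m$mean),
         covariance = unname(m$covariance), n = m$n,
         log_transform = m$log_transform)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_group_models
#' @export
read_group_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  stats::setNames(
    lapply(payload, function(p) {
      markers <- as.character(p$markers)
      structure(
        list(group = p$group, markers = markers,
             mean = stats::setNames(as.numeric(p$mean), markers),
             covariance = matrix(unlist(p$covariance), length(markers),
                                 length(markers),
                                 dimnames = list(markers, markers)),
             n = p$n, log_transform = p$log_transform),
        class = "gaussian_group_model"
      )
    }),
    names(payload)
  )
}
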