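# Shared fixtures and independent oracles used across the test files.

# Brute-force AUC oracle: concordance probability over all case-control
# pairs, counting ties as one half.  Independent of roc_curve().
auc_by_pair_counting <- function(scores, is_case) {
  cases <- scores[is_case]
  controls <- scores[!is_case]
  cmp <- outer(cases, controls, function(a, b)
    (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# A small cohort with a fixed seed, reused where the exact draw does not
# matter.
small_cohort <- function(seed = 11, separation_scale = 1) {
  simulate_cohort(cohort_config(seed = seed,
                                separation_scale = separation_scale))
}

# Group specs with inflated per-group sizes (same distributions as the
# defaults).
scaled_group_specs <- function(factor = 10, correlation = diag(4)) {
  specs <- default_group_specs(correlation)
  lapply(specs, function(s) {
    group_spec(s$name, s$n * factor, s$markers, s$age, s$weight, s$ga,
               s$correlation)
  })
}

# Reference cohort whose log10 D-dimer median follows a known quartic in
# gestational weeks, for median-model recovery tests.  Weight is drawn
# independently of the marker.
reference_with_curve <- function(n, ga_coefficients, sigma = 0.1,
                                 weight_slope = 0, seed = 1) {
  set.seed(seed)
  ga_days <- stats::runif(n, 63, 97)
  w <- ga_days / 7
  log_med <- ga_coefficients[1] + ga_coefficients[2] * w +
    ga_coefficients[3] * w^2 + ga_coefficients[4] * w^3 +
    ga_coefficients[5] * w^4
  weight <- stats::rnorm(n, 55, 8)
  conc <- 10^(log_med + weight_slope * (weight - 55) +
                stats::rnorm(n, 0, sigma))
  data.frame(
    subject_id = sprintf("R%05d", seq_len(n)),
    group = "control",
    maternal_age = rep(28, n),
    maternal_weight = weight,
    gestational_age_days = ga_days,
    dd_ng_ml = conc,
    papp_a_mu_l = rep(4000, n) * 10^stats::rnorm(n, 0, 0.2),
    free_b_hcg_ng_ml = rep(50, n) * 10^stats::rnorm(n, 0, 0.2),
    nt_cm = rep(1.4, n) * 10^stats::rnorm(n, 0, 0.1),
    stringsAsFactors = FALSE
  )
}

# MoM profile table built directly from given per-group marker matrices
# (bypasses the median-model machinery when only the risk layer is under
# test).  `values` is a named list group -> matrix with one column per
# marker in `markers`.
profiles_from_values <- function(values, markers = names(hdp_markers),
                                 maternal_age = 28) {
  rows <- lapply(names(values), function(g) {
    x <- values[[g]]
    df <- data.frame(group = g, maternal_age = maternal_age,
                     stringsAsFactors = FALSE)
    df <- df[rep(1, nrow(x)), , drop = FALSE]
    for (j in seq_along(markers)) {
      df[[paste0(markers[j], "_adj_mom")]] <- x[, j]
    }
    df
  })
  out <- do.call(rbind, rows)
  out$subject_id <- sprintf("P%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}
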