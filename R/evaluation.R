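#' Empirical ROC curve with DeLong inference
#'
#' Builds the empirical ROC over all distinct score thresholds (a subject
#' is called positive when its score is greater than or equal to the
#' threshold; ties are grouped, never randomised), computes the area by
#' the trapezoidal rule -- numerically identical to the tie-corrected
#' Mann-Whitney concordance probability -- and attaches a 95% confidence
#' interval and a two-sided test of AUC = 0.5.  DeLong's covariance
#' estimator is the default; the Hanley-McNeil binormal-free
#' approximation is available for comparison with legacy software output.
#'
#' @param scores Numeric vector of per-subject scores (larger = more
#'   case-like).
#' @param is_case Logical vector, `TRUE` for cases.
#' @param ci_method `"delong"` (default) or `"hanley"`.
#' @param conf_level Confidence level for the AUC interval.
#' @return Object of class `"hdp_roc"`: `thresholds` (descending,
#'   starting at `Inf`), `fpr`, `tpr`, `auc`, `auc_se`, `auc_ci_low`,
#'   `auc_ci_high`, `p_value`, `n_case`, `n_control`.
#' @examples
#' r <- roc_curve(c(1, 3, 2, 4), c(FALSE, TRUE, FALSE, TRUE))
#' r$auc  # 0.75
#' @export
roc_curve <- function(scores, is_case, ci_method = c("delong", "hanley"),
                      conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  stop_if_not(length(scores) == length(is_case),
              "scores and is_case must have equal length")
  stop_if_not(all(is.finite(scores)), "scores must be finite")
  is_case <- as.logical(is_case)
  m <- sum(is_case); n0 <- sum(!is_case)
  stop_if_not(m > 0 && n0 > 0, "both cases and controls must be present")

  th <- sort(unique(scores), decreasing = TRUE)
  # counts of cases/controls at each distinct score, cumulated
  idx <- match(scores, th)
  tp <- cumsum(tabulate(idx[is_case], nbins = length(th)))
  fp <- cumsum(tabulate(idx[!is_case], nbins = length(th)))
  thresholds <- c(Inf, th)
  tpr <- c(0, tp / m)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  # DeLong placements via midranks (fast, tie-corrected)
  r_all <- rank(scores, ties.method = "average")
  r_case <- rank(scores[is_case], ties.method = "average")
  r_ctrl <- rank(scores[!is_case], ties.method = "average")
  v10 <- (r_all[is_case] - r_case) / n0          # P(case_i > random control)
  v01 <- 1 - (r_all[!is_case] - r_ctrl) / m      # P(random case > control_j)
  if (ci_method == "delong") {
    var_auc <- stats::var(v10) / m + stats::var(v01) / n0
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    var_auc <- (auc * (1 - auc) + (m - 1) * (q1 - auc^2) +
                  (n0 - 1) * (q2 - auc^2)) / (m * n0)
  }
  se <- sqrt(max(var_auc, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p_value <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else
    as.numeric(auc == 0.5)

  structure(
    list(thresholds = thresholds, fpr = fpr, tpr = tpr,
         auc = auc, auc_se = se,
         auc_ci_low = max(0, auc - z * se),
         auc_ci_high = min(1, auc + z * se),
         p_value = p_value, n_case = m, n_control = n0,
         ci_method = ci_method),
    class = "hdp_roc"
  )
}

#' @export
print.hdp_roc <- function(x, ...) {
  cat(sprintf("ROC: %d cases vs %d controls\n", x$n_case, x$n_control))
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f, p = %.3g, %s)\n",
              x$auc, x$auc_ci_low, x$auc_ci_high, x$p_value, x$ci_method))
  invisible(x)
}

#' Youden-index operating point
#'
#' Selects the threshold maximising the Youden index (sensitivity +
#' specificity - 1) and fills the full screening-metric battery at that
#' cut-off.  Ties in the Youden index are broken toward higher
#' sensitivity (screening favours detection) and then toward the lower
#' threshold; the rule is deterministic.
#'
#' @param curve An [roc_curve()] result.
#' @param prevalence Optional external prevalence for PPV/NPV; by default
#'   the case-control mix of the curve is used.
#' @return A `screening_metrics` object (see [metrics_at_cutoff()]) with
#'   the selected `cutoff`.
#' @export
youden_cutoff <- function(curve, prevalence = NULL) {
  stop_if_not(inherits(curve, "hdp_roc"), "curve must be an roc_curve result")
  j <- curve$tpr - curve$fpr
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[curve$tpr[best] == max(curve$tpr[best])]
  if (length(best) > 1) best <- best[which.min(curve$thresholds[best])]
  metrics <- metrics_at_cutoff(curve$tpr[best], 1 - curve$fpr[best],
                               curve$n_case, curve$n_control, prevalence)
  metrics$cutoff <- curve$thresholds[best]
  metrics
}

#' Screening-metric battery at an operating point
#'
#' Computes, in closed form from an operating point and the class sizes:
#' false-positive and false-negative rates, the Youden index, positive
#' and negative predictive values at the case-control mix (or at a
#' supplied prevalence) and the diagnostic likelihood ratios.  `plr` is
#' `Inf` when specificity is 1.
#'
#' @param sensitivity,specificity Rates in \[0, 1\].
#' @param n_case,n_control Positive class sizes.
#' @param prevalence Optional prevalence in (0, 1) replacing the sample
#'   mix in PPV/NPV.
#' @return Object of class `"screening_metrics"`: `cutoff` (`NA` until
#'   set by [youden_cutoff()]), `sensitivity`, `specificity`, `youden`,
#'   `fpr`, `fnr`, `ppv`, `npv`, `plr`, `nlr`, `n_case`, `n_control`.
#' @examples
#' m <- metrics_at_cutoff(1.000, 0.660, 41, 150)
#' c(m$plr, m$ppv)  # 2.941, 0.446
#' @export
metrics_at_cutoff <- function(sensitivity, specificity, n_case, n_control,
                              prevalence = NULL) {
  stop_if_not(sensitivity >= 0 && sensitivity <= 1 &&
                specificity >= 0 && specificity <= 1,
              "sensitivity and specificity must lie in [0, 1]")
  stop_if_not(n_case > 0 && n_control > 0, "class sizes must be positive")
  fpr <- 1 - specificity
  fnr <- 1 - sensitivity
  w_case <- if (is.null(prevalence)) n_case else prevalence
  w_ctrl <- if (is.null(prevalence)) n_control else 1 - prevalence
  ppv_den <- sensitivity * w_case + fpr * w_ctrl
  npv_den <- specificity * w_ctrl + fnr * w_case
  structure(
    list(cutoff = NA_real_,
         sensitivity = sensitivity, specificity = specificity,
         youden = sensitivity + specificity - 1,
         fpr = fpr, fnr = fnr,
         ppv = if (ppv_den > 0) sensitivity * w_case / ppv_den else NA_real_,
         npv = if (npv_den > 0) specificity * w_ctrl / npv_den else NA_real_,
         plr = if (fpr > 0) sensitivity / fpr else Inf,
         nlr = if (specificity > 0) fnr / specificity else NA_real_,
         n_case = n_case, n_control = n_control),
    class = "screening_metrics"
  )
}

#' @export
print.screening_metrics <- function(x, ...) {
  cat(sprintf(paste0("cut-off %.4g | sens %.3f spec %.3f youden %.3f | ",
                     "FPR %.3f FNR %.3f | PPV %.3f NPV %.3f | +LR %.3f -LR %.3f\n"),
              x$cutoff, x$sensitivity, x$specificity, x$youden,
              x$fpr, x$fnr, x$ppv, x$npv, x$plr, x$nlr))
  invisible(x)
}

#' Group-comparison statistics
#'
#' Reproduces the descriptive/test battery applied to each variable of a
#' case-control cohort: per-group medians with 2.5/97.5 percentiles, a
#' one-sample Kolmogorov-Smirnov normality check per group (against a
#' normal with the sample mean and SD), a tie-corrected Kruskal-Wallis
#' test across all groups, and pairwise Mann-Whitney tests of each case
#' group against control.
#'
#' @param data `data.frame` containing `group_col` plus the variables.
#' @param variables Character vector of numeric columns to analyse;
#'   defaults to every numeric column.
#' @param group_col Name of the group label column.
#' @param control Label of the reference group for pairwise tests.
#' @return List with elements `summaries`, `kruskal`, `mann_whitney`
#'   (tidy `data.frame`s).
#' @export
group_tests <- function(data, variables = NULL, group_col = "group",
                        control = "control") {
  stop_if_not(group_col %in% names(data), "no '%s' column", group_col)
  g <- as.character(data[[group_col]])
  groups <- unique(g)
  stop_if_not(length(groups) >= 2, "need at least two groups")
  stop_if_not(all(table(g) > 0), "empty group")
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, TRUE)]
  }
  stop_if_not(length(variables) > 0, "no numeric variables to test")

  summaries <- do.call(rbind, lapply(variables, function(v) {
    do.call(rbind, lapply(groups, function(grp) {
      x <- data[[v]][g == grp]
      ks <- suppressWarnings(
        stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
      q <- stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
      data.frame(variable = v, group = grp, n = length(x),
                 median = q[1], p2_5 = q[2], p97_5 = q[3],
                 ks_D = unname(ks$statistic), ks_p = ks$p.value,
                 stringsAsFactors = FALSE)
    }))
  }))

  kruskal <- do.call(rbind, lapply(variables, function(v) {
    kt <- stats::kruskal.test(data[[v]], factor(g))
    data.frame(variable = v, chisq = unname(kt$statistic),
               df = unname(kt$parameter), p = kt$p.value,
               stringsAsFactors = FALSE)
  }))

  case_groups <- setdiff(groups, control)
  mann_whitney <- do.call(rbind, lapply(variables, function(v) {
    do.call(rbind, lapply(case_groups, function(grp) {
      wt <- suppressWarnings(
        stats::wilcox.test(data[[v]][g == grp], data[[v]][g == control]))
      data.frame(variable = v, group = grp, U = unname(wt$statistic),
                 p = wt$p.value, stringsAsFactors = FALSE)
    }))
  }))

  list(summaries = summaries, kruskal = kruskal, mann_whitney = mann_whitney)
}

marker_display <- c(dd = "DD", papp_a = "PAPP-A",
                    free_b_hcg = "free b-hCG", nt = "NT")

model_display_name <- function(markers) {
  paste(marker_display[markers], collapse = "+")
}

fmt_mpp <- function(median, lo, hi, digits = 2) {
  sprintf("%.*f (%.*f-%.*f)", digits, median, digits, lo, digits, hi)
}

#' Summary tables of the full analysis
#'
#' Assembles the four publication-style tables from a cohort, its MoM
#' profiles and the per-case-definition model runs:
#' \describe{
#'   \item{table1}{demographics per group (median, 2.5--97.5 percentile)
#'     with Kruskal-Wallis statistics.}
#'   \item{table2}{raw concentration and MoM summaries per marker and
#'     group with Kruskal-Wallis statistics.}
#'   \item{table3}{per model x case group: AUC, 95% CI, p, Youden
#'     cut-off, sensitivity, specificity, Youden index.  Cut-offs of
#'     single-marker models are reported on the adjusted-MoM scale (the
#'     marker value of the subject at the operating threshold);
#'     multi-marker cut-offs are log10 likelihood-ratio scores.}
#'   \item{table4}{per model x case group: FPR, FNR, PPV, NPV, +LR, -LR
#'     at the Youden cut-off and the study's case-control mix.}
#' }
#'
#' @param results_by_case Named list (`GH`, `PE`, `SPE`, `HDP`) of
#'   [run_all_models()] outputs.
#' @param cohort Cohort `data.frame`.
#' @param profiles MoM profiles from [compute_mom()].
#' @param ci_method Passed to [roc_curve()].
#' @param prevalence Optional prevalence for PPV/NPV.
#' @return List of `data.frame`s: `table1`, `table2`, `table3`, `table4`,
#'   plus `roc_points` (long `data.frame` of ROC coordinates).
#' @export
summarize_tables <- function(results_by_case, cohort, profiles,
                             ci_method = "delong", prevalence = NULL) {
  needed <- c("GH", "PE", "SPE", "HDP")
  missing_runs <- setdiff(needed, names(results_by_case))
  stop_if_not(length(missing_runs) == 0,
              "missing model runs for case group(s): %s",
              paste(missing_runs, collapse = ", "))
  for (cg in needed) {
    miss <- setdiff(names(risk_model_markers()), names(results_by_case[[cg]]))
    stop_if_not(length(miss) == 0, "case group %s lacks model(s): %s",
                cg, paste(miss, collapse = ", "))
  }

  # --- tables 1-2: descriptive batteries -------------------------------
  demo <- group_tests(cohort,
                      variables = c("maternal_age", "maternal_weight",
                                    "gestational_age_days"))
  table1 <- build_descriptive_table(demo,
    c(maternal_age = "Maternal age (years)",
      maternal_weight = "Maternal weight (kg)",
      gestational_age_days = "Gestational age at testing (days)"))

  conc_vars <- unname(hdp_markers)
  mom_vars <- paste0(names(hdp_markers), "_adj_mom")
  tab2_data <- merge(cohort[, c("subject_id", "group", conc_vars)],
                     profiles[, c("subject_id", mom_vars)], by = "subject_id")
  conc_tests <- group_tests(tab2_data, variables = c(conc_vars, mom_vars))
  labels2 <- c(
    stats::setNames(sprintf("%s (%s)", marker_display,
                            c("ng/mL", "mU/L", "ng/mL", "cm")), conc_vars),
    stats::setNames(paste(marker_display, "MoM"), mom_vars))
  table2 <- build_descriptive_table(conc_tests, labels2)

  # --- tables 3-4: screening performance -------------------------------
  rows3 <- list(); rows4 <- list(); roc_rows <- list()
  for (cg in needed) {
    for (id in names(risk_model_markers())) {
      res <- results_by_case[[cg]][[id]]
      spec <- attr(res, "spec")
      curve <- roc_curve(res$score, res$is_case, ci_method = ci_method)
      metrics <- youden_cutoff(curve, prevalence)
      cutoff <- metrics$cutoff
      cutoff_scale <- "score_log10_lr"
      if (length(spec$markers) == 1) {
        at <- which(res$score == cutoff)[1]
        if (!is.na(at)) {
          prof_row <- profiles[match(res$subject_id[at], profiles$subject_id), ]
          cutoff <- prof_row[[paste0(spec$markers, "_adj_mom")]]
          cutoff_scale <- "adjusted_mom"
        }
      }
      nm <- model_display_name(spec$markers)
      rows3[[paste(cg, id)]] <- data.frame(
        case_group = cg, model_id = as.integer(id), screening_indicators = nm,
        n_case = curve$n_case, auc = curve$auc,
        ci_low = curve$auc_ci_low, ci_high = curve$auc_ci_high,
        p = curve$p_value, cutoff = cutoff, cutoff_scale = cutoff_scale,
        sensitivity = metrics$sensitivity, specificity = metrics$specificity,
        youden = metrics$youden, stringsAsFactors = FALSE)
      rows4[[paste(cg, id)]] <- data.frame(
        case_group = cg, model_id = as.integer(id), screening_indicators = nm,
        fpr = metrics$fpr, fnr = metrics$fnr, ppv = metrics$ppv,
        npv = metrics$npv, plr = metrics$plr, nlr = metrics$nlr,
        stringsAsFactors = FALSE)
      roc_rows[[paste(cg, id)]] <- data.frame(
        case_group = cg, model_id = as.integer(id),
        threshold = curve$thresholds, fpr = curve$fpr, tpr = curve$tpr,
        stringsAsFactors = FALSE)
    }
  }
  list(table1 = table1, table2 = table2,
       table3 = do.call(rbind, c(rows3, list(make.row.names = FALSE))),
       table4 = do.call(rbind, c(rows4, list(make.row.names = FALSE))),
       roc_points = do.call(rbind, c(roc_rows, list(make.row.names = FALSE))))
}

# wide descriptive table: one row per group, one formatted column per
# variable, plus Kruskal-Wallis chi-square and p rows
build_descriptive_table <- function(tests, labels) {
  s <- tests$summaries
  groups <- unique(s$group)
  out <- data.frame(Groups = groups,
                    n = vapply(groups, function(g)
                      s$n[s$group == g][1], 0),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (v in names(labels)) {
    digits <- if (grepl("days", labels[[v]])) 0 else 2
    out[[labels[[v]]]] <- vapply(groups, function(g) {
      r <- s[s$variable == v & s$group == g, ]
      fmt_mpp(r$median, r$p2_5, r$p97_5, digits)
    }, "")
  }
  k <- tests$kruskal
  stat_row <- c("chi-square", "",
                vapply(names(labels), function(v)
                  sprintf("%.3f", k$chisq[k$variable == v]), ""))
  p_row <- c("P", "",
             vapply(names(labels), function(v) {
               p <- k$p[k$variable == v]
               if (p < 0.001) "<0.001" else sprintf("%.3f", p)
             }, ""))
  out <- rbind(out, stats::setNames(as.list(stat_row), names(out)),
               stats::setNames(as.list(p_row), names(out)))
  rownames(out) <- NULL
  out
}
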