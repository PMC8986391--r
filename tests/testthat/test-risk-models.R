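test_that("the ten built-in marker subsets match the study design", {
  mk <- risk_model_markers()
  expect_length(mk, 10)
  expect_identical(mk[["1"]], "dd")
  expect_identical(mk[["7"]], c("papp_a", "free_b_hcg"))
  expect_identical(mk[["10"]], c("dd", "papp_a", "free_b_hcg", "nt"))
  expect_error(risk_model_spec(11), "model_id")
  expect_error(risk_model_spec(markers = c("dd", "dd")), "subset")
  expect_error(risk_model_spec(1, case_group = "XX"), "case_group")
})

test_that("group density fitting returns sample moments and guards input", {
  set.seed(1)
  x <- matrix(10^rnorm(400, 0, 0.1), ncol = 2)
  profiles <- profiles_from_values(list(control = x), c("dd", "papp_a"))
  spec <- risk_model_spec(markers = c("dd", "papp_a"))
  fit <- fit_group_density(profiles, spec, "control")
  lx <- log10(x)
  expect_equal(unname(fit$mean), unname(colMeans(lx)), tolerance = 1e-12)
  expect_equal(unname(fit$covariance), unname(cov(lx)), tolerance = 1e-12)
  expect_equal(fit$n, 200)

  # univariate: 1x1 covariance equal to the sample variance
  spec1 <- risk_model_spec(markers = "dd")
  fit1 <- fit_group_density(profiles, spec1, "control")
  expect_equal(dim(fit1$covariance), c(1, 1))
  expect_equal(fit1$covariance[1, 1], var(lx[, 1]), tolerance = 1e-12)

  # fewer than 10 records
  expect_error(fit_group_density(profiles[1:5, ], spec, "control"), ">= 10")

  # constant vector: zero variance is an error naming the marker
  const <- profiles_from_values(list(control = matrix(2, 20, 1)), "dd")
  expect_error(fit_group_density(const, risk_model_spec(markers = "dd"),
                                 "control"), "zero variance.*dd")
})

test_that("density refit on its own draws recovers mean and covariance", {
  mom <- compute_mom(small_cohort(seed = 3), list(dd = dd_median_model()))
  # borrow a univariate fit, then extend to a known 2d Gaussian
  mu <- c(0.05, -0.02)
  sigma <- matrix(c(0.04, 0.015, 0.015, 0.09), 2)
  set.seed(99)
  n <- 10000
  draws <- MASS::mvrnorm(n, mu, sigma)
  profiles <- profiles_from_values(list(control = 10^draws),
                                   c("dd", "papp_a"))
  refit <- fit_group_density(profiles,
                             risk_model_spec(markers = c("dd", "papp_a")),
                             "control")
  se_mean <- sqrt(diag(sigma) / n)
  expect_true(all(abs(refit$mean - mu) < 3 * se_mean))
  se_cov <- sqrt((outer(diag(sigma), diag(sigma)) + sigma^2) / n)
  expect_true(all(abs(refit$covariance - sigma) < 3 * se_cov))
})

test_that("multivariate normal density matches closed forms", {
  std1 <- structure(list(group = "control", markers = "dd", mean = c(dd = 0),
                         covariance = matrix(1, 1, 1), n = 100,
                         log_transform = TRUE),
                    class = "gaussian_group_model")
  expect_equal(likelihood(std1, 0), 1 / sqrt(2 * pi), tolerance = 1e-12)

  std2 <- structure(list(group = "control", markers = c("dd", "nt"),
                         mean = c(dd = 0, nt = 0), covariance = diag(2),
                         n = 100, log_transform = TRUE),
                    class = "gaussian_group_model")
  expect_equal(likelihood(std2, c(0, 0)), 1 / (2 * pi), tolerance = 1e-12)

  # mode dominates any other point
  xs <- matrix(rnorm(40), ncol = 2)
  expect_true(all(likelihood(std2, c(0, 0)) >= likelihood(std2, xs)))

  expect_error(likelihood(std2, c(1, 2, 3)), "dimension mismatch")
  expect_error(likelihood(std2, c(NA, 1)), "finite")
})

test_that("likelihood ratios follow the Gaussian shift structure", {
  mk <- function(mu, var) structure(
    list(group = "g", markers = "dd", mean = c(dd = mu),
         covariance = matrix(var, 1, 1), n = 50, log_transform = TRUE),
    class = "gaussian_group_model")
  case <- mk(1, 1); ctrl <- mk(0, 1)

  # identical densities give LR = 1 everywhere
  xs <- seq(-3, 3, length.out = 21)
  expect_equal(likelihood_ratio(ctrl, ctrl, matrix(xs)), rep(1, 21),
               tolerance = 1e-12)
  # equal-variance shift: LR monotone increasing, LR = 1 at the midpoint
  lr <- likelihood_ratio(case, ctrl, matrix(xs))
  expect_true(all(diff(lr) > 0))
  expect_equal(likelihood_ratio(case, ctrl, 0.5), 1, tolerance = 1e-12)

  # no overflow at extreme log-LR
  far <- mk(0, 1e-4)
  expect_true(is.finite(likelihood_ratio(mk(1, 1e-4), far, 0.5)))

  bad <- mk(0, 1); bad$markers <- "nt"
  expect_error(likelihood_ratio(case, bad, 0), "marker sets")
})

test_that("maternal-age prior variants evaluate and order correctly", {
  expect_equal(maternal_age_prior(30), 0.000627 + exp(-7.6595),
               tolerance = 1e-12)
  expect_equal(maternal_age_prior(30), 1.099e-3, tolerance = 1e-3)
  for (v in c("canonical", "half_year", "trailing_term")) {
    r <- maternal_age_prior(c(20, 30, 40), v)
    expect_true(all(diff(r) > 0))
    expect_true(all(r > 0 & r < 1))
  }
  # the trailing-term parse scales the exponential component by e^-0.5
  a <- seq(15, 45, by = 5)
  rc <- maternal_age_prior(a, "canonical")
  rt <- maternal_age_prior(a, "trailing_term")
  expect_equal(rt - 0.000627, exp(-0.5) * (rc - 0.000627), tolerance = 1e-12)
  expect_error(maternal_age_prior(8), "10, 60")
})

test_that("risk combination follows the printed convention identities", {
  set.seed(4)
  vals <- list(control = matrix(10^rnorm(50, 0, 0.1), 50, 1),
               SPE = matrix(10^rnorm(50, 0.15, 0.1), 50, 1))
  profiles <- profiles_from_values(vals, "dd", maternal_age = 32)
  spec <- risk_model_spec(markers = "dd", case_group = "SPE")
  case_m <- fit_group_density(profiles, spec, "SPE")
  ctrl_m <- fit_group_density(profiles, spec, "control")
  res <- compute_risk(spec, case_m, ctrl_m, profiles)

  # as-printed: risk * LR = age prior, exactly
  expect_equal(res$risk_hdp * res$lr, res$risk_age, tolerance = 1e-12)
  expect_equal(res$score, log10(res$lr), tolerance = 1e-12)

  spec_d <- risk_model_spec(markers = "dd", case_group = "SPE",
                            risk_convention = "direct")
  res_d <- compute_risk(spec_d, case_m, ctrl_m, profiles)
  expect_equal(res_d$risk_hdp, res_d$lr * res_d$risk_age, tolerance = 1e-12)
  # ranking score identical under both conventions
  expect_equal(res_d$score, res$score, tolerance = 1e-12)

  # LR = 1 implies risk equals the age prior under both conventions
  res1 <- compute_risk(spec, ctrl_m, ctrl_m, profiles)
  expect_equal(res1$risk_hdp, res1$risk_age, tolerance = 1e-12)

  # construction check: case scores exceed control scores on average
  expect_gt(mean(res$score[profiles$group == "SPE"]),
            mean(res$score[profiles$group == "control"]))
})

test_that("log-LR scores are invariant to affine maps of marker space", {
  set.seed(5)
  n <- 120
  vals <- list(control = MASS::mvrnorm(n, c(0, 0, 0), diag(3) * 0.05),
               PE = MASS::mvrnorm(n, c(0.1, -0.1, 0.05),
                                  diag(3) * 0.08 + 0.01))
  markers <- c("dd", "papp_a", "free_b_hcg")
  base <- profiles_from_values(vals, markers)
  spec <- risk_model_spec(markers = markers, case_group = "PE",
                          log_transform = FALSE)
  score_of <- function(profiles) {
    cm <- fit_group_density(profiles, spec, "PE")
    km <- fit_group_density(profiles, spec, "control")
    compute_risk(spec, cm, km, profiles)$score
  }
  s0 <- score_of(base)
  for (rep in 1:5) {
    A <- matrix(rnorm(9), 3)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3)
    b <- rnorm(3)
    tvals <- lapply(vals, function(x) sweep(x %*% t(A), 2, -b))
    expect_equal(score_of(profiles_from_values(tvals, markers)), s0,
                 tolerance = 1e-8)
  }
})

test_that("adding an uninformative marker leaves expected log-LR unchanged", {
  set.seed(6)
  n <- 4000
  vals1 <- list(control = matrix(rnorm(n, 0, 0.2), ncol = 1),
                GH = matrix(rnorm(n, 0.15, 0.2), ncol = 1))
  noise <- list(control = matrix(rnorm(n, 0, 0.3), ncol = 1),
                GH = matrix(rnorm(n, 0, 0.3), ncol = 1))
  vals2 <- mapply(cbind, vals1, noise, SIMPLIFY = FALSE)
  score_mean <- function(vals, markers) {
    profiles <- profiles_from_values(lapply(vals, function(x) 10^x), markers)
    spec <- risk_model_spec(markers = markers, case_group = "GH")
    cm <- fit_group_density(profiles, spec, "GH")
    km <- fit_group_density(profiles, spec, "control")
    res <- compute_risk(spec, cm, km, profiles)
    mean(res$score[profiles$group == "GH"])
  }
  m1 <- score_mean(vals1, "dd")
  m2 <- score_mean(vals2, c("dd", "nt"))
  # Monte-Carlo error of the mean log-LR at n = 4000 is ~0.005
  expect_lt(abs(m2 - m1), 0.02)
})

test_that("run_all_models covers the ten specs with correct bookkeeping", {
  cohort <- small_cohort(seed = 8)
  mom <- compute_mom(cohort, fit_all_median_models(cohort))
  for (cg in c("GH", "PE", "SPE", "HDP")) {
    res <- run_all_models(mom, cg)
    expect_named(res, as.character(1:10))
    n_case <- c(GH = 126, PE = 53, SPE = 41, HDP = 220)[[cg]]
    for (id in names(res)) {
      expect_equal(nrow(res[[id]]), n_case + 150)
      expect_equal(sum(res[[id]]$is_case), n_case)
    }
    expect_false(isTRUE(all.equal(res[["1"]]$score, res[["10"]]$score)))
  }
  expect_error(run_all_models(mom[mom$group == "control", ], "SPE"), "empty")
})

test_that("fitted group models serialize through JSON", {
  cohort <- small_cohort(seed = 9)
  mom <- compute_mom(cohort, fit_all_median_models(cohort))
  spec <- risk_model_spec(markers = c("dd", "nt"), case_group = "SPE")
  models <- list(case = fit_group_density(mom, spec, "SPE"),
                 control = fit_group_density(mom, spec, "control"))
  path <- withr::local_tempfile(fileext = ".json")
  write_group_models(models, path)
  back <- read_group_models(path)
  expect_equal(back$case$mean, models$case$mean)
  expect_equal(unname(back$case$covariance), unname(models$case$covariance))
  x <- c(0.01, -0.02)
  expect_equal(likelihood_ratio(back$case, back$control, x),
               likelihood_ratio(models$case, models$control, x),
               tolerance = 1e-12)
})
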