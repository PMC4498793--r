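test_that("fixed-effect estimates match the closed-form group means", {
  # balanced two-level factor, one observation per subject: the class
  # coefficient must equal the difference of group means exactly
  set.seed(31)
  n <- 24
  cls <- rep(c("normal", "mild"), each = n / 2)
  vals <- rnorm(n, mean = ifelse(cls == "mild", 2.5, 2.0), sd = 0.3)
  desc <- descriptor_record(sprintf("S%02d", 1:n), 41, "whole", "GI", vals)
  cov <- data.frame(subject_id = sprintf("S%02d", 1:n), pma_30 = 30,
                    pma_40 = 41, class_cogm = cls, class_total = cls,
                    fissure_width = 1)
  dat <- join_covariates(desc, cov)
  expect_message(fit <- fit_lmm(dat, model_spec("GI", "class_cogm")),
                 "downgrading")
  est <- fit$coefficients$estimate[fit$coefficients$term == "class_cogmmild"]
  expect_equal(est, mean(vals[cls == "mild"]) - mean(vals[cls == "normal"]),
               tolerance = 1e-10)
  expect_equal(fit$engine, "lm")
})

test_that("rank-deficient designs are refused naming the aliased terms", {
  sim <- simulate_descriptor_cohort(n_subjects = 10,
                                    class_counts = c(normal = 5, mild = 5,
                                                     moderate_severe = 0),
                                    seed = 2)
  dat <- join_covariates(sim$descriptors, sim$covariates)
  dat$interval <- 10  # constant covariate: aliased with the intercept
  expect_error(fit_lmm(dat, model_spec("T_median", c("class_cogm", "interval"))),
               "aliased.*interval")
})

test_that("null cohorts give calibrated class estimates", {
  reps <- 20
  inside <- vapply(seq_len(reps), function(r) {
    sim <- simulate_descriptor_cohort(n_subjects = 40,
                                      class_counts = c(normal = 14, mild = 13,
                                                       moderate_severe = 13),
                                      effects = c(mild = 0, moderate_severe = 0),
                                      seed = 100 + r)
    dat <- join_covariates(sim$descriptors, sim$covariates)
    fit <- fit_lmm(dat, model_spec("T_median", "class_cogm"))
    cf <- fit$coefficients
    row <- cf[cf$term == "class_cogmmoderate_severe", ]
    abs(row$estimate) < 2 * row$se
  }, TRUE)
  expect_gte(mean(inside), 0.85)
})

test_that("an injected class effect is recovered within 2 SE", {
  sim <- simulate_descriptor_cohort(seed = 9)  # packaged +0.067 effect
  dat <- join_covariates(sim$descriptors, sim$covariates)
  fit <- fit_lmm(dat, model_spec("T_median", "class_cogm"))
  cf <- fit$coefficients
  row <- cf[cf$term == "class_cogmmoderate_severe", ]
  expect_lt(abs(row$estimate - 0.067), 2 * row$se)
  expect_equal(fit$engine, "lmer")
})

test_that("AIC selection prefers the generative model", {
  gen <- function(with_age, seed) {
    sim <- simulate_descriptor_cohort(n_subjects = 60,
                                      class_counts = c(normal = 20, mild = 20,
                                                       moderate_severe = 20),
                                      sd_subject = 0.05, sd_resid = 0.05,
                                      seed = seed)
    dat <- join_covariates(sim$descriptors, sim$covariates)
    if (with_age)
      dat$value <- dat$value + 0.1 * (dat$pma_40 - mean(dat$pma_40))
    dat
  }
  cand <- list(model_spec("T_median", "class_cogm"),
               model_spec("T_median", c("class_cogm", "pma_at_scan")))
  win_with <- vapply(1:25, function(r) {
    sel <- select_model_aic(gen(TRUE, 200 + r), cand)
    identical(sel$best$fixed, cand[[2]]$fixed)
  }, TRUE)
  expect_gte(mean(win_with), 0.9)
  win_without <- vapply(1:25, function(r) {
    sel <- select_model_aic(gen(FALSE, 300 + r), cand)
    identical(sel$best$fixed, cand[[1]]$fixed)
  }, TRUE)
  expect_gte(mean(win_without), 0.7)

  single <- select_model_aic(gen(FALSE, 1), cand[1])
  expect_identical(single$best, cand[[1]])
})

test_that("spearman matches a brute-force rank oracle and handles monotone maps", {
  expect_equal(spearman_assoc(1:10, 1:10)$rho, 1)
  expect_equal(spearman_assoc(seq(0.5, 5, by = 0.5),
                              -seq(0.5, 5, by = 0.5)^2)$rho, -1)
  set.seed(4)
  x <- rnorm(20); y <- 0.3 * x + rnorm(20)
  # brute force: ranks by counting, Pearson by its definition
  brute_rank <- function(v) vapply(v, function(vi) sum(v <= vi), 1.0)
  rx <- brute_rank(x); ry <- brute_rank(y)
  rho_bf <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  res <- spearman_assoc(x, y)
  expect_equal(res$rho, rho_bf, tolerance = 1e-12)
  expect_equal(res$rho, suppressWarnings(
    cor.test(x, y, method = "spearman")$estimate[["rho"]]), tolerance = 1e-12)
  expect_error(spearman_assoc(1:2, 1:2), "at least 3")
})

test_that("class effect table recovers injected directions and flags nulls", {
  mk <- function(descriptor, mu, effects, sds, seed)
    simulate_descriptor_cohort(n_subjects = 150,
                               class_counts = c(normal = 50, mild = 50,
                                                moderate_severe = 50),
                               descriptor = descriptor, mu = mu,
                               sd_subject = sds[1], sd_resid = sds[2],
                               effects = effects, seed = seed)
  s1 <- mk("T_median", 1.4, c(mild = 0.01, moderate_severe = 0.067),
           c(0.06, 0.05), 21)
  s2 <- mk("GI", 2.7, c(mild = -0.07, moderate_severe = -0.17),
           c(0.08, 0.06), 22)
  s3 <- mk("C_global", 4.2, c(mild = -0.29, moderate_severe = -0.86),
           c(0.5, 0.4), 23)
  tab <- rbind(
    class_effect_table(s1$descriptors, s1$covariates, responses = "T_median"),
    class_effect_table(s2$descriptors, s2$covariates, responses = "GI"),
    class_effect_table(s3$descriptors, s3$covariates, responses = "C_global"))
  ms <- tab[tab$class == "moderate_severe", ]
  expect_gt(ms$estimate[ms$descriptor == "T_median"], 0)
  expect_lt(ms$estimate[ms$descriptor == "GI"], 0)
  expect_lt(ms$estimate[ms$descriptor == "C_global"], 0)
  expect_true(all(ms$significant))

  # toy table with exact group means: estimates equal group-mean differences
  cls <- rep(c("normal", "mild", "moderate_severe"), each = 4)
  vals <- c(rep(1, 4), rep(1.2, 4), rep(1.5, 4))
  toy <- descriptor_record(sprintf("T%02d", 1:12), 41, "whole", "T_median", vals)
  covt <- data.frame(subject_id = sprintf("T%02d", 1:12), pma_30 = 30,
                     pma_40 = 41, class_cogm = cls, class_total = cls,
                     fissure_width = 1)
  # zero-residual toy data: the perfect-fit warning is the point
  suppressWarnings(suppressMessages(
    tt <- class_effect_table(toy, covt, responses = "T_median")))
  expect_equal(tt$estimate[tt$class == "mild"], 0.2, tolerance = 1e-10)
  expect_equal(tt$estimate[tt$class == "moderate_severe"], 0.5,
               tolerance = 1e-10)

  # zero-effect cohort: flagged not significant
  s0 <- mk("GI", 2.0, c(mild = 0, moderate_severe = 0), c(0.08, 0.06), 25)
  t0 <- class_effect_table(s0$descriptors, s0$covariates, responses = "GI")
  expect_false(any(t0$any_significant))
})
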