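test_that("REML matches the balanced one-way ANOVA closed form", {
  d <- one_way_data(ng = 40, r = 4, seed = 11)
  fit <- fit_lmm(d, y ~ 1, random = list(ranef_iid("g")))
  cf <- one_way_anova(d, r = 4)
  expect_equal(get_varcomp(fit, "g"), cf$s2g, tolerance = 1e-6)
  expect_equal(get_varcomp(fit, ".residual"), cf$s2e, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("REML agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  d <- line_tp_data(nl = 80, seed = 5)
  fit <- fit_lmm(d, value ~ factor(timepoint),
                 random = list(ranef_iid("line_id"),
                               ranef_iid(c("line_id", "timepoint"))))
  ref <- lme4::lmer(value ~ factor(timepoint) + (1 | line_id) +
                      (1 | line_id:timepoint), d, REML = TRUE)
  expect_equal(fit$loglik_reml, as.numeric(stats::logLik(ref)), tolerance = 1e-7)
  vc <- lme4::VarCorr(ref)
  expect_equal(get_varcomp(fit, "line_id"), as.numeric(vc$line_id),
               tolerance = 1e-4)
  expect_equal(get_varcomp(fit, "line_id:timepoint"),
               as.numeric(vc$`line_id:timepoint`), tolerance = 1e-4)
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-6)
})

test_that("constant response collapses to zero variances and the constant mean", {
  d <- one_way_data(ng = 20, r = 3, seed = 2)
  d$y <- 5
  fit <- fit_lmm(d, y ~ 1, random = list(ranef_iid("g")))
  expect_equal(unname(fit$beta["(Intercept)"]), 5)
  expect_lt(max(fit$varcomp$estimate[fit$varcomp$type == "variance"]), 1e-8)
})

test_that("shifting the response moves only the intercept", {
  d <- one_way_data(ng = 30, r = 3, seed = 3)
  f1 <- fit_lmm(d, y ~ 1, random = list(ranef_iid("g")))
  d2 <- d; d2$y <- d2$y + 100
  f2 <- fit_lmm(d2, y ~ 1, random = list(ranef_iid("g")))
  expect_equal(unname(f2$beta["(Intercept)"] - f1$beta["(Intercept)"]), 100,
               tolerance = 1e-6)
  expect_equal(f1$varcomp$estimate, f2$varcomp$estimate, tolerance = 1e-8)
})

test_that("row order of the data never changes the fit", {
  d <- line_tp_data(nl = 40, seed = 9)
  f1 <- fit_lmm(d, value ~ factor(timepoint),
                random = list(ranef_iid("line_id")))
  set.seed(1)
  d2 <- d[sample(nrow(d)), ]
  f2 <- fit_lmm(d2, value ~ factor(timepoint),
                random = list(ranef_iid("line_id")))
  expect_equal(f1$loglik_reml, f2$loglik_reml, tolerance = 1e-9)
  expect_equal(f1$varcomp$estimate, f2$varcomp$estimate, tolerance = 1e-7)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-7)
})

test_that("perturbed starting values reach the same restricted likelihood", {
  d <- line_tp_data(nl = 60, seed = 13)
  fits <- lapply(1:3, function(k)
    fit_lmm(d, value ~ factor(timepoint),
            random = list(ranef_iid("line_id"),
                          ranef_iid(c("line_id", "timepoint"))),
            starts = k))
  lls <- vapply(fits, `[[`, 1, "loglik_reml")
  expect_lt(diff(range(lls)) / abs(mean(lls)), 1e-6)
})

test_that("duplicated trait with common line effects drives r_g to the boundary", {
  set.seed(21)
  nl <- 120
  u <- rnorm(nl)
  d <- expand.grid(line_id = sprintf("L%03d", 1:nl), trait = c("A", "B"),
                   rep = 1:2, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  li <- as.integer(factor(d$line_id))
  d$value <- u[li] * ifelse(d$trait == "A", 1, 2) + rnorm(nrow(d), sd = 0.3)
  fit <- fit_lmm(d, value ~ trait, random = list(ranef_us2("line_id", "trait")),
                 residual = resid_diag("trait"))
  expect_gt(get_varcomp(fit, "line_id@trait", "cor"), 0.95)
})

test_that("non-identifiable specifications are refused with the terms named", {
  d <- tibble::tibble(g = sprintf("g%02d", 1:20), y = rnorm(20))
  expect_error(fit_lmm(d, y ~ 1, random = list(ranef_iid("g"))),
               "not identifiable.*g", )
})

test_that("likelihood-ratio test behaves at its boundary cases", {
  d <- line_tp_data(nl = 60, seed = 4)
  full <- fit_lmm(d, value ~ factor(timepoint),
                  random = list(ranef_iid("line_id"),
                                ranef_iid(c("line_id", "timepoint"))))
  reduced <- fit_lmm(d, value ~ factor(timepoint),
                     random = list(ranef_iid("line_id")))
  out <- lrt(full, reduced)
  expect_equal(out$df, 1)
  expect_gte(out$stat, 0)
  # identical fits: stat 0, p 1
  same <- lrt(full, full, df = 1)
  expect_equal(same$stat, 0)
  expect_equal(same$p, 1)
  # chi-square reference: stat 6.635 on 1 df is the 1% point
  expect_equal(stats::pchisq(6.635, 1, lower.tail = FALSE), 0.01,
               tolerance = 1e-3)
  # differing fixed structures are refused
  other <- fit_lmm(d, value ~ 1, random = list(ranef_iid("line_id")))
  expect_error(lrt(full, other), "not REML-comparable")
})

test_that("Wald table reports t = estimate/se and flags aliased levels", {
  d <- line_tp_data(nl = 50, seed = 6)
  fit <- fit_lmm(d, value ~ factor(timepoint), random = list(ranef_iid("line_id")))
  w <- wald_fixed(fit)
  expect_equal(w$t, w$estimate / w$se)
  expect_true(all(w$p >= 0 & w$p <= 1))
  # an aliased level: a factor column identical to another
  d$dup <- d$timepoint
  fit2 <- fit_lmm(d, value ~ factor(timepoint) + factor(dup),
                  random = list(ranef_iid("line_id")))
  w2 <- wald_fixed(fit2)
  expect_true(any(w2$aliased))
  expect_true(all(is.na(w2$estimate[w2$aliased])))
})

test_that("reported restricted likelihood is reproducible at the optimum", {
  d <- one_way_data(ng = 30, r = 3, seed = 8)
  fit <- fit_lmm(d, y ~ 1, random = list(ranef_iid("g")))
  refit <- fit_lmm(d, y ~ 1, random = list(ranef_iid("g")), starts = 1)
  expect_equal(fit$loglik_reml, refit$loglik_reml, tolerance = 1e-8)
})

test_that("tidy and glance expose fixed effects, variance components and fit summary", {
  d <- one_way_data(ng = 25, r = 3, seed = 10)
  fit <- fit_lmm(d, y ~ 1, random = list(ranef_iid("g")))
  td <- tidy(fit)
  expect_true(all(c("fixed", "varcomp") %in% td$effect_type))
  gl <- glance(fit)
  expect_equal(gl$nobs, 75)
  expect_true(gl$converged)
})
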