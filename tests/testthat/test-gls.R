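# varIdent GLS engine: closed-form reductions, reference-implementation
# agreement, parameter recovery, LRT and backward selection mechanics.

sim_groups <- function(n_per, means, sds, seed) {
  set.seed(seed)
  g <- factor(rep(names(means), each = n_per), levels = names(means))
  data.frame(g = g, y = rnorm(length(g), means[g], sds[g]))
}

test_that("dropping the variance structure reproduces OLS exactly", {
  d <- sim_groups(25, c(a = 1, b = 2, c = 0, d = 3), c(a = 1, b = 1, c = 1, d = 1), 1)
  f <- gls_varident(y ~ g, d, NULL, "ML")
  o <- lm(y ~ g, d)
  expect_lt(max(abs(f$coefficients$estimate - coef(o))), 1e-8)
  expect_equal(f$logLik, as.numeric(logLik(o)), tolerance = 1e-10)
  # closed-form REML log-likelihood for the homoscedastic case
  fr <- gls_varident(y ~ g, d, NULL, "REML")
  X <- model.matrix(~g, d); n <- nrow(d); p <- ncol(X)
  rss <- sum(resid(o)^2)
  ll <- -(n - p) / 2 * (log(2 * pi) + 1) - (n - p) / 2 * log(rss / (n - p)) -
    0.5 * as.numeric(determinant(crossprod(X))$modulus)
  expect_equal(fr$logLik, ll, tolerance = 1e-10)
})

test_that("coefficients and logLik agree with the nlme reference to 1e-4", {
  library(nlme)
  d <- sim_groups(12, c(a = 0, b = 1.5, c = -1, d = 2),
                  c(a = 1, b = 2.5, c = 0.7, d = 4), 42)
  for (meth in c("REML", "ML")) {
    mine <- gls_varident(y ~ g, d, "g", meth)
    ref <- nlme::gls(y ~ g, d, weights = nlme::varIdent(form = ~1 | g),
                     method = meth)
    expect_lt(max(abs(mine$coefficients$estimate - coef(ref))), 1e-4)
    expect_lt(abs(mine$logLik - as.numeric(logLik(ref))), 1e-4)
    expect_lt(abs(mine$AIC - AIC(ref)), 1e-3)
    ref_ratio <- coef(ref$modelStruct$varStruct, unconstrained = FALSE,
                      allCoef = TRUE)
    expect_lt(max(abs(mine$variance_ratios[names(ref_ratio)] - ref_ratio)),
              1e-3)
  }
})

test_that("a 3x sd ratio is recovered within 10% at n = 200 per group", {
  d <- sim_groups(200, c(a = 5, b = 7), c(a = 2, b = 6), 77)
  f <- gls_varident(y ~ g, d, "g", "REML")
  expect_true(f$variance_ratios["b"] >= 2.7 && f$variance_ratios["b"] <= 3.3)
  expect_true(f$converged)
})

test_that("AIC counts fixed effects, free ratios and the reference sd", {
  d <- sim_groups(10, c(a = 0, b = 1, c = 2, d = 3),
                  c(a = 1, b = 2, c = 1, d = 2), 3)
  f <- gls_varident(y ~ g, d, "g", "ML")
  expect_equal(f$AIC, -2 * f$logLik + 2 * (4 + 3 + 1))
  f0 <- gls_varident(y ~ 1, d, NULL, "ML")
  expect_equal(f0$AIC, -2 * f0$logLik + 2 * 2)
})

test_that("reference-level swap changes coefficients but not fit or likelihood", {
  d <- sim_groups(8, c(HD = -486, HU = -347, CV = -383, Mix = -360),
                  c(HD = 160, HU = 90, CV = 90, Mix = 70), 11)
  f1 <- gls_varident(y ~ g, d, "g", "REML",
                     reference_levels = list(g = "HD"))
  f2 <- gls_varident(y ~ g, d, "g", "REML",
                     reference_levels = list(g = "CV"))
  expect_false(isTRUE(all.equal(f1$coefficients$estimate,
                                f2$coefficients$estimate)))
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-6)
})

test_that("variance-ratio bias shrinks as replication grows", {
  err <- sapply(c(5, 50, 500), function(n_per) {
    est <- sapply(1:8, function(s) {
      d <- sim_groups(n_per, c(a = 0, b = 0), c(a = 1, b = 2), 1000 + s)
      gls_varident(y ~ g, d, "g", "REML")$variance_ratios["b"]
    })
    abs(mean(est) - 2)
  })
  expect_lt(err[3], err[1] + 0.02)
  expect_lt(err[3], 0.05)
})

test_that("degenerate inputs are rejected with informative errors", {
  d <- sim_groups(5, c(a = 0, b = 1), c(a = 1, b = 1), 2)
  d$x1 <- as.numeric(d$g == "a"); d$x2 <- 1 - d$x1
  expect_error(gls_varident(y ~ g + x1 + x2, d, NULL), "aliased")
  d1 <- d[c(1:5, 6), ]; d1$g <- factor(c(rep("a", 5), "b"))
  expect_error(gls_varident(y ~ 1, d1, "g"), "at least 2")
  expect_error(gls_varident(y ~ g, d, "nope"), "not in data")
})

test_that("the likelihood-ratio test behaves as specified", {
  d <- sim_groups(10, c(a = 0, b = 2, c = 1, d = 0.5),
                  c(a = 1, b = 1, c = 1, d = 1), 21)
  full <- gls_varident(y ~ g, d, NULL, "ML")
  # identical models: L = 0, p = 1 (guard against tiny negative values)
  same <- gls_varident(y ~ g, d, NULL, "ML")
  lt0 <- gls_lrt(full, same)
  expect_equal(lt0$L_ratio, 0)
  expect_equal(lt0$p, 1)
  red <- gls_varident(y ~ 1, d, NULL, "ML")
  lt <- gls_lrt(full, red)
  expect_equal(lt$df, 3L)
  expect_gte(lt$L_ratio, 0)
  expect_true(lt$p >= 0 && lt$p <= 1)
  # REML fits with different fixed effects are refused
  fr <- gls_varident(y ~ g, d, NULL, "REML")
  rr <- gls_varident(y ~ 1, d, NULL, "REML")
  expect_error(gls_lrt(fr, rr), "not comparable")
  # varIdent vs homoscedastic under REML (same fixed effects) is legal
  fv <- gls_varident(y ~ g, d, "g", "REML")
  lt2 <- gls_lrt(fv, fr)
  expect_equal(lt2$df, 3L)
})

test_that("the variance-structure LRT is calibrated on homoscedastic data", {
  # equal means, equal sds: the varIdent-vs-homoscedastic REML likelihood
  # ratio should stay below the chi-square critical value in >= 90% of seeds
  crit <- qchisq(0.95, 3)
  n_reject <- 0L
  for (s in 1:200) {
    set.seed(derive_seed(s, 55))
    d <- data.frame(g = factor(rep(letters[1:4], each = 5)), y = rnorm(20))
    fv <- gls_varident(y ~ 1, d, "g", "REML")
    fh <- gls_varident(y ~ 1, d, NULL, "REML")
    if (2 * (fv$logLik - fh$logLik) > crit) n_reject <- n_reject + 1L
  }
  expect_gte(200L - n_reject, 180L)
})

test_that("backward selection drops a null factor and keeps a strong one", {
  # null data
  d0 <- make_experiment(experiment_design(core_shapes = "square",
                                          replicates = 5, seed = 63),
                        sigma_by_group = c(HD = 1, HU = 1, CV = 1, Mix = 1),
                        mu_by_group = c(HD = 0, HU = 0, CV = 0, Mix = 0),
                        shape_effect = 0)
  kept <- sapply(1:20, function(s) {
    d <- make_experiment(experiment_design(core_shapes = "square",
                                           replicates = 5,
                                           seed = derive_seed(s, 5)),
                         sigma_by_group = c(HD = 1, HU = 1, CV = 1, Mix = 1),
                         mu_by_group = c(HD = 0, HU = 0, CV = 0, Mix = 0),
                         shape_effect = 0)
    sel <- backward_select(response ~ treatment, d, varident = "treatment")
    grepl("treatment", deparse(sel$formula))
  })
  expect_lt(mean(kept), 0.5)
  # strong factor is retained
  kept2 <- sapply(1:20, function(s) {
    d <- make_experiment(experiment_design(core_shapes = "square",
                                           replicates = 5,
                                           seed = derive_seed(s, 6)),
                         sigma_by_group = c(HD = 1, HU = 1, CV = 1, Mix = 1),
                         mu_by_group = c(HD = 0, HU = 4, CV = 0, Mix = 0),
                         shape_effect = 0)
    sel <- backward_select(response ~ treatment, d, varident = "treatment")
    grepl("treatment", deparse(sel$formula))
  })
  expect_gte(mean(kept2), 0.95)
  # intercept-only start returns unchanged with a single trace entry
  sel0 <- backward_select(response ~ 1, d0)
  expect_equal(deparse(sel0$formula), "response ~ 1")
  expect_equal(nrow(sel0$trace), 1L)
  # trace records variance stage and candidate AICs when varIdent offered
  sel1 <- backward_select(response ~ treatment, d0, varident = "treatment")
  expect_true(any(sel1$trace$stage == "variance"))
  expect_true(any(sel1$trace$stage == "fixed"))
  expect_true(all(is.finite(sel1$trace$AIC)))
})

test_that("heteroscedastic data at the experimental scale selects varIdent", {
  picked <- sapply(1:10, function(s) {
    d <- make_experiment(experiment_design(core_shapes = "square",
                                           replicates = 5,
                                           seed = derive_seed(s, 7)),
                         sigma_by_group = c(HD = 60, HU = 4, CV = 4, Mix = 4),
                         mu_by_group = c(HD = 0, HU = 0, CV = 0, Mix = 0),
                         shape_effect = 0)
    backward_select(response ~ treatment, d,
                    varident = "treatment")$varident_kept
  })
  expect_gte(mean(picked), 0.9)
})
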