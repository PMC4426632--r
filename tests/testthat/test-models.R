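test_that("meta-regression recovers closed-form limits", {
  set.seed(1)
  y <- rnorm(12, 0.3)
  # equal variances, intercept only: GLS intercept is the plain mean
  f <- meta_regress(y, rep(0.02, 12))
  expect_equal(unname(f$beta["intrcpt"]), mean(y), tolerance = 1e-8)

  # v_i = 0: coefficients collapse to OLS on the same design
  x <- rnorm(12)
  f0 <- meta_regress(y, rep(0, 12), mods = data.frame(x = x))
  ols <- coef(lm(y ~ x))
  expect_equal(unname(f0$beta), unname(ols), tolerance = 1e-8)

  # WLS oracle: with tau2 forced to 0 by heterogeneity-free data, the GLS
  # solution equals the closed-form weighted least squares
  yy <- c(0.1, 0.2, 0.15, 0.3, 0.25, 0.18)
  vv <- c(0.01, 0.02, 0.015, 0.01, 0.03, 0.02)
  fd <- meta_regress(yy, vv, method = "DL")
  if (fd$tau2 == 0) {
    w <- 1 / vv
    expect_equal(unname(fd$beta["intrcpt"]), sum(w * yy) / sum(w), tolerance = 1e-10)
  }

  # guards
  expect_error(meta_regress(y[1:3], rep(0.1, 3), mods = data.frame(a = 1:3, b = 1:3)),
               class = "pollscape_singular_error")
  expect_error(meta_regress(y[1:3], rep(0.1, 3), mods = data.frame(a = rnorm(3))),
               class = "pollscape_domain_error")
})

test_that("meta-regression slope recovery is unbiased", {
  set.seed(42)
  k <- 50
  slopes <- replicate(200, {
    x <- rnorm(k, sd = 10)
    v <- runif(k, 0.002, 0.01)
    y <- 0.01 * x + rnorm(k, sd = 0.05) + rnorm(k, sd = sqrt(v))
    unname(meta_regress(y, v, mods = data.frame(x = x))$beta["x"])
  })
  se_mc <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.01), 3 * se_mc)
})

test_that("VAF behaves at its anchors and under rescaling", {
  set.seed(8)
  k <- 30
  x <- rnorm(k)
  y <- 0.5 * x + rnorm(k, sd = 0.3)
  v <- rep(0.01, k)
  null_fit <- meta_regress(y, v)
  mod_fit <- meta_regress(y, v, mods = data.frame(x = x))
  expect_equal(as.numeric(vaf(null_fit, null_fit)), 0)
  out <- vaf(null_fit, mod_fit)
  expect_gt(out, 50)  # strong moderator absorbs most heterogeneity
  expect_lte(out, 100)

  # invariance to rescaling all effects by a constant
  null2 <- meta_regress(10 * y, 100 * v)
  mod2 <- meta_regress(10 * y, 100 * v, mods = data.frame(x = x))
  expect_equal(vaf(null2, mod2), out, tolerance = 1e-4)

  # tau2_model = 0 -> 100%: the moderator explains all heterogeneity
  y0 <- 2 * x + rnorm(k, sd = 0.001)
  n0 <- meta_regress(y0, v)
  m0 <- meta_regress(y0, v, mods = data.frame(x = x))
  if (m0$tau2 == 0 && n0$tau2 > 0) expect_equal(as.numeric(vaf(n0, m0)), 100)

  # undefined when the null has no heterogeneity
  flat <- meta_regress(rnorm(k, sd = 0.001), rep(1, k))
  if (flat$tau2 == 0) expect_true(is.na(vaf(flat, flat)))

  expect_error(vaf(null_fit, meta_regress(y[-1], v[-1])),
               class = "pollscape_domain_error")
})

test_that("stepwise selection keeps strong signals and honours constraints", {
  set.seed(12)
  k <- 40
  d <- data.frame(site = 1:k, a = rnorm(k), b = rnorm(k), c = rnorm(k))
  d$var <- runif(k, 0.005, 0.02)
  d$y <- 1 + 0.5 * d$a + rnorm(k, sd = sqrt(d$var))
  fit <- stepwise_select(d, "y", c("a", "b", "c"), engine = "meta", var_col = "var")
  expect_true("a" %in% fit$terms)

  # forbidden pair never co-occurs in any evaluated model
  fb <- matrix(c("a", "b"), 1)
  fit2 <- stepwise_select(d, "y", c("a", "b", "c"), forbidden = fb,
                          engine = "meta", var_col = "var")
  co <- vapply(fit2$evaluated, function(tm) {
    mains <- unique(unlist(strsplit(tm, ":")))
    all(c("a", "b") %in% mains)
  }, TRUE)
  expect_false(any(co))
  expect_true("a" %in% fit2$terms)

  # interactions enter only alongside both mains
  d$y2 <- 1 + 0.4 * d$a + 0.4 * d$b + 0.8 * d$a * d$b + rnorm(k, sd = 0.1)
  fit3 <- stepwise_select(d, "y2", c("a", "b"), engine = "glm",
                          include_interactions = TRUE)
  if ("a:b" %in% fit3$terms) expect_true(all(c("a", "b") %in% fit3$terms))
  for (tm in fit3$evaluated) {
    if ("a:b" %in% tm) expect_true(all(c("a", "b") %in% tm))
  }

  # deterministic under re-run
  fit4 <- stepwise_select(d, "y", c("a", "b", "c"), engine = "meta", var_col = "var")
  expect_identical(fit$terms, fit4$terms)
})

test_that("pure-noise predictors are rarely retained", {
  set.seed(77)
  rates <- replicate(300, {
    k <- 40
    d <- data.frame(y = rnorm(k), a = rnorm(k), b = rnorm(k), c = rnorm(k))
    length(stepwise_select(d, "y", c("a", "b", "c"), engine = "glm")$terms)
  })
  # documented property of AIC selection: per-predictor retention well
  # under 30%
  expect_lt(mean(rates) / 3, 0.30)
})

test_that("the composition GLM mirrors OLS and recovers a known slope", {
  set.seed(5)
  k <- 50
  d <- data.frame(edge = rnorm(k, sd = 3))
  d$scc <- 0.5 + 0.02 * d$edge + rnorm(k, sd = 0.05)
  fit <- glm_composition(d, "scc", "edge")
  expect_true("edge" %in% fit$terms)
  expect_equal(unname(coef(fit$fit)[2]), unname(coef(lm(scc ~ edge, d))["edge"]),
               tolerance = 1e-10)

  # slope recovery across replicates
  set.seed(6)
  sl <- replicate(100, {
    d <- data.frame(edge = rnorm(k, sd = 3))
    d$scc <- 0.5 + 0.02 * d$edge + rnorm(k, sd = 0.05)
    f <- glm_composition(d, "scc", "edge")
    if ("edge" %in% f$terms) unname(coef(f$fit)[2]) else NA_real_
  })
  expect_gt(mean(!is.na(sl)), 0.9)
  expect_lt(abs(mean(sl, na.rm = TRUE) - 0.02), 3 * sd(sl, na.rm = TRUE) / sqrt(sum(!is.na(sl))))

  # zero-variance response short-circuits to intercept-only
  d$flat <- 0.4
  expect_warning(f0 <- glm_composition(d, "flat", "edge"),
                 class = "pollscape_zero_variance")
  expect_length(f0$terms, 0)
})

test_that("the sampling-effort bias check adjusts only when needed", {
  set.seed(19)
  k <- 200
  dr <- rnorm(k)
  v <- rep(0.01, k)
  # injected dependence is removed
  y <- 0.5 * dr + rnorm(k, sd = 0.1)
  res <- sampling_bias_check(y, v, dr)
  expect_true(res$adjusted)
  expect_lt(abs(cor(res$effects, dr)), 0.05)

  # independent effects pass through (usually)
  y2 <- rnorm(k, sd = 0.1)
  res2 <- sampling_bias_check(y2, v, dr)
  if (!res2$adjusted) expect_identical(res2$effects, y2)

  # constant delta_r skips with a warning
  expect_warning(res3 <- sampling_bias_check(y2, v, rep(0, k)),
                 class = "pollscape_constant_deltar")
  expect_true(res3$skipped)
})

test_that("Moran's I screen has the right null expectation and power", {
  set.seed(23)
  vals <- rnorm(11)
  coords <- cbind(runif(11), runif(11))
  res <- morans_i(vals, coords)
  expect_equal(res$expected, -0.1)
  expect_false(res$undefined)

  # a smooth spatial gradient is detected
  xs <- seq(0, 1, length.out = 30)
  res2 <- morans_i(xs, cbind(xs, 0.01 * rnorm(30)))
  expect_gt(res2$observed, 0)
  expect_lt(res2$p, 0.05)

  # constant field is undefined; duplicates warn
  expect_true(morans_i(rep(1, 5), cbind(1:5, 1:5))$undefined)
  expect_warning(morans_i(rnorm(5), cbind(c(1, 1, 2, 3, 4), c(1, 1, 2, 3, 4))),
                 class = "pollscape_dup_coords")
})
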