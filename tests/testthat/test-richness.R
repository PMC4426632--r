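test_that("rarefaction matches exhaustive enumeration and vegan", {
  # spec'd toy: X = (3,2,1), m = 2 over all 15 individual pairs
  s <- ref_sample(c(a = 3, b = 2, c = 1))
  expect_equal(rarefy(s, 2), brute_rarefy(c(3, 2, 1), 2))

  # one-species sample is flat at 1; full effort returns S_obs
  expect_equal(rarefy(ref_sample(c(x = 9)), 4), 1)
  expect_equal(rarefy(s, s$n), s$s_obs)

  # enumeration oracle across random abundance vectors
  set.seed(21)
  for (i in 1:10) {
    x <- sample(1:4, sample(2:4, 1), replace = TRUE)
    sx <- ref_sample(setNames(x, paste0("s", seq_along(x))))
    for (m in seq_len(sx$n)) {
      expect_equal(rarefy(sx, m), brute_rarefy(x, m), tolerance = 1e-10)
    }
  }

  # independent library cross-check (vegan implements the same estimator)
  skip_if_not_installed("vegan")
  x <- c(12, 7, 5, 3, 1, 1, 1)
  sx <- ref_sample(setNames(x, paste0("s", 1:7)))
  for (m in c(2, 10, 25)) {
    expect_equal(rarefy(sx, m), as.numeric(vegan::rarefy(x, m)), tolerance = 1e-8)
  }

  expect_error(rarefy(s, 7), class = "pollscape_effort_error")
  expect_error(rarefy(s, 0), class = "pollscape_domain_error")
})

test_that("extrapolation follows the Chao1 closed form and its cap", {
  # X = (1,1): n = 2, f1 = 2, f2 = 0 -> f0 = 1/2, S(3) = 2 + 1/3 exactly
  s11 <- ref_sample(c(a = 1, b = 1))
  expect_equal(extrapolate(s11, 1), 2 + 1/3, tolerance = 1e-12)

  # no singletons: asymptote already reached
  s0 <- ref_sample(c(a = 4, b = 3, c = 2))
  expect_equal(extrapolate(s0, 5), s0$s_obs)

  # bounded by S_obs + f0 and monotone in added effort
  set.seed(2)
  x <- c(5, 3, 2, 2, 1, 1, 1, 1)
  sx <- ref_sample(setNames(x, paste0("s", 1:8)))
  f0 <- (sx$n - 1) / sx$n * sx$f1^2 / (2 * sx$f2)
  vals <- vapply(1:(2 * sx$n), function(m) extrapolate(sx, m), 1)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals <= sx$s_obs + f0))

  # continuity with the interpolated curve at m = n
  expect_lt(abs(extrapolate(sx, 1) - rarefy(sx, sx$n)), 1)
  curve <- vapply(c(sx$n - 2, sx$n, sx$n + 2), function(m) richness_at(sx, m), 1)
  expect_true(all(diff(curve) >= 0))

  # the 3x ceiling: n + m_star = 3n allowed, one more refused
  expect_silent(extrapolate(sx, 2 * sx$n))
  expect_error(extrapolate(sx, 2 * sx$n + 1), class = "pollscape_cap_error")
})

test_that("the site quality filter enforces its three criteria at the boundary", {
  mk <- function(S, n) {
    base <- rep(1L, S); base[1] <- base[1] + (n - S)
    ref_sample(setNames(base, paste0("sp", 1:S)))
  }
  expect_true(site_filter(mk(5, 10), mk(5, 99))$pass)   # ratio 9.9 < 10
  f <- site_filter(mk(5, 10), mk(5, 100))               # ratio 10 fails
  expect_false(f$pass)
  expect_match(f$reasons, "10-fold")
  f2 <- site_filter(mk(4, 50), mk(20, 50))              # S = 4 fails period 1
  expect_false(f2$pass)
  expect_match(f2$reasons, "5 species.*period 1")
  expect_true(site_filter(mk(5, 50), mk(5, 50))$pass)
  f3 <- site_filter(mk(5, 9), mk(5, 50))                # n = 9 fails
  expect_false(f3$pass)
  expect_match(f3$reasons[1], "10 records")
  expect_true(site_filter(mk(5, 10), mk(5, 10))$pass)   # n = 10 passes
})

test_that("richness change is null-centred, reproducible and seed-stable", {
  set.seed(9)
  x <- setNames(rpois(30, 4) + 1L, paste0("sp", 1:30))
  s <- ref_sample(x)
  rc <- richness_change(s, s, B = 200, seed = 4)
  expect_equal(rc$n_cmp, s$n)
  expect_equal(rc$logratio_plugin, 0)
  expect_lt(abs(rc$logratio), 2 * sqrt(rc$var_logratio))
  expect_false(any(rc$extrapolated))

  # same seed identical; different seeds agree on the variance scale
  rc2 <- richness_change(s, s, B = 200, seed = 4)
  expect_identical(rc$logratio, rc2$logratio)
  expect_identical(rc$var_logratio, rc2$var_logratio)
  v <- vapply(1:4, function(sd) richness_change(s, s, B = 1000, seed = sd)$var_logratio, 1)
  expect_lt(max(v) / min(v), 1.2)

  # comparison effort honours the 3x ceiling and flags extrapolation
  s_small <- ref_sample(setNames(c(9, 3, 2, 1, 1), paste0("a", 1:5)))  # n = 16
  s_big <- ref_sample(setNames(rep(4L, 20), paste0("b", 1:20)))        # n = 80
  rc3 <- richness_change(s_small, s_big, B = 50, seed = 1)
  expect_equal(rc3$n_cmp, 48)  # min(80, 3 * 16)
  expect_true(rc3$extrapolated[1])
  expect_false(rc3$extrapolated[2])

  # filter is enforced unless disabled
  tiny <- ref_sample(setNames(rep(1L, 4), paste0("t", 1:4)))
  expect_error(richness_change(tiny, s, B = 10, seed = 1),
               class = "pollscape_filter_error")
})

test_that("a doubled community is detected as significant enrichment", {
  # period 2 holds twice the species at equal effort: logratio must be
  # recovered as clearly positive
  set.seed(31)
  hits <- 0L
  for (i in 1:25) {
    cfg <- community_config(S_pool = 90, fisher_alpha = 60, n1 = 400, n2 = 400,
                            turnover_frac = 0, richness_ratio = 2, seed = i)
    p <- generate_assemblages(cfg)
    rc <- richness_change(as_ref_sample(p, 1), as_ref_sample(p, 2),
                          B = 100, seed = i)
    if (rc$logratio - 1.96 * sqrt(rc$var_logratio) > 0) hits <- hits + 1L
  }
  expect_gte(hits, 23)
})

test_that("long-format records reduce to per-site reference samples", {
  rec <- data.frame(
    site = c("A", "A", "A", "A", "B", "B"),
    period = c(1, 1, 2, 2, 1, 1),
    species = c("x", "x", "x", "y", "z", "z"),
    count = c(2, 1, 4, 1, 1, 1))
  expect_warning(ss <- samples_from_records(rec), class = "pollscape_missing_period")
  expect_named(ss, "A")
  expect_equal(ss$A$hist$x, c(x = 3L))
  expect_equal(ss$A$curr$n, 5L)
  expect_equal(ss$A$curr$f1, 1L)
})
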