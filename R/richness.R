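#' Reference sample of individual-based occurrence records
#'
#' Per site and period, the records reduce to a species abundance vector
#' `X_i` (number of individual records per species). The derived quantities
#' driving effort correction are the total effort `n`, observed richness
#' `S_obs`, and the singleton/doubleton counts `f1`, `f2`.
#'
#' @param abundances integer vector of per-species record counts (zeros are
#'   dropped); may be named by species.
#' @return object of class `ref_sample` with fields `x`, `n`, `s_obs`,
#'   `f1`, `f2`.
#' @export
ref_sample <- function(abundances) {
  x <- abundances[!is.na(abundances) & abundances > 0]
  if (!length(x)) stop2("empty sample", class = "pollscape_domain_error")
  if (any(x != round(x))) {
    stop2("abundances must be integer record counts", class = "pollscape_domain_error")
  }
  x <- stats::setNames(as.integer(round(x)), names(x))
  structure(list(x = x, n = as.integer(sum(x)),
                 s_obs = length(x), f1 = sum(x == 1), f2 = sum(x == 2)),
            class = "ref_sample")
}

#' @export
print.ref_sample <- function(x, ...) {
  cat(sprintf("<ref_sample> n = %d records, S_obs = %d, f1 = %d, f2 = %d\n",
              x$n, x$s_obs, x$f1, x$f2))
  invisible(x)
}

#' Interpolated (rarefied) species richness
#'
#' Expected number of species in a random subsample of `m` individuals drawn
#' without replacement from the reference sample:
#' `S(m) = S_obs - sum_i C(n - x_i, m) / C(n, m)`, terms with `n - x_i < m`
#' vanishing. Monotone nondecreasing in `m`, with `S(n) = S_obs`.
#'
#' @param sample a [ref_sample()].
#' @param m subsample size, `1 <= m <= n`. For `m > n` use [extrapolate()].
#' @return expected richness (numeric scalar).
#' @export
rarefy <- function(sample, m) {
  stopifnot(inherits(sample, "ref_sample"))
  assert_scalar_number(m, "m", min = 1)
  if (m != round(m)) stop2("`m` must be an integer effort", class = "pollscape_domain_error")
  if (m > sample$n) {
    stop2("m exceeds the reference effort n; use extrapolate()",
          class = "pollscape_effort_error")
  }
  x <- sample$x; n <- sample$n
  keep <- (n - x) >= m
  miss <- numeric(length(x))
  # C(n - x_i, m) / C(n, m) on the log scale for stability
  miss[keep] <- exp(lchoose(n - x[keep], m) - lchoose(n, m))
  sample$s_obs - sum(miss)
}

# Chao1-style estimate of the number of unseen species, with the standard
# bias-corrected fallback when no doubletons are present.
chao_f0 <- function(n, f1, f2) {
  if (f1 == 0) return(0)
  if (f2 > 0) (n - 1) / n * f1^2 / (2 * f2) else (n - 1) / n * f1 * (f1 - 1) / 2
}

#' Extrapolated species richness beyond the observed effort
#'
#' Predicts richness at effort `n + m_star` from the Chao1 unseen-species
#' estimate `f0 = ((n-1)/n) f1^2 / (2 f2)` (or `((n-1)/n) f1 (f1-1)/2` when
#' `f2 = 0`):
#' `S(n + m_star) = S_obs + f0 * (1 - (1 - f1 / (n f0 + f1))^m_star)`.
#' Extrapolation is only trusted to short range: target efforts beyond three
#' times the reference effort are refused.
#'
#' @param sample a [ref_sample()].
#' @param m_star additional effort beyond `n` (`>= 1`); requires
#'   `n + m_star <= cap_multiplier * n`.
#' @param cap_multiplier extrapolation ceiling as a multiple of `n`
#'   (default 3).
#' @return predicted richness (numeric scalar).
#' @export
extrapolate <- function(sample, m_star, cap_multiplier = 3) {
  stopifnot(inherits(sample, "ref_sample"))
  assert_scalar_number(m_star, "m_star", min = 1)
  n <- sample$n
  if (n + m_star > cap_multiplier * n) {
    stop2(sprintf("target effort %d exceeds the %gx extrapolation cap (n = %d)",
                  n + as.integer(m_star), cap_multiplier, n),
          class = "pollscape_cap_error")
  }
  f1 <- sample$f1
  f0 <- chao_f0(n, f1, sample$f2)
  if (f0 == 0) return(as.numeric(sample$s_obs))
  sample$s_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^m_star)
}

#' Richness at an arbitrary target effort (interpolating or extrapolating)
#'
#' @param sample a [ref_sample()].
#' @param m target effort; interpolates for `m <= n`, extrapolates (subject
#'   to the cap) for `m > n`.
#' @param cap_multiplier extrapolation ceiling (default 3).
#' @return expected/predicted richness.
#' @export
richness_at <- function(sample, m, cap_multiplier = 3) {
  if (m <= sample$n) rarefy(sample, m)
  else extrapolate(sample, m - sample$n, cap_multiplier = cap_multiplier)
}

#' Site data-quality filter
#'
#' Sites with very poor sampling are excluded a priori: a site passes only
#' if both periods have at least 5 species and at least 10 records, and the
#' record counts differ by less than 10-fold.
#'
#' @param sample1,sample2 [ref_sample()] objects for the historical and
#'   current periods.
#' @param min_species,min_records,max_effort_ratio the three thresholds
#'   (defaults 5, 10, 10).
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   violated criteria, empty when passing).
#' @export
site_filter <- function(sample1, sample2, min_species = 5, min_records = 10,
                        max_effort_ratio = 10) {
  stopifnot(inherits(sample1, "ref_sample"), inherits(sample2, "ref_sample"))
  reasons <- character()
  for (p in 1:2) {
    s <- list(sample1, sample2)[[p]]
    if (s$s_obs < min_species) {
      reasons <- c(reasons, sprintf("minimum %d species violated in period %d (S = %d)",
                                    min_species, p, s$s_obs))
    }
    if (s$n < min_records) {
      reasons <- c(reasons, sprintf("minimum %d records violated in period %d (n = %d)",
                                    min_records, p, s$n))
    }
  }
  ratio <- max(sample1$n, sample2$n) / min(sample1$n, sample2$n)
  if (!(ratio < max_effort_ratio)) {
    reasons <- c(reasons, sprintf(
      "record-count ratio %.3g not below %g-fold", ratio, max_effort_ratio))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Effort-corrected richness change between two periods
#'
#' Both periods are brought to a common comparison effort
#' `n_cmp = min(max(n1, n2), cap * min(n1, n2))` — as much of the larger
#' sample as the extrapolation ceiling permits — and richness change is the
#' ratio `S2(n_cmp) / S1(n_cmp)`, reported on the log scale ("logratio").
#' A nonparametric bootstrap (records resampled with replacement within each
#' period, effort held fixed) supplies the variance and a standard bias
#' adjustment `2 * plugin - mean(bootstrap)`, guarding against under- or
#' over-representation of singletons and doubletons in the record databases.
#'
#' @param sample1,sample2 [ref_sample()] objects (historical, current).
#' @param B bootstrap replicates (default 1000; `>= 2`).
#' @param seed integer seed (required, for reproducibility).
#' @param cap_multiplier extrapolation ceiling (default 3).
#' @param apply_filter refuse sites failing [site_filter()] (default TRUE).
#' @return object of class `richness_change`: list with `n_cmp`, `x1_hat`,
#'   `x2_hat`, `ratio`, `logratio` (bias-adjusted), `logratio_plugin`,
#'   `var_logratio`, `B`, `extrapolated` (logical length 2), `delta_r`
#'   (`log(n2/n1)`).
#' @export
richness_change <- function(sample1, sample2, B = 1000, seed,
                            cap_multiplier = 3, apply_filter = TRUE) {
  stopifnot(inherits(sample1, "ref_sample"), inherits(sample2, "ref_sample"))
  if (missing(seed)) stop2("`seed` is required", class = "pollscape_config_error")
  assert_scalar_number(B, "B", min = 2)
  if (apply_filter) {
    flt <- site_filter(sample1, sample2)
    if (!flt$pass) {
      stop2("site fails the quality filter: ", paste(flt$reasons, collapse = "; "),
            class = "pollscape_filter_error")
    }
  }
  n1 <- sample1$n; n2 <- sample2$n
  n_cmp <- min(max(n1, n2), cap_multiplier * min(n1, n2))
  point <- function(s1, s2) {
    log(richness_at(s2, n_cmp, cap_multiplier) / richness_at(s1, n_cmp, cap_multiplier))
  }
  plugin <- point(sample1, sample2)
  boot <- numeric(B)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (b in seq_len(B)) {
    r1 <- ref_sample(stats::rmultinom(1, n1, sample1$x / n1)[, 1])
    r2 <- ref_sample(stats::rmultinom(1, n2, sample2$x / n2)[, 1])
    boot[b] <- point(r1, r2)
  }
  v <- stats::var(boot)
  if (v == 0) warn2("degenerate bootstrap: all replicates identical",
                    class = "pollscape_degenerate_bootstrap")
  structure(list(
    n_cmp = n_cmp,
    x1_hat = richness_at(sample1, n_cmp, cap_multiplier),
    x2_hat = richness_at(sample2, n_cmp, cap_multiplier),
    ratio = exp(2 * plugin - mean(boot)),
    logratio = 2 * plugin - mean(boot),
    logratio_plugin = plugin,
    var_logratio = v,
    B = as.integer(B),
    extrapolated = c(n_cmp > n1, n_cmp > n2),
    delta_r = log(n2 / n1)
  ), class = "richness_change")
}

#' @export
print.richness_change <- function(x, ...) {
  cat(sprintf(
    "<richness_change> n_cmp = %d: S1 = %.2f, S2 = %.2f, logratio = %.4f (var %.2e)%s\n",
    x$n_cmp, x$x1_hat, x$x2_hat, x$logratio, x$var_logratio,
    if (any(x$extrapolated)) " [extrapolated]" else ""))
  invisible(x)
}

#' Long-format occurrence records to per-site reference samples
#'
#' @param records data frame with columns `site`, `period` (1 or 2),
#'   `species`, and optionally `count` (default 1 per row, i.e. one record
#'   per individual occurrence).
#' @return named list (by site) of lists with elements `hist` and `curr`
#'   [ref_sample()] objects; sites missing a period are dropped with a
#'   warning.
#' @export
samples_from_records <- function(records) {
  need <- c("site", "period", "species")
  if (!all(need %in% names(records))) {
    stop2("records need columns site, period, species", class = "pollscape_domain_error")
  }
  if (is.null(records$count)) records$count <- 1L
  out <- list()
  dropped <- character()
  for (s in unique(records$site)) {
    rs <- records[records$site == s, ]
    per <- lapply(1:2, function(p) {
      rp <- rs[rs$period == p, ]
      if (!nrow(rp)) return(NULL)
      ref_sample(tapply(rp$count, rp$species, sum))
    })
    if (is.null(per[[1]]) || is.null(per[[2]])) dropped <- c(dropped, as.character(s))
    else out[[as.character(s)]] <- list(hist = per[[1]], curr = per[[2]])
  }
  if (length(dropped)) {
    warn2("sites missing a period dropped: ", paste(dropped, collapse = ", "),
          class = "pollscape_missing_period")
  }
  out
}
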