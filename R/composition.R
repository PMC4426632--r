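#' Shared-species relative abundance in each period
#'
#' For the species observed in both periods, `U` is their total relative
#' abundance in the historical sample and `V` in the current sample. The
#' plug-in estimator is `U = sum_shared x1_i / n1` (and symmetrically for
#' `V`). The bias-corrected variant adds an unseen-shared-species correction
#' in the style of the Chao abundance-based shared-species estimator: the
#' historical abundance mass of species that are rare (singletons) in the
#' *other* period is inflated by `((n2-1)/n2) * fp1 / (2 * max(fp2, 1))`,
#' where `fp1`/`fp2` count shared species observed once/twice in the current
#' sample; values are clamped to 1 (the raw value is kept as an attribute).
#'
#' @param sample1,sample2 named [ref_sample()] objects (species names on the
#'   abundance vectors identify sharing).
#' @param variant `"plugin"` (default) or `"bias_corrected"`.
#' @return object of class `shared_abundance`: list with `u`, `v`,
#'   `shared_species`, `variant`; attributes `u_raw`, `v_raw`.
#' @export
shared_abundance <- function(sample1, sample2,
                             variant = c("plugin", "bias_corrected")) {
  variant <- match.arg(variant)
  stopifnot(inherits(sample1, "ref_sample"), inherits(sample2, "ref_sample"))
  if (is.null(names(sample1$x)) || is.null(names(sample2$x))) {
    stop2("samples must carry species names", class = "pollscape_domain_error")
  }
  shared <- intersect(names(sample1$x), names(sample2$x))
  u <- sum(sample1$x[shared]) / sample1$n
  v <- sum(sample2$x[shared]) / sample2$n
  if (variant == "bias_corrected" && length(shared)) {
    u <- u + chao_shared_correction(sample1, sample2, shared)
    v <- v + chao_shared_correction(sample2, sample1, shared)
  }
  structure(list(u = min(u, 1), v = min(v, 1), shared_species = shared,
                 variant = variant),
            u_raw = u, v_raw = v, class = "shared_abundance")
}

# Correction to the period-A shared mass for shared species that are rare in
# period B (singletons/doubletons there): unseen shared abundance estimated
# from cross-period rarity. Interpretation of the Chao et al. abundance-based
# shared-species estimator; reduces to zero when no shared species is a
# singleton in B.
chao_shared_correction <- function(sample_a, sample_b, shared) {
  xb <- sample_b$x[shared]
  fp1 <- sum(xb == 1)
  fp2 <- sum(xb == 2)
  if (fp1 == 0) return(0)
  nb <- sample_b$n
  mass_a_of_b_singletons <- sum(sample_a$x[shared][xb == 1]) / sample_a$n
  (nb - 1) / nb * fp1 / (2 * max(fp2, 1)) * mass_a_of_b_singletons / max(fp1, 1)
}

#' Species composition change (SCC) from shared-abundance estimates
#'
#' An abundance-based Jaccard-type dissimilarity on the shared-species
#' relative abundances: `SCC = 1 - UV / (U + V - UV)`, with `SCC = 1` when
#' `U = V = 0` (no species in common) and `SCC = 0` when `U = V = 1`
#' (identical species lists). Symmetric in `(U, V)` and decreasing in each.
#'
#' @param u,v shared relative abundances in `[0, 1]`, or a single
#'   `shared_abundance` object as `u`.
#' @return object of class `composition_change`: list with `scc`, `u`, `v`,
#'   `variant`.
#' @export
scc <- function(u, v = NULL) {
  variant <- NA_character_
  if (inherits(u, "shared_abundance")) {
    variant <- u$variant; v <- u$v; u <- u$u
  }
  for (z in c(u, v)) {
    if (!is.numeric(z) || length(z) != 1L || is.na(z) || z < 0 || z > 1) {
      stop2("U and V must be single values in [0, 1]", class = "pollscape_domain_error")
    }
  }
  val <- if (u + v == 0) 1 else 1 - (u * v) / (u + v - u * v)
  structure(list(scc = val, u = u, v = v, variant = variant),
            class = "composition_change")
}

#' @export
print.composition_change <- function(x, ...) {
  cat(sprintf("<composition_change> SCC = %.4f (U = %.3f, V = %.3f)\n",
              x$scc, x$u, x$v))
  invisible(x)
}

#' Incidence-based turnover index (beta-sim)
#'
#' `beta_sim = min(b, c) / (min(b, c) + a)` with `a` the number of shared
#' species and `b`, `c` the numbers unique to each side; insensitive to
#' richness differences. Reported alongside SCC as an uncorrected
#' incidence-only cross-check.
#'
#' @param species1,species2 character vectors of species (or named
#'   [ref_sample()] objects).
#' @return numeric in `[0, 1]`.
#' @export
beta_sim <- function(species1, species2) {
  if (inherits(species1, "ref_sample")) species1 <- names(species1$x)
  if (inherits(species2, "ref_sample")) species2 <- names(species2$x)
  s1 <- unique(species1); s2 <- unique(species2)
  if (!length(s1) || !length(s2)) {
    stop2("empty species set", class = "pollscape_domain_error")
  }
  a <- length(intersect(s1, s2))
  b <- length(setdiff(s1, s2)); cc <- length(setdiff(s2, s1))
  m <- min(b, cc)
  if (m + a == 0) return(0)
  m / (m + a)
}

#' Per-site composition change from two period samples
#'
#' Convenience wrapper: shared abundances, SCC and beta-sim in one tibble
#' row.
#'
#' @inheritParams shared_abundance
#' @return tibble with `u`, `v`, `scc`, `beta_sim`, `variant`,
#'   `n_shared`.
#' @export
composition_change <- function(sample1, sample2,
                               variant = c("plugin", "bias_corrected")) {
  sa <- shared_abundance(sample1, sample2, variant)
  cc <- scc(sa)
  tibble::tibble(u = sa$u, v = sa$v, scc = cc$scc,
                 beta_sim = beta_sim(sample1, sample2),
                 variant = sa$variant,
                 n_shared = length(sa$shared_species))
}
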