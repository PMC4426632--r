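#' Configuration for a synthetic paired-landscape world
#'
#' Describes a pair of co-registered categorical land-cover rasters (a
#' historical and a current period) holding a set of non-overlapping
#' disc-shaped focal sites dominated by one class (a heathland analogue),
#' with a configurable fraction of cells reassigned between periods inside
#' each site and inside each buffer ring around it. Defaults emulate the
#' shape of the real inputs this pipeline targets: a 9-class legend (8 broad
#' historical-survey-like classes plus "other") on a grid of 100 m cells
#' with buffer rings at 1 and 2 km.
#'
#' @param grid_dims `c(rows, cols)` in cells.
#' @param cell_size cell edge, metres.
#' @param class_names legend (first class is the focal/site-dominant one).
#' @param class_mixture per-class background cover fractions, summing to 1.
#' @param n_sites number of focal sites.
#' @param site_radius site disc radius, metres.
#' @param site_dominance probability a site cell takes the focal class.
#' @param buffer_radii strictly increasing ring radii, metres.
#' @param swap_fraction_site fraction of site cells reassigned between
#'   periods, in `[0, 1]`.
#' @param swap_fraction_buffer same, per buffer ring (recycled over rings).
#' @param swap_target_weights optional named nonnegative weights over
#'   classes governing which class a swapped cell becomes (default uniform
#'   over the other classes).
#' @param seed integer seed.
#' @return a validated `landscape_config` list.
#' @export
landscape_config <- function(grid_dims = c(200, 200), cell_size = 100,
                             class_names = c("heathland", "woodland", "grassland",
                                             "arable", "urban", "orchard", "water",
                                             "garden", "other"),
                             class_mixture = c(0.26, 0.14, 0.18, 0.18, 0.09,
                                               0.03, 0.04, 0.03, 0.05),
                             n_sites = 10, site_radius = 500, site_dominance = 0.7,
                             buffer_radii = c(1000, 2000),
                             swap_fraction_site = 0.2, swap_fraction_buffer = 0.1,
                             swap_target_weights = NULL, seed = 1L) {
  if (length(grid_dims) != 2L || any(grid_dims < 1)) {
    stop2("grid_dims must be two positive integers", class = "pollscape_config_error")
  }
  if (length(class_mixture) != length(class_names) ||
      abs(sum(class_mixture) - 1) > 1e-9 || any(class_mixture < 0)) {
    stop2("class_mixture must be nonnegative and sum to 1",
          class = "pollscape_config_error")
  }
  for (f in c(swap_fraction_site, swap_fraction_buffer)) {
    if (any(f < 0 | f > 1)) {
      stop2("swap fractions must lie in [0, 1]", class = "pollscape_config_error")
    }
  }
  if (is.unsorted(buffer_radii, strictly = TRUE) || any(buffer_radii <= 0)) {
    stop2("buffer_radii must be strictly increasing and positive",
          class = "pollscape_config_error")
  }
  structure(list(grid_dims = as.integer(grid_dims), cell_size = cell_size,
                 class_names = class_names, class_mixture = class_mixture,
                 n_sites = as.integer(n_sites), site_radius = site_radius,
                 site_dominance = site_dominance, buffer_radii = buffer_radii,
                 swap_fraction_site = swap_fraction_site,
                 swap_fraction_buffer = swap_fraction_buffer,
                 swap_target_weights = swap_target_weights,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

#' Generate a paired synthetic landscape with known change
#'
#' Builds the historical raster (background cells i.i.d. from the cover
#' mixture; site discs filled with the focal class at the configured
#' dominance), then derives the current raster by reassigning exactly
#' `round(fraction * n_cells)` cells (to a different class) within each
#' site and each buffer ring. Sites are placed so that their outermost
#' rings do not overlap, which keeps the per-zone change exact; cells
#' outside every zone are left unchanged.
#'
#' @param cfg a [landscape_config()].
#' @param site_overrides optional list (one entry per site, `NULL` allowed)
#'   overriding `swap_fraction_site`, `swap_fraction_buffer` or
#'   `swap_target_weights` for that site — used to give sites heterogeneous
#'   ground-truth change.
#' @param max_tries placement retries before giving up.
#' @return object of class `synthetic_landscape`: list with `hist`, `curr`
#'   ([land_raster]s), `sites` (per site: `id`, `centre`, `mask`, `zones`),
#'   `legend`, `cfg`.
#' @export
generate_landscape <- function(cfg, site_overrides = NULL, max_tries = 2000L) {
  stopifnot(inherits(cfg, "landscape_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(cfg$seed, "landscape"))

  nr <- cfg$grid_dims[1]; nc <- cfg$grid_dims[2]
  K <- length(cfg$class_names)
  legend <- stats::setNames(cfg$class_names, seq_len(K))
  grid <- matrix(sample.int(K, nr * nc, replace = TRUE, prob = cfg$class_mixture), nr, nc)

  r_cells <- cfg$site_radius / cfg$cell_size
  sep_cells <- 2 * (cfg$site_radius + max(cfg$buffer_radii)) / cfg$cell_size
  margin <- ceiling(r_cells)
  if (2 * margin >= min(nr, nc)) {
    stop2("grid too small for the site radius", class = "pollscape_placement_error")
  }
  centres <- matrix(numeric(), 0, 2)
  tries <- 0L
  while (nrow(centres) < cfg$n_sites) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop2(sprintf("could not place %d non-overlapping sites in %d tries",
                    cfg$n_sites, max_tries),
            class = "pollscape_placement_error")
    }
    cand <- c(stats::runif(1, margin + 1, nr - margin),
              stats::runif(1, margin + 1, nc - margin))
    if (nrow(centres) == 0 ||
        all(sqrt((centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2) >= sep_cells)) {
      centres <- rbind(centres, cand)
    }
  }

  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  sites <- vector("list", cfg$n_sites)
  for (j in seq_len(cfg$n_sites)) {
    mask <- (rows - centres[j, 1])^2 + (cols - centres[j, 2])^2 <= r_cells^2
    n_site <- sum(mask)
    focal <- sample(c(TRUE, FALSE), n_site, TRUE,
                    c(cfg$site_dominance, 1 - cfg$site_dominance))
    fill <- ifelse(focal, 1L,
                   sample.int(K, n_site, TRUE, cfg$class_mixture))
    grid[mask] <- fill
    zones <- suppressWarnings(
      build_zones(mask, cfg$buffer_radii, cfg$cell_size))
    sites[[j]] <- list(id = sprintf("site_%02d", j),
                       centre = centres[j, ] * cfg$cell_size,
                       mask = mask, zones = zones)
  }

  curr <- grid
  for (j in seq_len(cfg$n_sites)) {
    ov <- site_overrides[[j]] %||% list()
    frac_site <- ov$swap_fraction_site %||% cfg$swap_fraction_site
    frac_buf <- rep(ov$swap_fraction_buffer %||% cfg$swap_fraction_buffer,
                    length.out = length(cfg$buffer_radii))
    tw <- ov$swap_target_weights %||% cfg$swap_target_weights
    tw_site <- ov$swap_target_weights_site %||% tw
    tw_buf <- ov$swap_target_weights_buffer %||% tw
    zone_masks <- c(list(sites[[j]]$mask), sites[[j]]$zones$annuli)
    fracs <- c(frac_site, frac_buf)
    tws <- c(list(tw_site), rep(list(tw_buf), length(cfg$buffer_radii)))
    for (z in seq_along(zone_masks)) {
      curr <- swap_cells(curr, zone_masks[[z]], fracs[z], K, tws[[z]])
    }
  }

  structure(list(hist = land_raster(grid, legend, cfg$cell_size),
                 curr = land_raster(curr, legend, cfg$cell_size),
                 sites = sites, legend = legend, cfg = cfg),
            class = "synthetic_landscape")
}

# reassign exactly round(frac * |zone|) zone cells to a *different* class,
# drawn from `target_weights` (uniform over the other classes by default)
swap_cells <- function(grid, zone_mask, frac, K, target_weights = NULL) {
  idx <- which(zone_mask)
  n_swap <- round(frac * length(idx))
  if (n_swap == 0L) return(grid)
  pick <- if (length(idx) == 1L) idx else sample(idx, n_swap)
  w <- rep(1, K)
  if (!is.null(target_weights)) {
    if (length(target_weights) != K || any(target_weights < 0)) {
      stop2("swap_target_weights must be K nonnegative weights",
            class = "pollscape_config_error")
    }
    w <- as.numeric(target_weights)
  }
  for (i in pick) {
    wi <- w
    wi[grid[i]] <- 0
    if (sum(wi) == 0) wi <- as.numeric(seq_len(K) != grid[i])
    grid[i] <- sample.int(K, 1L, prob = wi)
  }
  grid
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf("<synthetic_landscape> %dx%d cells, %d sites\n",
              nrow(x$hist$grid), ncol(x$hist$grid), length(x$sites)))
  invisible(x)
}

#' Configuration for synthetic two-period assemblages
#'
#' Describes a species pool with Fisher log-series relative abundances and
#' two sampling periods of individual occurrence records. The period-1
#' community is a random pool subset; the period-2 community keeps a
#' fraction `1 - turnover_frac` of it (the rest replaced from unused pool
#' species) and is sized to `richness_ratio` times the period-1 richness.
#'
#' @param S_pool species-pool size.
#' @param fisher_alpha log-series shape (larger = more even).
#' @param n1,n2 record counts drawn per period (each record is one
#'   individual occurrence).
#' @param turnover_frac fraction of period-1 species replaced in period 2,
#'   in `[0, 1]`.
#' @param richness_ratio target ratio of period-2 to period-1 community
#'   richness (> 0).
#' @param seed integer seed.
#' @return a validated `community_config` list.
#' @export
community_config <- function(S_pool = 100, fisher_alpha = 50, n1 = 500, n2 = 500,
                             turnover_frac = 0.2, richness_ratio = 1, seed = 1L) {
  assert_scalar_number(n1, "n1", min = 1); assert_scalar_number(n2, "n2", min = 1)
  assert_scalar_number(turnover_frac, "turnover_frac", min = 0, max = 1)
  assert_scalar_number(richness_ratio, "richness_ratio", min = .Machine$double.eps)
  assert_scalar_number(S_pool, "S_pool", min = 1)
  assert_scalar_number(fisher_alpha, "fisher_alpha", min = .Machine$double.eps)
  cfg <- structure(list(S_pool = as.integer(S_pool), fisher_alpha = fisher_alpha,
                        n1 = as.integer(n1), n2 = as.integer(n2),
                        turnover_frac = turnover_frac,
                        richness_ratio = richness_ratio, seed = as.integer(seed)),
                   class = "community_config")
  sizes <- community_sizes(cfg)  # validates feasibility
  cfg$S1 <- sizes$S1; cfg$S2 <- sizes$S2
  cfg
}

# community sizes implied by the pool, ratio and turnover: the largest S1
# for which S1 + (S2 - retained) distinct species fit in the pool
community_sizes <- function(cfg) {
  rho <- cfg$richness_ratio; t <- cfg$turnover_frac
  denom <- 1 + rho - (1 - t) * min(1, rho)
  S1 <- min(cfg$S_pool, floor(cfg$S_pool / denom))
  S2 <- round(rho * S1)
  retained <- round((1 - t) * min(S1, S2))
  if (S1 < 1 || S2 < 1 || S1 + (S2 - retained) > cfg$S_pool) {
    stop2("S_pool too small for the requested richness_ratio/turnover_frac",
          class = "pollscape_config_error")
  }
  list(S1 = S1, S2 = S2, retained = retained)
}

# logarithmic-series variates: P(a) proportional to x^a / a, a >= 1
rlogseries <- function(n, x, a_max = 5000L) {
  stopifnot(x > 0, x < 1)
  a <- seq_len(a_max)
  pk <- exp(a * log(x) - log(a))
  sample.int(a_max, n, replace = TRUE, prob = pk)
}

#' Generate a two-period assemblage pair with known ground truth
#'
#' Draws `n1` and `n2` individual records (multinomially) from the period
#' communities described by the configuration. Ground-truth community
#' species sets are attached so tests can verify the realised turnover and
#' richness ratio against their targets.
#'
#' @param cfg a [community_config()].
#' @param site_id optional site label; folded into the seed so every site
#'   gets an independent, reproducible draw.
#' @return object of class `assemblage_pair`: list with `hist` and `curr`
#'   occurrence tibbles (`species`, `count`) and `truth` (list: `species1`,
#'   `species2`, `S1`, `S2`, `shared_fraction`).
#' @export
generate_assemblages <- function(cfg, site_id = NULL) {
  stopifnot(inherits(cfg, "community_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(cfg$seed, paste0("assemblage:", site_id %||% "")))

  sizes <- community_sizes(cfg)
  N0 <- (cfg$n1 + cfg$n2) / 2
  x <- N0 / (N0 + cfg$fisher_alpha)
  pool_ab <- rlogseries(cfg$S_pool, x)
  pool_names <- sprintf("sp%03d", seq_len(cfg$S_pool))

  sp1 <- sample(pool_names, sizes$S1)
  keep <- if (sizes$retained > 0) sample(sp1, sizes$retained) else character()
  newcomers <- sample(setdiff(pool_names, sp1), sizes$S2 - sizes$retained)
  sp2 <- c(keep, newcomers)

  draw <- function(sp, n) {
    p <- pool_ab[match(sp, pool_names)]
    cnt <- stats::rmultinom(1, n, p / sum(p))[, 1]
    tibble::tibble(species = sp, count = as.integer(cnt))[cnt > 0, ]
  }
  structure(list(
    hist = draw(sp1, cfg$n1),
    curr = draw(sp2, cfg$n2),
    truth = list(species1 = sort(sp1), species2 = sort(sp2),
                 S1 = sizes$S1, S2 = sizes$S2,
                 shared_fraction = sizes$retained / min(sizes$S1, sizes$S2))
  ), class = "assemblage_pair")
}

#' @export
print.assemblage_pair <- function(x, ...) {
  cat(sprintf("<assemblage_pair> n1 = %d (S = %d obs / %d true), n2 = %d (S = %d / %d)\n",
              sum(x$hist$count), nrow(x$hist), x$truth$S1,
              sum(x$curr$count), nrow(x$curr), x$truth$S2))
  invisible(x)
}

#' @describeIn generate_assemblages convert one period of an assemblage
#'   pair to a [ref_sample()].
#' @param pair an `assemblage_pair`.
#' @param period 1 (historical) or 2 (current).
#' @export
as_ref_sample <- function(pair, period) {
  tab <- if (period == 1) pair$hist else pair$curr
  ref_sample(stats::setNames(tab$count, tab$species))
}

#' Synthetic per-class pollinator suitability scores
#'
#' Stands in for the expert-elicited habitat suitability weights (one score
#' in `[0, 1]` per land-cover class) that the real analysis takes as input.
#' Deterministic given the seed.
#'
#' @param legend named character vector (codes -> class names).
#' @param seed integer seed.
#' @return named numeric vector of scores in `[0, 1]`, named by class name.
#' @export
generate_suitability_table <- function(legend, seed = 1L) {
  if (!length(legend)) stop2("empty legend", class = "pollscape_domain_error")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "suitability"))
  stats::setNames(round(stats::runif(length(legend)), 2), unname(legend))
}

#' Write the occurrence tables of assemblage pairs as a long-format CSV
#'
#' @param pairs named list of `assemblage_pair` objects (names = site ids).
#' @param path output CSV path; columns `site`, `period`, `species`,
#'   `count`.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(pairs, path) {
  rows <- lapply(names(pairs), function(s) {
    p <- pairs[[s]]
    rbind(data.frame(site = s, period = 1L, p$hist),
          data.frame(site = s, period = 2L, p$curr))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
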