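#' Land-cover change metrics for every site and zone
#'
#' Runs [percent_change()], [weight_change()] and the adjacency/edge-change
#' analysis for each focal site at every zone (the site itself plus each
#' buffer ring).
#'
#' @param landscape a `synthetic_landscape` (or any list with `hist`,
#'   `curr` [land_raster]s and `sites` carrying `mask` + `zones`).
#' @param suitability named suitability scores (class name -> `[0, 1]`).
#' @param double_count_like passed to [adjacency_matrix()].
#' @return list of tibbles: `cover` (site, zone, class, delta_pct, score,
#'   weighted_delta), `index` (site, zone, suitability_change_index),
#'   `edges` (site, zone, class1, class2, adj_hist, adj_curr, delta).
#' @export
site_metrics <- function(landscape, suitability, double_count_like = FALSE) {
  cover <- list(); index <- list(); edges <- list()
  for (s in landscape$sites) {
    zones <- c(list(site = s$mask), s$zones$annuli)
    for (zn in names(zones)) {
      if (!any(zones[[zn]])) next
      pc <- percent_change(landscape$hist, landscape$curr, zones[[zn]])
      wc <- weight_change(pc, suitability)
      cover[[length(cover) + 1L]] <- tibble::tibble(
        site = s$id, zone = zn, class = wc$table$class,
        delta_pct = wc$table$delta_pct, score = wc$table$score,
        weighted_delta = wc$table$weighted_delta)
      index[[length(index) + 1L]] <- tibble::tibble(
        site = s$id, zone = zn, suitability_change_index = wc$index)
      ec <- edge_change(
        adjacency_matrix(landscape$hist, zones[[zn]], double_count_like),
        adjacency_matrix(landscape$curr, zones[[zn]], double_count_like))
      et <- edge_change_table(ec)
      edges[[length(edges) + 1L]] <- tibble::tibble(site = s$id, zone = zn, et)
    }
  }
  list(cover = do.call(rbind, cover), index = do.call(rbind, index),
       edges = do.call(rbind, edges))
}

#' Wide per-site predictor table for one zone and predictor family
#'
#' @param metrics output of [site_metrics()].
#' @param zone zone name (`"site"`, `"ring_1000m"`, ...).
#' @param family `"cover"` (per-class suitability-weighted changes plus the
#'   suitability-change index) or `"edge"` (adjacency-change per class
#'   pair).
#' @param pairs for the edge family, character vector of class pairs as
#'   `"classA.classB"`; default: all pairs with nonzero variance.
#' @return tibble, one row per site; first column `site`.
#' @export
zone_predictors <- function(metrics, zone, family = c("cover", "edge"),
                            pairs = NULL) {
  family <- match.arg(family)
  if (family == "cover") {
    cv <- metrics$cover[metrics$cover$zone == zone, ]
    wide <- stats::reshape(as.data.frame(cv[c("site", "class", "weighted_delta")]),
                           idvar = "site", timevar = "class", direction = "wide")
    names(wide) <- sub("^weighted_delta\\.", "", names(wide))
    idx <- metrics$index[metrics$index$zone == zone, c("site", "suitability_change_index")]
    out <- merge(wide, as.data.frame(idx), by = "site", sort = TRUE)
    tibble::as_tibble(out)
  } else {
    ed <- metrics$edges[metrics$edges$zone == zone, ]
    ed$pair <- paste(ed$class1, ed$class2, sep = ".")
    wide <- stats::reshape(as.data.frame(ed[c("site", "pair", "delta")]),
                           idvar = "site", timevar = "pair", direction = "wide")
    names(wide) <- sub("^delta\\.", "", names(wide))
    if (is.null(pairs)) {
      v <- vapply(wide[-1], stats::var, 1)
      pairs <- names(wide[-1])[is.finite(v) & v > 0]
    }
    tibble::as_tibble(wide[c("site", intersect(pairs, names(wide)))])
  }
}

#' Per-site richness-change stage
#'
#' Applies the data-quality filter and the effort-corrected richness-change
#' estimator to every site's assemblage pair.
#'
#' @param pairs named list of `assemblage_pair` objects (names = site ids),
#'   or the output of [samples_from_records()].
#' @param B bootstrap replicates.
#' @param seed master seed (each site gets a derived seed).
#' @param cap_multiplier extrapolation ceiling.
#' @return tibble: one row per site with `pass`, `reasons`, and (for
#'   passing sites) `n1`, `n2`, `n_cmp`, `x1_hat`, `x2_hat`, `logratio`,
#'   `var_logratio`, `delta_r`, `extrapolated`.
#' @export
richness_stage <- function(pairs, B = 1000, seed, cap_multiplier = 3) {
  rows <- lapply(names(pairs), function(id) {
    p <- pairs[[id]]
    s1 <- if (inherits(p, "assemblage_pair")) as_ref_sample(p, 1) else p$hist
    s2 <- if (inherits(p, "assemblage_pair")) as_ref_sample(p, 2) else p$curr
    flt <- site_filter(s1, s2)
    base <- tibble::tibble(site = id, pass = flt$pass,
                           reasons = paste(flt$reasons, collapse = "; "),
                           n1 = s1$n, n2 = s2$n)
    if (!flt$pass) {
      return(cbind(base, tibble::tibble(n_cmp = NA_integer_, x1_hat = NA_real_,
                                        x2_hat = NA_real_, logratio = NA_real_,
                                        var_logratio = NA_real_, delta_r = NA_real_,
                                        extrapolated = NA)))
    }
    rc <- richness_change(s1, s2, B = B, seed = derive_seed(seed, paste0("boot:", id)),
                          cap_multiplier = cap_multiplier)
    cbind(base, tibble::tibble(n_cmp = rc$n_cmp, x1_hat = rc$x1_hat,
                               x2_hat = rc$x2_hat, logratio = rc$logratio,
                               var_logratio = rc$var_logratio, delta_r = rc$delta_r,
                               extrapolated = any(rc$extrapolated)))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Per-site composition-change stage
#'
#' Computes shared abundances, SCC and beta-sim for every site that passes
#' the richness-stage quality filter (the same exclusion rule applies to
#' both analyses).
#'
#' @inheritParams richness_stage
#' @param variant shared-abundance estimator variant.
#' @return tibble: `site`, `u`, `v`, `scc`, `beta_sim`, `variant`,
#'   `n_shared`.
#' @export
composition_stage <- function(pairs, variant = c("plugin", "bias_corrected")) {
  variant <- match.arg(variant)
  rows <- lapply(names(pairs), function(id) {
    p <- pairs[[id]]
    s1 <- if (inherits(p, "assemblage_pair")) as_ref_sample(p, 1) else p$hist
    s2 <- if (inherits(p, "assemblage_pair")) as_ref_sample(p, 2) else p$curr
    if (!site_filter(s1, s2)$pass) return(NULL)
    cbind(tibble::tibble(site = id), composition_change(s1, s2, variant))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Fixed reference suitability scores for the synthetic legend
#'
#' A plausible expert-style weighting of the synthetic land-cover classes
#' for pollinator habitat value (heathland and woodland high, arable and
#' water low). Used where a deterministic, non-random table is wanted.
#'
#' @param legend named character vector (codes -> class names).
#' @return named numeric scores in `[0, 1]`.
#' @export
default_suitability <- function(legend) {
  ref <- c(heathland = 0.9, woodland = 0.7, grassland = 0.6, arable = 0.2,
           urban = 0.3, orchard = 0.5, water = 0.1, garden = 0.6, other = 0.4)
  out <- ref[unname(legend)]
  out[is.na(out)] <- 0.5
  stats::setNames(as.numeric(out), unname(legend))
}

#' Generate a coupled synthetic world with known drivers
#'
#' Builds a landscape and per-site assemblages in which two ground truths
#' hold by construction: richness change (logratio) is driven only by the
#' change in urban cover in the first buffer ring
#' (`logratio = beta_richness * delta_pct_urban_ring1`), and species
#' turnover (hence SCC) is driven only by the change in grassland–arable
#' edge habitat within the site
#' (`turnover = 0.5 + beta_turnover * delta_adjacency`, clamped to
#' `[0.05, 0.95]`). Per-site heterogeneity in the drivers is created by
#' varying each site's swap fraction and swap-target weights.
#'
#' @param seed integer seed.
#' @param n_sites number of sites (default 30).
#' @param beta_richness logratio units per percentage point of urban change
#'   (default 0.05).
#' @param beta_turnover turnover units per adjacency-change unit
#'   (default 0.05).
#' @param n_records records per period per site (default 400).
#' @return list: `landscape`, `suitability`, `pairs`, `metrics`, `truth`
#'   (tibble: site, urban_ring1, edge_grass_arable_site, logratio_true,
#'   turnover).
#' @export
generate_world <- function(seed, n_sites = 30, beta_richness = 0.05,
                           beta_turnover = 0.05, n_records = 400) {
  cfg <- landscape_config(
    grid_dims = c(320, 320), cell_size = 100,
    class_mixture = c(0.20, 0.10, 0.22, 0.22, 0.10, 0.03, 0.04, 0.03, 0.06),
    n_sites = n_sites, site_radius = 500, site_dominance = 0.55,
    buffer_radii = c(1000, 1500),
    swap_fraction_site = 0.25, swap_fraction_buffer = 0.15, seed = seed)
  K <- length(cfg$class_names)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "world"))
  # per-site driver intensities: urban gain/loss in ring 1, grass-arable
  # edge gain/loss in the site
  u_bias <- stats::runif(n_sites, -1, 1)
  g_bias <- stats::runif(n_sites, -1, 1)
  overrides <- lapply(seq_len(n_sites), function(j) {
    wb <- rep(1, K); names(wb) <- cfg$class_names
    wb["urban"] <- if (u_bias[j] > 0) 1 + 12 * u_bias[j] else 0
    ws <- rep(1, K); names(ws) <- cfg$class_names
    ws[c("grassland", "arable")] <- if (g_bias[j] > 0) 1 + 8 * g_bias[j] else 0
    list(swap_fraction_site = 0.15 + 0.35 * abs(g_bias[j]),
         swap_fraction_buffer = 0.08 + 0.25 * abs(u_bias[j]),
         swap_target_weights_site = ws, swap_target_weights_buffer = wb)
  })
  land <- generate_landscape(cfg, site_overrides = overrides, max_tries = 10000L)
  suit <- default_suitability(land$legend)
  metrics <- site_metrics(land, suit)

  ring1 <- sprintf("ring_%gm", cfg$buffer_radii[1])
  cover_r1 <- metrics$cover[metrics$cover$zone == ring1 &
                              metrics$cover$class == "urban", ]
  edges_site <- metrics$edges[metrics$edges$zone == "site" &
                                metrics$edges$class1 == "grassland" &
                                metrics$edges$class2 == "arable", ]
  truth <- tibble::tibble(
    site = vapply(land$sites, `[[`, "", "id"),
    urban_ring1 = cover_r1$delta_pct[match(vapply(land$sites, `[[`, "", "id"),
                                           cover_r1$site)],
    edge_grass_arable_site = edges_site$delta[match(vapply(land$sites, `[[`, "", "id"),
                                                    edges_site$site)])
  truth$logratio_true <- beta_richness * truth$urban_ring1
  truth$turnover <- pmin(0.95, pmax(0.05,
                                    0.5 + beta_turnover * truth$edge_grass_arable_site))

  pairs <- list()
  for (j in seq_len(n_sites)) {
    rho <- min(2, max(0.5, exp(truth$logratio_true[j])))
    ccfg <- community_config(S_pool = 120, fisher_alpha = 40,
                             n1 = n_records, n2 = n_records,
                             turnover_frac = truth$turnover[j],
                             richness_ratio = rho,
                             seed = derive_seed(seed, paste0("comm:", j)))
    pairs[[truth$site[j]]] <- generate_assemblages(ccfg, site_id = truth$site[j])
  }
  list(landscape = land, suitability = suit, pairs = pairs, metrics = metrics,
       truth = truth, ring1 = ring1)
}

#' Fit the driver-recovery models on a coupled world
#'
#' Runs the richness and composition stages, screens collinearity, and
#' performs the constrained stepwise selection: an inverse-variance
#' random-effects meta-regression of logratio on the ring-1 cover-change
#' predictors, and a Gaussian GLM of SCC on the within-site edge-change
#' predictors.
#'
#' @param world output of [generate_world()].
#' @param B bootstrap replicates for the richness stage (default 50; the
#'   point estimates, not the bootstrap, carry the recovery signal).
#' @param seed seed for the bootstrap stage.
#' @return list: `richness_fit`, `scc_fit` (`stepwise_fit` objects),
#'   `richness_tbl`, `scc_tbl`, `data_rich`, `data_scc`.
#' @export
analyze_world <- function(world, B = 50, seed = 1L) {
  rich <- richness_stage(world$pairs, B = B, seed = seed)
  comp <- composition_stage(world$pairs)
  cover_pred <- zone_predictors(world$metrics, world$ring1, "cover")
  cover_cand <- c("heathland", "woodland", "grassland", "arable", "urban")
  edge_pred <- zone_predictors(world$metrics, "site", "edge",
                               pairs = c("grassland.arable", "heathland.woodland",
                                         "woodland.grassland", "arable.urban"))
  ok <- rich[rich$pass, c("site", "logratio", "var_logratio")]
  d_rich <- merge(ok, as.data.frame(cover_pred), by = "site")
  scr <- screen_collinearity(d_rich[cover_cand])
  rfit <- stepwise_select(d_rich, "logratio", cover_cand, forbidden = scr$forbidden,
                          engine = "meta", var_col = "var_logratio")
  d_scc <- merge(as.data.frame(comp[c("site", "scc")]), as.data.frame(edge_pred),
                 by = "site")
  edge_cand <- setdiff(names(edge_pred), "site")
  scr2 <- screen_collinearity(d_scc[edge_cand])
  sfit <- glm_composition(d_scc, "scc", edge_cand, forbidden = scr2$forbidden)
  list(richness_fit = rfit, scc_fit = sfit, richness_tbl = rich, scc_tbl = comp,
       data_rich = tibble::as_tibble(d_rich), data_scc = tibble::as_tibble(d_scc))
}

#' Run the full synthetic pipeline end to end
#'
#' generate -> land-cover metrics -> richness -> composition -> spatial and
#' effort-bias screens -> constrained model selection, as one reproducible,
#' optionally logged run. All randomness derives from the single master
#' seed, so re-running an identical configuration reproduces every output.
#'
#' @param landscape_cfg a [landscape_config()].
#' @param community_cfg a [community_config()] (per-site seeds are derived
#'   from `seed`, overriding its own).
#' @param seed master integer seed.
#' @param B bootstrap replicates for the richness stage.
#' @param variant shared-abundance estimator variant for SCC.
#' @param out_dir optional directory; when given, all stage tables are
#'   written as CSV together with a JSON run manifest.
#' @return list: `landscape`, `suitability`, `metrics`, `richness`,
#'   `composition`, `moran`, `bias_check`, `models`, `manifest`.
#' @export
run_pipeline <- function(landscape_cfg = landscape_config(),
                         community_cfg = community_config(),
                         seed = 1L, B = 200,
                         variant = c("plugin", "bias_corrected"),
                         out_dir = NULL) {
  variant <- match.arg(variant)
  land <- generate_landscape(
    landscape_config_with_seed(landscape_cfg, derive_seed(seed, "stage:landscape")))
  suit <- generate_suitability_table(land$legend, seed = derive_seed(seed, "stage:suit"))
  metrics <- site_metrics(land, suit)

  pairs <- list()
  for (s in land$sites) {
    ccfg <- community_cfg
    ccfg$seed <- derive_seed(seed, paste0("stage:community:", s$id))
    pairs[[s$id]] <- generate_assemblages(ccfg, site_id = s$id)
  }
  rich <- richness_stage(pairs, B = B, seed = derive_seed(seed, "stage:richness"))
  comp <- composition_stage(pairs, variant = variant)
  ok <- rich[rich$pass, ]
  if (nrow(ok) == 0L) {
    stop2("no site passes the data-quality filter; models stage refused",
          class = "pollscape_no_sites")
  }

  centres <- do.call(rbind, lapply(land$sites, `[[`, "centre"))
  rownames(centres) <- vapply(land$sites, `[[`, "", "id")
  coords_ok <- centres[ok$site, , drop = FALSE]
  moran <- list(
    logratio = if (nrow(ok) >= 4) morans_i(ok$logratio, coords_ok) else NULL,
    scc = if (nrow(comp) >= 4) morans_i(comp$scc, centres[comp$site, , drop = FALSE])
          else NULL)
  bias <- sampling_bias_check(ok$logratio, ok$var_logratio, ok$delta_r)

  models <- list()
  zones <- unique(metrics$cover$zone)
  cover_classes <- unique(metrics$cover$class)
  for (zn in zones) {
    pred <- zone_predictors(metrics, zn, "cover")
    cand0 <- intersect(cover_classes, names(pred))
    d <- merge(as.data.frame(ok[c("site", "logratio", "var_logratio")]),
               as.data.frame(pred), by = "site")
    keep <- cand0[vapply(d[cand0], stats::var, 1) > 0]
    if (length(keep) < 1L || nrow(d) < 4L) next
    scr <- suppressWarnings(screen_collinearity(d[keep]))
    keep <- setdiff(keep, scr$dropped)
    models[[paste0("richness_cover_", zn)]] <- tryCatch(
      stepwise_select(d, "logratio", keep, forbidden = scr$forbidden,
                      engine = "meta", var_col = "var_logratio"),
      error = function(e) e)
    dd <- merge(as.data.frame(comp[c("site", "scc")]), as.data.frame(pred), by = "site")
    models[[paste0("scc_cover_", zn)]] <- tryCatch(
      glm_composition(dd, "scc", keep, forbidden = scr$forbidden),
      error = function(e) e)
  }

  manifest <- list(seed = seed, B = B, variant = variant,
                   landscape_cfg = unclass(landscape_cfg),
                   community_cfg = unclass(community_cfg),
                   package_version = as.character(utils::packageVersion("pollscape")),
                   n_sites_pass = nrow(ok))
  res <- list(landscape = land, suitability = suit, metrics = metrics,
              richness = rich, composition = comp, moran = moran,
              bias_check = bias, models = models, manifest = manifest)
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

landscape_config_with_seed <- function(cfg, seed) {
  cfg$seed <- as.integer(seed)
  cfg
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$metrics$cover, file.path(out_dir, "cover_change.csv"),
                   row.names = FALSE)
  utils::write.csv(res$metrics$index, file.path(out_dir, "suitability_index.csv"),
                   row.names = FALSE)
  utils::write.csv(res$metrics$edges, file.path(out_dir, "edge_change.csv"),
                   row.names = FALSE)
  utils::write.csv(res$richness, file.path(out_dir, "richness_change.csv"),
                   row.names = FALSE)
  utils::write.csv(res$composition, file.path(out_dir, "composition_change.csv"),
                   row.names = FALSE)
  write_ascii_grid(res$landscape$hist, file.path(out_dir, "landcover_hist.asc"))
  write_ascii_grid(res$landscape$curr, file.path(out_dir, "landcover_curr.asc"))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
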