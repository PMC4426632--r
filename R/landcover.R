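#' Build site and buffer-ring zones around a site mask
#'
#' Pollinator-relevant landscape context is scored at the site itself and in
#' buffer rings outside it (the field convention is 1, 2, 5 and 10 km).
#' Rings are built by thresholding the Euclidean distance from each outside
#' cell (centre) to the nearest site cell: ring k holds cells with
#' `r_{k-1} < d <= r_k`. Site cells belong to no ring.
#'
#' @param site_mask logical matrix, `TRUE` inside the site.
#' @param radii strictly increasing positive radii in metres.
#' @param cell_size cell edge length in metres.
#' @param mode `"annulus"` (default; disjoint rings) or `"disc"` (each zone
#'   is the full buffer out to its radius, site still excluded).
#' @return an object of class `zone_set`: list with `site`, `annuli` (named
#'   list of logical matrices), `radii`, `mode`, and `flags` (tibble marking
#'   empty zones).
#' @export
build_zones <- function(site_mask, radii, cell_size, mode = c("annulus", "disc")) {
  mode <- match.arg(mode)
  if (!is.matrix(site_mask) || !is.logical(site_mask)) {
    stop2("`site_mask` must be a logical matrix", class = "pollscape_domain_error")
  }
  if (!any(site_mask)) stop2("empty site mask", class = "pollscape_domain_error")
  assert_scalar_number(cell_size, "cell_size", min = .Machine$double.eps)
  if (length(radii) < 1L || any(radii <= 0) || is.unsorted(radii, strictly = TRUE)) {
    stop2("`radii` must be strictly increasing and positive",
          class = "pollscape_domain_error")
  }
  # distances are only needed out to the outermost radius: crop to the
  # site's bounding box padded by that radius, treat everything beyond as
  # infinitely far
  pad_cells <- ceiling(max(radii) / cell_size) + 1L
  rr <- range(which(rowSums(site_mask) > 0))
  cr <- range(which(colSums(site_mask) > 0))
  wr <- max(1L, rr[1] - pad_cells):min(nrow(site_mask), rr[2] + pad_cells)
  wc <- max(1L, cr[1] - pad_cells):min(ncol(site_mask), cr[2] + pad_cells)
  d <- matrix(Inf, nrow(site_mask), ncol(site_mask))
  d[wr, wc] <- distance_to_site(site_mask[wr, wc, drop = FALSE]) * cell_size
  lower <- if (mode == "annulus") c(0, radii[-length(radii)]) else rep(0, length(radii))
  annuli <- vector("list", length(radii))
  empty <- logical(length(radii))
  for (k in seq_along(radii)) {
    ring <- !site_mask & d > lower[k] & d <= radii[k]
    annuli[[k]] <- ring
    empty[k] <- !any(ring)
  }
  names(annuli) <- sprintf("ring_%gm", radii)
  if (any(empty)) {
    warn2("empty buffer zone(s): ", paste(names(annuli)[empty], collapse = ", "),
          class = "pollscape_empty_zone")
  }
  structure(list(site = site_mask, annuli = annuli, radii = radii, mode = mode,
                 flags = tibble::tibble(zone = c("site", names(annuli)),
                                        empty = c(FALSE, empty))),
            class = "zone_set")
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("<zone_set> site: %d cells; %s mode; rings at %s m (%s cells)\n",
              sum(x$site), x$mode, paste(x$radii, collapse = "/"),
              paste(vapply(x$annuli, sum, 1), collapse = "/")))
  invisible(x)
}

# Euclidean distance (in cell units) from every cell to the nearest site
# cell; 0 inside the site. Exact, via the boundary cells of the site,
# chunked to bound memory.
distance_to_site <- function(site_mask) {
  nr <- nrow(site_mask); nc <- ncol(site_mask)
  d <- matrix(0, nr, nc)
  out_idx <- which(!site_mask)
  if (!length(out_idx)) return(d)
  # only boundary site cells can be nearest to an outside cell
  pad <- function(m, r, c) {
    res <- matrix(FALSE, nr, nc)
    src_r <- seq_len(nr) - r; src_c <- seq_len(nc) - c
    ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
    res[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
    res
  }
  interior <- site_mask & pad(site_mask, 1, 0) & pad(site_mask, -1, 0) &
    pad(site_mask, 0, 1) & pad(site_mask, 0, -1)
  bnd_idx <- which(site_mask & !interior)
  if (!length(bnd_idx)) bnd_idx <- which(site_mask)
  br <- (bnd_idx - 1L) %% nr + 1L; bc <- (bnd_idx - 1L) %/% nr + 1L
  orow <- (out_idx - 1L) %% nr + 1L; ocol <- (out_idx - 1L) %/% nr + 1L
  chunk <- max(1L, floor(4e6 / length(bnd_idx)))
  for (s in seq(1L, length(out_idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(out_idx))
    dr <- outer(orow[s:e], br, "-"); dc <- outer(ocol[s:e], bc, "-")
    d[out_idx[s:e]] <- sqrt(.rowMins(dr * dr + dc * dc))
  }
  d
}

.rowMins <- function(m) {
  if (is.null(dim(m))) return(min(m))
  do.call(pmin, c(as.data.frame(m), list(na.rm = TRUE)))
}

#' Per-class percentage-point cover change within a zone
#'
#' For each legend class c, `delta_pct = 100 * (n_curr(c) - n_hist(c)) / N`
#' where N is the number of zone cells valid (non-nodata) in both periods.
#' Because the classes partition the zone, the changes sum to zero.
#'
#' @param hist,curr co-registered [land_raster] objects sharing a legend.
#' @param zone logical matrix selecting the zone (defaults to the full grid).
#' @return tibble with columns `class`, `cover_hist_pct`, `cover_curr_pct`,
#'   `delta_pct`; attribute `nodata_fraction` gives the excluded share.
#' @export
percent_change <- function(hist, curr, zone = NULL) {
  check_pair(hist, curr)
  if (is.null(zone)) zone <- matrix(TRUE, nrow(hist$grid), ncol(hist$grid))
  if (!any(zone)) stop2("empty zone", class = "pollscape_domain_error")
  valid <- zone & !is.na(hist$grid) & !is.na(curr$grid)
  n_valid <- sum(valid)
  if (n_valid == 0L) {
    stop2("zone contains no valid (non-nodata) cells", class = "pollscape_nodata_error")
  }
  codes <- as.integer(names(hist$legend))
  cnt <- function(g) tabulate(match(g[valid], codes), nbins = length(codes))
  n_h <- cnt(hist$grid); n_c <- cnt(curr$grid)
  out <- tibble::tibble(
    class = unname(hist$legend),
    cover_hist_pct = 100 * n_h / n_valid,
    cover_curr_pct = 100 * n_c / n_valid,
    delta_pct = 100 * (n_c - n_h) / n_valid
  )
  attr(out, "nodata_fraction") <- 1 - n_valid / sum(zone)
  out
}

check_pair <- function(hist, curr) {
  stopifnot(inherits(hist, "land_raster"), inherits(curr, "land_raster"))
  if (!same_geometry(hist, curr)) {
    stop2("rasters are not co-registered (geometry differs)",
          class = "pollscape_geometry_error")
  }
  if (!identical(hist$legend, curr$legend)) {
    stop2("rasters do not share a legend", class = "pollscape_legend_error")
  }
  invisible(TRUE)
}

#' Suitability-weighted cover change and the suitability-change index
#'
#' Each per-class percentage-point change is multiplied by that class's
#' pollinator suitability score (an expert-assigned weight in `[0, 1]`);
#' their sum is the site's change-in-habitat-suitability index used as a
#' model predictor.
#'
#' @param change tibble from [percent_change()].
#' @param suitability named numeric vector of scores in `[0, 1]`, named by
#'   class name; every class in `change` must have a score.
#' @return list with `table` (the input tibble plus `score` and
#'   `weighted_delta` columns) and `index` (sum of weighted changes).
#' @export
weight_change <- function(change, suitability) {
  miss <- setdiff(change$class, names(suitability))
  if (length(miss)) {
    stop2("missing suitability score for: ", paste(miss, collapse = ", "),
          class = "pollscape_config_error")
  }
  sc <- suitability[change$class]
  if (any(!is.finite(sc)) || any(sc < 0 | sc > 1)) {
    stop2("suitability scores must lie in [0, 1]", class = "pollscape_config_error")
  }
  tab <- change
  tab$score <- unname(sc)
  tab$weighted_delta <- tab$score * tab$delta_pct
  list(table = tab, index = sum(tab$weighted_delta))
}

#' Cell-adjacency (edge) tally within a zone
#'
#' Counts unordered rook-adjacent (4-neighbour) cell pairs whose two cells
#' both lie in the zone, tallied by the unordered pair of land-cover classes
#' involved; like-class pairs sit on the diagonal. Edge habitat between two
#' cover types is proxied by their adjacency count.
#'
#' @param raster a [land_raster].
#' @param zone logical matrix (defaults to the full grid).
#' @param double_count_like if `TRUE`, diagonal (like-class) tallies are
#'   doubled, matching the double-sided convention of some landscape-metric
#'   software. Differences between periods are invariant to this choice.
#' @return symmetric integer matrix with class-name dimnames.
#' @export
adjacency_matrix <- function(raster, zone = NULL, double_count_like = FALSE) {
  stopifnot(inherits(raster, "land_raster"))
  g <- raster$grid
  if (is.null(zone)) zone <- matrix(TRUE, nrow(g), ncol(g))
  if (!any(zone)) stop2("empty zone", class = "pollscape_domain_error")
  codes <- as.integer(names(raster$legend))
  K <- length(codes)
  idx <- matrix(match(g, codes), nrow(g))
  tab <- matrix(0, K, K)
  add_pairs <- function(a, b, za, zb) {
    keep <- za & zb & !is.na(a) & !is.na(b)
    if (!any(keep)) return(invisible())
    i <- pmin(a[keep], b[keep]); j <- pmax(a[keep], b[keep])
    t2 <- table(factor(i, levels = seq_len(K)), factor(j, levels = seq_len(K)))
    tab <<- tab + unclass(t2)
  }
  if (ncol(g) > 1L) {
    add_pairs(idx[, -ncol(g), drop = FALSE], idx[, -1, drop = FALSE],
              zone[, -ncol(g), drop = FALSE], zone[, -1, drop = FALSE])
  }
  if (nrow(g) > 1L) {
    add_pairs(idx[-nrow(g), , drop = FALSE], idx[-1, , drop = FALSE],
              zone[-nrow(g), , drop = FALSE], zone[-1, , drop = FALSE])
  }
  m <- tab + t(tab) - diag(diag(tab), K)
  if (double_count_like) diag(m) <- 2 * diag(m)
  dimnames(m) <- list(unname(raster$legend), unname(raster$legend))
  m
}

#' Between-period change in the cell-adjacency matrix
#'
#' @param A_hist,A_curr symmetric adjacency tallies from [adjacency_matrix()]
#'   computed on the same zone with the same legend.
#' @return object of class `edge_change`: list with `A_hist`, `A_curr`,
#'   `delta` (= `A_curr - A_hist`).
#' @export
edge_change <- function(A_hist, A_curr) {
  if (!identical(dimnames(A_hist), dimnames(A_curr))) {
    stop2("adjacency matrices do not share a legend", class = "pollscape_legend_error")
  }
  structure(list(A_hist = A_hist, A_curr = A_curr, delta = A_curr - A_hist),
            class = "edge_change")
}

#' @export
print.edge_change <- function(x, ...) {
  cat("<edge_change> net |delta| =", sum(abs(x$delta[upper.tri(x$delta, diag = TRUE)])), "\n")
  invisible(x)
}

#' Tidy table of unordered class-pair edge changes
#'
#' @param ec an [edge_change()] object.
#' @param drop_zero drop pairs with no adjacency in either period.
#' @return tibble with `class1`, `class2`, `adj_hist`, `adj_curr`, `delta`.
#' @export
edge_change_table <- function(ec, drop_zero = FALSE) {
  stopifnot(inherits(ec, "edge_change"))
  cls <- rownames(ec$delta)
  ut <- which(upper.tri(ec$delta, diag = TRUE), arr.ind = TRUE)
  out <- tibble::tibble(
    class1 = cls[ut[, 1]], class2 = cls[ut[, 2]],
    adj_hist = ec$A_hist[ut], adj_curr = ec$A_curr[ut], delta = ec$delta[ut]
  )
  if (drop_zero) out <- out[out$adj_hist != 0 | out$adj_curr != 0, ]
  out
}

#' Screen predictors for collinearity before model selection
#'
#' Land-cover change predictors are often strongly (negatively) correlated —
#' e.g. a loss of heathland showing up as a gain of woodland — so pairs that
#' are significantly correlated across sites are barred from entering the
#' same regression model.
#'
#' @param predictors data frame / tibble, one row per site, one column per
#'   predictor (numeric).
#' @param alpha significance level for flagging a pair (default 0.05).
#' @return list with `report` (tibble: `var1`, `var2`, `r`, `p`,
#'   `forbidden`), `forbidden` (2-column character matrix of barred pairs)
#'   and `dropped` (zero-variance predictors, removed with a warning).
#' @export
screen_collinearity <- function(predictors, alpha = 0.05) {
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) < 3L) {
    stop2("need at least 3 sites to screen collinearity",
          class = "pollscape_domain_error")
  }
  variances <- vapply(predictors, stats::var, 1)
  dropped <- names(predictors)[variances == 0 | !is.finite(variances)]
  if (length(dropped)) {
    warn2("zero-variance predictor(s) excluded: ", paste(dropped, collapse = ", "),
          class = "pollscape_zero_variance")
    predictors <- predictors[setdiff(names(predictors), dropped)]
  }
  vars <- names(predictors)
  pairs <- if (length(vars) >= 2L) utils::combn(vars, 2L) else matrix(character(), 2, 0)
  n <- ncol(pairs)
  r <- p <- numeric(n)
  for (k in seq_len(n)) {
    ct <- stats::cor.test(predictors[[pairs[1, k]]], predictors[[pairs[2, k]]])
    r[k] <- unname(ct$estimate); p[k] <- ct$p.value
  }
  report <- tibble::tibble(var1 = pairs[1, ], var2 = pairs[2, ], r = r, p = p,
                           forbidden = p < alpha)
  list(report = report,
       forbidden = as.matrix(report[report$forbidden, c("var1", "var2")]),
       dropped = dropped)
}
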