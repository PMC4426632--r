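#' Categorical land-cover raster
#'
#' A minimal container for a single-period categorical land-cover map: an
#' integer matrix of class codes, a legend mapping codes to class names, and
#' the cell size in metres. `NA` cells are nodata. Two periods to be compared
#' must share grid geometry, cell size and legend.
#'
#' @param grid integer matrix of class codes (`NA` = nodata).
#' @param legend named character vector; names are the integer codes as
#'   strings, values the class names.
#' @param cell_size cell edge length in metres.
#' @return an object of class `land_raster`.
#' @export
land_raster <- function(grid, legend, cell_size) {
  if (!is.matrix(grid)) stop2("`grid` must be a matrix", class = "pollscape_domain_error")
  storage.mode(grid) <- "integer"
  assert_scalar_number(cell_size, "cell_size", min = .Machine$double.eps)
  legend <- validate_legend(legend)
  codes <- unique(grid[!is.na(grid)])
  missing <- setdiff(as.character(codes), names(legend))
  if (length(missing)) {
    stop2("grid contains codes absent from legend: ", paste(missing, collapse = ", "),
          class = "pollscape_legend_error")
  }
  structure(list(grid = grid, legend = legend, cell_size = cell_size),
            class = "land_raster")
}

validate_legend <- function(legend) {
  if (is.null(names(legend)) || anyNA(suppressWarnings(as.integer(names(legend))))) {
    stop2("`legend` must be a character vector named by integer codes",
          class = "pollscape_legend_error")
  }
  if (anyDuplicated(names(legend)) || anyDuplicated(legend)) {
    stop2("legend codes and class names must be unique", class = "pollscape_legend_error")
  }
  storage.mode(legend) <- "character"
  legend
}

#' @export
print.land_raster <- function(x, ...) {
  cat(sprintf("<land_raster> %d x %d cells @ %gm, %d classes, %.1f%% nodata\n",
              nrow(x$grid), ncol(x$grid), x$cell_size, length(x$legend),
              100 * mean(is.na(x$grid))))
  invisible(x)
}

#' @export
dim.land_raster <- function(x) dim(x$grid)

same_geometry <- function(a, b) {
  identical(dim(a$grid), dim(b$grid)) && isTRUE(all.equal(a$cell_size, b$cell_size))
}

#' Reclassify a raster to a broader legend
#'
#' Collapses a fine classification (e.g. a 23-class contemporary land-cover
#' map) onto a broad scheme (e.g. 8 historical survey classes plus "other")
#' via a many-to-one code mapping. Cell geometry is unchanged.
#'
#' @param raster a [land_raster].
#' @param mapping data frame with columns `from` (fine code), `to` (broad
#'   code); every non-nodata code in the raster must appear in `from` unless
#'   `default_to` is given.
#' @param legend named character vector: the broad legend (codes -> names).
#' @param default_to optional broad code that unmapped fine codes fall into
#'   (the "other" class). If `NULL`, unmapped codes are an error.
#' @return a [land_raster] with the broad legend.
#' @export
reclassify <- function(raster, mapping, legend, default_to = NULL) {
  stopifnot(inherits(raster, "land_raster"))
  if (!all(c("from", "to") %in% names(mapping))) {
    stop2("`mapping` needs columns `from` and `to`", class = "pollscape_domain_error")
  }
  legend <- validate_legend(legend)
  codes <- unique(raster$grid[!is.na(raster$grid)])
  unmapped <- setdiff(codes, mapping$from)
  if (length(unmapped) && is.null(default_to)) {
    stop2("unmapped codes with no default: ", paste(sort(unmapped), collapse = ", "),
          class = "pollscape_legend_error")
  }
  lut_idx <- match(raster$grid, mapping$from)
  out <- mapping$to[lut_idx]
  if (!is.null(default_to)) out[is.na(lut_idx) & !is.na(raster$grid)] <- default_to
  out <- matrix(as.integer(out), nrow = nrow(raster$grid))
  land_raster(out, legend, raster$cell_size)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text categorical raster export (integer codes, `nodata_value -9999`).
#' The legend is written alongside as `<path>.legend.csv`.
#'
#' @param raster a [land_raster].
#' @param path output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  g <- raster$grid
  g[is.na(g)] <- -9999L
  hdr <- c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    "xllcorner 0", "yllcorner 0",
    sprintf("cellsize %g", raster$cell_size),
    "nodata_value -9999"
  )
  body <- apply(g, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  utils::write.csv(
    data.frame(code = as.integer(names(raster$legend)), class = unname(raster$legend)),
    paste0(path, ".legend.csv"), row.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#'
#' @param path `.asc` file path; `<path>.legend.csv` must exist unless
#'   `legend` is supplied.
#' @param legend optional named character vector overriding the sidecar file.
#' @return a [land_raster].
#' @export
read_ascii_grid <- function(path, legend = NULL) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- grep(paste0("^", key, " "), hdr, value = TRUE)
    as.numeric(strsplit(ln, " +")[[1]][2])
  }
  nodata <- val("nodata_value")
  body <- lines[-(1:6)]
  g <- do.call(rbind, lapply(strsplit(trimws(body), " +"), as.integer))
  g[g == nodata] <- NA_integer_
  if (is.null(legend)) {
    leg_df <- utils::read.csv(paste0(path, ".legend.csv"))
    legend <- stats::setNames(as.character(leg_df$class), leg_df$code)
  }
  land_raster(g, legend, val("cellsize"))
}
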