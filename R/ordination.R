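#' PCA of the genotype dosage matrix
#'
#' Column-mean-centred PCA of individual allele dosages, with missing
#' calls imputed by the locus mean (standard practice on low-missingness
#' SNP panels). Component signs are fixed so that the largest-magnitude
#' entry of each loading vector is positive, making scores reproducible
#' across platforms.
#'
#' @param genotypes a [genotype_matrix()].
#' @param n_components number of components to keep.
#' @return A `pca_result` list: `scores` (individuals x components),
#'   `loadings`, `explained` (variance fractions, non-increasing),
#'   `center`, `n_imputed`.
#' @export
pca_genotypes <- function(genotypes, n_components = 2L) {
  x <- unclass(genotypes)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 individuals and >= 2 loci")
  all_na <- colSums(!is.na(x)) == 0
  if (any(all_na))
    stop("locus with no observed genotypes: ",
         colnames(x)[which(all_na)[1]])
  n_imputed <- sum(is.na(x))
  mu <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0)) x[is.na(x[, j]), j] <- mu[j]
  n_components <- min(n_components, nrow(x) - 1L, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x, 2, flip, `*`)[, seq_len(n_components), drop = FALSE]
  loadings <- sweep(pc$rotation, 2, flip, `*`)[, seq_len(n_components),
                                               drop = FALSE]
  explained <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  structure(list(scores = scores, loadings = loadings,
                 explained = explained, center = pc$center,
                 n_imputed = n_imputed),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d individuals, %d components (%s of variance); %d calls imputed\n",
              nrow(x$scores), length(x$explained),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "),
              x$n_imputed))
  invisible(x)
}

#' Per-group score summaries (mean +/- one standard deviation)
#'
#' Componentwise mean and sd of ordination scores per group, the numbers
#' behind mean +/- sd summary ellipses.
#'
#' @param scores individuals x components matrix.
#' @param grouping factor-like vector, one entry per individual.
#' @return data frame of `group`, `component`, `mean`, `sd`, `n`;
#'   singleton groups carry `NA` sd and a `degenerate` flag.
#' @export
group_ellipses <- function(scores, grouping) {
  scores <- as.matrix(scores)
  stopifnot(length(grouping) == nrow(scores))
  rows <- list()
  for (g in unique(as.character(grouping))) {
    sel <- as.character(grouping) == g
    for (j in seq_len(ncol(scores))) {
      v <- scores[sel, j]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, component = j, mean = mean(v),
        sd = if (sum(sel) > 1) stats::sd(v) else NA_real_,
        n = sum(sel), degenerate = sum(sel) < 2,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Sample-size-weighted geographic contour surface
#'
#' Interpolates a per-population value (e.g. a mean PC score) over a
#' geographic grid by weight-scaled inverse-distance-squared averaging:
#' `cell = sum(w_i v_i / d_i^2) / sum(w_i / d_i^2)`, with the weight slot
#' carrying population sample size. A cell coincident with a data point
#' takes that point's value exactly; all interpolated values stay within
#' the data range (convex combination).
#'
#' @param points data frame with `lat`, `lon`, `value`, `weight`
#'   (positive).
#' @param nrows,ncols grid dimensions.
#' @param xllcorner,yllcorner,cellsize grid georeferencing; defaults wrap
#'   the point cloud with half a cell of margin.
#' @return A [raster_grid()] of interpolated values.
#' @export
weighted_contour_surface <- function(points, nrows = 50, ncols = 50,
                                     xllcorner = NULL, yllcorner = NULL,
                                     cellsize = NULL) {
  req <- c("lat", "lon", "value", "weight")
  stopifnot(all(req %in% names(points)), nrow(points) >= 1)
  if (any(points$weight <= 0)) stop("weights must be positive")
  key <- paste(points$lat, points$lon)
  if (anyDuplicated(key)) {
    dup <- split(points$value, key)
    clash <- vapply(dup, function(v) length(unique(v)) > 1, logical(1))
    if (any(clash)) stop("duplicate coordinates with conflicting values")
    points <- points[!duplicated(key), , drop = FALSE]
  }
  if (is.null(cellsize))
    cellsize <- max(diff(range(points$lon)), diff(range(points$lat)), 1e-6) /
      max(nrows, ncols)
  if (is.null(xllcorner)) xllcorner <- min(points$lon) - cellsize / 2
  if (is.null(yllcorner)) yllcorner <- min(points$lat) - cellsize / 2
  grid <- raster_grid(matrix(NA_real_, nrows, ncols), xllcorner, yllcorner,
                      cellsize)
  cc <- grid_coordinates(grid)
  vals <- matrix(NA_real_, nrows, ncols)
  for (r in seq_len(nrows)) {
    for (cl in seq_len(ncols)) {
      d2 <- (points$lat - cc$lat[r])^2 + (points$lon - cc$lon[cl])^2
      hit <- which(d2 < 1e-18)
      if (length(hit)) {
        vals[r, cl] <- points$value[hit[1]]
      } else {
        w <- points$weight / d2
        vals[r, cl] <- sum(w * points$value) / sum(w)
      }
    }
  }
  raster_grid(vals, xllcorner, yllcorner, cellsize)
}
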