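#' Read and write the genotype CSV format
#'
#' The repository's genotype interchange format is a flat CSV with header
#' `individual,population,cohort,species,lat,lon,<locus1>,...` and dosage
#' cells `0|1|2|NA`. Loci whose name starts with `"mt"` are treated as
#' haploid mitochondrial markers unless `haploid_loci` overrides this.
#'
#' @param path file path.
#' @param haploid_loci optional character vector of locus names to treat as
#'   haploid, overriding the `"mt"` prefix convention.
#' @return `read_genotype_csv()`: a list with elements `genotypes`
#'   (a [genotype_matrix()]) and `samples` (a [sample_table()]).
#' @export
read_genotype_csv <- function(path, haploid_loci = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = "NA")
  meta_cols <- c("individual", "population", "cohort", "species", "lat", "lon")
  if (length(names(df)) < 7 || !identical(names(df)[1:6], meta_cols))
    stop("malformed header: expected 'individual,population,cohort,species,lat,lon,<loci>'")
  locus_ids <- names(df)[-(1:6)]
  geno <- as.matrix(df[, -(1:6), drop = FALSE])
  if (!is.numeric(geno)) {
    bad <- which(!is.na(geno) & is.na(suppressWarnings(as.numeric(geno))),
                 arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("unknown allele code '%s' at row %d, locus '%s'",
                   geno[bad[1, 1], bad[1, 2]], bad[1, 1], locus_ids[bad[1, 2]]))
    storage.mode(geno) <- "double"
  }
  rownames(geno) <- df$individual
  pl <- rep(2L, length(locus_ids))
  if (is.null(haploid_loci)) {
    pl[startsWith(locus_ids, "mt")] <- 1L
  } else {
    pl[locus_ids %in% haploid_loci] <- 1L
  }
  g <- genotype_matrix(geno, ploidy = pl)
  s <- sample_table(df[, meta_cols], genotypes = g)
  list(genotypes = g, samples = s)
}

#' @rdname read_genotype_csv
#' @param genotypes a [genotype_matrix()].
#' @param samples a matching [sample_table()].
#' @return `write_genotype_csv()`: the path, invisibly.
#' @export
write_genotype_csv <- function(genotypes, samples, path) {
  samples <- sample_table(samples, genotypes = genotypes)
  df <- cbind(samples[, c("individual", "population", "cohort", "species",
                          "lat", "lon")],
              as.data.frame(unclass(genotypes)[, , drop = FALSE]))
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write genotypes in the two-rows-per-individual STRUCTURE format
#'
#' Emits the classic text layout consumed by the Structure program and its
#' ecosystem: two lines per individual (one allele per line per locus), the
#' M allele coded `1`, the P allele coded `2`, missing as `-9`, and the
#' population as an integer code. Heterozygotes put allele 1 on the first
#' line and allele 2 on the second. Haploid loci write the same allele on
#' both lines.
#'
#' @param genotypes a [genotype_matrix()].
#' @param samples a [sample_table()] covering every individual.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_structure_file <- function(genotypes, samples, path) {
  missing_ind <- setdiff(rownames(genotypes), samples$individual)
  if (length(missing_ind))
    stop("individuals absent from sample table: ",
         paste(utils::head(missing_ind, 3), collapse = ", "))
  samples <- sample_table(samples, genotypes = genotypes)
  pop_code <- as.integer(factor(samples$population,
                                levels = unique(samples$population)))
  pl <- ploidy(genotypes)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(genotypes))) {
    row1 <- row2 <- integer(ncol(genotypes))
    for (j in seq_len(ncol(genotypes))) {
      g <- genotypes[i, j]
      if (is.na(g)) {
        row1[j] <- row2[j] <- -9L
      } else if (pl[j] == 1L) {
        row1[j] <- row2[j] <- if (g == 1) 1L else 2L
      } else {
        alleles <- c(rep(1L, g), rep(2L, 2 - g))
        row1[j] <- alleles[1]; row2[j] <- alleles[2]
      }
    }
    id <- rownames(genotypes)[i]
    writeLines(c(paste(c(id, pop_code[i], row1), collapse = " "),
                 paste(c(id, pop_code[i], row2), collapse = " ")), con)
  }
  invisible(path)
}

#' ESRI ASCII raster grids
#'
#' Minimal reader/writer for the ESRI ASCII grid format used to carry the
#' climate surfaces of the distribution model (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value` header; values
#' row-major from the top row). In memory a grid is a `raster_grid`: a
#' numeric matrix (top row first, `NA` for nodata) with georeferencing
#' attributes.
#'
#' @param values numeric matrix, top raster row in row 1; `NA` = nodata.
#' @param xllcorner,yllcorner lower-left corner, decimal degrees.
#' @param cellsize cell edge, degrees.
#' @param nodata sentinel written to file for `NA` cells.
#' @return A `raster_grid` object.
#' @export
raster_grid <- function(values, xllcorner = 0, yllcorner = 0, cellsize = 1,
                        nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  structure(values, xllcorner = xllcorner, yllcorner = yllcorner,
            cellsize = cellsize, nodata = nodata,
            class = c("raster_grid", "matrix"))
}

#' @rdname raster_grid
#' @param path file path.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("malformed ESRI ASCII header: missing ",
         paste(setdiff(req, names(hdr)), collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop(sprintf("value count %d does not match declared %d x %d grid",
                 length(vals), hdr$nrows, hdr$ncols))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  raster_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
}

#' @rdname raster_grid
#' @param grid a `raster_grid`.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  nodata <- attr(grid, "nodata")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(grid)),
               paste("nrows", nrow(grid)),
               paste("xllcorner", format(attr(grid, "xllcorner"))),
               paste("yllcorner", format(attr(grid, "yllcorner"))),
               paste("cellsize", format(attr(grid, "cellsize"))),
               paste("NODATA_value", format(nodata))), con)
  m <- unclass(grid)
  m[is.na(m)] <- nodata
  for (r in seq_len(nrow(m)))
    writeLines(paste(format(m[r, ], trim = TRUE, digits = 15), collapse = " "),
               con)
  invisible(path)
}

#' Coordinates of raster cell centres
#'
#' @param grid a [raster_grid()].
#' @return list with `lon` (per column) and `lat` (per row, top row first).
#' @export
grid_coordinates <- function(grid) {
  cs <- attr(grid, "cellsize")
  lon <- attr(grid, "xllcorner") + (seq_len(ncol(grid)) - 0.5) * cs
  lat <- attr(grid, "yllcorner") + (nrow(grid) - seq_len(nrow(grid)) + 0.5) * cs
  list(lon = lon, lat = lat)
}
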