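#' Construct a genotype matrix of species-diagnostic allele dosages
#'
#' The central container of the pipeline: an individuals x loci matrix of
#' allele dosages, where the dosage at a locus is the count of the
#' *T. marmoratus*-diagnostic ("M") allele. Diploid nuclear loci take values
#' 0/1/2, the haploid mitochondrial locus 0/1; missing calls are `NA`.
#' Dosage 0 therefore means homozygous (or hemizygous) for the
#' *T. pygmaeus* ("P") allele, which makes admixture proportions and PCA
#' axes directly interpretable as "fraction of M ancestry".
#'
#' @param dosage numeric matrix, individuals in rows, loci in columns,
#'   with `NA` for missing calls. Dimnames, if present, seed the ids.
#' @param individual_ids,locus_ids character vectors of unique identifiers;
#'   default to the dimnames of `dosage`.
#' @param ploidy integer vector (1 or 2) per locus. Defaults to 2
#'   everywhere except loci whose name starts with `"mt"`.
#'
#' @return An object of class `genotype_matrix`: the validated dosage
#'   matrix with a `ploidy` attribute.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, NA), 2, 2,
#'   dimnames = list(c("i1", "i2"), c("locA", "locB"))))
#' ploidy(g)
#' @export
genotype_matrix <- function(dosage, individual_ids = rownames(dosage),
                            locus_ids = colnames(dosage), ploidy = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(individual_ids))
    individual_ids <- sprintf("ind%d", seq_len(nrow(dosage)))
  if (is.null(locus_ids))
    locus_ids <- sprintf("locus%d", seq_len(ncol(dosage)))
  individual_ids <- as.character(individual_ids)
  locus_ids <- as.character(locus_ids)
  if (length(individual_ids) != nrow(dosage))
    stop("individual_ids length does not match number of rows")
  if (length(locus_ids) != ncol(dosage))
    stop("locus_ids length does not match number of columns")
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  if (anyDuplicated(locus_ids))
    stop("duplicate locus ids: ",
         paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "))
  if (is.null(ploidy)) ploidy <- ifelse(startsWith(locus_ids, "mt"), 1L, 2L)
  ploidy <- as.integer(ploidy)
  if (length(ploidy) == 1L) ploidy <- rep(ploidy, length(locus_ids))
  if (length(ploidy) != length(locus_ids))
    stop("ploidy must have one entry per locus")
  if (!all(ploidy %in% c(1L, 2L))) stop("ploidy must be 1 or 2")
  dimnames(dosage) <- list(individual_ids, locus_ids)
  for (j in seq_along(locus_ids)) {
    v <- dosage[, j]
    bad <- which(!is.na(v) & (v < 0 | v > ploidy[j] | v != round(v)))
    if (length(bad))
      stop(sprintf("dosage out of range at individual '%s', locus '%s' (value %s, ploidy %d)",
                   individual_ids[bad[1]], locus_ids[j], format(v[bad[1]]), ploidy[j]))
  }
  structure(dosage, ploidy = ploidy, class = c("genotype_matrix", "matrix"))
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
ploidy <- function(x) attr(x, "ploidy")

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%d diploid, %d haploid); %.1f%% missing\n",
              nrow(x), ncol(x), sum(attr(x, "ploidy") == 2L),
              sum(attr(x, "ploidy") == 1L), 100 * mean(is.na(x))))
  invisible(x)
}

#' Subset a genotype matrix, keeping the per-locus ploidy in step
#' @param x a `genotype_matrix`.
#' @param i,j row (individual) and column (locus) indices.
#' @param ... ignored.
#' @param drop ignored; result is always a `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  pl <- attr(x, "ploidy")
  m <- unclass(x)
  attr(m, "ploidy") <- NULL
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  out <- m[i, j, drop = FALSE]
  names(pl) <- colnames(m)
  genotype_matrix(out, ploidy = pl[colnames(out)])
}

#' Construct and validate a per-individual sample table
#'
#' Metadata companion to [genotype_matrix()]: one row per individual with
#' population membership, WGS84 coordinates, sampling cohort
#' (`reference` panels of known pure species vs the `study` transect),
#' and the species label where known.
#'
#' @param df data frame with columns `individual`, `population`, `cohort`
#'   (`"reference"` or `"study"`), `species` (`"M"`, `"P"` or `"unknown"`),
#'   `lat`, `lon`.
#' @param genotypes optional `genotype_matrix`; if supplied, the table must
#'   cover exactly its individuals (order is aligned to the matrix).
#' @return A `sample_table` data frame.
#' @export
sample_table <- function(df, genotypes = NULL) {
  req <- c("individual", "population", "cohort", "species", "lat", "lon")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("sample table missing columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$individual <- as.character(df$individual)
  df$population <- as.character(df$population)
  if (anyDuplicated(df$individual))
    stop("duplicate individuals in sample table")
  if (!all(df$cohort %in% c("reference", "study")))
    stop("cohort must be 'reference' or 'study'")
  if (!all(df$species %in% c("M", "P", "unknown")))
    stop("species must be 'M', 'P' or 'unknown'")
  bad_ref <- df$cohort == "reference" & df$species == "unknown"
  if (any(bad_ref))
    stop("reference individuals must carry a species label: ",
         paste(utils::head(df$individual[bad_ref], 3), collapse = ", "))
  if (!is.null(genotypes)) {
    ids <- rownames(genotypes)
    if (!setequal(ids, df$individual))
      stop("sample table and genotype matrix cover different individuals")
    df <- df[match(ids, df$individual), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("sample_table", "data.frame")
  df
}
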