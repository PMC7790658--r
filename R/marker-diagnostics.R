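#' Cohen's kappa species-diagnosticity of one locus
#'
#' Scores how well allele identity at a locus predicts the species of
#' reference individuals. Every non-missing allele copy is one observation
#' (a heterozygote contributes one allele to each column; a haploid locus
#' contributes one allele per individual), the "prediction" is the allele
#' itself (M allele predicts species M), and kappa is the chance-corrected
#' agreement `(p_o - p_e) / (1 - p_e)` of the 2x2 allele-by-species table.
#' kappa = 1 means a fixed difference: perfectly diagnostic.
#'
#' @param genotypes a [genotype_matrix()].
#' @param samples a [sample_table()]; only `reference` individuals with a
#'   known species label enter the table.
#' @param locus locus id or column index.
#' @return kappa, with the 2x2 table as attribute `"table"`
#'   (rows = allele M/P, columns = true species M/P).
#' @export
allele_kappa <- function(genotypes, samples, locus) {
  samples <- sample_table(samples, genotypes = genotypes)
  j <- if (is.character(locus)) match(locus, colnames(genotypes)) else locus
  if (is.na(j)) stop("unknown locus: ", locus)
  ref <- samples$cohort == "reference" & samples$species %in% c("M", "P")
  g <- unclass(genotypes)[ref, j]
  pl <- ploidy(genotypes)[j]
  sp <- samples$species[ref]
  ok <- !is.na(g)
  # allele-copy counts: dosage g gives g M-alleles and (ploidy - g) P-alleles
  tab <- matrix(0, 2, 2, dimnames = list(allele = c("M", "P"),
                                         species = c("M", "P")))
  for (s in c("M", "P")) {
    sel <- ok & sp == s
    tab["M", s] <- sum(g[sel])
    tab["P", s] <- sum(pl - g[sel])
  }
  if (any(colSums(tab) == 0))
    stop("a species has no observed alleles at locus ", colnames(genotypes)[j])
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (abs(1 - p_e) < 1e-12) {
    # both margins degenerate: agreement is all-or-nothing
    if (tab["M", "P"] + tab["P", "M"] == 0) 1 else 0
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  structure(kappa, table = tab)
}

#' Per-locus marker diagnosticity report
#'
#' @param genotypes a [genotype_matrix()].
#' @param samples a [sample_table()] with reference individuals.
#' @return A `marker_report` data frame: `locus`, `ploidy`, `kappa`,
#'   per-species M-allele frequencies in the reference panels,
#'   `missing_frac`, `informative` (polymorphic between species) and space
#'   for the `diagnostic` flag filled by [diagnosticity_screen()].
#' @export
marker_report <- function(genotypes, samples) {
  samples <- sample_table(samples, genotypes = genotypes)
  loci <- colnames(genotypes)
  kap <- freqM <- freqP <- numeric(length(loci))
  for (j in seq_along(loci)) {
    k <- allele_kappa(genotypes, samples, j)
    tab <- attr(k, "table")
    kap[j] <- as.numeric(k)
    freqM[j] <- tab["M", "M"] / sum(tab[, "M"])
    freqP[j] <- tab["M", "P"] / sum(tab[, "P"])
  }
  out <- data.frame(locus = loci, ploidy = ploidy(genotypes), kappa = kap,
                    freq_m_in_M = freqM, freq_m_in_P = freqP,
                    missing_frac = colMeans(is.na(unclass(genotypes))),
                    informative = abs(freqM - freqP) > 0,
                    diagnostic = NA, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("marker_report", "data.frame")
  out
}

#' Partition a marker panel by diagnosticity
#'
#' A locus is *diagnostic* when kappa >= `kappa_threshold` (inclusive),
#' *informative-only* when its between-species allele-frequency difference
#' is non-zero but kappa falls below the screen, and *uninformative*
#' otherwise. The screen is monotone: raising the threshold never adds
#' markers.
#'
#' @param reports a [marker_report()].
#' @param kappa_threshold screen threshold (default 0.9).
#' @return The report with the `diagnostic` flag filled and a `class`
#'   column in `{"diagnostic", "informative", "uninformative"}`.
#' @export
diagnosticity_screen <- function(reports, kappa_threshold = 0.9) {
  reports$diagnostic <- reports$kappa >= kappa_threshold
  reports$class <- ifelse(reports$diagnostic, "diagnostic",
                          ifelse(reports$informative, "informative",
                                 "uninformative"))
  reports
}

#' Missing-call fractions
#'
#' @param genotypes a [genotype_matrix()].
#' @return list with `overall` (fraction of missing calls over all
#'   individuals x loci) and `per_locus` (named vector).
#' @export
missingness <- function(genotypes) {
  if (length(genotypes) == 0) stop("empty genotype matrix")
  m <- is.na(unclass(genotypes))
  list(overall = mean(m), per_locus = colMeans(m))
}
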