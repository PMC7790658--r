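#' Exact Hardy-Weinberg test for a biallelic locus
#'
#' Full-enumeration conditional exact test: given the observed allele
#' counts, every compatible heterozygote count is enumerated, with
#' conditional probability proportional to
#' `n! / (n_MM! n_MP! n_PP!) * 2^n_MP`, and the two-sided p-value is the
#' summed probability of all configurations no more probable than the
#' observed one. Biallelic loci are exactly enumerable, so no Monte Carlo
#' chain is involved.
#'
#' @param n_MM,n_MP,n_PP observed genotype counts (MM homozygote,
#'   heterozygote, PP homozygote).
#' @return p-value in (0, 1], with attribute `"direction"` equal to
#'   `"deficit"`, `"excess"` or `"none"` (observed vs Hardy-Weinberg
#'   expected heterozygosity).
#' @export
hwe_exact <- function(n_MM, n_MP, n_PP) {
  if (any(c(n_MM, n_MP, n_PP) < 0)) stop("negative genotype counts")
  n <- n_MM + n_MP + n_PP
  if (n < 1) stop("need at least one individual")
  n1 <- 2 * n_MM + n_MP  # M alleles
  n2 <- 2 * n_PP + n_MP  # P alleles
  hets <- seq(n1 %% 2, min(n1, n2), by = 2)
  logw <- hets * log(2) - lfactorial((n1 - hets) / 2) - lfactorial(hets) -
    lfactorial((n2 - hets) / 2)
  prob <- exp(logw - max(logw))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_MP, hets)]
  p <- sum(prob[prob <= p_obs * (1 + 1e-9)])
  exp_het <- 2 * (n1 / (2 * n)) * (n2 / (2 * n)) * n
  direction <- if (n_MP < exp_het - 1e-12) "deficit"
               else if (n_MP > exp_het + 1e-12) "excess" else "none"
  structure(min(p, 1), direction = direction)
}

#' Hardy-Weinberg scan over populations and diploid loci
#'
#' Runs [hwe_exact()] for every population x diploid-locus combination
#' with at least one genotyped individual, and flags rejections under the
#' Benjamini-Hochberg correction, both within each population's test
#' family and pooled over all populations.
#'
#' @param genotypes a [genotype_matrix()].
#' @param samples a [sample_table()].
#' @param alpha FDR level.
#' @return data frame of `population`, `locus`, genotype counts, `p`,
#'   `direction`, `p_bh_within`, `reject_within`, `p_bh_pooled`,
#'   `reject_pooled`.
#' @export
hwe_scan <- function(genotypes, samples, alpha = 0.05) {
  samples <- sample_table(samples, genotypes = genotypes)
  dip <- which(ploidy(genotypes) == 2L)
  rows <- list()
  for (pop in unique(samples$population)) {
    sel <- samples$population == pop
    for (j in dip) {
      g <- unclass(genotypes)[sel, j]
      g <- g[!is.na(g)]
      if (!length(g)) next
      cnt <- c(sum(g == 2), sum(g == 1), sum(g == 0))
      p <- hwe_exact(cnt[1], cnt[2], cnt[3])
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop, locus = colnames(genotypes)[j],
        n_MM = cnt[1], n_MP = cnt[2], n_PP = cnt[3],
        p = as.numeric(p), direction = attr(p, "direction"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  within <- lapply(split(seq_len(nrow(out)), out$population), function(idx) {
    adj <- bh_adjust(out$p[idx], alpha)
    data.frame(idx = idx, p_bh_within = adj$p_adjusted,
               reject_within = adj$reject)
  })
  within <- do.call(rbind, within)
  out$p_bh_within[within$idx] <- within$p_bh_within
  out$reject_within[within$idx] <- within$reject_within
  pooled <- bh_adjust(out$p, alpha)
  out$p_bh_pooled <- pooled$p_adjusted
  out$reject_pooled <- pooled$reject
  out
}

#' Permutation G-test of genotypic linkage disequilibrium
#'
#' Tests association between the genotypes of two diploid loci within one
#' population: `G = 2 * sum(O * ln(O / E))` over the non-empty cells of
#' the genotype contingency table, with a Monte Carlo null obtained by
#' permuting one locus's genotypes across individuals. Individuals missing
#' either locus are dropped. A locus monomorphic in the population yields
#' `p = 1` by convention.
#'
#' @param g_i,g_j dosage vectors of the two loci over the same individuals.
#' @param B number of permutations.
#' @param seed RNG seed.
#' @return list with `G`, `p` (`(1 + #\{G* >= G\}) / (B + 1)`), `n`
#'   (individuals used) and `B`.
#' @export
genotypic_ld_test <- function(g_i, g_j, B = 999L, seed = 1L) {
  ok <- !is.na(g_i) & !is.na(g_j)
  g_i <- g_i[ok]; g_j <- g_j[ok]
  if (length(g_i) < 2) stop("need >= 2 individuals with both loci scored")
  if (length(unique(g_i)) < 2 || length(unique(g_j)) < 2) {
    ht_log("monomorphic locus in LD test; p = 1 by convention")
    return(list(G = 0, p = 1, n = length(g_i), B = as.integer(B)))
  }
  g_stat <- function(x, y) {
    tab <- table(x, y)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    keep <- tab > 0
    2 * sum(tab[keep] * log(tab[keep] / E[keep]))
  }
  G <- g_stat(g_i, g_j)
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(B))
      if (g_stat(g_i, sample(g_j)) >= G - 1e-12) exceed <- exceed + 1L
    list(G = G, p = (1 + exceed) / (B + 1), n = length(g_i),
         B = as.integer(B))
  })
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment of a family of p-values with rejection flags at
#' level `alpha`.
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return list with `p_adjusted` and logical `reject`.
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) stop("empty p-value list")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Admixture linkage disequilibrium of a population
#'
#' Barton-Gale-style admixture LD: dosages at diploid diagnostic loci are
#' scaled to `x = dosage / 2` in `{0, 0.5, 1}`, the pairwise disequilibrium
#' `D_ij` is the sample covariance of `(x_i, x_j)` over individuals with
#' both loci scored (pairwise deletion), and `D-bar` is the mean over all
#' locus pairs. Mixing of differentiated gene pools makes `D-bar` positive;
#' a panmictic population gives `D-bar ~ 0`. The 95% confidence interval is
#' a percentile bootstrap over individuals.
#'
#' @param genotypes a [genotype_matrix()] restricted to one population
#'   (diploid loci are selected automatically by ploidy).
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return list with `D_bar`, `ci` (length 2), `n_boot`, `significant`
#'   (CI excludes 0), and the pairwise matrix `D`.
#' @export
admixture_ld <- function(genotypes, n_boot = 1000L, seed = 1L) {
  dip <- ploidy(genotypes) == 2L
  x <- unclass(genotypes)[, dip, drop = FALSE] / 2
  if (nrow(x) < 2) stop("need >= 2 individuals")
  if (ncol(x) < 2) stop("need >= 2 diploid loci")
  dbar <- function(m) {
    D <- stats::cov(m, use = "pairwise.complete.obs")
    mean(D[upper.tri(D)], na.rm = TRUE)
  }
  D <- stats::cov(x, use = "pairwise.complete.obs")
  obs <- mean(D[upper.tri(D)], na.rm = TRUE)
  with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(b)
      dbar(x[sample(nrow(x), replace = TRUE), , drop = FALSE]), numeric(1))
    ci <- unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE))
    list(D_bar = obs, ci = ci, n_boot = as.integer(n_boot),
         significant = ci[1] > 0 || ci[2] < 0, D = D)
  })
}
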