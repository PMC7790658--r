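#' Fit the admixture model by maximum-likelihood EM
#'
#' The admixture (STRUCTURE-type) model: individual `i` has cluster
#' proportions `q_i` (summing to 1 over `K` clusters) and cluster `k` has
#' allele frequency `p_kl` at locus `l`; the dosage at a locus of ploidy
#' `c` is `Binomial(c, sum_k q_ik * p_kl)`. The fit alternates closed-form
#' EM updates of Q and P from expected allele-assignment counts, which
#' makes the log-likelihood non-decreasing at every iteration. Haploid
#' mtDNA loci enter with ploidy 1; missing genotypes are skipped in the
#' likelihood. Initialisation is random (Dirichlet rows for Q, uniform P)
#' from `seed`, so replicate restarts explore the likelihood surface.
#'
#' @param genotypes a [genotype_matrix()].
#' @param K number of ancestral clusters.
#' @param seed RNG seed for initialisation.
#' @param max_iter iteration cap.
#' @param tol stop when the log-likelihood gain drops below this.
#' @return An `admixture_fit` list: `K`, `Q` (individuals x K), `P`
#'   (K x loci), `logL`, `trace` (logL per iteration), `n_iter`,
#'   `converged`, `seed`.
#' @export
fit_admixture <- function(genotypes, K, seed = 1L, max_iter = 500L,
                          tol = 1e-6) {
  g <- unclass(genotypes)
  n <- nrow(g); L <- ncol(g)
  if (n == 0 || L == 0) stop("empty genotype matrix")
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of individuals")
  pl <- ploidy(genotypes)
  W <- !is.na(g)                       # observed mask
  gm <- ifelse(W, g, 0)
  C <- sweep(matrix(as.numeric(W), n, L), 2, pl, `*`)  # ploidy where observed
  const <- sum(lchoose(C[W], gm[W]))
  loglik <- function(theta) {
    th <- pmin(pmax(theta, 1e-12), 1 - 1e-12)
    const + sum((gm * log(th) + (C - gm) * log(1 - th))[W])
  }
  if (K == 1L) {
    p <- colSums(gm) / colSums(C)
    theta <- matrix(p, n, L, byrow = TRUE)
    ll <- loglik(theta)
    return(structure(list(K = 1L, Q = matrix(1, n, 1,
                            dimnames = list(rownames(g), NULL)),
                          P = matrix(p, 1, L, dimnames = list(NULL, colnames(g))),
                          logL = ll, trace = ll, n_iter = 0L,
                          converged = TRUE, seed = as.integer(seed)),
                     class = "admixture_fit"))
  }
  with_seed(seed, {
    Q <- matrix(stats::rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)
    P <- matrix(stats::runif(K * L, 0.1, 0.9), K, L)
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      theta <- Q %*% P
      theta <- pmin(pmax(theta, 1e-12), 1 - 1e-12)
      A_sum_i <- matrix(0, K, L)   # expected M alleles per (k, l)
      AB_sum_i <- matrix(0, K, L)  # expected total alleles per (k, l)
      QN <- matrix(0, n, K)        # expected alleles per (i, k)
      for (k in seq_len(K)) {
        Ak <- gm * (Q[, k] %o% P[k, ]) / theta
        Bk <- (C - gm) * (Q[, k] %o% (1 - P[k, ])) / (1 - theta)
        A_sum_i[k, ] <- colSums(Ak)
        AB_sum_i[k, ] <- colSums(Ak + Bk)
        QN[, k] <- rowSums(Ak + Bk)
      }
      Q <- QN / rowSums(QN)
      P <- A_sum_i / pmax(AB_sum_i, 1e-12)
      P <- pmin(pmax(P, 1e-9), 1 - 1e-9)
      ll <- loglik(Q %*% P)
      trace <- c(trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    structure(list(K = as.integer(K),
                   Q = `dimnames<-`(Q, list(rownames(g), NULL)),
                   P = `dimnames<-`(P, list(NULL, colnames(g))),
                   logL = trace[length(trace)], trace = trace,
                   n_iter = length(trace), converged = converged,
                   seed = as.integer(seed)),
              class = "admixture_fit")
  })
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K = %d, %d individuals, %d loci, logL = %.3f (%s after %d iterations)\n",
              x$K, nrow(x$Q), ncol(x$P), x$logL,
              if (x$converged) "converged" else "iteration cap hit", x$n_iter))
  invisible(x)
}

#' Replicate random restarts of the admixture EM
#'
#' @param genotypes a [genotype_matrix()].
#' @param K number of clusters.
#' @param n_restarts independent restarts; the best-likelihood fit is kept.
#' @param seed base seed; restart r uses `seed + r`.
#' @param ... passed to [fit_admixture()].
#' @return list with `best` (an `admixture_fit`) and `logLs` (one per
#'   restart, the replicate likelihoods used by [evanno_delta_k()]).
#' @export
fit_admixture_restarts <- function(genotypes, K, n_restarts = 10L, seed = 1L,
                                   ...) {
  fits <- lapply(seq_len(n_restarts), function(r)
    fit_admixture(genotypes, K, seed = seed + r, ...))
  logLs <- vapply(fits, `[[`, numeric(1), "logL")
  list(best = fits[[which.max(logLs)]], logLs = logLs)
}

#' Fit the admixture model over a range of K
#'
#' @param genotypes a [genotype_matrix()].
#' @param K_range integer vector of K values (e.g. `1:5`).
#' @param n_restarts restarts per K.
#' @param seed base seed.
#' @param ... passed to [fit_admixture()].
#' @return list with `fits` (best fit per K), `logL_matrix`
#'   (restarts x K, columns named by K) and `K_range`.
#' @export
admixture_scan <- function(genotypes, K_range = 1:5, n_restarts = 10L,
                           seed = 1L, ...) {
  res <- lapply(seq_along(K_range), function(i)
    fit_admixture_restarts(genotypes, K_range[i], n_restarts,
                           seed = seed + 1000L * i, ...))
  logL_matrix <- vapply(res, `[[`, numeric(n_restarts), "logLs")
  colnames(logL_matrix) <- K_range
  list(fits = lapply(res, `[[`, "best"), logL_matrix = logL_matrix,
       K_range = K_range)
}

#' Evanno delta-K model selection
#'
#' From replicate log-likelihoods per K, computes the second difference of
#' the replicate means, `L''(K) = L(K+1) - 2 L(K) + L(K-1)`, and
#' `delta K = |L''(K)| / sd(L(K))`. Delta K is defined only for interior
#' K values; the K maximising it is the supported number of clusters
#' (K = 1 cannot be evaluated by this statistic and is compared by
#' likelihood separately).
#'
#' @param logL_matrix replicates x K matrix of log-likelihoods, columns
#'   named by (consecutive) K values.
#' @return list with `table` (K, mean_logL, sd_logL, Lpp, delta_K for
#'   interior K) and `best_K`.
#' @export
evanno_delta_k <- function(logL_matrix) {
  logL_matrix <- as.matrix(logL_matrix)
  Ks <- as.integer(colnames(logL_matrix))
  if (length(Ks) < 3) stop("need >= 3 consecutive K values")
  if (nrow(logL_matrix) < 2) stop("need >= 2 replicates per K")
  if (any(diff(Ks) != 1L)) stop("K values must be consecutive")
  mu <- colMeans(logL_matrix)
  sdv <- apply(logL_matrix, 2, stats::sd)
  interior <- 2:(length(Ks) - 1)
  if (any(sdv[interior] == 0))
    stop("sd(L(K)) is zero for an interior K: replicates are degenerate; ",
         "use more restarts or a looser convergence tolerance")
  Lpp <- mu[interior + 1] - 2 * mu[interior] + mu[interior - 1]
  dK <- abs(Lpp) / sdv[interior]
  tab <- data.frame(K = Ks[interior], mean_logL = mu[interior],
                    sd_logL = sdv[interior], Lpp = Lpp, delta_K = dK,
                    row.names = NULL)
  list(table = tab, best_K = tab$K[which.max(tab$delta_K)])
}

#' Classify individuals from their admixture proportion
#'
#' Applies the purity thresholds to the M-cluster admixture proportion:
#' `q > 0.95` is pure M, `q < 0.05` pure P, anything else (including the
#' boundary values exactly) genetically admixed.
#'
#' @param q_m numeric vector of admixture proportions in `[0, 1]`.
#' @param lower,upper purity thresholds (strict inequalities).
#' @return character vector in `{"pure_M", "pure_P", "admixed"}`.
#' @export
classify_q <- function(q_m, lower = 0.05, upper = 0.95) {
  if (any(is.na(q_m)) || any(q_m < 0 | q_m > 1))
    stop("admixture proportions must lie in [0, 1]")
  ifelse(q_m > upper, "pure_M", ifelse(q_m < lower, "pure_P", "admixed"))
}

#' Extract the M-cluster admixture proportion from a fit
#'
#' Cluster labels are arbitrary under the admixture likelihood; the
#' M-like cluster is identified as the one whose allele-frequency vector
#' is largest on average (dosages count the M allele).
#'
#' @param fit an `admixture_fit`.
#' @return named vector `q_m`, one entry per individual.
#' @export
q_m <- function(fit) {
  k <- which.max(rowMeans(fit$P))
  stats::setNames(fit$Q[, k], rownames(fit$Q))
}

#' Population means of the admixture proportion
#'
#' @param q_m named per-individual admixture proportions.
#' @param samples a [sample_table()].
#' @return data frame of `population`, `n`, `mean_q_m`.
#' @export
population_q <- function(q_m, samples) {
  stopifnot(all(names(q_m) %in% samples$individual))
  pop <- samples$population[match(names(q_m), samples$individual)]
  agg <- stats::aggregate(q_m, list(population = pop),
                          function(v) c(n = length(v), mean = mean(v)))
  data.frame(population = agg$population, n = agg$x[, "n"],
             mean_q_m = agg$x[, "mean"], stringsAsFactors = FALSE)
}
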