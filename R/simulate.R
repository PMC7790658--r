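# run code under a temporary RNG state so simulators are pure in `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic diagnostic-SNP panel
#'
#' Describes the marker panel the generator emulates: by default 60 nuclear
#' SNPs of which 54 carry a fixed allele-frequency difference between the
#' two parental species (the diagnostic regime), plus one haploid
#' mitochondrial marker, with 2.3% of genotype calls missing at random.
#' The remaining off-target nuclear loci get a small parental differential
#' (`delta_offtarget`) so they are polymorphic and species-informative but
#' fall well below the kappa >= 0.9 diagnosticity screen.
#'
#' @param n_loci_nuclear number of nuclear SNP loci.
#' @param n_diagnostic how many of them are simulated in the diagnostic
#'   regime (parental differential `delta`).
#' @param delta parental allele-frequency differential of diagnostic loci,
#'   in `[0, 1]`; 1 is a fixed difference.
#' @param delta_offtarget differential of the non-diagnostic loci.
#' @param include_mtdna add one haploid mtDNA locus (`mtND4`), fixed
#'   between species.
#' @param missing_rate i.i.d. missing-call probability.
#' @param seed RNG seed for everything drawn from this spec.
#' @return A `sim_panel_spec` list with per-locus allele frequencies
#'   `freq_M`, `freq_P` (frequency of the M allele in each species),
#'   locus ids, ploidy, and a logical `diagnostic_truth` vector.
#' @export
sim_panel_spec <- function(n_loci_nuclear = 60L, n_diagnostic = 54L,
                           delta = 1, delta_offtarget = 0.2,
                           include_mtdna = TRUE, missing_rate = 0.023,
                           seed = 1L) {
  stopifnot(n_diagnostic <= n_loci_nuclear, n_diagnostic >= 0,
            delta >= 0, delta <= 1,
            delta_offtarget >= 0, delta_offtarget <= 1,
            missing_rate >= 0, missing_rate <= 1)
  n_loci_nuclear <- as.integer(n_loci_nuclear)
  n_diagnostic <- as.integer(n_diagnostic)
  locus_ids <- sprintf("snp%02d", seq_len(n_loci_nuclear))
  diag_truth <- seq_len(n_loci_nuclear) <= n_diagnostic
  d <- ifelse(diag_truth, delta, delta_offtarget)
  freq_M <- 0.5 + d / 2
  freq_P <- 0.5 - d / 2
  pl <- rep(2L, n_loci_nuclear)
  if (include_mtdna) {
    locus_ids <- c(locus_ids, "mtND4")
    freq_M <- c(freq_M, 1)
    freq_P <- c(freq_P, 0)
    diag_truth <- c(diag_truth, TRUE)
    pl <- c(pl, 1L)
  }
  structure(list(n_loci_nuclear = n_loci_nuclear, n_diagnostic = n_diagnostic,
                 delta = delta, delta_offtarget = delta_offtarget,
                 include_mtdna = include_mtdna, missing_rate = missing_rate,
                 seed = as.integer(seed), locus_ids = locus_ids,
                 freq_M = freq_M, freq_P = freq_P, ploidy = pl,
                 diagnostic_truth = diag_truth),
            class = "sim_panel_spec")
}

# dosages for individuals with per-allele M probability `prob` (vector over
# individuals) at loci with parental frequencies from `spec`
draw_dosages <- function(spec, prob_m) {
  n <- length(prob_m)
  L <- length(spec$locus_ids)
  # allele-level M probability at locus l: q * f_M + (1 - q) * f_P
  p <- outer(prob_m, spec$freq_M) + outer(1 - prob_m, spec$freq_P)
  d <- matrix(stats::rbinom(n * L, size = rep(spec$ploidy, each = n),
                            prob = p), n, L)
  colnames(d) <- spec$locus_ids
  d
}

mask_missing <- function(m, rate) {
  if (rate > 0) m[stats::runif(length(m)) < rate] <- NA
  m
}

#' Simulate the two pure-species reference panels
#'
#' Draws genotypes for pure individuals of each species binomially from the
#' species-specific allele frequencies in the panel spec, then masks calls
#' missing at random. Default sample sizes mirror a typical validation
#' design of 118 M and 120 P reference individuals.
#'
#' @param spec a [sim_panel_spec()].
#' @param n_per_species named vector `c(M = ..., P = ...)`.
#' @return list of `genotypes` ([genotype_matrix()]) and `samples`
#'   ([sample_table()], cohort `"reference"`).
#' @export
simulate_reference_panels <- function(spec,
                                      n_per_species = c(M = 118L, P = 120L)) {
  stopifnot(inherits(spec, "sim_panel_spec"),
            all(c("M", "P") %in% names(n_per_species)))
  with_seed(spec$seed, {
    nM <- as.integer(n_per_species[["M"]])
    nP <- as.integer(n_per_species[["P"]])
    d <- draw_dosages(spec, c(rep(1, nM), rep(0, nP)))
    d <- mask_missing(d, spec$missing_rate)
    ids <- c(sprintf("refM_%03d", seq_len(nM)), sprintf("refP_%03d", seq_len(nP)))
    rownames(d) <- ids
    g <- genotype_matrix(d, ploidy = spec$ploidy)
    s <- sample_table(data.frame(
      individual = ids,
      population = rep(c("ref_M", "ref_P"), c(nM, nP)),
      cohort = "reference",
      species = rep(c("M", "P"), c(nM, nP)),
      lat = rep(c(41.2, 37.3), c(nM, nP)),
      lon = rep(c(-8.5, -8.5), c(nM, nP)),
      stringsAsFactors = FALSE), genotypes = g)
    list(genotypes = g, samples = s)
  })
}

#' Specification of a synthetic sampled landscape
#'
#' Describes the geography the admixed-landscape generator emulates: a set
#' of breeding ponds with coordinates and sample sizes, a mean admixture
#' proportion per pond (an isolated enclave of mostly-M ancestry inside a
#' pure-P landscape), an optional exponentially decaying introgression tail
#' `q(d) = q0 * exp(-d / lambda)` with distance `d` (km) from a reference
#' point, and optional within-pond full-sib family sampling.
#'
#' @param populations data frame with columns `population`, `lat`, `lon`,
#'   `n` (individuals), `qbar` (mean admixture proportion; `NA` means "use
#'   the footprint tail"), and optionally `n_families`, `family_size`
#'   (0 / absent = no family structure).
#' @param q0,lambda footprint tail amplitude and decay length (km);
#'   `q0 = 0` disables the tail.
#' @param origin `c(lat, lon)` of the tail's reference point (the enclave).
#' @param q_concentration Beta concentration of individual q around the
#'   pond mean (larger = tighter); pond means of exactly 0 or 1 are exact.
#' @param seed RNG seed.
#' @return A `sim_landscape_spec` list.
#' @export
sim_landscape_spec <- function(populations, q0 = 0, lambda = 10,
                               origin = NULL, q_concentration = 100,
                               seed = 1L) {
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  req <- c("population", "lat", "lon", "n", "qbar")
  if (!all(req %in% names(populations)))
    stop("populations needs columns: ", paste(req, collapse = ", "))
  if (is.null(populations$n_families)) populations$n_families <- 0L
  if (is.null(populations$family_size)) populations$family_size <- 0L
  stopifnot(all(populations$n >= 1),
            all(is.na(populations$qbar) |
                (populations$qbar >= 0 & populations$qbar <= 1)),
            q0 >= 0, q0 <= 1, lambda > 0, q_concentration > 0)
  bad <- populations$n_families * populations$family_size > populations$n
  if (any(bad))
    stop("family structure exceeds population size in: ",
         paste(populations$population[bad], collapse = ", "))
  if (is.null(origin))
    origin <- c(populations$lat[1], populations$lon[1])
  structure(list(populations = populations, q0 = q0, lambda = lambda,
                 origin = origin, q_concentration = q_concentration,
                 seed = as.integer(seed)),
            class = "sim_landscape_spec")
}

# great-circle-free planar km distance; adequate at landscape scale
km_dist <- function(lat1, lon1, lat2, lon2) {
  sqrt(((lat1 - lat2) * 111.32)^2 +
       ((lon1 - lon2) * 111.32 * cos(lat1 * pi / 180))^2)
}

draw_individual_q <- function(qbar, n, conc) {
  if (qbar <= 0 || qbar >= 1) return(rep(qbar, n))
  stats::rbeta(n, qbar * conc, (1 - qbar) * conc)
}

# child dosage by Mendelian segregation: one allele drawn from each parent;
# haploid (mtDNA) loci inherit the maternal copy only
segregate <- function(mom, dad, pl) {
  a1 <- stats::rbinom(length(mom), 1, mom / pl)
  a2 <- stats::rbinom(length(dad), 1, dad / pl)
  ifelse(pl == 1L, a1, a1 + a2)
}

#' Simulate an admixed landscape of breeding ponds
#'
#' Each individual receives an admixture proportion q drawn around its
#' pond's mean (or from the footprint tail for ponds with `qbar = NA`), and
#' each allele copy is independently of M origin with probability q — the
#' same likelihood the admixture-model EM assumes, so parameter recovery is
#' a clean test. Ponds with family structure instead draw two parents per
#' family and produce full sibs by Mendelian segregation, which induces the
#' heterozygote deficit and admixture linkage disequilibrium expected when
#' larvae are sampled from within families.
#'
#' @param panel a [sim_panel_spec()].
#' @param land a [sim_landscape_spec()].
#' @return list of `genotypes`, `samples` (cohort `"study"`, species
#'   `"unknown"`), and `truth`: a data frame of each individual's planted
#'   admixture proportion `q`.
#' @export
simulate_admixed_landscape <- function(panel, land) {
  stopifnot(inherits(panel, "sim_panel_spec"),
            inherits(land, "sim_landscape_spec"))
  with_seed(land$seed, {
    pops <- land$populations
    all_d <- list(); all_meta <- list(); all_q <- list()
    for (p in seq_len(nrow(pops))) {
      n <- pops$n[p]
      qbar <- pops$qbar[p]
      if (is.na(qbar)) {
        d_km <- km_dist(pops$lat[p], pops$lon[p], land$origin[1], land$origin[2])
        qbar <- land$q0 * exp(-d_km / land$lambda)
      }
      nf <- pops$n_families[p]; fs <- pops$family_size[p]
      n_fam_ind <- nf * fs
      q_ind <- numeric(0); d <- NULL
      if (n_fam_ind > 0) {
        fam_rows <- list()
        for (f in seq_len(nf)) {
          q_par <- draw_individual_q(qbar, 2, land$q_concentration)
          par_d <- draw_dosages(panel, q_par)
          kids <- t(matrix(vapply(seq_len(fs), function(k)
            segregate(par_d[1, ], par_d[2, ], panel$ploidy),
            numeric(ncol(par_d))), nrow = ncol(par_d)))
          colnames(kids) <- colnames(par_d)
          fam_rows[[f]] <- kids
          q_ind <- c(q_ind, rep(mean(q_par), fs))
        }
        d <- do.call(rbind, fam_rows)
      }
      n_free <- n - n_fam_ind
      if (n_free > 0) {
        q_free <- draw_individual_q(qbar, n_free, land$q_concentration)
        d <- rbind(d, draw_dosages(panel, q_free))
        q_ind <- c(q_ind, q_free)
      }
      ids <- sprintf("%s_%03d", pops$population[p], seq_len(n))
      rownames(d) <- ids
      all_d[[p]] <- d
      all_meta[[p]] <- data.frame(
        individual = ids, population = pops$population[p], cohort = "study",
        species = "unknown", lat = pops$lat[p], lon = pops$lon[p],
        stringsAsFactors = FALSE)
      all_q[[p]] <- data.frame(individual = ids, q = q_ind,
                               stringsAsFactors = FALSE)
    }
    d <- mask_missing(do.call(rbind, all_d), panel$missing_rate)
    g <- genotype_matrix(d, ploidy = panel$ploidy)
    s <- sample_table(do.call(rbind, all_meta), genotypes = g)
    list(genotypes = g, samples = s, truth = do.call(rbind, all_q))
  })
}

#' Specification of a synthetic environmental presence table
#'
#' The two-species climate model's inputs: localities with one driver
#' climate variable drawn uniformly on a range, a presence label that is
#' `"M"` with the logistic probability
#' `p = 1 / (1 + exp(beta1 * driver + beta0))` (coefficients written in the
#' exponent convention, so `beta1 = -0.156`, `beta0 = 7.767` gives a
#' probability of species M that rises with the driver), and nuisance
#' climate variables calibrated to target Spearman correlations with the
#' driver.
#'
#' @param n_localities number of localities.
#' @param driver_range range of the driver variable (mm for a precipitation
#'   driver).
#' @param beta1,beta0 logistic coefficients in the exponent convention.
#' @param driver_name column name of the driver.
#' @param nuisance named numeric vector of target Spearman correlations,
#'   one per nuisance variable (names become columns).
#' @param seed RNG seed.
#' @return A `sim_env_spec` list.
#' @export
sim_env_spec <- function(n_localities = 108L, driver_range = c(0, 100),
                         beta1 = -0.156, beta0 = 7.767,
                         driver_name = "bio17",
                         nuisance = c(bio12 = 0.6, bio01 = -0.5, bio02 = 0.2),
                         seed = 1L) {
  stopifnot(n_localities >= 2, length(driver_range) == 2,
            driver_range[1] < driver_range[2])
  if (length(nuisance) && any(abs(nuisance) > 1))
    stop("unattainable Spearman correlation target (|r_s| > 1)")
  structure(list(n_localities = as.integer(n_localities),
                 driver_range = driver_range, beta1 = beta1, beta0 = beta0,
                 driver_name = driver_name, nuisance = nuisance,
                 seed = as.integer(seed)),
            class = "sim_env_spec")
}

# mix normal scores of the driver with noise; bisect the mixing weight until
# the measured Spearman correlation is within tol of the target
calibrate_nuisance <- function(driver, target, tol = 0.02) {
  n <- length(driver)
  zd <- stats::qnorm(rank(driver, ties.method = "average") / (n + 1))
  if (abs(target) >= 1 - 1e-12)
    return(sign(target) * (driver - min(driver) + 1)^1.3)  # pure monotone map
  noise <- stats::rnorm(n)
  s <- sign(target); ta <- abs(target)
  lo <- 0; hi <- 1
  for (iter in 1:50) {
    a <- (lo + hi) / 2
    v <- a * zd + sqrt(1 - a^2) * noise
    r <- stats::cor(driver, v, method = "spearman")
    if (abs(r - ta) <= tol) return(s * v)
    if (r < ta) lo <- a else hi <- a
  }
  stop(sprintf("could not calibrate nuisance variable to r_s = %.2f", target))
}

#' Simulate presence/absence localities from a logistic climate model
#'
#' @param spec a [sim_env_spec()].
#' @return An `EnvTable` data frame: `locality`, `lat`, `lon`, the driver
#'   column, nuisance columns, `species` (`"M"`/`"P"`), and the generating
#'   probability `p_m`.
#' @export
simulate_env_presence <- function(spec) {
  stopifnot(inherits(spec, "sim_env_spec"))
  with_seed(spec$seed, {
    n <- spec$n_localities
    x <- stats::runif(n, spec$driver_range[1], spec$driver_range[2])
    p <- 1 / (1 + exp(spec$beta1 * x + spec$beta0))
    species <- ifelse(stats::runif(n) < p, "M", "P")
    out <- data.frame(locality = sprintf("loc%04d", seq_len(n)),
                      lat = stats::runif(n, 37, 42),
                      lon = stats::runif(n, -9.5, -6),
                      stringsAsFactors = FALSE)
    out[[spec$driver_name]] <- x
    for (nm in names(spec$nuisance))
      out[[nm]] <- calibrate_nuisance(x, spec$nuisance[[nm]])
    out$species <- species
    out$p_m <- p
    out
  })
}

#' Simulate a smooth climate raster for hindcast testing
#'
#' A deterministic-in-seed surface built from a linear trend plus a few
#' random low-frequency sinusoids, clipped to `value_range`.
#'
#' @param nrows,ncols grid dimensions.
#' @param value_range range the values are scaled into.
#' @param nodata_frac fraction of cells masked as nodata.
#' @param seed RNG seed.
#' @param ... passed to [raster_grid()] (georeferencing).
#' @return A [raster_grid()].
#' @export
simulate_climate_raster <- function(nrows = 20, ncols = 20,
                                    value_range = c(0, 100),
                                    nodata_frac = 0, seed = 1L, ...) {
  with_seed(seed, {
    r <- outer(seq_len(nrows) / nrows, seq_len(ncols) / ncols,
               function(a, b) a + 0.5 * b)
    for (k in 1:3) {
      ph <- stats::runif(2, 0, 2 * pi); fr <- stats::runif(2, 1, 3)
      r <- r + 0.3 * outer(sin(fr[1] * pi * seq_len(nrows) / nrows + ph[1]),
                           cos(fr[2] * pi * seq_len(ncols) / ncols + ph[2]))
    }
    r <- (r - min(r)) / (max(r) - min(r))
    r <- value_range[1] + r * diff(value_range)
    if (nodata_frac > 0)
      r[stats::runif(length(r)) < nodata_frac] <- NA
    raster_grid(r, ...)
  })
}
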