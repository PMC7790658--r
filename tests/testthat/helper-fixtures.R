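# small in-code fixtures shared across test files

# genotype matrix from a plain matrix with default ids
gm <- function(m, ploidy = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("i%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("L%02d", seq_len(ncol(m)))
  genotype_matrix(m, ploidy = ploidy)
}

# reference-cohort sample table for a genotype matrix, split into two species
ref_samples <- function(g, species) {
  sample_table(data.frame(
    individual = rownames(g), population = paste0("pop_", species),
    cohort = "reference", species = species,
    lat = 39, lon = -9, stringsAsFactors = FALSE), genotypes = g)
}

# independent full-enumeration HWE oracle: exact factorial arithmetic over
# every genotype configuration compatible with the observed allele counts
hwe_oracle <- function(n_MM, n_MP, n_PP) {
  n <- n_MM + n_MP + n_PP
  n1 <- 2 * n_MM + n_MP
  configs <- list(); w <- c()
  for (a in 0:n) for (b in 0:(n - a)) {
    c_ <- n - a - b
    if (2 * a + b != n1) next
    configs[[length(configs) + 1]] <- c(a, b, c_)
    w <- c(w, factorial(n) / (factorial(a) * factorial(b) * factorial(c_)) *
             2^b)
  }
  prob <- w / sum(w)
  obs <- which(vapply(configs, function(x)
    all(x == c(n_MM, n_MP, n_PP)), logical(1)))
  sum(prob[prob <= prob[obs] * (1 + 1e-9)])
}
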