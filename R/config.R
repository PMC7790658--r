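#' Pipeline configuration
#'
#' A single validated list of the thresholds, iteration counts and seeds
#' every stage reads its parameters from. Defaults follow the analysis
#' conventions of the pipeline: diagnosticity screen at kappa >= 0.9,
#' admixture-class thresholds Q in (0.05, 0.95), collinearity pruning at
#' |r_s| < 0.7, stepwise entry/removal at p_in = 0.05 / p_out = 0.10,
#' 1,000 bootstrap replicates for admixture LD, and 10 EM restarts.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param kappa_threshold diagnosticity screen threshold on Cohen's kappa.
#' @param q_threshold purity threshold on the admixture proportion.
#' @param r_s_threshold Spearman collinearity threshold.
#' @param p_in,p_out stepwise likelihood-ratio entry/removal p-values.
#' @param n_boot bootstrap replicates for admixture LD.
#' @param n_restarts EM random restarts per K.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, kappa_threshold = 0.9,
                            q_threshold = 0.95, r_s_threshold = 0.7,
                            p_in = 0.05, p_out = 0.10, n_boot = 1000L,
                            n_restarts = 10L, max_iter = 500L, tol = 1e-6) {
  cfg <- list(seed = as.integer(seed), kappa_threshold = kappa_threshold,
              q_threshold = q_threshold, r_s_threshold = r_s_threshold,
              p_in = p_in, p_out = p_out, n_boot = as.integer(n_boot),
              n_restarts = as.integer(n_restarts),
              max_iter = as.integer(max_iter), tol = tol)
  with(cfg, {
    stopifnot(kappa_threshold >= -1, kappa_threshold <= 1,
              q_threshold > 0.5, q_threshold < 1,
              r_s_threshold >= 0, r_s_threshold <= 1,
              p_in > 0, p_in < 1, p_out > 0, p_out < 1, p_in <= p_out,
              n_boot >= 1, n_restarts >= 1, max_iter >= 1, tol > 0)
  })
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys override the defaults.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

# stage seeds are derived, not reused, so stages stay independent
stage_seed <- function(cfg, stage) {
  offsets <- c(simulate = 101L, design = 202L, markers = 303L,
               popgen = 404L, admixture = 505L, pca = 606L, sdm = 707L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (cfg$seed * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

ht_log <- function(fmt, ...) {
  message(sprintf(paste0("[hybridtrace] ", fmt), ...))
}
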