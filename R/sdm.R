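#' Prune collinear climate variables by Spearman/UPGMA clustering
#'
#' Computes all pairwise Spearman correlations among candidate climate
#' variables, clusters them by UPGMA (average linkage) on the distance
#' `1 - |r_s|`, cuts the dendrogram at the partial-independence criterion
#' `|r_s| < r_threshold`, and retains one representative per cluster: the
#' variable with the lowest mean `|r_s|` to all variables outside its
#' cluster (the least redundant choice). When every variable falls in one
#' cluster the fallback is the lowest mean within-cluster `|r_s|`, ties
#' broken alphabetically. The result is deterministic.
#'
#' @param env data frame of localities; `variables` selects the candidate
#'   columns (default: every numeric column except coordinates and labels).
#' @param r_threshold Spearman threshold (default 0.7).
#' @param variables optional character vector of candidate column names.
#' @return list with `retained` (character), `clusters` (named integer
#'   membership), `tree` (an `hclust`), `r_s` (correlation matrix).
#' @export
collinearity_prune <- function(env, r_threshold = 0.7, variables = NULL) {
  if (is.null(variables)) {
    drop <- c("locality", "lat", "lon", "species", "p_m")
    variables <- setdiff(names(env)[vapply(env, is.numeric, logical(1))], drop)
  }
  if (length(variables) < 2) stop("need >= 2 candidate variables")
  X <- as.matrix(env[, variables, drop = FALSE])
  if (nrow(X) < 3) stop("need >= 3 localities")
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(const))
    stop("constant variable (Spearman undefined): ",
         variables[which(const)[1]])
  r_s <- stats::cor(X, method = "spearman")
  d <- stats::as.dist(1 - abs(r_s))
  tree <- stats::hclust(d, method = "average")
  clusters <- stats::cutree(tree, h = 1 - r_threshold)
  retained <- character(0)
  for (cl in sort(unique(clusters))) {
    members <- names(clusters)[clusters == cl]
    outside <- setdiff(variables, members)
    if (length(members) == 1) {
      retained <- c(retained, members)
    } else if (length(outside)) {
      score <- rowMeans(abs(r_s[members, outside, drop = FALSE]))
      retained <- c(retained, members[order(score, members)[1]])
    } else {
      score <- rowMeans(abs(r_s[members, members, drop = FALSE]))
      retained <- c(retained, members[order(score, members)[1]])
    }
  }
  list(retained = retained[order(match(retained, variables))],
       clusters = clusters, tree = tree, r_s = r_s)
}

#' Maximum-likelihood logistic regression
#'
#' Binomial GLM fit (iteratively reweighted least squares) of a binary
#' species label on climate predictors, with explicit detection of
#' complete separation, under which the ML estimate does not exist.
#'
#' @param X numeric predictor matrix (no intercept column).
#' @param y binary labels (0/1 or logical).
#' @return list with `coefficients` (intercept first), `se`, `logL`,
#'   `fitted`, and the underlying `glm` object.
#' @export
fit_logistic <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  if (nrow(X) <= ncol(X) + 1) stop("more parameters than observations")
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(const)) stop("constant predictor column: ",
                       colnames(X)[which(const)[1]])
  df <- data.frame(y = y, X)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                     family = stats::binomial()))
  eps <- 1e-8
  if (any(abs(fit$coefficients[-1]) > 1e3) ||
      (all(fit$fitted.values[y == 1] > 1 - eps) &&
       all(fit$fitted.values[y == 0] < eps)))
    stop("complete separation: logistic coefficients diverge")
  list(coefficients = stats::coef(fit),
       se = summary(fit)$coefficients[, "Std. Error"],
       logL = as.numeric(stats::logLik(fit)),
       fitted = fit$fitted.values, glm = fit)
}

# log-likelihood of a binomial glm given a formula on `data`
.logL_glm <- function(formula, data) {
  as.numeric(stats::logLik(suppressWarnings(
    stats::glm(formula, data = data, family = stats::binomial()))))
}

#' Forward stepwise logistic regression under the likelihood-ratio criterion
#'
#' Classic forward-stepwise selection: at each step the candidate with the
#' smallest likelihood-ratio chi-square p-value enters if `p < p_in`; then
#' every included variable is re-tested and removed if its removal
#' p-value exceeds `p_out`. Ties are broken by candidate-list order; the
#' loop stops when no change occurs, with a step cap and visited-state
#' check guarding against cycles.
#'
#' @param env data frame with a binary species column and the candidate
#'   predictors.
#' @param candidates character vector of candidate variable names (ideally
#'   pre-pruned by [collinearity_prune()]).
#' @param response column holding the labels; `"M"` (or 1) is the positive
#'   class.
#' @param p_in,p_out entry and removal p-value criteria.
#' @param max_steps cycle guard.
#' @return An `sdm_model` list: `variables`, `coefficients` (exponent
#'   convention: `p = 1 / (1 + exp(b1 x1 + ... + b0))` has
#'   `coefficients` reported on the standard logit scale), `se`, `logL`,
#'   `auc`, `auc_se`, `trace` (one row per tested step), `fit`.
#' @export
forward_stepwise_lr <- function(env, candidates, response = "species",
                                p_in = 0.05, p_out = 0.10, max_steps = 50L) {
  y <- env[[response]]
  if (!is.numeric(y)) y <- as.numeric(y == "M")
  stopifnot(all(y %in% c(0, 1)))
  data <- cbind(data.frame(.y = y), env[, candidates, drop = FALSE])
  included <- character(0)
  trace <- list()
  seen <- character(0)
  fml <- function(vars) stats::as.formula(
    paste(".y ~", if (length(vars)) paste(vars, collapse = " + ") else "1"))
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    ll0 <- .logL_glm(fml(included), data)
    pool <- setdiff(candidates, included)
    if (length(pool)) {
      p_add <- vapply(pool, function(v) {
        ll1 <- .logL_glm(fml(c(included, v)), data)
        stats::pchisq(2 * max(ll1 - ll0, 0), df = 1, lower.tail = FALSE)
      }, numeric(1))
      best <- which(p_add == min(p_add))[1]  # candidate order breaks ties
      if (p_add[best] < p_in) {
        included <- c(included, pool[best])
        trace[[length(trace) + 1L]] <- data.frame(
          step = step, action = "add", variable = pool[best],
          p = p_add[best], stringsAsFactors = FALSE)
        changed <- TRUE
      }
    }
    if (length(included)) {
      ll_full <- .logL_glm(fml(included), data)
      p_drop <- vapply(included, function(v) {
        ll1 <- .logL_glm(fml(setdiff(included, v)), data)
        stats::pchisq(2 * max(ll_full - ll1, 0), df = 1, lower.tail = FALSE)
      }, numeric(1))
      worst <- which(p_drop == max(p_drop))[1]
      if (p_drop[worst] > p_out) {
        trace[[length(trace) + 1L]] <- data.frame(
          step = step, action = "remove", variable = included[worst],
          p = p_drop[worst], stringsAsFactors = FALSE)
        included <- setdiff(included, included[worst])
        changed <- TRUE
      }
    }
    state <- paste(sort(included), collapse = "|")
    if (!changed || state %in% seen) break
    seen <- c(seen, state)
  }
  if (length(included)) {
    fit <- fit_logistic(as.matrix(data[, included, drop = FALSE]), y)
    names(fit$coefficients) <- c("(Intercept)", included)
    scores <- fit$fitted
  } else {
    fit <- list(coefficients = c("(Intercept)" = stats::qlogis(mean(y))),
                se = NA_real_,
                logL = sum(stats::dbinom(y, 1, mean(y), log = TRUE)),
                fitted = rep(mean(y), length(y)), glm = NULL)
    scores <- fit$fitted
  }
  a <- if (length(included)) auc(scores, y) else list(auc = NA, se = NA)
  structure(list(variables = included, coefficients = fit$coefficients,
                 se = fit$se, logL = fit$logL, auc = a$auc, auc_se = a$se,
                 trace = if (length(trace)) do.call(rbind, trace) else
                   data.frame(step = integer(), action = character(),
                              variable = character(), p = numeric()),
                 fit = fit),
            class = "sdm_model")
}

#' @export
print.sdm_model <- function(x, ...) {
  if (length(x$variables)) {
    terms <- paste(sprintf("%+.4g*%s", -x$coefficients[-1], x$variables),
                   collapse = " ")
    cat(sprintf("sdm_model: p_m = 1/(1 + exp(%s %+.4g)); AUC = %.3f +/- %.3f\n",
                terms, -x$coefficients[1], x$auc, x$auc_se))
  } else {
    cat("sdm_model: empty model (no variable met the entry criterion)\n")
  }
  invisible(x)
}

#' Area under the ROC curve with Hanley-McNeil standard error
#'
#' Mann-Whitney formulation (ties count one half) with the Hanley-McNeil
#' normal-model standard error.
#'
#' @param scores numeric scores, higher = more M-like.
#' @param labels binary labels (1/`"M"` = positive).
#' @return list with `auc` and `se`.
#' @export
auc <- function(scores, labels) {
  y <- if (is.numeric(labels)) as.numeric(labels) else as.numeric(labels == "M")
  if (length(unique(y)) < 2) stop("both classes must be present")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  A <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (n1 - 1) * (Q1 - A^2) + (n0 - 1) * (Q2 - A^2)) /
             (n1 * n0))
  list(auc = A, se = se)
}

#' Project a fitted model onto climate rasters and stack hindcasts
#'
#' For each climate reconstruction (a named list of [raster_grid()]s, one
#' per selected variable), evaluates the fitted logistic surface cellwise,
#' thresholds it at `p_m > 0.5` into a binary presence grid, and sums the
#' binaries into a cumulative grid (0..number of reconstructions) — the
#' count of models supporting presence. Nodata propagates.
#'
#' @param model an `sdm_model` with at least one selected variable.
#' @param raster_sets list of named lists of aligned [raster_grid()]s.
#' @return list with `probability` (list of grids), `binary` (list) and
#'   `cumulative` (one grid).
#' @export
hindcast_stack <- function(model, raster_sets) {
  if (!length(model$variables)) stop("empty model cannot be projected")
  ref <- raster_sets[[1]][[1]]
  check_aligned <- function(g)
    identical(dim(g), dim(ref)) &&
      isTRUE(all.equal(c(attr(g, "xllcorner"), attr(g, "yllcorner"),
                         attr(g, "cellsize")),
                       c(attr(ref, "xllcorner"), attr(ref, "yllcorner"),
                         attr(ref, "cellsize"))))
  prob <- list(); bin <- list()
  cum <- matrix(0, nrow(ref), ncol(ref))
  nodata <- matrix(FALSE, nrow(ref), ncol(ref))
  for (s in seq_along(raster_sets)) {
    set <- raster_sets[[s]]
    missing_vars <- setdiff(model$variables, names(set))
    if (length(missing_vars))
      stop("raster set ", s, " lacks variable(s): ",
           paste(missing_vars, collapse = ", "))
    eta <- matrix(model$coefficients[1], nrow(ref), ncol(ref))
    na_here <- matrix(FALSE, nrow(ref), ncol(ref))
    for (v in model$variables) {
      g <- set[[v]]
      if (!check_aligned(g)) stop("raster set ", s, " is misaligned")
      eta <- eta + model$coefficients[v] * unclass(g)
      na_here <- na_here | is.na(unclass(g))
    }
    p <- stats::plogis(eta)
    p[na_here] <- NA
    b <- (p > 0.5) * 1
    prob[[s]] <- raster_grid(p, attr(ref, "xllcorner"),
                             attr(ref, "yllcorner"), attr(ref, "cellsize"))
    bin[[s]] <- raster_grid(b, attr(ref, "xllcorner"),
                            attr(ref, "yllcorner"), attr(ref, "cellsize"))
    nodata <- nodata | na_here
    bb <- b; bb[is.na(bb)] <- 0
    cum <- cum + bb
  }
  cum[nodata] <- NA
  list(probability = prob, binary = bin,
       cumulative = raster_grid(cum, attr(ref, "xllcorner"),
                                attr(ref, "yllcorner"),
                                attr(ref, "cellsize")))
}
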