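#' @title Approximate Bayesian computation
#' @name abc_infer
#' @description Reference-table construction from the structured-coalescent
#'   simulator, rejection sampling on MAD-standardised Euclidean distances,
#'   local-linear (Beaumont-style) regression adjustment with an optional
#'   single-hidden-layer neural-network variant, ABC model posterior
#'   probabilities, a PCA goodness-of-fit check, and conversion of split
#'   times from coalescent units to generations and years.
NULL

#' Uniform prior specification
#'
#' Defaults follow the study design: per-deme `theta` on the
#' reference-locus scale in (0.01, 10), split times in 4Ne units in
#' (0.0001, 0.5), migration rates in 4Nm units in (0, 50). When a model has
#' two split times the ordering `tau1 <= tau2` is enforced by rejection of
#' violating draws.
#'
#' @param theta,tau,M length-2 numeric bounds `(lower, upper)`.
#' @return List of class `prior_spec`.
#' @export
prior_spec <- function(theta = c(0.01, 10), tau = c(1e-4, 0.5), M = c(0, 50)) {
  for (b in list(theta, tau, M))
    if (length(b) != 2L || b[1L] >= b[2L]) stop("bounds must be (lower < upper)")
  structure(list(theta = theta, tau = tau, M = M), class = "prior_spec")
}

#' @rdname prior_spec
#' @param spec a model specification (see [model_catalogue()]).
#' @param priors a `prior_spec`.
#' @param n number of draws.
#' @return `draw_params()`: an `n x n_params` matrix of prior draws.
#' @export
draw_params <- function(spec, priors, n) {
  p <- length(spec$param_type)
  out <- matrix(0, n, p, dimnames = list(NULL, spec$param_names))
  for (j in seq_len(p)) {
    b <- priors[[spec$param_type[j]]]
    out[, j] <- runif(n, b[1L], b[2L])
  }
  taus <- which(spec$param_type == "tau")
  if (length(taus) > 1L) {
    bad <- which(out[, taus[1L]] > out[, taus[2L]])
    while (length(bad)) {
      b <- priors$tau
      out[bad, taus] <- cbind(runif(length(bad), b[1L], b[2L]),
                              runif(length(bad), b[1L], b[2L]))
      bad <- bad[out[bad, taus[1L]] > out[bad, taus[2L]]]
    }
  }
  out
}

#' Build an ABC reference table
#'
#' Draws parameters from the priors, simulates a dataset per draw under the
#' model specification, and records the summary-statistic vectors.
#'
#' @param spec a model specification (see [model_catalogue()] /
#'   [im_model_spec()]).
#' @param priors a [prior_spec()].
#' @param n_sims number of simulations.
#' @param sample_sizes haplotype-count matrix (loci x groups) or named
#'   vector of individuals per group (see [simulate_dataset()]).
#' @param rng_seed seed; the table is reproducible given the seed.
#' @param loci a [locus_set()] used by the model constructor.
#' @return Object of class `reference_table` with `params` and `stats`
#'   matrices, the model id, seed and priors.
#' @export
build_reference_table <- function(spec, priors, n_sims, sample_sizes,
                                  rng_seed = NULL, loci = default_locus_set()) {
  stopifnot(n_sims >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  params <- draw_params(spec, priors, n_sims)
  stats <- NULL
  bad <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    sim <- simulate_dataset(spec$make(params[i, ], loci), sample_sizes,
                            group_deme = spec$group_deme)
    sv <- sim_summary_vector(sim)
    if (is.null(stats))
      stats <- matrix(0, n_sims, length(sv), dimnames = list(NULL, names(sv)))
    stats[i, ] <- as.numeric(sv)
    bad[i] <- any(!is.finite(sv))
  }
  structure(list(params = params, stats = stats, model = spec$id,
                 flagged = bad, seed = rng_seed, priors = priors,
                 n_sims = n_sims),
            class = "reference_table")
}

# MAD-standardise reference and observed statistics; drop zero-MAD columns.
# Nonnegative (diversity-type) statistics are log1p-compressed first, so
# that the distance lives on a relative scale and low-diversity demes are
# not swamped; sign-carrying columns (Tajima's D) keep their natural scale.
.standardise_stats <- function(stats, observed, log_stats = TRUE) {
  if (log_stats) {
    loggable <- apply(stats, 2L, min) >= 0 & observed >= 0
    stats[, loggable] <- log1p(stats[, loggable])
    observed[loggable] <- log1p(observed[loggable])
  }
  scale <- apply(stats, 2L, mad)
  keep <- scale > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance statistic(s) excluded from the distance")
  list(stats = sweep(stats[, keep, drop = FALSE], 2L, scale[keep], "/"),
       observed = observed[keep] / scale[keep], keep = keep, scale = scale)
}

#' ABC rejection step
#'
#' Statistics are log1p-compressed (except Tajima's D, which can be
#' negative) and standardised by the reference-table median absolute
#' deviation; the `ceiling(tolerance * n_sims)` rows closest to the
#' observed vector in Euclidean distance are retained. The log compression
#' puts the heavy-tailed diversity statistics on a relative scale so that
#' low-diversity demes are not ignored by the distance.
#'
#' @param observed observed `summary_stat_vector` (or numeric vector in the
#'   table's column order).
#' @param table a [build_reference_table()] result.
#' @param tolerance acceptance rate in (0, 1].
#' @return List with `index`, `distance` (all rows), `params`, `stats` of
#'   the retained rows, and the tolerance used.
#' @export
abc_rejection <- function(observed, table, tolerance) {
  if (tolerance <= 0 || tolerance > 1) stop("tolerance must be in (0, 1]")
  obs <- as.numeric(observed)
  if (!all(is.finite(obs))) stop("observed statistics must be finite")
  std <- .standardise_stats(table$stats, obs)
  d2 <- rowSums(sweep(std$stats, 2L, std$observed, "-")^2)
  n_keep <- ceiling(tolerance * nrow(table$stats))
  idx <- order(d2)[seq_len(n_keep)]
  list(index = idx, distance = sqrt(d2),
       params = table$params[idx, , drop = FALSE],
       stats = table$stats[idx, , drop = FALSE],
       stats_std = std$stats[idx, , drop = FALSE],
       observed = obs, observed_std = std$observed,
       tolerance = tolerance, keep = std$keep)
}

# logit transform to the prior support (keeps adjusted draws inside bounds)
.to_logit <- function(x, lo, hi) {
  eps <- (hi - lo) * 1e-8
  x <- pmin(pmax(x, lo + eps), hi - eps)
  log((x - lo) / (hi - x))
}
.from_logit <- function(z, lo, hi) lo + (hi - lo) / (1 + exp(-z))

#' Posterior construction from the retained draws
#'
#' Builds the ABC posterior from the rejection sample with Epanechnikov
#' kernel weights in the rejection distance. The default (`"rejection"`)
#' uses the weighted retained draws directly. `"loclinear"` applies
#' Beaumont-style local-linear regression adjustment of each parameter
#' (logit-transformed to its prior support) on the standardised
#' statistics; `"neuralnet"` substitutes a single-hidden-layer network
#' fitted by [nnet::nnet()]. Back-transforming from the logit scale keeps
#' every adjusted draw inside the prior support.
#'
#' The weighted rejection sample is the default because, for this
#' pipeline's 27-dimensional statistic vector, the nearest few hundred
#' rows of a feasible reference table span a region far too wide for the
#' local-linear approximation; the regression variants then extrapolate
#' and can inflate the reference-scale theta severalfold while the plain
#' rejection posterior stays calibrated (see the methods vignette).
#'
#' @param retained result of [abc_rejection()].
#' @param spec the model specification (for parameter types/bounds).
#' @param priors the [prior_spec()] used.
#' @param method `"rejection"` (default), `"loclinear"` or `"neuralnet"`.
#' @param level credible level for the HPD intervals (default 0.95).
#' @return Object of class `abc_posterior`: raw and adjusted draws,
#'   weights, and a per-parameter summary (mean, median, HPD bounds).
#' @export
regression_adjust <- function(retained, spec, priors,
                              method = c("rejection", "loclinear", "neuralnet"),
                              level = 0.95) {
  method <- match.arg(method)
  if (nrow(retained$params) < 20L) stop("need >= 20 retained rows")
  dmax <- max(retained$distance[retained$index])
  w <- if (dmax > 0) 1 - (retained$distance[retained$index] / dmax)^2 else
    rep(1, length(retained$index))
  w[w <= 0] <- min(w[w > 0]) / 10
  X <- sweep(retained$stats_std, 2L, retained$observed_std, "-")
  adj <- retained$params
  for (j in seq_len(if (method == "rejection") 0L else ncol(adj))) {
    b <- priors[[spec$param_type[j]]]
    z <- .to_logit(retained$params[, j], b[1L], b[2L])
    fitted_resid <- tryCatch({
      if (method == "loclinear") {
        fit <- lm(z ~ X, weights = w)
        beta <- coef(fit)[-1L]
        beta[is.na(beta)] <- 0
        z - as.numeric(X %*% beta)   # prediction at X = 0 plus residual
      } else {
        if (!requireNamespace("nnet", quietly = TRUE))
          stop("nnet not available")
        fit <- nnet::nnet(X, z, weights = w, size = 5L, linout = TRUE,
                          decay = 0.01, maxit = 500L, trace = FALSE)
        at_obs <- as.numeric(predict(fit, matrix(0, 1L, ncol(X))))
        at_obs + (z - as.numeric(predict(fit, X)))
      }
    }, error = function(e) {
      warning("regression adjustment failed (", conditionMessage(e),
              "); falling back to unadjusted rejection draws")
      z
    })
    adj[, j] <- .from_logit(fitted_resid, b[1L], b[2L])
  }
  summ <- do.call(rbind, lapply(seq_len(ncol(adj)), function(j) {
    hpd <- weighted_hpd(adj[, j], w, level)
    data.frame(parameter = colnames(adj)[j],
               mean = weighted.mean(adj[, j], w),
               median = weighted_quantile(adj[, j], w, 0.5),
               hpd_lower = hpd[1L], hpd_upper = hpd[2L],
               stringsAsFactors = FALSE)
  }))
  structure(list(raw = retained$params, adjusted = adj, weights = w,
                 summary = summ, tolerance = retained$tolerance,
                 method = method, level = level),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("<abc_posterior> %d weighted draws (%s adjustment, tolerance %.3g)\n",
              nrow(x$adjusted), x$method, x$tolerance))
  s <- x$summary
  for (k in seq_len(nrow(s)))
    cat(sprintf("  %-10s mean %.5g  %d%% HPD [%.5g, %.5g]\n", s$parameter[k],
                s$mean[k], round(100 * x$level), s$hpd_lower[k], s$hpd_upper[k]))
  invisible(x)
}

#' Weighted empirical quantile
#' @param x draws. @param w nonnegative weights. @param p probability.
#' @return The weighted quantile of `x`.
#' @export
weighted_quantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= p)[1L]]
}

#' Weighted highest-posterior-density interval
#'
#' Shortest interval containing `level` posterior mass, from the weighted
#' empirical distribution of the draws.
#'
#' @param x draws. @param w weights. @param level credible level.
#' @return Length-2 vector `(lower, upper)`.
#' @export
weighted_hpd <- function(x, w, level = 0.95) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  n <- length(x)
  best <- c(x[1L], x[n]); best_len <- x[n] - x[1L]
  for (i in seq_len(n)) {
    target <- (if (i > 1L) cw[i - 1L] else 0) + level
    j <- which(cw >= min(target, 1))[1L]
    if (is.na(j)) break
    if (cw[n] - (if (i > 1L) cw[i - 1L] else 0) < level) break
    len <- x[j] - x[i]
    if (len < best_len) { best_len <- len; best <- c(x[i], x[j]) }
  }
  best
}

#' ABC model posterior probabilities
#'
#' Pooled rejection over per-model reference tables: the posterior
#' probability of each model is its share of the retained rows. An optional
#' multinomial-logistic refinement ([nnet::multinom()] on model labels
#' against statistics, evaluated at the observed point) is available.
#'
#' @param observed observed summary vector.
#' @param tables named list of `reference_table`s (one per model).
#' @param tolerance overall acceptance rate.
#' @param refine use the multinomial-logistic refinement.
#' @return List of class `model_posterior`: `prob` (named, sums to 1),
#'   `bayes_factors` (probability-ratio matrix), `retained` counts.
#' @export
model_posterior <- function(observed, tables, tolerance = 0.005, refine = FALSE) {
  if (length(tables) < 2L) stop("need >= 2 models")
  ids <- vapply(tables, function(t) as.character(t$model), "")
  names(tables) <- ids
  stats <- do.call(rbind, lapply(tables, function(t) t$stats))
  labels <- rep(ids, vapply(tables, function(t) nrow(t$stats), 0L))
  n_each <- vapply(tables, function(t) nrow(t$stats), 0L)
  if (length(unique(n_each)) > 1L)
    warning("unequal table sizes; shares are reweighted by table size")
  obs <- as.numeric(observed)
  std <- .standardise_stats(stats, obs)
  d2 <- rowSums(sweep(std$stats, 2L, std$observed, "-")^2)
  n_keep <- max(1L, ceiling(tolerance * nrow(stats)))
  idx <- order(d2)[seq_len(n_keep)]
  if (!length(idx)) stop("zero rows retained; increase the tolerance")
  counts <- table(factor(labels[idx], levels = ids))
  # correct for unequal simulation effort per model
  share <- as.numeric(counts) / n_each
  prob <- share / sum(share)
  names(prob) <- ids
  if (refine) {
    if (!requireNamespace("nnet", quietly = TRUE))
      stop("nnet not available for the multinomial refinement")
    keep_n <- min(length(d2), max(n_keep * 50L, 2000L))
    sub <- order(d2)[seq_len(keep_n)]
    df <- data.frame(std$stats[sub, , drop = FALSE])
    df$model <- droplevels(factor(labels[sub], levels = ids))
    fit <- nnet::multinom(model ~ ., data = df, trace = FALSE, maxit = 500L)
    newd <- data.frame(matrix(std$observed, 1L,
                              dimnames = list(NULL, colnames(std$stats))))
    pr <- predict(fit, newdata = newd, type = "probs")
    present <- levels(df$model)
    if (length(present) == 2L) pr <- c(1 - pr, pr)  # binomial special case
    prob <- setNames(rep(0, length(ids)), ids)
    prob[present] <- as.numeric(pr)
  }
  bf <- outer(prob, prob, function(a, b) a / b)
  structure(list(prob = prob, bayes_factors = bf,
                 retained = as.numeric(counts), tolerance = tolerance),
            class = "model_posterior")
}

#' @export
print.model_posterior <- function(x, ...) {
  o <- order(-x$prob)
  cat("<model_posterior>\n")
  for (i in o)
    cat(sprintf("  model %-4s PP = %.3f (retained %d)\n",
                names(x$prob)[i], x$prob[i], x$retained[i]))
  invisible(x)
}

#' PCA goodness-of-fit check
#'
#' PCA is fitted on the prior-predictive statistics; the posterior cloud
#' and the observed point are projected onto the first two components, and
#' the observed point's Mahalanobis percentile within the posterior cloud
#' is reported. The fit passes when that percentile does not exceed the
#' configured cut-off.
#'
#' @param prior_stats matrix of prior-predictive summary statistics.
#' @param posterior_stats matrix of posterior-predictive (retained)
#'   statistics.
#' @param observed observed summary vector.
#' @param percentile pass/fail cut-off (default 95).
#' @return List of class `gof_report`: `percentile`, `pass`, projected
#'   scores.
#' @export
gof_pca <- function(prior_stats, posterior_stats, observed, percentile = 95) {
  if (nrow(prior_stats) < 3L || nrow(posterior_stats) < 3L)
    stop("need >= 3 rows of prior and posterior statistics")
  keep <- apply(prior_stats, 2L, sd) > 0
  if (!all(keep)) warning("dropping ", sum(!keep), " constant statistic column(s)")
  pca <- prcomp(prior_stats[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  proj <- function(m) predict(pca, m[, keep, drop = FALSE])[, 1:2, drop = FALSE]
  post <- proj(posterior_stats)
  obs <- proj(matrix(as.numeric(observed), 1L,
                     dimnames = list(NULL, colnames(prior_stats))))
  S <- cov(post)
  d_obs <- mahalanobis(obs, colMeans(post), S)
  d_post <- mahalanobis(post, colMeans(post), S)
  pct <- 100 * mean(d_post <= as.numeric(d_obs))
  structure(list(percentile = pct, pass = pct <= percentile,
                 prior_scores = proj(prior_stats), posterior_scores = post,
                 observed_score = obs),
            class = "gof_report")
}

#' Convert split times from coalescent units to generations and years
#'
#' Per locus, `4Ne = theta_locus / (rate_per_site_per_year * length *
#' generation_time)`; `generations = tau * 4Ne`; `years = generations *
#' generation_time`. The cross-locus summary is the arithmetic mean.
#'
#' @param tau_4Ne split time in 4Ne units.
#' @param theta_locus named vector of per-locus theta (4 Ne mu).
#' @param rate_table data.frame with columns `name`, `length`, `rate`
#'   (substitutions per site per lineage per million years), e.g. a
#'   [locus_set()].
#' @param generation_time generation time in years (default 1).
#' @return List with per-locus `generations` and `years` and their means.
#' @export
convert_time_units <- function(tau_4Ne, theta_locus, rate_table,
                               generation_time = 1) {
  if (any(rate_table$rate <= 0) || any(rate_table$length <= 0))
    stop("input error: rates and lengths must be positive")
  if (tau_4Ne < 0) stop("input error: tau must be >= 0")
  rate_yr <- rate_table$rate * 1e-6          # per site per year
  theta <- theta_locus[rate_table$name]
  four_ne <- theta / (rate_yr * rate_table$length * generation_time)
  gens <- tau_4Ne * four_ne
  years <- gens * generation_time
  list(per_locus = data.frame(locus = rate_table$name,
                              four_Ne = unname(four_ne),
                              generations = unname(gens),
                              years = unname(years)),
       generations = mean(gens), years = mean(years))
}
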