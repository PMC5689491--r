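#' @title ESU validation protocol
#' @name esu_protocol
#' @description The eight-model catalogue of migration/collapse hypotheses
#'   over three biogeographical units (BUs) with a designated sister pair,
#'   coalescent model choice by ABC posterior probabilities, the
#'   collapse/retain decision rule, model averaging of theta and M, the
#'   mtDNA haplotype-exclusivity check, and the end-to-end pipeline.
NULL

# specification of one simulable model: parameter layout plus constructor
.model_spec <- function(id, description, demes, routes, group_deme,
                        collapse, root_cap = NULL) {
  theta_names <- paste0("theta_", demes)
  m_names <- unlist(lapply(routes, function(r)
    c(paste0("M_", r[1L], ".", r[2L]), paste0("M_", r[2L], ".", r[1L]))))
  param_names <- c(theta_names, m_names)
  param_type <- c(rep("theta", length(demes)), rep("M", length(m_names)))
  force(routes); force(demes); force(root_cap)
  make <- function(par, loci = default_locus_set()) {
    theta <- setNames(par[seq_along(demes)], demes)
    mig <- matrix(0, length(demes), length(demes),
                  dimnames = list(demes, demes))
    k <- length(demes)
    for (r in routes) {
      mig[r[1L], r[2L]] <- par[k + 1L]
      mig[r[2L], r[1L]] <- par[k + 2L]
      k <- k + 2L
    }
    demographic_model(theta, mig, root_cap = root_cap, loci = loci)
  }
  list(id = id, description = description, demes = demes, routes = routes,
       group_deme = group_deme, collapse = collapse, root_cap = root_cap,
       make = make, param_names = param_names, param_type = param_type)
}

#' The eight-model catalogue of ESU hypotheses
#'
#' Island models over three BUs `(a, b, c)` with sister pair `(a, b)`:
#' gene flow, when present, is bidirectional (two directed rates per open
#' route), and collapsed models merge BUs into a single panmictic deme.
#'
#' 1. all three units interconnected; 2. `b`-`c` isolated, other routes
#' open; 3. `a`-`c` isolated, other routes open; 4. only the sister route
#' open, `c` fully isolated; 5. all isolated; 6. sisters collapsed,
#' connected with `c`; 7. sisters collapsed, isolated from `c`;
#' 8. panmixia.
#'
#' @param labels three BU labels; the first two are the sister pair from
#'   the configured lineage-tree topology.
#' @param root_cap forced root-join time (4Ne units) for the models whose
#'   migration graph is not connected (default 20).
#' @return Named list of eight model specifications.
#' @export
model_catalogue <- function(labels = c("C", "P", "Q"), root_cap = 20) {
  if (length(labels) != 3L)
    stop("unsupported configuration: the catalogue is defined for 3 BUs")
  a <- labels[1L]; b <- labels[2L]; c3 <- labels[3L]
  ident <- setNames(labels, labels)
  ab <- paste0(a, b)
  coll <- setNames(c(ab, ab, c3), labels)
  all3 <- setNames(as.list(labels), labels)
  coll_groups <- list(c(a, b), c3); names(coll_groups) <- c(ab, c3)
  list(
    "1" = .model_spec("1", "all units interconnected", labels,
                      list(c(a, b), c(a, c3), c(b, c3)), ident, all3),
    "2" = .model_spec("2", paste(b, "and", c3, "isolated from each other"),
                      labels, list(c(a, b), c(a, c3)), ident, all3),
    "3" = .model_spec("3", paste(a, "and", c3, "isolated from each other"),
                      labels, list(c(a, b), c(b, c3)), ident, all3),
    "4" = .model_spec("4", paste(a, "and", b, "interconnected, isolated from", c3),
                      labels, list(c(a, b)), ident, all3, root_cap = root_cap),
    "5" = .model_spec("5", "all units isolated from each other", labels,
                      list(), ident, all3, root_cap = root_cap),
    "6" = .model_spec("6", paste(a, "+", b, "panmictic, connected with", c3),
                      c(ab, c3), list(c(ab, c3)), coll, coll_groups),
    "7" = .model_spec("7", paste(a, "+", b, "panmictic, isolated from", c3),
                      c(ab, c3), list(), coll, coll_groups, root_cap = root_cap),
    "8" = .model_spec("8", "panmixia",
                      "ALL", list(), setNames(rep("ALL", 3L), labels),
                      setNames(list(labels), "ALL"))
  )
}

#' Isolation-with-migration model for parameter estimation
#'
#' The estimation model combines the configured lineage-tree topology
#' `((a, b), c)` with the gene-flow routes of the best island model:
#' population splits at `tau1` (sisters) and `tau2` (root), plus two
#' directed migration rates per open route.
#'
#' @param labels three deme labels, sister pair first.
#' @param routes list of open routes (pairs of labels), e.g. the routes of
#'   catalogue model 3.
#' @return A model specification usable with [build_reference_table()].
#' @export
im_model_spec <- function(labels = c("C", "P", "Q"),
                          routes = list(c(labels[1L], labels[2L]),
                                        c(labels[2L], labels[3L]))) {
  if (length(labels) != 3L) stop("estimation model is defined for 3 demes")
  a <- labels[1L]; b <- labels[2L]; c3 <- labels[3L]
  theta_names <- paste0("theta_", labels)
  m_names <- unlist(lapply(routes, function(r)
    c(paste0("M_", r[1L], ".", r[2L]), paste0("M_", r[2L], ".", r[1L]))))
  param_names <- c(theta_names, "tau1", "tau2", m_names)
  param_type <- c(rep("theta", 3L), "tau", "tau", rep("M", length(m_names)))
  make <- function(par, loci = default_locus_set()) {
    theta <- setNames(par[1:3], labels)
    mig <- matrix(0, 3L, 3L, dimnames = list(labels, labels))
    k <- 5L
    for (r in routes) {
      mig[r[1L], r[2L]] <- par[k + 1L]
      mig[r[2L], r[1L]] <- par[k + 2L]
      k <- k + 2L
    }
    splits <- data.frame(time = c(par[4L], par[5L]),
                         from = c(a, b), to = c(b, c3),
                         stringsAsFactors = FALSE)
    demographic_model(theta, mig, splits = splits, loci = loci)
  }
  list(id = "IM", description = sprintf("((%s,%s),%s) isolation with migration",
                                        a, b, c3),
       demes = labels, routes = routes,
       group_deme = setNames(labels, labels), collapse = NULL,
       make = make, param_names = param_names, param_type = param_type)
}

#' Validate BUs as ESUs by coalescent model choice
#'
#' Builds a reference table per catalogue model, computes ABC model
#' posterior probabilities, and applies the decision rule: BUs are distinct
#' ESUs unless the best-supported model collapses them into a single deme.
#' An inconclusive choice (top two models within 0.05 posterior
#' probability) is flagged, never silently resolved.
#'
#' @param observed observed `summary_stat_vector` (groups in catalogue
#'   label order).
#' @param catalogue a [model_catalogue()].
#' @param sample_sizes haplotype-count matrix (loci x groups).
#' @param priors a [prior_spec()].
#' @param n_sims simulations per model.
#' @param tolerance pooled rejection acceptance rate.
#' @param rng_seed base seed (each model uses `rng_seed + model index`).
#' @param loci a [locus_set()].
#' @param refine use the multinomial-logistic refinement of the model
#'   probabilities (default `TRUE`; it separates the catalogue's
#'   boundary-nested neighbours far better than raw retention shares).
#' @return List of class `esu_validation`: `best`, `prob`, `esus` (list of
#'   BU groups per validated ESU), `inconclusive`, `model_choice`, and the
#'   reference tables (for goodness-of-fit reuse).
#' @export
validate_esus <- function(observed, catalogue, sample_sizes,
                          priors = prior_spec(), n_sims = 5000,
                          tolerance = 0.005, rng_seed = 1L,
                          loci = default_locus_set(),
                          refine = TRUE) {
  tables <- vector("list", length(catalogue))
  names(tables) <- names(catalogue)
  for (k in seq_along(catalogue)) {
    tables[[k]] <- build_reference_table(catalogue[[k]], priors, n_sims,
                                         sample_sizes,
                                         rng_seed = rng_seed + k,
                                         loci = loci)
  }
  if (refine && !requireNamespace("nnet", quietly = TRUE)) {
    warning("nnet unavailable; falling back to raw retention shares")
    refine <- FALSE
  }
  mp <- model_posterior(observed, tables, tolerance, refine = refine)
  o <- order(-mp$prob)
  best <- names(mp$prob)[o[1L]]
  inconclusive <- (mp$prob[o[1L]] - mp$prob[o[2L]]) < 0.05
  esus <- esu_set_from_model(catalogue[[best]])
  structure(list(best = best, prob = mp$prob, esus = esus,
                 inconclusive = unname(inconclusive), model_choice = mp,
                 tables = tables),
            class = "esu_validation")
}

#' ESU set implied by a catalogue model
#'
#' The decision rule is a function only of the model's collapse structure:
#' each simulated deme of the model is one ESU, containing the BUs mapped
#' to it.
#'
#' @param spec one model specification from [model_catalogue()].
#' @return Named list: one character vector of BU labels per ESU.
#' @export
esu_set_from_model <- function(spec) {
  split(names(spec$group_deme), factor(unname(spec$group_deme),
                                       levels = spec$demes))
}

#' Reciprocal mtDNA haplotype exclusivity between ESUs
#'
#' For every ESU pair, `TRUE` iff no collapsed mtDNA haplotype occurs in
#' both units.
#'
#' @param mt_alignment mitochondrial `haplotype_alignment`.
#' @param assignment named vector mapping `individual_id` to an ESU label.
#' @return Symmetric logical matrix over ESU labels (diagonal `NA`), with
#'   attribute `"all_exclusive"`.
#' @export
mtdna_exclusivity <- function(mt_alignment, assignment) {
  cls <- haplotype_classes(mt_alignment)
  esu <- assignment[mt_alignment$individual_id]
  if (anyNA(esu)) stop("individuals in the mtDNA alignment lack an ESU assignment")
  units <- sort(unique(esu))
  sets <- lapply(units, function(u) unique(cls[esu == u]))
  names(sets) <- units
  out <- matrix(NA, length(units), length(units), dimnames = list(units, units))
  for (i in seq_along(units)) for (j in seq_along(units)) if (i < j) {
    out[i, j] <- out[j, i] <- length(intersect(sets[[i]], sets[[j]])) == 0L
  }
  attr(out, "all_exclusive") <- all(out[upper.tri(out)])
  out
}

#' Model-averaged parameter estimates
#'
#' Probability-weighted mixture of per-model posterior draws. A parameter
#' absent from a model (a closed route's M) contributes a point mass at 0.
#'
#' @param posteriors named list of `abc_posterior` objects, keyed by model.
#' @param probabilities named model probabilities (renormalised with a
#'   warning if they do not sum to 1).
#' @param n_draws mixture draws to return (default 2000).
#' @return List with `mean` (named vector over the parameter union) and
#'   `draws` (mixture sample matrix).
#' @export
model_average_params <- function(posteriors, probabilities, n_draws = 2000) {
  if (!setequal(names(posteriors), names(probabilities)))
    stop("input error: posterior/probability model sets differ")
  probabilities <- probabilities[names(posteriors)]
  if (abs(sum(probabilities) - 1) > 1e-8) {
    warning("model probabilities do not sum to 1; renormalising")
    probabilities <- probabilities / sum(probabilities)
  }
  all_pars <- unique(unlist(lapply(posteriors, function(p) colnames(p$adjusted))))
  avg <- setNames(numeric(length(all_pars)), all_pars)
  for (m in names(posteriors)) {
    mu <- setNames(numeric(length(all_pars)), all_pars)
    s <- posteriors[[m]]$summary
    mu[s$parameter] <- s$mean
    avg <- avg + probabilities[[m]] * mu
  }
  pick <- sample(names(posteriors), n_draws, replace = TRUE,
                 prob = probabilities)
  draws <- matrix(0, n_draws, length(all_pars),
                  dimnames = list(NULL, all_pars))
  for (m in unique(pick)) {
    rows <- which(pick == m)
    p <- posteriors[[m]]
    take <- sample.int(nrow(p$adjusted), length(rows), replace = TRUE,
                       prob = p$weights / sum(p$weights))
    draws[rows, colnames(p$adjusted)] <- p$adjusted[take, , drop = FALSE]
  }
  list(mean = avg, draws = draws, probabilities = probabilities)
}

#' Run the full ESU-delimitation pipeline
#'
#' Discovery (spatial clustering), IBD screen (Mantel test on GENPOFAD
#' distances), validation (ABC model choice over the eight-model
#' catalogue), parameter estimation (ABC on the isolation-with-migration
#' model combining the configured topology with the best model's routes),
#' calendar-time conversion and the mtDNA exclusivity check.
#'
#' @param alignments named list of `haplotype_alignment`s.
#' @param sample_table validated sample table.
#' @param config list of stage settings: `cluster` ([cluster_config()]),
#'   `n_perm` (Mantel permutations, default 10000), `priors`
#'   ([prior_spec()]), `n_sims_choice`, `n_sims_est`, `tolerance_choice`,
#'   `tolerance_est`, `rng_seed`, `loci`, optional `sister_pair` (defaults
#'   to the BU pair with the smallest multilocus dxy), `generation_time`.
#' @return Object of class `esu_report`.
#' @export
run_pipeline <- function(alignments, sample_table, config = list()) {
  cfg <- modifyList(list(cluster = cluster_config(n_iter = 2e4, thinning = 20),
                         n_perm = 10000, priors = prior_spec(),
                         n_sims_choice = 5000, n_sims_est = 20000,
                         tolerance_choice = 0.005, tolerance_est = NULL,
                         rng_seed = 1L, loci = default_locus_set(),
                         sister_pair = NULL, generation_time = 1),
                    config)
  ids <- unlist(lapply(alignments, function(a) a$individual_id))
  missing <- setdiff(unique(ids), sample_table$individual_id)
  if (length(missing))
    stop("validation error: individuals without sample-table rows: ",
         paste(head(missing), collapse = ", "))

  # --- discovery -----------------------------------------------------------
  trace <- run_mcmc(alignments, sample_table, cfg$cluster)
  pk <- posterior_K(trace)
  assignment <- modal_partition(trace)

  # --- isolation by distance ----------------------------------------------
  locus_mats <- lapply(alignments, genpofad_locus_matrix)
  gen_mat <- combine_locus_matrices(locus_mats, standardize = TRUE)
  site_gen <- site_level_matrix(gen_mat, sample_table)
  site_geo <- geographic_distance_matrix(sample_table)
  ibd <- mantel_test(site_gen, site_geo, n_perm = cfg$n_perm,
                     transform = "log10", rng_seed = cfg$rng_seed)

  # --- summaries and observed statistics ----------------------------------
  demes <- assignment[trace$ind_ids]
  bu_labels <- sort(unique(unname(demes)))
  summaries <- lapply(alignments, locus_summary, demes = demes)
  observed <- summary_vector(alignments, demes)
  counts <- t(vapply(alignments, function(a) {
    tab <- table(factor(demes[a$individual_id], levels = bu_labels))
    as.integer(tab)
  }, integer(length(bu_labels))))
  dimnames(counts) <- list(vapply(alignments, function(a) a$locus_name, ""),
                           bu_labels)

  if (length(bu_labels) != 3L)
    stop("unsupported configuration: the validation catalogue requires 3 BUs, found ",
         length(bu_labels))

  # --- sister pair from configured topology (default: smallest dxy) -------
  sister <- cfg$sister_pair
  if (is.null(sister)) {
    dxy_sum <- Reduce(`+`, lapply(summaries, attr, "dxy"))
    pair <- which(dxy_sum == min(dxy_sum[upper.tri(dxy_sum)]), arr.ind = TRUE)[1L, ]
    sister <- rownames(dxy_sum)[sort(pair)]
  }
  labels <- c(sister, setdiff(bu_labels, sister))

  # observed vector and counts must follow sorted-label order already
  catalogue <- model_catalogue(labels)
  set.seed(cfg$rng_seed)
  validation <- validate_esus(observed, catalogue, counts,
                              priors = cfg$priors, n_sims = cfg$n_sims_choice,
                              tolerance = cfg$tolerance_choice,
                              rng_seed = cfg$rng_seed, loci = cfg$loci)

  # --- parameter estimation under the topology + best routes --------------
  best_spec <- catalogue[[validation$best]]
  estimation <- NULL
  conversion <- NULL
  if (length(best_spec$demes) == 3L) {
    # estimation is only meaningful when the best model keeps 3 units
    est_spec <- im_model_spec(labels, routes = best_spec$routes)
    est_table <- build_reference_table(est_spec, cfg$priors, cfg$n_sims_est,
                                       counts, rng_seed = cfg$rng_seed + 100L,
                                       loci = cfg$loci)
    tol <- if (is.null(cfg$tolerance_est))
      min(1, 200 / cfg$n_sims_est) else cfg$tolerance_est
    rej <- abc_rejection(observed, est_table, tol)
    estimation <- regression_adjust(rej, est_spec, cfg$priors)
    gof <- gof_pca(est_table$stats, rej$stats, observed)
    est_mean <- setNames(estimation$summary$mean, estimation$summary$parameter)
    theta_ref <- est_mean[paste0("theta_", labels[1L])]
    theta_locus <- setNames(theta_ref * cfg$loci$rel_rate, cfg$loci$name)
    conversion <- list(
      tau1 = convert_time_units(est_mean[["tau1"]], theta_locus, cfg$loci,
                                cfg$generation_time),
      tau2 = convert_time_units(est_mean[["tau2"]], theta_locus, cfg$loci,
                                cfg$generation_time))
    estimation <- list(posterior = estimation, gof = gof, spec = est_spec)
  }

  # --- mtDNA exclusivity ---------------------------------------------------
  mt <- which(vapply(alignments, function(a)
    a$ploidy_mode == "mitochondrial", TRUE))
  exclusivity <- if (length(mt))
    mtdna_exclusivity(alignments[[mt[1L]]], demes) else NULL

  structure(list(posterior_K = pk, assignment = assignment,
                 ibd = ibd, summaries = summaries,
                 validation = validation, estimation = estimation,
                 time_conversion = conversion,
                 mtdna_exclusivity = exclusivity,
                 labels = labels,
                 provenance = list(rng_seed = cfg$rng_seed,
                                   config = cfg[setdiff(names(cfg), "loci")],
                                   package_version =
                                     as.character(utils::packageVersion("esudelim")))),
            class = "esu_report")
}

#' @export
print.esu_report <- function(x, ...) {
  cat("=== ESU delimitation report ===\n")
  cat(sprintf("Discovered units: modal K = %s (PP = %.2f)\n",
              names(x$posterior_K)[which.max(x$posterior_K)],
              max(x$posterior_K)))
  cat(sprintf("IBD Mantel: r^2 = %.3f, p = %.3g\n", x$ibd$r_squared, x$ibd$p))
  cat(sprintf("Best model: %s (PP = %.3f)%s\n", x$validation$best,
              max(x$validation$prob),
              if (x$validation$inconclusive) " [inconclusive]" else ""))
  cat("Validated ESUs:", paste(vapply(x$validation$esus, paste, "",
                                      collapse = "+"), collapse = ", "), "\n")
  if (!is.null(x$estimation)) {
    s <- x$estimation$posterior$summary
    for (k in seq_len(nrow(s)))
      cat(sprintf("  %-12s mean %.5g  95%% HPD [%.5g, %.5g]\n",
                  s$parameter[k], s$mean[k], s$hpd_lower[k], s$hpd_upper[k]))
    if (!is.null(x$time_conversion))
      cat(sprintf("  split times: tau1 ~ %.3g years, tau2 ~ %.3g years\n",
                  x$time_conversion$tau1$years, x$time_conversion$tau2$years))
  }
  if (!is.null(x$mtdna_exclusivity))
    cat("mtDNA exclusivity:",
        if (attr(x$mtdna_exclusivity, "all_exclusive"))
          "all ESU pairs exclusive" else "shared haplotypes present", "\n")
  invisible(x)
}
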