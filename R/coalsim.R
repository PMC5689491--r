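#' @title Structured-coalescent simulation
#' @name coalsim
#' @description Island and isolation-with-migration models under the
#'   structured coalescent with infinite-sites mutation. Scaling contract:
#'   internal time unit is `2 N_ref` generations; deme `theta_i = 4 N_e mu`
#'   on the reference-locus scale; migration `M_ij = 4 N_e m` (effective
#'   migrants, per-lineage backward rate `M/2`); split times `tau` are input
#'   in `4 N_e` units and doubled internally. `theta_i` is the per-locus
#'   theta of the first (reference) locus, whose inheritance also fixes the
#'   time scale: locus `l` multiplies the effective deme sizes by
#'   `inheritance_l / inheritance_ref` (so a nuclear locus coalesces 4x
#'   slower than an mtDNA reference while split times are shared) and its
#'   mutation rate by the raw per-locus rate ratio `r_l`. For the reference
#'   locus `E[pi] = theta`, `E[S] = theta a1(n)` and, for an isolated deme
#'   pair split at `tau`, `E[dxy] = theta (1 + 2 tau)`.
NULL

#' Locus configuration set
#'
#' @param name locus names.
#' @param length locus lengths in bp (used when rendering sequences and for
#'   time-unit conversion).
#' @param rate substitution rate per site per lineage per million years.
#' @param inheritance inheritance scalar (0.25 for mtDNA, 1 for nuclear).
#' @param ploidy `"mitochondrial"` or `"nuclear"`.
#' @return A `data.frame` with an extra column `rel_rate`: per-locus total
#'   mutation rate relative to the first (reference) locus.
#' @export
locus_set <- function(name, length, rate, inheritance, ploidy) {
  stopifnot(length(name) == length(length), all(rate > 0), all(length > 0))
  rel_rate <- (rate * length) / (rate[1L] * length[1L])
  data.frame(name = name, length = length, rate = rate,
             inheritance = inheritance, ploidy = ploidy,
             rel_rate = rel_rate, stringsAsFactors = FALSE)
}

#' Default three-locus set emulating the study design
#'
#' One 896-bp mitochondrial locus (0.01 substitutions/site/lineage/My) and
#' two nuclear loci: a 601-bp exon (0.0043) and a 518-bp intron (0.0087).
#'
#' @return A [locus_set()] data.frame.
#' @export
default_locus_set <- function() {
  locus_set(name = c("mt1", "nuc1", "nuc2"),
            length = c(896L, 601L, 518L),
            rate = c(0.01, 0.0043, 0.0087),
            inheritance = c(0.25, 1, 1),
            ploidy = c("mitochondrial", "nuclear", "nuclear"))
}

#' Specify a demographic model
#'
#' @param theta named vector of per-deme `theta_i = 4 N_e mu` on the
#'   reference-locus scale; names are the deme labels. The first deme is the
#'   reference for time scaling.
#' @param mig square migration matrix `M_ij = 4 N_e m` (zero diagonal),
#'   rows/cols in deme order; `NULL` for a single deme or full isolation.
#' @param splits optional `data.frame(time, from, to)`: population merges
#'   (backwards in time) at `time` in `4 N_e` units, moving deme `from` into
#'   deme `to`; times must increase. The ancestral deme takes the arithmetic
#'   mean of the two child thetas.
#' @param root_cap forced root join time (`4 N_e` units) joining all demes
#'   that remain after the splits; required for configurations whose
#'   migration graph cannot bring every lineage pair together.
#' @param loci a [locus_set()] (defaults to [default_locus_set()]).
#' @return An object of class `demographic_model`.
#' @export
demographic_model <- function(theta, mig = NULL, splits = NULL, root_cap = NULL,
                              loci = default_locus_set()) {
  if (is.null(names(theta))) names(theta) <- paste0("D", seq_along(theta))
  d <- length(theta)
  if (any(theta <= 0)) stop("theta must be positive")
  if (is.null(mig)) mig <- matrix(0, d, d)
  mig <- as.matrix(mig)
  if (!all(dim(mig) == d)) stop("migration matrix dimension mismatch")
  diag(mig) <- 0
  if (any(mig < 0)) stop("migration rates must be >= 0")
  dimnames(mig) <- list(names(theta), names(theta))
  if (!is.null(splits)) {
    stopifnot(all(c("time", "from", "to") %in% names(splits)))
    if (is.unsorted(splits$time, strictly = FALSE))
      stop("split times must be increasing into the past")
    if (any(splits$time <= 0)) stop("split times must be positive")
  }
  structure(list(theta = theta, mig = mig, splits = splits,
                 root_cap = root_cap, loci = loci, labels = names(theta)),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  routes <- which(x$mig > 0 & upper.tri(x$mig) | t(x$mig) > 0 & upper.tri(x$mig),
                  arr.ind = TRUE)
  cat(sprintf("<demographic_model> %d deme(s): %s\n", length(x$theta),
              paste(sprintf("%s (theta=%.3g)", x$labels, x$theta), collapse = ", ")))
  if (nrow(routes)) {
    for (k in seq_len(nrow(routes))) {
      i <- routes[k, 1]; j <- routes[k, 2]
      cat(sprintf("  route %s<->%s: M = %.3g / %.3g\n", x$labels[i], x$labels[j],
                  x$mig[i, j], x$mig[j, i]))
    }
  }
  if (!is.null(x$splits))
    for (k in seq_len(nrow(x$splits)))
      cat(sprintf("  split: %s -> %s at tau = %.4g\n",
                  x$splits$from[k], x$splits$to[k], x$splits$time[k]))
  if (!is.null(x$root_cap)) cat(sprintf("  root cap at tau = %.4g\n", x$root_cap))
  invisible(x)
}

#' Check whether a model terminates without a forced root join
#'
#' Graph reachability over bidirectionalised migration routes plus split
#' merges: the model terminates iff every deme pair ends up in a single
#' component.
#'
#' @param model a `demographic_model`.
#' @return `"terminating"` or `"needs_root_cap"`.
#' @export
isolation_check <- function(model) {
  d <- length(model$theta)
  parent <- seq_len(d)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) parent[find(i)] <<- find(j)
  for (i in seq_len(d)) for (j in seq_len(d))
    if (i != j && (model$mig[i, j] > 0 || model$mig[j, i] > 0)) union2(i, j)
  if (!is.null(model$splits))
    for (k in seq_len(nrow(model$splits)))
      union2(match(model$splits$from[k], model$labels),
             match(model$splits$to[k], model$labels))
  roots <- unique(vapply(seq_len(d), find, 0L))
  if (length(roots) == 1L) "terminating" else "needs_root_cap"
}

# compile merge-event schedule (internal time units) and base relative sizes
.compile_schedule <- function(model) {
  labels <- model$labels
  theta <- model$theta
  theta_ref <- theta[1L]
  alive <- rep(TRUE, length(theta))
  ev_time <- ev_x <- numeric(0)
  ev_from <- ev_to <- integer(0)
  if (!is.null(model$splits)) {
    for (k in seq_len(nrow(model$splits))) {
      fi <- match(model$splits$from[k], labels)
      ti <- match(model$splits$to[k], labels)
      if (is.na(fi) || is.na(ti)) stop("split references unknown deme")
      if (!alive[fi] || !alive[ti]) stop("split references an already merged deme")
      anc <- mean(c(theta[fi], theta[ti]))
      theta[ti] <- anc
      alive[fi] <- FALSE
      ev_time <- c(ev_time, 2 * model$splits$time[k])
      ev_from <- c(ev_from, fi - 1L)
      ev_to <- c(ev_to, ti - 1L)
      ev_x <- c(ev_x, anc / theta_ref)
    }
  }
  if (sum(alive) > 1L) {
    if (is.null(model$root_cap)) {
      if (isolation_check(model) == "needs_root_cap")
        stop("configuration error: non-terminating model without root_cap")
    } else {
      rem <- which(alive)
      anc <- mean(theta[rem])
      t_cap <- 2 * model$root_cap
      if (length(ev_time) && t_cap < max(ev_time))
        stop("root_cap earlier than the last split")
      for (d0 in rem[-1L]) {
        ev_time <- c(ev_time, t_cap)
        ev_from <- c(ev_from, d0 - 1L)
        ev_to <- c(ev_to, rem[1L] - 1L)
        ev_x <- c(ev_x, anc / theta_ref)
      }
    }
  }
  list(x_base = unname(model$theta / theta_ref),
       ev_time = ev_time, ev_from = ev_from, ev_to = ev_to, ev_x = ev_x)
}

# resolve group->deme mapping and per-locus haplotype counts
.sample_plan <- function(model, sample_sizes, group_deme = NULL) {
  loci <- model$loci
  if (is.vector(sample_sizes)) {
    # individuals per group: expand by ploidy per locus
    groups <- names(sample_sizes)
    if (is.null(groups)) groups <- model$labels[seq_along(sample_sizes)]
    counts <- t(vapply(seq_len(nrow(loci)), function(l) {
      mult <- if (loci$ploidy[l] == "nuclear") 2L else 1L
      as.integer(sample_sizes * mult)
    }, integer(length(sample_sizes))))
    dimnames(counts) <- list(loci$name, groups)
  } else {
    counts <- as.matrix(sample_sizes)
    if (is.null(colnames(counts))) colnames(counts) <- model$labels[seq_len(ncol(counts))]
    if (nrow(counts) != nrow(loci)) stop("sample size matrix needs one row per locus")
    rownames(counts) <- loci$name
  }
  groups <- colnames(counts)
  if (is.null(group_deme)) {
    group_deme <- setNames(groups, groups)
  }
  deme_idx <- match(unname(group_deme[groups]), model$labels)
  if (anyNA(deme_idx)) stop("group mapped to unknown deme")
  list(counts = counts, groups = groups, deme_idx = deme_idx)
}

#' Sample a genealogy under a demographic model
#'
#' @param model a `demographic_model`.
#' @param sample_sizes named vector of sampled lineages per deme (for this
#'   genealogy; no ploidy expansion is applied).
#' @param locus row index into `model$loci` whose inheritance scalar applies
#'   (default 1).
#' @return List with `parent` (1-based, `NA` at root), `node_time`
#'   (internal units), `leaf_deme`, `tmrca`, `total_length`.
#' @export
sample_genealogy <- function(model, sample_sizes, locus = 1L) {
  sched <- .compile_schedule(model)
  inh <- model$loci$inheritance[locus] / model$loci$inheritance[1L]
  plan <- .sample_plan(model, matrix(sample_sizes, nrow = nrow(model$loci),
                                     ncol = length(sample_sizes), byrow = TRUE,
                                     dimnames = list(model$loci$name,
                                                     names(sample_sizes))))
  res <- cpp_sim_locus(as.integer(plan$counts[locus, ]),
                       as.integer(plan$deme_idx - 1L),
                       sched$x_base * inh, model$mig,
                       sched$ev_time, as.integer(sched$ev_from),
                       as.integer(sched$ev_to), sched$ev_x * inh,
                       0.0, FALSE, TRUE)
  parent <- res$parent + 1L
  parent[parent == 0L] <- NA_integer_
  list(parent = parent, node_time = res$node_time,
       leaf_deme = plan$groups[rep(seq_along(plan$groups),
                                   plan$counts[locus, ])],
       tmrca = res$tmrca, total_length = res$total_length)
}

#' Simulate a multilocus dataset (or its summary statistics)
#'
#' Independent genealogies per locus; locus `l` uses relative mutation rate
#' `r_l` and its inheritance scalar. Statistics are returned on the
#' per-locus-total infinite-sites scale used throughout the ABC engine.
#'
#' @param model a `demographic_model`.
#' @param sample_sizes either a named vector of individuals per sampling
#'   group (ploidy-expanded per locus) or a matrix of haplotype counts with
#'   one row per locus and one column per group.
#' @param group_deme optional named map from sampling group to model deme
#'   (used by collapsed models where several groups share a deme).
#' @param want_matrix also return the 0/1 haplotype matrices.
#' @return List with `stats` (per locus: `S`, `pi`, `pi_within`, `dxy`,
#'   `n`, ...), `groups`, and (optionally) `genotypes` per locus.
#' @export
simulate_dataset <- function(model, sample_sizes, group_deme = NULL,
                             want_matrix = FALSE) {
  sched <- .compile_schedule(model)
  plan <- .sample_plan(model, sample_sizes, group_deme)
  theta_ref <- model$theta[[1L]]
  loci <- model$loci
  stats <- vector("list", nrow(loci))
  names(stats) <- loci$name
  for (l in seq_len(nrow(loci))) {
    inh <- loci$inheritance[l] / loci$inheritance[1L]
    res <- cpp_sim_locus(as.integer(plan$counts[l, ]),
                         as.integer(plan$deme_idx - 1L),
                         sched$x_base * inh, model$mig,
                         sched$ev_time, as.integer(sched$ev_from),
                         as.integer(sched$ev_to), sched$ev_x * inh,
                         theta_ref * loci$rel_rate[l], want_matrix, FALSE)
    res$pi_within <- setNames(res$pi_within, plan$groups)
    if (length(plan$groups) > 1L)
      names(res$dxy) <- combn(plan$groups, 2L, paste, collapse = "-")
    stats[[l]] <- res
  }
  out <- list(stats = stats, groups = plan$groups, counts = plan$counts)
  if (want_matrix) {
    out$genotypes <- lapply(stats, function(s) s$genotypes)
    out$leaf_group <- lapply(stats, function(s) plan$groups[s$leaf_group])
    out$stats <- lapply(stats, function(s) s[c("S", "pi", "pi_within", "dxy",
                                               "n", "tmrca", "total_length")])
  }
  out
}

#' Summary-statistic vector of a simulated dataset
#'
#' @param sim output of [simulate_dataset()].
#' @param locus_names,deme_labels optional overrides for the names used.
#' @return A `summary_stat_vector` aligned with [summary_vector()].
#' @export
sim_summary_vector <- function(sim, locus_names = names(sim$stats),
                               deme_labels = sim$groups) {
  summary_vector_from_stats(sim$stats, locus_names, deme_labels)
}
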