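#' @title Spatially explicit Bayesian clustering
#' @name spatial_cluster
#' @description Discovery of biogeographical units (BUs) by MCMC over a
#'   coloured Voronoi tessellation: nuclei follow a Poisson(lambda) prior in
#'   the bounding box, each nucleus carries one of `K_max` colours,
#'   individuals inherit the colour of their nearest nucleus, and per-colour
#'   allele frequencies (haplotype classes per locus) are integrated out
#'   analytically under Dirichlet(1, ..., 1) priors — the uncorrelated
#'   allele-frequencies model. The number of occupied colours ("effective
#'   K") is reported; its posterior is the posterior over the number of
#'   units.
#'
#'   Every locus is modelled with at least two allele classes: an apparently
#'   monomorphic locus keeps one unobserved-allele slot in the Dirichlet
#'   prior, so that it still contributes the Bayesian-Occam penalty against
#'   spurious subdivision instead of a perfectly flat likelihood.
NULL

#' Configuration for the clustering MCMC
#'
#' @param K_max maximum number of colours (default 10).
#' @param n_iter MCMC iterations (default 1e6).
#' @param thinning keep every `thinning`-th iteration (default 1e3).
#' @param burn_in fraction of the thinned trace discarded (default 0.1).
#' @param lambda Poisson prior mean on the number of nuclei; default twice
#'   the number of sampling sites (set when the data are seen).
#' @param rng_seed RNG seed; runs are fully reproducible given the seed.
#' @param bbox optional bounding box `c(xmin, xmax, ymin, ymax)` in
#'   lon/lat; default is the data range padded by 10%.
#' @return List of class `cluster_config`.
#' @export
cluster_config <- function(K_max = 10L, n_iter = 1e6, thinning = 1e3,
                           burn_in = 0.1, lambda = NULL, rng_seed = 1L,
                           bbox = NULL) {
  stopifnot(K_max >= 1L, n_iter >= thinning, is.null(lambda) || lambda > 0)
  structure(list(K_max = as.integer(K_max), n_iter = as.integer(n_iter),
                 thinning = as.integer(thinning), burn_in = burn_in,
                 lambda = lambda, rng_seed = rng_seed, bbox = bbox),
            class = "cluster_config")
}

# per-locus copy-level allele data for the collapsed likelihood
.allele_data <- function(alignments, ind_ids) {
  lapply(alignments, function(aln) {
    cls <- haplotype_classes(aln)
    idx <- match(aln$individual_id, ind_ids)
    keep <- !is.na(idx)
    list(ind = idx[keep], allele = cls[keep],
         A = max(max(cls), 2L))  # >= 2 allele classes, see module notes
  })
}

# collapsed Dirichlet-multinomial log marginal likelihood of a colouring
.cluster_loglik <- function(col_of_ind, ad, K_max) {
  ll <- 0
  for (l in ad) {
    cnt <- tabulate(col_of_ind[l$ind] + K_max * (l$allele - 1L),
                    nbins = K_max * l$A)
    dim(cnt) <- c(K_max, l$A)
    nc <- .rowSums(cnt, K_max, l$A)
    ll <- ll + sum(lgamma(l$A) - lgamma(l$A + nc)) + sum(lgamma(1 + cnt))
  }
  ll
}

#' Run the tessellation MCMC
#'
#' Moves: nucleus relocation (uniform in the box), nucleus recolouring
#' (uniform colour), and nucleus birth/death under the Poisson(lambda)
#' prior, each accepted by Metropolis-Hastings on the collapsed likelihood.
#'
#' @param alignments list of `haplotype_alignment`s; haplotype classes per
#'   locus are the alleles (mtDNA one copy per individual, nuclear two).
#' @param sample_table validated sample table georeferencing every
#'   individual.
#' @param config a [cluster_config()].
#' @return Object of class `cluster_trace`: retained iterations with nuclei,
#'   colours, per-individual colours, effective K and log posterior.
#' @export
run_mcmc <- function(alignments, sample_table, config = cluster_config()) {
  ind_ids <- sort(unique(unlist(lapply(alignments, function(a) a$individual_id))))
  if (length(ind_ids) < 2L) stop("degenerate input: need >= 2 individuals")
  loc <- match(ind_ids, sample_table$individual_id)
  if (anyNA(loc))
    stop("individuals without coordinates: ",
         paste(head(ind_ids[is.na(loc)]), collapse = ", "))
  xy <- cbind(sample_table$lon[loc], sample_table$lat[loc])
  ad <- .allele_data(alignments, ind_ids)
  n <- length(ind_ids)
  K <- config$K_max

  set.seed(config$rng_seed)
  lambda <- if (is.null(config$lambda)) 2 * length(unique(sample_table$site_id))
            else config$lambda
  bbox <- config$bbox
  if (is.null(bbox)) {
    rx <- range(xy[, 1L]); ry <- range(xy[, 2L])
    px <- max(diff(rx), 1e-6) * 0.1; py <- max(diff(ry), 1e-6) * 0.1
    bbox <- c(rx[1L] - px, rx[2L] + px, ry[1L] - py, ry[2L] + py)
  }
  m_max <- max(20L, as.integer(lambda + 8 * sqrt(lambda)))

  nuc_xy <- cbind(runif(m_max, bbox[1L], bbox[2L]), runif(m_max, bbox[3L], bbox[4L]))
  nuc_col <- sample.int(K, m_max, replace = TRUE)
  active <- c(rep(TRUE, max(1L, round(lambda))), rep(FALSE, m_max - max(1L, round(lambda))))
  dmat <- outer(xy[, 1L], nuc_xy[, 1L], "-")^2 + outer(xy[, 2L], nuc_xy[, 2L], "-")^2

  nearest <- function() {
    act <- which(active)
    act[max.col(-dmat[, act, drop = FALSE], ties.method = "first")]
  }
  nn <- nearest()
  colind <- nuc_col[nn]
  ll <- .cluster_loglik(colind, ad, K)

  n_keep <- config$n_iter %/% config$thinning
  first_keep <- ceiling(config$burn_in * n_keep) + 1L
  kept <- 0L
  tr_cols <- matrix(0L, n, max(0L, n_keep - first_keep + 1L))
  tr_effK <- integer(ncol(tr_cols))
  tr_ll <- numeric(ncol(tr_cols))
  tr_nuclei <- vector("list", ncol(tr_cols))

  for (it in seq_len(config$n_iter)) {
    move <- runif(1)
    m <- sum(active)
    if (move < 0.35) {                       # relocate
      j <- which(active)[sample.int(m, 1L)]
      old_col_j <- dmat[, j]
      prop <- c(runif(1, bbox[1L], bbox[2L]), runif(1, bbox[3L], bbox[4L]))
      dmat[, j] <- (xy[, 1L] - prop[1L])^2 + (xy[, 2L] - prop[2L])^2
      nn2 <- nearest(); ci2 <- nuc_col[nn2]
      ll2 <- if (identical(ci2, colind)) ll else .cluster_loglik(ci2, ad, K)
      if (log(runif(1)) < ll2 - ll) {
        nuc_xy[j, ] <- prop; nn <- nn2; colind <- ci2; ll <- ll2
      } else dmat[, j] <- old_col_j
    } else if (move < 0.70) {                # recolour
      j <- which(active)[sample.int(m, 1L)]
      newc <- sample.int(K, 1L)
      if (newc != nuc_col[j]) {
        ci2 <- colind
        ci2[nn == j] <- newc
        ll2 <- if (any(nn == j)) .cluster_loglik(ci2, ad, K) else ll
        if (log(runif(1)) < ll2 - ll) {
          nuc_col[j] <- newc; colind <- ci2; ll <- ll2
        }
      }
    } else if (move < 0.85) {                # birth
      free <- which(!active)
      if (length(free)) {
        j <- free[1L]
        prop <- c(runif(1, bbox[1L], bbox[2L]), runif(1, bbox[3L], bbox[4L]))
        newc <- sample.int(K, 1L)
        dmat[, j] <- (xy[, 1L] - prop[1L])^2 + (xy[, 2L] - prop[2L])^2
        active[j] <- TRUE
        nn2 <- nearest(); ci2 <- nuc_col[nn2]
        ci2[nn2 == j] <- newc
        ll2 <- .cluster_loglik(ci2, ad, K)
        if (log(runif(1)) < ll2 - ll + log(lambda / (m + 1))) {
          nuc_xy[j, ] <- prop; nuc_col[j] <- newc; nn <- nn2; colind <- ci2; ll <- ll2
        } else active[j] <- FALSE
      }
    } else {                                 # death
      if (m >= 2L) {
        j <- which(active)[sample.int(m, 1L)]
        active[j] <- FALSE
        nn2 <- nearest(); ci2 <- nuc_col[nn2]
        ll2 <- if (identical(ci2, colind)) ll else .cluster_loglik(ci2, ad, K)
        if (log(runif(1)) < ll2 - ll + log(m / lambda)) {
          nn <- nn2; colind <- ci2; ll <- ll2
        } else active[j] <- TRUE
      }
    }
    if (!is.finite(ll))
      stop("internal error: non-finite likelihood (m = ", sum(active), ")")

    if (it %% config$thinning == 0L) {
      idx <- it %/% config$thinning
      if (idx >= first_keep) {
        kept <- kept + 1L
        tr_cols[, kept] <- colind
        tr_effK[kept] <- length(unique(colind))
        tr_ll[kept] <- ll + dpois(sum(active), lambda, log = TRUE)
        act <- which(active)
        tr_nuclei[[kept]] <- list(xy = nuc_xy[act, , drop = FALSE],
                                  col = nuc_col[act])
      }
    }
  }

  structure(list(ind_ids = ind_ids, coords = xy, bbox = bbox,
                 K_max = K, lambda = lambda, config = config,
                 cols = tr_cols[, seq_len(kept), drop = FALSE],
                 effK = tr_effK[seq_len(kept)], log_post = tr_ll[seq_len(kept)],
                 nuclei = tr_nuclei[seq_len(kept)]),
            class = "cluster_trace")
}

#' @export
print.cluster_trace <- function(x, ...) {
  pk <- posterior_K(x)
  cat(sprintf("<cluster_trace> %d retained iterations, %d individuals; modal K = %s (PP = %.2f)\n",
              length(x$effK), length(x$ind_ids),
              names(pk)[which.max(pk)], max(pk)))
  invisible(x)
}

#' Posterior distribution of the effective number of units K
#'
#' @param trace a `cluster_trace`.
#' @return Named numeric vector of posterior probabilities over effective K.
#' @export
posterior_K <- function(trace) {
  if (!length(trace$effK)) stop("input error: empty trace")
  tab <- table(factor(trace$effK, levels = seq_len(trace$K_max)))
  p <- as.numeric(tab) / sum(tab)
  names(p) <- seq_len(trace$K_max)
  p[p > 0 | seq_along(p) <= max(trace$effK)]
}

# per-iteration colour relabelling by greedy maximum-overlap matching
# against the highest-posterior iteration; returns aligned colour matrix
.align_trace <- function(trace) {
  ref <- trace$cols[, which.max(trace$log_post)]
  K <- trace$K_max
  maps <- vector("list", ncol(trace$cols))
  aligned <- trace$cols
  for (t in seq_len(ncol(trace$cols))) {
    cur <- trace$cols[, t]
    overlap <- table(factor(cur, levels = 1:K), factor(ref, levels = 1:K))
    map <- integer(K)
    free_rows <- rep(TRUE, K); free_cols <- rep(TRUE, K)
    while (any(free_rows) && any(free_cols) && max(overlap[free_rows, free_cols]) > 0) {
      sub <- which(overlap == max(overlap[free_rows, free_cols]), arr.ind = TRUE)
      sub <- sub[free_rows[sub[, 1L]] & free_cols[sub[, 2L]], , drop = FALSE]
      i <- sub[1L, 1L]; j <- sub[1L, 2L]
      map[i] <- j
      free_rows[i] <- FALSE; free_cols[j] <- FALSE
    }
    leftover <- which(map == 0L)
    map[leftover] <- which(free_cols)[seq_along(leftover)]
    maps[[t]] <- map
    aligned[, t] <- map[cur]
  }
  list(aligned = aligned, maps = maps)
}

#' Modal partition and co-assignment matrix
#'
#' Colours are aligned across iterations by greedy maximum-overlap matching
#' to the highest-posterior iteration; each individual is then assigned its
#' most frequent aligned colour. The label-free co-assignment matrix (the
#' fraction of iterations in which two individuals share a colour) is
#' attached as attribute `"coassignment"`.
#'
#' @param trace a `cluster_trace`.
#' @return Named vector mapping `individual_id` to a cluster label.
#' @export
modal_partition <- function(trace) {
  if (!length(trace$effK)) stop("input error: empty trace")
  al <- .align_trace(trace)$aligned
  modal <- apply(al, 1L, function(v) {
    tab <- tabulate(v, nbins = trace$K_max)
    which.max(tab)
  })
  co <- matrix(0, nrow(al), nrow(al))
  for (t in seq_len(ncol(al))) co <- co + outer(al[, t], al[, t], "==")
  co <- co / ncol(al)
  dimnames(co) <- list(trace$ind_ids, trace$ind_ids)
  # renumber the surviving colours BU1..BUk by decreasing unit size
  sizes <- sort(table(modal), decreasing = TRUE)
  relab <- setNames(paste0("BU", seq_along(sizes)), names(sizes))
  out <- setNames(unname(relab[as.character(modal)]), trace$ind_ids)
  attr(out, "coassignment") <- co
  out
}

#' Posterior membership surface over a spatial grid
#'
#' For every grid cell, the fraction of retained iterations in which the
#' cell's nearest nucleus carries each aligned colour.
#'
#' @param trace a `cluster_trace`.
#' @param grid_spec list with `nx`, `ny` (grid resolution; default 50 x 50).
#' @return List of class `membership_surface`: `x`, `y` cell-centre
#'   coordinates and `prob`, an `nx*ny x K_max` matrix whose rows sum to 1.
#' @export
membership_surface <- function(trace, grid_spec = list(nx = 50L, ny = 50L)) {
  if (is.null(grid_spec$nx) || is.null(grid_spec$ny) ||
      grid_spec$nx < 1L || grid_spec$ny < 1L)
    stop("input error: empty grid")
  al <- .align_trace(trace)
  bb <- trace$bbox
  gx <- seq(bb[1L], bb[2L], length.out = grid_spec$nx)
  gy <- seq(bb[3L], bb[4L], length.out = grid_spec$ny)
  cells <- cbind(rep(gx, times = grid_spec$ny), rep(gy, each = grid_spec$nx))
  prob <- matrix(0, nrow(cells), trace$K_max)
  for (t in seq_along(trace$nuclei)) {
    nu <- trace$nuclei[[t]]
    d <- outer(cells[, 1L], nu$xy[, 1L], "-")^2 + outer(cells[, 2L], nu$xy[, 2L], "-")^2
    ncol_cell <- al$maps[[t]][nu$col[max.col(-d, ties.method = "first")]]
    prob[cbind(seq_len(nrow(cells)), ncol_cell)] <-
      prob[cbind(seq_len(nrow(cells)), ncol_cell)] + 1
  }
  prob <- prob / length(trace$nuclei)
  structure(list(x = gx, y = gy, prob = prob, K_max = trace$K_max),
            class = "membership_surface")
}
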