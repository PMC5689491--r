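#' @title GENPOFAD multilocus distances and isolation by distance
#' @name distmat
#' @description Individual-level GENPOFAD distances per locus, their
#'   standardised multilocus combination, aggregation to sampling sites,
#'   great-circle geographic distances, and the Mantel permutation test of
#'   isolation by distance (IBD).
NULL

# bitmask encoding of IUPAC state sets: A=1, C=2, G=4, T=8; N/- = 0 (missing)
.iupac_masks <- local({
  m <- integer(0)
  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  for (code in names(IUPAC_SETS)) m[code] <- sum(bit[IUPAC_SETS[[code]]])
  m["N"] <- 0L
  m["-"] <- 0L
  m
})
.popcount4 <- vapply(0:15, function(v) sum(bitwAnd(v, c(1L, 2L, 4L, 8L)) > 0L), 0L)

# per-individual genotype state-set masks at every site of one locus:
# union of the 1-2 haplotype masks (list: one integer matrix per individual)
.genotype_masks <- function(aln) {
  masks <- matrix(.iupac_masks[aln$seq], nrow = nrow(aln$seq))
  ids <- unique(aln$individual_id)
  out <- matrix(0L, length(ids), ncol(masks), dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    rows <- which(aln$individual_id == ids[i])
    v <- masks[rows[1L], ]
    if (length(rows) > 1L) v <- bitwOr(v, masks[rows[2L], ])
    out[i, ] <- v
  }
  out
}

#' GENPOFAD distance between two genotypes at one locus
#'
#' Per usable site, with `A` and `B` the nucleotide state sets of the two
#' individuals (IUPAC codes decomposed, heterozygous copies pooled), the
#' site distance is `1 - |A intersect B| / max(|A|, |B|)`; the locus
#' distance is the mean over usable sites. Sites where either individual is
#' missing (`N`/gap in all copies) are skipped pairwise.
#'
#' @param maskA,maskB integer vectors of per-site state-set bitmasks
#'   (`A=1, C=2, G=4, T=8`), as produced internally from an alignment.
#' @return Distance in `[0, 1]`.
#' @export
genpofad_site_mean <- function(maskA, maskB) {
  usable <- maskA > 0L & maskB > 0L
  if (!any(usable)) stop("degenerate input: no usable sites shared by the pair")
  a <- maskA[usable]; b <- maskB[usable]
  inter <- .popcount4[bitwAnd(a, b) + 1L]
  mx <- pmax(.popcount4[a + 1L], .popcount4[b + 1L])
  mean(1 - inter / mx)
}

#' Per-locus GENPOFAD distance matrix over individuals
#'
#' @param aln a `haplotype_alignment`.
#' @return Symmetric matrix (zero diagonal) over the individuals of `aln`,
#'   entries in `[0, 1]`.
#' @export
genpofad_locus_matrix <- function(aln) {
  gm <- .genotype_masks(aln)
  ids <- rownames(gm)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- genpofad_site_mean(gm[i, ], gm[j, ])
  }
  D
}

#' Combine per-locus distance matrices into a multilocus matrix
#'
#' Each locus matrix is optionally divided by its maximum entry (the POFAD
#' standardisation), then matrices are averaged element-wise. Individuals
#' missing from a locus (for example, individuals without mtDNA) are
#' averaged over the loci at which both members of a pair are typed.
#'
#' @param matrices list of square labelled matrices; labels may differ
#'   across loci, but every individual pair must be co-typed at >= 1 locus.
#' @param standardize divide each matrix by its maximum before averaging.
#' @return Combined symmetric distance matrix over the label union.
#' @export
combine_locus_matrices <- function(matrices, standardize = TRUE) {
  if (length(matrices) < 1L) stop("need at least one matrix")
  labs <- sort(unique(unlist(lapply(matrices, rownames))))
  acc <- cnt <- matrix(0, length(labs), length(labs),
                       dimnames = list(labs, labs))
  for (m in matrices) {
    if (standardize && max(m) > 0) m <- m / max(m)
    i <- match(rownames(m), labs)
    acc[i, i] <- acc[i, i] + m
    cnt[i, i] <- cnt[i, i] + 1
  }
  if (any(cnt == 0))
    stop("input error: label sets differ between locus matrices ",
         "(some individual pair is never co-typed)")
  acc / cnt
}

#' Aggregate an individual distance matrix to sampling sites
#'
#' Site-pair distance is the mean over all cross-site individual pairs;
#' the diagonal is zero.
#'
#' @param indiv_matrix symmetric matrix over individual ids.
#' @param sample_table validated sample table mapping individuals to sites.
#' @return Symmetric matrix over `site_id`s.
#' @export
site_level_matrix <- function(indiv_matrix, sample_table) {
  ids <- rownames(indiv_matrix)
  site <- sample_table$site_id[match(ids, sample_table$individual_id)]
  if (anyNA(site)) stop("input error: individuals missing from sample table")
  sites <- sort(unique(sample_table$site_id))
  if (!all(sites %in% site)) {
    missing <- setdiff(sites, site)
    stop("input error: site(s) with no individuals in the matrix: ",
         paste(missing, collapse = ", "))
  }
  D <- matrix(0, length(sites), length(sites), dimnames = list(sites, sites))
  for (i in seq_along(sites)) for (j in seq_along(sites)) if (i < j) {
    a <- which(site == sites[i]); b <- which(site == sites[j])
    D[i, j] <- D[j, i] <- mean(indiv_matrix[a, b])
  }
  D
}

#' Great-circle distance matrix between sampling sites (km)
#'
#' Haversine distances on a sphere of radius 6371 km, from the mean
#' coordinates of the individuals at each site.
#'
#' @param sample_table validated sample table.
#' @return Symmetric matrix over `site_id`s, in kilometres.
#' @export
geographic_distance_matrix <- function(sample_table) {
  sites <- sort(unique(sample_table$site_id))
  coord <- t(vapply(sites, function(s) {
    rows <- sample_table$site_id == s
    c(lon = mean(sample_table$lon[rows]), lat = mean(sample_table$lat[rows]))
  }, c(lon = 0.0, lat = 0.0)))
  D <- matrix(0, length(sites), length(sites), dimnames = list(sites, sites))
  for (i in seq_along(sites)) for (j in seq_along(sites)) if (i < j) {
    d <- geosphere::distHaversine(coord[i, ], coord[j, ], r = 6371000) / 1000
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Mantel test of matrix association
#'
#' Pearson correlation of the off-diagonal entries after an optional
#' transform, with a one-tailed (positive-association) permutation p-value
#' `p = (1 + #\{permuted r >= observed r\}) / (n_perm + 1)` from joint
#' row/column shuffles of one matrix. For the IBD screen both matrices are
#' log10-transformed; zero distances are replaced by half the smallest
#' positive entry of their matrix before taking logs.
#'
#' @param matA,matB symmetric matrices with identical labels.
#' @param n_perm number of permutations (default 10000).
#' @param transform `"log10"` or `"none"`.
#' @param rng_seed optional seed for reproducible permutations.
#' @return List of class `mantel_result`: `r`, `r_squared`, `p`, `n_perm`.
#' @export
mantel_test <- function(matA, matB, n_perm = 10000, transform = c("none", "log10"),
                        rng_seed = NULL) {
  transform <- match.arg(transform)
  if (!identical(rownames(matA), rownames(matB))) {
    if (!setequal(rownames(matA), rownames(matB)))
      stop("input error: matrices have different labels")
    matB <- matB[rownames(matA), rownames(matA)]
  }
  if (n_perm < 1) stop("n_perm must be >= 1")
  tf <- function(m) {
    if (transform == "none") return(m)
    v <- m[upper.tri(m)]
    pos <- v[v > 0]
    if (!length(pos)) stop("undefined statistic: all off-diagonal entries are zero")
    repl <- min(pos) / 2
    m[m <= 0] <- repl
    log10(m)
  }
  A <- tf(matA); B <- tf(matB)
  if (var(A[upper.tri(A)]) == 0 || var(B[upper.tri(B)]) == 0)
    stop("undefined statistic: zero variance in a distance triangle")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  fit <- vegan::mantel(as.dist(A), as.dist(B), method = "pearson",
                       permutations = n_perm)
  structure(list(r = unname(fit$statistic),
                 r_squared = unname(fit$statistic)^2,
                 p = fit$signif, n_perm = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f (r^2 = %.4f), one-tailed p = %.4g (%d permutations)\n",
              x$r, x$r_squared, x$p, x$n_perm))
  invisible(x)
}

#' Write a labelled square distance matrix as TSV
#' @param mat symmetric labelled matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(mat, path) {
  write.table(cbind(id = rownames(mat), as.data.frame(mat)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled square distance matrix from TSV
#' @param path TSV written by [write_distance_matrix()].
#' @return Symmetric labelled matrix.
#' @export
read_distance_matrix <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  m
}
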