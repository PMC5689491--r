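#' @title Population-genetic summary statistics
#' @name popstats
#' @description Segregating sites, haplotype and nucleotide diversity,
#'   Tajima's D and between-deme divergence, computed over globally masked
#'   alignment columns (complete deletion of any column carrying a gap, `N`
#'   or an IUPAC ambiguity). The same statistic set, stacked into a fixed
#'   ordering, is the summary vector consumed by the ABC engine.
NULL

# 4 x L matrix of base counts per column (assumes masked, ACGT-only input)
.base_counts <- function(mat) {
  apply(mat, 2L, function(col) tabulate(match(col, DNA_BASES), 4L))
}

.masked <- function(aln, policy = "complete") {
  keep <- usable_columns(aln$seq, policy)
  if (!any(keep)) stop("degenerate input: no usable (unmasked) columns")
  aln$seq[, keep, drop = FALSE]
}

#' Number of segregating sites
#'
#' @param aln a `haplotype_alignment` (or character matrix of masked sites).
#' @return Count of unmasked columns with at least two distinct states.
#' @export
segregating_sites <- function(aln) {
  mat <- if (is.matrix(aln)) aln else .masked(aln)
  if (nrow(mat) < 2L) stop("degenerate input: need >= 2 sequences")
  cnt <- .base_counts(mat)
  sum(colSums(cnt > 0L) >= 2L)
}

#' Haplotype count and haplotype diversity
#'
#' `Hd = n (1 - sum p_i^2) / (n - 1)` over haplotype frequencies `p_i`
#' (Nei's unbiased gene diversity on haplotype classes).
#'
#' @param aln a `haplotype_alignment`.
#' @param site_mask_policy see [usable_columns()].
#' @return List with `h` (unique haplotypes) and `Hd` in `[0, 1]`.
#' @export
haplotype_diversity <- function(aln, site_mask_policy = "complete") {
  if (n_sequences(aln) < 2L) stop("degenerate input: need >= 2 sequences")
  hap <- collapse_haplotypes(aln, site_mask_policy)
  n <- sum(hap$count)
  p <- hap$count / n
  list(h = nrow(hap), Hd = n * (1 - sum(p^2)) / (n - 1))
}

# mean pairwise difference count over all C(n,2) pairs (total, not per site)
.mean_pairwise_diffs <- function(mat) {
  n <- nrow(mat)
  cnt <- .base_counts(mat)
  same <- colSums(choose(cnt, 2L))
  sum(choose(n, 2L) - same) / choose(n, 2L)
}

#' Nucleotide diversity per site
#'
#' Mean pairwise difference count over all sequence pairs, divided by the
#' number of usable (unmasked) columns.
#'
#' @inheritParams segregating_sites
#' @return Per-site nucleotide diversity (>= 0).
#' @export
nucleotide_diversity <- function(aln) {
  mat <- if (is.matrix(aln)) aln else .masked(aln)
  if (nrow(mat) < 2L) stop("degenerate input: need >= 2 sequences")
  .mean_pairwise_diffs(mat) / ncol(mat)
}

#' Tajima's (1989) normalising constants
#' @param n sample size (number of sequences).
#' @return Named list of constants `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# D from totals; S = 0 yields the undefined flag rather than an error
.tajima_d_from_totals <- function(pi_total, S, n) {
  if (S < 1) return(list(D = NA_real_, defined = FALSE, S = S))
  k <- tajima_constants(n)
  D <- (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  list(D = D, defined = TRUE, S = S)
}

#' Tajima's D
#'
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the 1989 constants,
#' where `pi` is the mean pairwise difference count per locus (a total, not
#' per site). `S = 0` returns an undefined flag, not an error.
#'
#' @inheritParams segregating_sites
#' @return List with `D` (numeric, `NA` when undefined), `defined`, `S`.
#' @export
tajimas_d <- function(aln) {
  mat <- if (is.matrix(aln)) aln else .masked(aln)
  if (nrow(mat) < 2L) stop("degenerate input: need >= 2 sequences")
  cnt <- .base_counts(mat)
  S <- sum(colSums(cnt > 0L) >= 2L)
  .tajima_d_from_totals(.mean_pairwise_diffs(mat), S, nrow(mat))
}

#' Between-population divergence (dxy) per site
#'
#' Average number of nucleotide substitutions per site between two groups:
#' mean difference count over all cross-population sequence pairs, divided
#' by the usable length. Columns are masked jointly across both groups.
#'
#' @param alnA,alnB `haplotype_alignment`s of the same locus (or character
#'   matrices already restricted to a shared usable column set).
#' @return Per-site divergence (>= 0).
#' @export
dxy_between <- function(alnA, alnB) {
  if (is.matrix(alnA) && is.matrix(alnB)) {
    matA <- alnA; matB <- alnB
  } else {
    if (alnA$length != alnB$length)
      stop("alignments have different lengths; same locus required")
    keep <- usable_columns(rbind(alnA$seq, alnB$seq), "complete")
    if (!any(keep)) stop("degenerate input: no usable columns")
    matA <- alnA$seq[, keep, drop = FALSE]
    matB <- alnB$seq[, keep, drop = FALSE]
  }
  if (nrow(matA) < 1L || nrow(matB) < 1L)
    stop("degenerate input: empty group")
  cntA <- .base_counts(matA)
  cntB <- .base_counts(matB)
  nA <- nrow(matA); nB <- nrow(matB)
  diffs <- sum(nA * nB - colSums(cntA * cntB))
  diffs / (nA * nB) / ncol(matA)
}

# rows of an alignment belonging to each deme, demes in sorted label order
.deme_rows <- function(aln, demes) {
  lab <- demes[aln$individual_id]
  if (anyNA(lab))
    stop("individuals without deme assignment in locus ", aln$locus_name)
  split(seq_len(nrow(aln$seq)), factor(lab, levels = sort(unique(demes))))
}

#' Per-locus summary table (global and per deme)
#'
#' One row per unit (Total plus each deme) with `n`, `S`, `h`, `Hd`,
#' per-site `pi` and Tajima's D; pairwise per-site `dxy` between demes is
#' attached as attribute `"dxy"`.
#'
#' @param aln a `haplotype_alignment`.
#' @param demes named vector mapping `individual_id` to deme label.
#' @return A `data.frame` of class `locus_summary`.
#' @export
locus_summary <- function(aln, demes) {
  mat <- .masked(aln)
  rows <- .deme_rows(aln, demes)
  unit_stats <- function(idx, unit) {
    sub <- mat[idx, , drop = FALSE]
    hap <- aln
    hap$seq <- aln$seq[idx, , drop = FALSE]
    hap$individual_id <- aln$individual_id[idx]
    hap$copy_index <- aln$copy_index[idx]
    hd <- haplotype_diversity(hap)
    td <- .tajima_d_from_totals(.mean_pairwise_diffs(sub), segregating_sites(sub), nrow(sub))
    data.frame(locus = aln$locus_name, unit = unit, n = nrow(sub),
               S = td$S, h = hd$h, Hd = hd$Hd,
               pi = .mean_pairwise_diffs(sub) / ncol(sub),
               tajD = td$D, stringsAsFactors = FALSE)
  }
  out <- rbind(unit_stats(seq_len(nrow(mat)), "Total"),
               do.call(rbind, Map(unit_stats, rows, names(rows))))
  rownames(out) <- NULL
  labs <- names(rows)
  dxy <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(labs)) for (j in seq_along(labs)) if (i < j) {
    d <- dxy_between(mat[rows[[i]], , drop = FALSE], mat[rows[[j]], , drop = FALSE])
    dxy[i, j] <- dxy[j, i] <- d
  }
  diag(dxy) <- 0
  attr(out, "dxy") <- dxy
  class(out) <- c("locus_summary", class(out))
  out
}

#' Write per-locus summary tables as TSV
#' @param summaries list of [locus_summary()] tables.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summaries, path) {
  tab <- do.call(rbind, lapply(summaries, function(s) as.data.frame(unclass(s))))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Names of the summary-statistic vector, in its fixed documented order
#'
#' Order: per locus `(pi, S, D)`, then per locus x deme within-deme `pi`,
#' then per locus x deme-pair `dxy`. Loci keep dataset order; demes are
#' sorted by label; pairs follow [combn()] order over sorted demes. `pi` and
#' `dxy` here are per-locus totals (mean pairwise difference counts), the
#' scale on which infinite-sites coalescent simulations live.
#'
#' @param locus_names character vector of locus names.
#' @param deme_labels character vector of deme labels (will be sorted).
#' @return Character vector of statistic names, length
#'   `L*3 + L*d + L*choose(d,2)`.
#' @export
summary_vector_names <- function(locus_names, deme_labels) {
  d <- sort(unique(deme_labels))
  pairs <- if (length(d) > 1L) combn(d, 2L, paste, collapse = "-") else character()
  cross <- function(prefix, suffixes) {
    if (!length(suffixes)) return(character())
    as.vector(t(outer(locus_names, suffixes,
                      function(l, s) paste0(prefix, ".", l, ".", s))))
  }
  c(as.vector(t(outer(locus_names, c("pi", "S", "D"),
                      function(l, s) paste0(s, ".", l)))),
    cross("piw", d), cross("dxy", pairs))
}

#' Summary-statistic vector for the ABC engine
#'
#' Stacks per-locus statistics in the fixed order of
#' [summary_vector_names()]. Undefined Tajima's D (S = 0) is encoded as 0;
#' the positions of undefined entries are attached as the logical attribute
#' `"D_undefined"` so the vector length stays constant.
#'
#' @param alignments list of `haplotype_alignment`s (one per locus).
#' @param demes named vector mapping `individual_id` to deme label.
#' @return Named numeric vector of class `summary_stat_vector`.
#' @export
summary_vector <- function(alignments, demes) {
  locus_names <- vapply(alignments, function(a) a$locus_name, "")
  deme_labels <- sort(unique(demes))
  pi_v <- S_v <- D_v <- numeric(0)
  piw <- dxy <- numeric(0)
  D_undef <- logical(0)
  for (aln in alignments) {
    mat <- .masked(aln)
    rows <- .deme_rows(aln, demes)
    small <- names(rows)[lengths(rows) < 2L]
    if (length(small))
      stop(sprintf("degenerate input: deme %s has < 2 haplotypes at locus %s",
                   small[1L], aln$locus_name))
    pit <- .mean_pairwise_diffs(mat)
    S <- segregating_sites(mat)
    td <- .tajima_d_from_totals(pit, S, nrow(mat))
    pi_v <- c(pi_v, pit); S_v <- c(S_v, S)
    D_v <- c(D_v, if (td$defined) td$D else 0)
    D_undef <- c(D_undef, !td$defined)
    piw <- c(piw, vapply(rows, function(idx)
      .mean_pairwise_diffs(mat[idx, , drop = FALSE]), 0.0))
    if (length(rows) > 1L) {
      cmb <- combn(length(rows), 2L)
      dxy <- c(dxy, apply(cmb, 2L, function(ij) {
        A <- mat[rows[[ij[1L]]], , drop = FALSE]
        B <- mat[rows[[ij[2L]]], , drop = FALSE]
        dxy_between(A, B) * ncol(mat)  # per-locus total scale
      }))
    }
  }
  out <- c(rbind(pi_v, S_v, D_v))
  out <- c(out, piw, dxy)
  names(out) <- summary_vector_names(locus_names, deme_labels)
  attr(out, "D_undefined") <- D_undef
  class(out) <- "summary_stat_vector"
  out
}

#' Summary vector from simulator output
#'
#' Maps the per-locus statistics returned by [simulate_dataset()] (already
#' on the per-locus-total, infinite-sites scale) into the same fixed
#' ordering as [summary_vector()].
#'
#' @param stats list (one element per locus) of lists with `S`, `pi`,
#'   `pi_within`, `dxy`, `n`.
#' @param locus_names,deme_labels labels; demes must be sorted consistently
#'   with the simulation group order.
#' @return Named numeric vector of class `summary_stat_vector`.
#' @export
summary_vector_from_stats <- function(stats, locus_names, deme_labels) {
  pi_v <- vapply(stats, function(s) s$pi, 0.0)
  S_v <- vapply(stats, function(s) as.numeric(s$S), 0.0)
  td <- lapply(stats, function(s) .tajima_d_from_totals(s$pi, s$S, s$n))
  D_v <- vapply(td, function(z) if (z$defined) z$D else 0, 0.0)
  piw <- unlist(lapply(stats, function(s) s$pi_within))
  dxy <- unlist(lapply(stats, function(s) s$dxy))
  out <- c(c(rbind(pi_v, S_v, D_v)), piw, dxy)
  names(out) <- summary_vector_names(locus_names, deme_labels)
  attr(out, "D_undefined") <- !vapply(td, function(z) z$defined, TRUE)
  class(out) <- "summary_stat_vector"
  out
}
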