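#' @title Study-shaped synthetic data
#' @name synthetic_data
#' @description Generates georeferenced three-deme, three-locus fixture
#'   datasets with known truth: 13 sampling sites in three mountain-region
#'   demes, 88 individuals, one 896-bp mitochondrial locus (86 haplotypes:
#'   two individuals lack mtDNA) and two nuclear loci (176 phased haplotypes
#'   each), simulated under a configurable isolation-with-migration truth
#'   model and written in the package's FASTA/TSV formats together with a
#'   JSON truth sidecar.
NULL

#' Default truth model for study-like fixtures
#'
#' Three demes `(C, P, Q)` with topology `((C, P), Q)` and stepping-stone
#' gene flow (routes C-P and P-Q): per-deme theta on the reference-locus
#' scale 3.4/1.2/1.6, split times `tau1 = 0.15` and `tau2 = 0.39` (4Ne
#' units on the mtDNA-anchored scale), and restricted migration
#' `M_CP = 0.65, M_PC = 0.65, M_PQ = 0.48, M_QP = 0.75` (under one
#' effective migrant per generation). Theta matches the study-scale point
#' estimates; tau and the migration scale are calibrated so the generated
#' data reproduce the study system's observable signal — per-locus
#' diversities of the published magnitude together with three geographic
#' clusters that spatial clustering can actually recover (see the methods
#' vignette for the reasoning).
#'
#' @param loci a [locus_set()].
#' @return A `demographic_model`.
#' @export
default_truth_model <- function(loci = default_locus_set()) {
  theta <- c(C = 3.4, P = 1.2, Q = 1.6)
  mig <- matrix(0, 3, 3, dimnames = list(names(theta), names(theta)))
  mig["C", "P"] <- 0.65; mig["P", "C"] <- 0.65
  mig["P", "Q"] <- 0.48; mig["Q", "P"] <- 0.75
  splits <- data.frame(time = c(0.15, 0.39), from = c("C", "P"),
                       to = c("P", "Q"), stringsAsFactors = FALSE)
  demographic_model(theta, mig, splits = splits, loci = loci)
}

#' Study-shaped sampling design
#'
#' Haplotype counts per locus and deme: 35/17/34 mitochondrial and
#' 70/36/70 nuclear haplotypes for demes C/P/Q (88 individuals, two of
#' which lack mtDNA).
#'
#' @return Integer matrix (loci x demes).
#' @export
study_sample_sizes <- function() {
  m <- rbind(mt1 = c(35L, 17L, 34L),
             nuc1 = c(70L, 36L, 70L),
             nuc2 = c(70L, 36L, 70L))
  colnames(m) <- c("C", "P", "Q")
  m
}

#' Template describing the study geography and truth model
#'
#' Three deme centroids in the southeastern Brazilian sky islands, 13
#' sampling sites (6/2/5 per deme), per-site individual counts summing to
#' 35/18/35 individuals, the three default loci and the default truth
#' model.
#'
#' @param truth_model a `demographic_model` (default
#'   [default_truth_model()]).
#' @param jitter site scatter around the deme centroids, degrees (default
#'   0.35).
#' @param rng_seed seed used for geography and simulation.
#' @return List of class `study_template`.
#' @export
study_template <- function(truth_model = default_truth_model(),
                           jitter = 0.35, rng_seed = 1L) {
  centroids <- data.frame(deme = c("C", "P", "Q"),
                          lat = c(-20.25, -21.95, -20.20),
                          lon = c(-46.55, -46.60, -43.90),
                          stringsAsFactors = FALSE)
  sites <- data.frame(
    site_id = sprintf("S%02d", 1:13),
    deme = c(rep("C", 6L), rep("P", 2L), rep("Q", 5L)),
    n_ind = c(6L, 6L, 6L, 6L, 6L, 5L,   # C: 35
              9L, 9L,                   # P: 18
              7L, 7L, 7L, 7L, 7L),      # Q: 35
    stringsAsFactors = FALSE)
  structure(list(centroids = centroids, sites = sites,
                 truth_model = truth_model,
                 sample_sizes = study_sample_sizes(),
                 jitter = jitter, rng_seed = rng_seed),
            class = "study_template")
}

#' Generate the georeferenced sample table of a template
#'
#' Site coordinates are jittered around their deme centroid; individuals
#' are assigned to sites in deme blocks (`C01..C35`, `P01..P18`,
#' `Q01..Q35`).
#'
#' @param template a [study_template()].
#' @return List with `sample_table` (validated) and `true_demes` (named
#'   vector individual -> deme).
#' @export
make_geography <- function(template) {
  set.seed(template$rng_seed)
  st <- template$sites
  cen <- template$centroids[match(st$deme, template$centroids$deme), ]
  st$lat <- cen$lat + rnorm(nrow(st), 0, template$jitter)
  st$lon <- cen$lon + rnorm(nrow(st), 0, template$jitter)
  rows <- do.call(rbind, lapply(split(st, st$deme), function(block) {
    deme <- block$deme[1L]
    ind <- sprintf("%s%02d", deme, seq_len(sum(block$n_ind)))
    data.frame(individual_id = ind,
               site_id = rep(block$site_id, block$n_ind),
               lat = rep(block$lat, block$n_ind),
               lon = rep(block$lon, block$n_ind),
               deme = deme, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  list(sample_table = validate_sample_table(rows[, 1:4]),
       true_demes = setNames(rows$deme, rows$individual_id))
}

# render one locus's 0/1 infinite-sites matrix to sequences of the given
# length: segregating columns go to random distinct positions of a random
# template sequence; the derived state is a random different base
.render_sequences <- function(geno, locus_length) {
  S <- ncol(geno)
  if (S > locus_length)
    stop("locus too short to hold ", S, " segregating sites")
  template <- sample(DNA_BASES, locus_length, replace = TRUE)
  pos <- sample.int(locus_length, S)
  derived <- vapply(pos, function(p)
    sample(setdiff(DNA_BASES, template[p]), 1L), "")
  vapply(seq_len(nrow(geno)), function(i) {
    s <- template
    hit <- geno[i, ] == 1L
    s[pos[hit]] <- derived[hit]
    paste(s, collapse = "")
  }, "")
}

#' Generate a complete study-like dataset with known truth
#'
#' Simulates the template's truth model, renders the infinite-sites
#' matrices into FASTA-ready sequences, builds the sample table, and (when
#' `dir` is given) writes per-locus FASTA files, `samples.tsv` and a
#' `truth.json` sidecar. Outputs are byte-identical for a fixed seed.
#'
#' @param template a [study_template()].
#' @param dir optional output directory (created if missing).
#' @return List with `alignments` (named list of `haplotype_alignment`s),
#'   `sample_table`, `true_demes`, `truth` (parameters and seed), and
#'   `paths` when files were written.
#' @export
generate_study_like_dataset <- function(template = study_template(), dir = NULL) {
  geo <- make_geography(template)
  model <- template$truth_model
  loci <- model$loci
  counts <- template$sample_sizes
  set.seed(template$rng_seed + 1L)
  sim <- simulate_dataset(model, counts, want_matrix = TRUE)

  by_deme <- split(names(geo$true_demes), geo$true_demes)
  alignments <- list()
  for (l in seq_len(nrow(loci))) {
    seqs <- .render_sequences(sim$genotypes[[l]], loci$length[l])
    nuclear <- loci$ploidy[l] == "nuclear"
    ind <- character(0); copy <- integer(0)
    for (g in colnames(counts)) {
      k <- counts[l, g]
      if (nuclear) {
        n_ind <- k %/% 2L
        ind <- c(ind, rep(by_deme[[g]][seq_len(n_ind)], each = 2L))
        copy <- c(copy, rep(c(0L, 1L), n_ind))
      } else {
        ind <- c(ind, by_deme[[g]][seq_len(k)])  # trailing individuals lack mtDNA
        copy <- c(copy, rep(0L, k))
      }
    }
    alignments[[loci$name[l]]] <-
      haplotype_alignment(ind, copy, seqs, loci$name[l], loci$ploidy[l])
  }

  truth <- list(
    K = length(model$labels),
    demes = geo$true_demes,
    theta = as.list(model$theta),
    tau = as.list(setNames(model$splits$time, c("tau1", "tau2"))),
    M = {
      open <- which(model$mig > 0, arr.ind = TRUE)
      setNames(as.list(model$mig[open]),
               paste0("M_", model$labels[open[, 1L]], ".",
                      model$labels[open[, 2L]]))
    },
    rng_seed = template$rng_seed)

  out <- list(alignments = alignments, sample_table = geo$sample_table,
              true_demes = geo$true_demes, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list()
    for (nm in names(alignments)) {
      paths[[nm]] <- file.path(dir, paste0(nm, ".fasta"))
      write_fasta_alignment(alignments[[nm]], paths[[nm]])
    }
    paths$sample_table <- file.path(dir, "samples.tsv")
    write.table(geo$sample_table, paths$sample_table, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths$truth <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out$paths <- paths
  }
  out
}
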