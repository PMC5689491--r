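#' @title Phased multilocus sequence data and sampling metadata
#' @name seqdata
#' @description Readers, writers and validators for per-locus phased
#'   haplotype alignments (FASTA) and the georeferenced sample table (TSV).
#'   Mitochondrial loci carry one haplotype per individual; nuclear loci carry
#'   two, with the copy encoded in the FASTA header as `ID|a` / `ID|b`.
NULL

#' Construct a phased haplotype alignment
#'
#' @param individual_id character vector, one entry per sequence record.
#' @param copy_index integer vector of haplotype copies (0 for mitochondrial
#'   records, 0/1 for the two phased copies of a nuclear locus).
#' @param sequences character vector of equal-length sequences over
#'   `A,C,G,T,-,N` and IUPAC ambiguity codes; lowercase is normalised.
#' @param locus_name name of the locus.
#' @param ploidy_mode `"mitochondrial"` (one copy per individual) or
#'   `"nuclear"` (exactly two copies per individual).
#' @return An object of class `haplotype_alignment` with fields `locus_name`,
#'   `ploidy_mode`, `length`, `individual_id`, `copy_index` and `seq` (a
#'   character matrix, one row per record).
#' @export
haplotype_alignment <- function(individual_id, copy_index, sequences,
                                locus_name, ploidy_mode = c("mitochondrial", "nuclear")) {
  ploidy_mode <- match.arg(ploidy_mode)
  if (length(individual_id) != length(sequences) ||
      length(copy_index) != length(sequences))
    stop("individual_id, copy_index and sequences must have equal length")
  if (length(sequences) == 0L) stop("alignment is empty")
  sequences <- unname(toupper(sequences))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("format error: ragged alignment (sequences of unequal length)")
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  dimnames(mat) <- NULL
  bad <- setdiff(unique(as.vector(mat)), ALLOWED_CHARS)
  if (length(bad))
    stop("format error: disallowed characters in sequences: ",
         paste(bad, collapse = ", "))
  key <- paste(individual_id, copy_index)
  if (anyDuplicated(key))
    stop("format error: duplicate (individual, copy) records")
  tab <- table(individual_id)
  expected <- if (ploidy_mode == "mitochondrial") 1L else 2L
  if (any(tab != expected))
    stop(sprintf("format error: %s locus requires exactly %d cop%s per individual (offender: %s)",
                 ploidy_mode, expected, if (expected == 1L) "y" else "ies",
                 names(tab)[which(tab != expected)[1L]]))
  if (ploidy_mode == "mitochondrial" && any(copy_index != 0L))
    stop("format error: mitochondrial records must have copy_index 0")
  structure(list(
    locus_name = locus_name,
    ploidy_mode = ploidy_mode,
    length = lens[1L],
    individual_id = as.character(individual_id),
    copy_index = as.integer(copy_index),
    seq = mat
  ), class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("<haplotype_alignment> locus %s (%s): %d sequences x %d sites, %d individuals\n",
              x$locus_name, x$ploidy_mode, nrow(x$seq), x$length,
              length(unique(x$individual_id))))
  invisible(x)
}

#' Number of sequences in an alignment
#' @param aln a `haplotype_alignment`.
#' @return Integer count of haplotype records.
#' @export
n_sequences <- function(aln) nrow(aln$seq)

#' Read a per-locus FASTA alignment
#'
#' Headers follow the grammar `ID` for mitochondrial loci and `ID|a` /
#' `ID|b` for the two phased copies of a nuclear locus.
#'
#' @inheritParams haplotype_alignment
#' @param path FASTA file.
#' @param locus_name locus label; defaults to the file name without extension.
#' @return A validated [haplotype_alignment()].
#' @export
read_fasta_alignment <- function(path, ploidy_mode = c("mitochondrial", "nuclear"),
                                 locus_name = NULL) {
  ploidy_mode <- match.arg(ploidy_mode)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(locus_name))
    locus_name <- sub("\\.[^.]*$", "", basename(path))
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  seqs <- as.character(ss)
  if (ploidy_mode == "nuclear") {
    m <- regmatches(headers, regexec("^(.*)\\|([ab])$", headers))
    ok <- lengths(m) == 3L
    if (!all(ok))
      stop("format error: nuclear FASTA headers must end in |a or |b (offender: ",
           headers[!ok][1L], ")")
    ind <- vapply(m, `[`, "", 2L)
    copy <- ifelse(vapply(m, `[`, "", 3L) == "a", 0L, 1L)
  } else {
    ind <- headers
    copy <- rep(0L, length(headers))
  }
  haplotype_alignment(ind, copy, seqs, locus_name, ploidy_mode)
}

#' Write a haplotype alignment to FASTA
#'
#' Inverse of [read_fasta_alignment()]: nuclear copies 0/1 are rendered as
#' `|a` / `|b` header suffixes.
#'
#' @param aln a `haplotype_alignment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- apply(aln$seq, 1L, paste, collapse = "")
  headers <- if (aln$ploidy_mode == "nuclear")
    paste0(aln$individual_id, "|", c("a", "b")[aln$copy_index + 1L])
  else aln$individual_id
  writeLines(paste0(">", headers, "\n", seqs), path)
  invisible(path)
}

#' Read the georeferenced sample table
#'
#' @param path TSV file with header columns `individual_id`, `site_id`,
#'   `lat`, `lon` (WGS84 decimal degrees).
#' @return A `data.frame` with one validated row per individual.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_sample_table(tab)
}

#' Validate a sample table
#' @param tab data.frame with columns `individual_id`, `site_id`, `lat`, `lon`.
#' @return The validated table (character ids, numeric coordinates).
#' @export
validate_sample_table <- function(tab) {
  need <- c("individual_id", "site_id", "lat", "lon")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("format error: sample table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$individual_id))
    stop("format error: duplicated individual_id in sample table")
  lat <- suppressWarnings(as.numeric(tab$lat))
  lon <- suppressWarnings(as.numeric(tab$lon))
  if (anyNA(lat) || anyNA(lon))
    stop("format error: non-numeric coordinate in sample table")
  if (any(abs(lat) > 90)) stop("range error: |latitude| > 90")
  if (any(abs(lon) > 180)) stop("range error: |longitude| > 180")
  data.frame(individual_id = as.character(tab$individual_id),
             site_id = as.character(tab$site_id),
             lat = lat, lon = lon, stringsAsFactors = FALSE)
}

#' Columns retained by a site-masking policy
#'
#' The default policy is complete deletion: any column containing a gap,
#' `N`, or an IUPAC ambiguity in any compared sequence is dropped.
#'
#' @param mat character matrix of aligned sequences.
#' @param policy `"complete"` (drop columns with any gap/ambiguity) or
#'   `"none"` (keep everything).
#' @return Logical vector over columns, `TRUE` = usable.
#' @export
usable_columns <- function(mat, policy = c("complete", "none")) {
  policy <- match.arg(policy)
  if (policy == "none") return(rep(TRUE, ncol(mat)))
  apply(mat, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
}

#' Collapse sequences into unique haplotypes
#'
#' Haplotypes are compared only at columns retained by the masking policy.
#' Output order is deterministic: by count (descending), then by sequence
#' (lexicographic), so the result is invariant to input ordering.
#'
#' @param aln a `haplotype_alignment`.
#' @param site_mask_policy see [usable_columns()].
#' @return A `data.frame` with columns `haplotype` (masked sequence),
#'   `count`, and a list-column `members` of record labels
#'   (`individual_id:copy_index`).
#' @export
collapse_haplotypes <- function(aln, site_mask_policy = c("complete", "none")) {
  site_mask_policy <- match.arg(site_mask_policy)
  keep <- usable_columns(aln$seq, site_mask_policy)
  if (!any(keep))
    stop("degenerate input: all alignment columns are masked")
  key <- apply(aln$seq[, keep, drop = FALSE], 1L, paste, collapse = "")
  labels <- paste0(aln$individual_id, ":", aln$copy_index)
  groups <- split(labels, key)
  out <- data.frame(haplotype = names(groups),
                    count = lengths(groups),
                    stringsAsFactors = FALSE)
  out$members <- unname(groups)
  ord <- order(-out$count, out$haplotype)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Integer haplotype-class labels per record
#'
#' Encodes each sequence record as the index of its collapsed haplotype
#' class (the "alleles" used by the spatial clustering model).
#'
#' @inheritParams collapse_haplotypes
#' @return Integer vector, one entry per record of `aln`, in record order.
#' @export
haplotype_classes <- function(aln, site_mask_policy = c("complete", "none")) {
  site_mask_policy <- match.arg(site_mask_policy)
  keep <- usable_columns(aln$seq, site_mask_policy)
  if (!any(keep)) stop("degenerate input: all alignment columns are masked")
  key <- apply(aln$seq[, keep, drop = FALSE], 1L, paste, collapse = "")
  match(key, sort(unique(key)))
}

#' Validate a deme assignment against a sample table
#'
#' @param assignment named character vector or list mapping
#'   `individual_id` to a deme label.
#' @param sample_table a validated sample table.
#' @return Named character vector of deme labels.
#' @export
validate_deme_assignment <- function(assignment, sample_table) {
  assignment <- unlist(assignment)
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stop("assignment must be named by individual_id")
  unknown <- setdiff(names(assignment), sample_table$individual_id)
  if (length(unknown))
    stop("assignment names unknown individuals: ", paste(head(unknown), collapse = ", "))
  if (any(table(assignment) < 1L)) stop("every deme needs at least one individual")
  assignment
}
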