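#' Alignment container
#'
#' A light container for an aligned set of equal-length nucleotide sequences
#' with sample ids and optional population/species labels.
#'
#' @param seq character vector of equal-length upper-case sequences.
#' @param ids character vector of unique sample identifiers.
#' @param pop optional character vector of population labels (recycled NA).
#' @return An object of class `hm_alignment`: a list with elements `ids`,
#'   `pop`, `seq` and `length`.
#' @examples
#' aln <- hm_alignment(c("ACGT", "ACGA"), ids = c("s1", "s2"))
#' aln$length
#' @export
hm_alignment <- function(seq, ids = NULL, pop = NULL) {
  if (!is.character(seq) || !length(seq)) .stopf("'seq' must be a non-empty character vector")
  seq <- toupper(seq)
  L <- unique(nchar(seq))
  if (length(L) != 1L) .stopf("all sequences must have the same length")
  if (L < 1L) .stopf("alignment length must be >= 1")
  if (is.null(ids)) ids <- paste0("seq", seq_along(seq))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) .stopf("sample ids must be unique")
  if (length(ids) != length(seq)) .stopf("'ids' and 'seq' lengths differ")
  if (is.null(pop)) pop <- rep(NA_character_, length(seq))
  pop <- as.character(rep_len(pop, length(seq)))
  structure(list(ids = ids, pop = pop, seq = seq, length = L),
            class = "hm_alignment")
}

#' @export
print.hm_alignment <- function(x, ...) {
  cat(sprintf("<hm_alignment> %d sequences x %d bp", length(x$seq), x$length))
  if (!all(is.na(x$pop)))
    cat(sprintf("; populations: %s", paste(names(table(x$pop)), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Subset an alignment by population
#'
#' @param aln an [hm_alignment()].
#' @param pop population label(s) to keep.
#' @return An `hm_alignment` with the matching samples.
#' @export
subset_population <- function(aln, pop) {
  stopifnot(inherits(aln, "hm_alignment"))
  keep <- aln$pop %in% pop
  if (!any(keep)) .stopf("no samples with population label(s): %s", paste(pop, collapse = ", "))
  hm_alignment(aln$seq[keep], aln$ids[keep], aln$pop[keep])
}

#' Read an alignment from FASTA with an optional population map
#'
#' Wrapped or single-line FASTA is accepted (parsed with \pkg{ape}). The
#' population map is a two-column CSV (`id,population`).
#'
#' @param fasta path to a FASTA file.
#' @param popmap optional path to the id-to-population CSV.
#' @return An [hm_alignment()].
#' @export
read_alignment <- function(fasta, popmap = NULL) {
  dna <- ape::read.FASTA(fasta)
  if (!length(dna)) .stopf("empty alignment: %s", fasta)
  seqs <- toupper(vapply(as.character(dna), paste0, "", collapse = ""))
  pop <- NULL
  if (!is.null(popmap)) {
    pm <- read.csv(popmap, stringsAsFactors = FALSE)
    if (ncol(pm) < 2L) .stopf("population map must have two columns (id, population)")
    pop <- pm[[2L]][match(names(dna), pm[[1L]])]
  }
  hm_alignment(unname(seqs), names(dna), pop)
}

#' Write an alignment to FASTA (and optionally its population map)
#'
#' @param aln an [hm_alignment()].
#' @param fasta output FASTA path.
#' @param popmap optional output CSV path for the id-to-population map.
#' @return Invisibly, `fasta`.
#' @export
write_alignment <- function(aln, fasta, popmap = NULL) {
  stopifnot(inherits(aln, "hm_alignment"))
  mat <- do.call(rbind, strsplit(tolower(aln$seq), ""))
  rownames(mat) <- aln$ids
  ape::write.FASTA(ape::as.DNAbin(mat), fasta)
  if (!is.null(popmap))
    write.csv(data.frame(id = aln$ids, population = aln$pop), popmap, row.names = FALSE)
  invisible(fasta)
}

# Sites free of gaps/ambiguities across all sequences ("complete" deletion).
.retained_sites <- function(seqmat, gap_policy = c("complete", "none")) {
  gap_policy <- match.arg(gap_policy)
  if (gap_policy == "none") return(seq_len(ncol(seqmat)))
  ok <- apply(seqmat, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  which(ok)
}

.seq_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, ""))
  rownames(m) <- aln$ids
  m
}
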