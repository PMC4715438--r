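# Genotype table IO and the Weir-Cockerham FST estimator.

#' Write a diploid genotype table (TSV)
#'
#' One row per individual: `id`, `pop`, then two integer columns per locus
#' (`L1.a1`, `L1.a2`, ...); missing data coded -9.
#'
#' @param gm genotype data.frame.
#' @param file output TSV path.
#' @return Invisibly, `file`.
#' @export
write_genotypes <- function(gm, file) {
  write.table(gm, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a diploid genotype table (TSV)
#'
#' @param file path written by [write_genotypes()].
#' @return A genotype data.frame.
#' @export
read_genotypes <- function(file) {
  read.delim(file, stringsAsFactors = FALSE)
}

#' Read a STRUCTURE-format genotype file
#'
#' Supports the one-row (two columns per locus) and two-row (one line per
#' allele set) layouts. The first column is the individual label and the
#' second the population; missing data coded -9.
#'
#' @param file path to the STRUCTURE input file.
#' @param rows_per_individual 1 or 2.
#' @return A genotype data.frame in the package's two-columns-per-locus
#'   layout.
#' @export
read_structure_genotypes <- function(file, rows_per_individual = 1) {
  rows_per_individual <- .check_count(rows_per_individual, "rows_per_individual")
  x <- read.table(file, header = FALSE, stringsAsFactors = FALSE)
  if (rows_per_individual == 1L) {
    n_loci <- (ncol(x) - 2L) / 2L
    if (n_loci != floor(n_loci)) .stopf("expected two columns per locus")
    out <- x
  } else if (rows_per_individual == 2L) {
    if (nrow(x) %% 2L != 0L) .stopf("odd number of rows for two-row format")
    odd <- x[seq(1L, nrow(x), 2L), , drop = FALSE]
    evn <- x[seq(2L, nrow(x), 2L), , drop = FALSE]
    if (!all(odd[[1L]] == evn[[1L]])) .stopf("row pairs do not share ids")
    n_loci <- ncol(x) - 2L
    out <- odd[, 1:2, drop = FALSE]
    for (l in seq_len(n_loci)) {
      out[[paste0("L", l, ".a1")]] <- odd[[l + 2L]]
      out[[paste0("L", l, ".a2")]] <- evn[[l + 2L]]
    }
  } else .stopf("rows_per_individual must be 1 or 2")
  names(out)[1:2] <- c("id", "pop")
  if (rows_per_individual == 1L) {
    n_loci <- (ncol(out) - 2L) / 2L
    names(out)[-(1:2)] <- as.vector(t(outer(paste0("L", seq_len(n_loci)),
                                            c(".a1", ".a2"), paste0)))
  }
  out
}

#' Multilocus Weir-Cockerham FST
#'
#' Variance-component estimator of Weir & Cockerham for diploid codominant
#' data: per-allele, per-locus components a (among populations),
#' b (among individuals within populations) and c (within individuals) are
#' summed over alleles and loci; FST = sum(a) / sum(a + b + c). Missing
#' genotypes (-9) are excluded locus-wise.
#'
#' @param gm genotype data.frame (`id`, `pop`, two columns per locus).
#' @return A list with `fst` (multilocus estimate) and `per_locus`.
#' @export
wc_fst <- function(gm) {
  allele_cols <- setdiff(names(gm), c("id", "pop"))
  n_loci <- length(allele_cols) / 2L
  pops <- unique(gm$pop)
  r <- length(pops)
  if (r < 2L) .stopf("need >= 2 populations")
  per_locus <- rep(NA_real_, n_loci)
  A <- B <- C <- 0
  for (l in seq_len(n_loci)) {
    a1 <- gm[[allele_cols[2L * l - 1L]]]
    a2 <- gm[[allele_cols[2L * l]]]
    ok <- a1 != -9 & a2 != -9
    if (!any(ok)) next
    al <- sort(unique(c(a1[ok], a2[ok])))
    if (length(al) < 2L) { per_locus[l] <- 0; next }
    ni <- vapply(pops, function(p) sum(ok & gm$pop == p), 0)
    if (sum(ni > 0) < 2L) next
    use_pops <- pops[ni > 0]
    ni <- ni[ni > 0]
    ri <- length(use_pops)
    nbar <- mean(ni)
    nc <- (ri * nbar - sum(ni^2) / (ri * nbar)) / (ri - 1)
    la <- lb <- lc <- 0
    for (alle in al) {
      p_i <- h_i <- numeric(ri)
      for (k in seq_len(ri)) {
        sel <- ok & gm$pop == use_pops[k]
        p_i[k] <- (sum(a1[sel] == alle) + sum(a2[sel] == alle)) / (2 * ni[k])
        h_i[k] <- sum((a1[sel] == alle) != (a2[sel] == alle)) / ni[k]
      }
      pbar <- sum(ni * p_i) / (ri * nbar)
      s2 <- sum(ni * (p_i - pbar)^2) / ((ri - 1) * nbar)
      hbar <- sum(ni * h_i) / (ri * nbar)
      a_c <- nbar / nc * (s2 - (pbar * (1 - pbar) - (ri - 1) / ri * s2 - hbar / 4) / (nbar - 1))
      b_c <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (ri - 1) / ri * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      c_c <- hbar / 2
      la <- la + a_c; lb <- lb + b_c; lc <- lc + c_c
    }
    per_locus[l] <- if ((la + lb + lc) != 0) la / (la + lb + lc) else NA_real_
    A <- A + la; B <- B + lb; C <- C + lc
  }
  list(fst = A / (A + B + C), per_locus = per_locus)
}
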