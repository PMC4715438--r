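# Post-processing of Bayesian assignment output: Evanno DeltaK and
# mean-centred genotype PCA.

#' Evanno DeltaK from a table of Ln P(K) replicates
#'
#' `DeltaK(K) = mean_r |lnP(K+1) - 2 lnP(K) + lnP(K-1)| / sd_r lnP(K)`,
#' defined for interior K of a contiguous K range with at least two
#' replicates each.
#'
#' @param table data.frame with columns `K`, `replicate`, `lnP` (a
#'   `replicate` column is synthesised when absent and rows per K align).
#' @return A list of class `hm_deltak`: data.frame `summary` with per-K
#'   `mean_lnP`, `sd_lnP`, `L2` (|second difference| averaged over
#'   replicates) and `deltaK`, plus `best_K` (argmax of DeltaK).
#' @export
evanno_delta_k <- function(table) {
  if (!is.data.frame(table) || !all(c("K", "lnP") %in% names(table)))
    .stopf("'table' must have columns K and lnP")
  ks <- sort(unique(table$K))
  if (length(ks) < 3L) .stopf("DeltaK needs at least 3 contiguous K values")
  if (any(diff(ks) != 1L)) .stopf("K values must be contiguous")
  reps <- split(table$lnP, table$K)
  nrep <- vapply(reps, length, 1L)
  if (any(nrep < 2L)) .stopf("need >= 2 replicates per K")
  if (length(unique(nrep)) != 1L)
    .stopf("unbalanced replicates per K are not supported")
  R <- unname(nrep[1L])
  lnp <- do.call(cbind, reps)  # R x K matrix, columns ordered by K
  mean_lnp <- colMeans(lnp)
  sd_lnp <- apply(lnp, 2L, sd)
  nk <- length(ks)
  L2 <- deltaK <- rep(NA_real_, nk)
  for (i in 2L:(nk - 1L)) {
    if (sd_lnp[i] == 0)
      .stopf("sd of lnP is zero at K = %d; DeltaK undefined", ks[i])
    l2 <- mean(abs(lnp[, i + 1L] - 2 * lnp[, i] + lnp[, i - 1L]))
    L2[i] <- l2
    deltaK[i] <- l2 / sd_lnp[i]
  }
  summary <- data.frame(K = ks, n_replicates = R, mean_lnP = mean_lnp,
                        sd_lnP = sd_lnp, L2 = L2, deltaK = deltaK,
                        row.names = NULL)
  best <- ks[which.max(deltaK)]
  structure(list(summary = summary, best_K = best), class = "hm_deltak")
}

#' @export
print.hm_deltak <- function(x, ...) {
  cat(sprintf("Evanno DeltaK: best K = %d\n", x$best_K))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Scrape Ln P(K) values from STRUCTURE run logs
#'
#' Extracts `(K, replicate, lnP)` triples from STRUCTURE output files using
#' the "populations assumed" and "Estimated Ln Prob of Data" lines.
#'
#' @param files character vector of STRUCTURE output file paths.
#' @return A data.frame with columns `K`, `replicate`, `lnP`.
#' @export
read_structure_lnp <- function(files) {
  rows <- lapply(files, function(f) {
    ln <- readLines(f, warn = FALSE)
    kline <- grep("populations assumed", ln, value = TRUE)
    pline <- grep("Estimated Ln Prob of Data", ln, value = TRUE)
    if (!length(kline) || !length(pline))
      .stopf("file %s does not look like a STRUCTURE log", f)
    K <- as.integer(sub(".*?(\\d+)\\s+populations assumed.*", "\\1", kline[1L]))
    lnP <- as.numeric(sub(".*=\\s*", "", pline[1L]))
    data.frame(K = K, lnP = lnP, file = f, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$replicate <- stats::ave(seq_len(nrow(out)), out$K, FUN = seq_along)
  out[, c("K", "replicate", "lnP")]
}

#' Mean-centred PCA of a diploid genotype matrix
#'
#' Genotypes are expanded to one-hot allele counts (one column per observed
#' allele per locus, values 0/1/2), missing genotypes are imputed to the
#' column mean, columns are mean-centred without scaling, and the
#' eigendecomposition is taken via [prcomp()]. The sign of each axis is
#' fixed so that its largest-magnitude loading is positive.
#'
#' @param gm genotype data.frame as produced by [sim_microsats()] /
#'   [read_genotypes()]: columns `id`, `pop`, then two integer columns per
#'   locus with missing coded -9.
#' @param n_axes number of axes to return (default all).
#' @return A list of class `hm_genopca`: `scores` (individuals x axes),
#'   `explained` (variance fractions), `loadings`, `pop`, `dropped_loci`.
#' @export
genotype_pca <- function(gm, n_axes = NULL) {
  enc <- .one_hot_genotypes(gm)
  X <- enc$X
  if (nrow(X) < 3L) .stopf("need >= 3 individuals")
  # impute missing to column mean
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2L, flip, `*`)
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  if (!is.null(n_axes)) {
    n_axes <- min(.check_count(n_axes, "n_axes"), ncol(scores))
    scores <- scores[, seq_len(n_axes), drop = FALSE]
    loadings <- loadings[, seq_len(n_axes), drop = FALSE]
  }
  rownames(scores) <- enc$ids
  structure(list(scores = scores, explained = expl, loadings = loadings,
                 pop = enc$pop, dropped_loci = enc$dropped),
            class = "hm_genopca")
}

#' @export
print.hm_genopca <- function(x, ...) {
  cat(sprintf("<hm_genopca> %d individuals, %d axes; PC1-3 explain %.1f%%\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$explained[seq_len(min(3, length(x$explained)))])))
  invisible(x)
}

# One-hot allele-count encoding. Returns X (n x columns, NA where the
# genotype is missing), ids, pop, dropped loci names.
.one_hot_genotypes <- function(gm) {
  if (!is.data.frame(gm) || ncol(gm) < 4L)
    .stopf("genotype table must have id, pop and >= 1 locus (2 columns)")
  allele_cols <- setdiff(names(gm), c("id", "pop"))
  if (length(allele_cols) %% 2L != 0L) .stopf("expected two columns per locus")
  n_loci <- length(allele_cols) / 2L
  n <- nrow(gm)
  blocks <- list()
  dropped <- character(0)
  for (l in seq_len(n_loci)) {
    c1 <- gm[[allele_cols[2L * l - 1L]]]
    c2 <- gm[[allele_cols[2L * l]]]
    a1 <- ifelse(c1 == -9, NA, c1)
    a2 <- ifelse(c2 == -9, NA, c2)
    alleles <- sort(unique(c(a1, a2)))
    alleles <- alleles[!is.na(alleles)]
    lname <- sub("\\.a[12]$", "", allele_cols[2L * l - 1L])
    if (!length(alleles)) {
      dropped <- c(dropped, lname)
      next
    }
    B <- matrix(NA_real_, n, length(alleles),
                dimnames = list(NULL, paste0(lname, ".", alleles)))
    known <- !is.na(a1) & !is.na(a2)
    for (k in seq_along(alleles)) {
      B[known, k] <- (a1[known] == alleles[k]) + (a2[known] == alleles[k])
    }
    blocks[[length(blocks) + 1L]] <- B
  }
  if (length(dropped))
    warning("dropped all-missing loci: ", paste(dropped, collapse = ", "))
  if (!length(blocks)) .stopf("no usable loci")
  list(X = do.call(cbind, blocks), ids = gm$id, pop = gm$pop, dropped = dropped)
}
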