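# Sequence diversity summaries, neutrality tests and mismatch-distribution
# expansion analysis.

#' Collapse an alignment into a haplotype table
#'
#' Sites containing gaps or ambiguity codes are removed first under the
#' default complete-deletion policy; haplotypes are then the distinct
#' retained-site strings, ordered by first occurrence.
#'
#' @param aln an [hm_alignment()].
#' @param gap_policy `"complete"` (drop every site with a non-ACGT character
#'   in any sequence) or `"none"`.
#' @return An object of class `hm_haplotypes`: list with `haplotypes`
#'   (character vector over retained sites), `counts`, `freq`, `membership`
#'   (haplotype index per sample), `n`, `H`, `L` (retained length),
#'   `retained_sites`, `pop` and `ids`.
#' @examples
#' aln <- hm_alignment(c("AAT", "AAT", "AAC"))
#' collapse_haplotypes(aln)$H
#' @export
collapse_haplotypes <- function(aln, gap_policy = c("complete", "none")) {
  stopifnot(inherits(aln, "hm_alignment"))
  if (!length(aln$seq)) .stopf("empty alignment")
  gap_policy <- match.arg(gap_policy)
  m <- .seq_matrix(aln)
  keep <- .retained_sites(m, gap_policy)
  if (!length(keep)) .stopf("no sites retained after gap/ambiguity deletion")
  red <- apply(m[, keep, drop = FALSE], 1L, paste0, collapse = "")
  uniq <- red[!duplicated(red)]           # first-occurrence order
  memb <- match(red, uniq)
  counts <- tabulate(memb, nbins = length(uniq))
  structure(list(haplotypes = unname(uniq), counts = counts,
                 freq = counts / length(red), membership = memb,
                 n = length(red), H = length(uniq), L = length(keep),
                 retained_sites = keep, pop = aln$pop, ids = aln$ids),
            class = "hm_haplotypes")
}

#' @export
print.hm_haplotypes <- function(x, ...) {
  cat(sprintf("<hm_haplotypes> n = %d samples, H = %d haplotypes, %d retained sites\n",
              x$n, x$H, x$L))
  invisible(x)
}

# Hamming distances between haplotype strings (equal length assumed).
.hap_dist <- function(haps) {
  H <- length(haps)
  m <- do.call(rbind, strsplit(haps, ""))
  d <- matrix(0L, H, H)
  if (H > 1L) for (i in seq_len(H - 1L)) for (j in (i + 1L):H) {
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  }
  d
}

#' Diversity summaries from a haplotype table
#'
#' Computes the number of segregating sites S, unbiased haplotype diversity
#' `h = n (1 - sum p_i^2) / (n - 1)` and nucleotide diversity `pi` (mean
#' pairwise difference per retained site over all sample pairs).
#'
#' @param haps an `hm_haplotypes` from [collapse_haplotypes()].
#' @return A list with `S`, `h`, `pi`, plus `n`, `H`, `L` and
#'   `mean_pairwise` (mean pairwise differences per sequence).
#' @export
diversity_stats <- function(haps) {
  stopifnot(inherits(haps, "hm_haplotypes"))
  if (haps$n < 2L) .stopf("haplotype diversity undefined for n < 2")
  m <- do.call(rbind, strsplit(haps$haplotypes, ""))
  S <- sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
  p <- haps$freq
  h <- haps$n * (1 - sum(p^2)) / (haps$n - 1)
  d <- .hap_dist(haps$haplotypes)
  cnt <- haps$counts
  # sum of pairwise differences over all sample pairs
  tot <- sum(d * tcrossprod(cnt)) / 2
  npairs <- haps$n * (haps$n - 1) / 2
  k_bar <- tot / npairs
  list(S = as.integer(S), h = h, pi = k_bar / haps$L,
       n = haps$n, H = haps$H, L = haps$L, mean_pairwise = k_bar)
}

# Tajima's constants and statistic from (n, S, mean pairwise differences).
.tajima_d_value <- function(n, S, k_bar) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_bar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Tajima's D with a coalescent p-value
#'
#' The statistic uses the standard a1, a2, b1, b2, c1, c2, e1, e2 constants;
#' the two-tailed p-value comes from neutral coalescent replicates
#' conditioned on the observed sample size and number of segregating sites
#' (mutations placed on the genealogy proportionally to branch length).
#'
#' @param aln an [hm_alignment()].
#' @param n_replicates number of neutral replicates for the p-value.
#' @param seed integer seed.
#' @param gap_policy see [collapse_haplotypes()].
#' @return A list with `D`, `p`, `S`, `mean_pairwise`, `n`, `n_replicates`.
#' @export
tajimas_d <- function(aln, n_replicates = 1000, seed = 1,
                      gap_policy = c("complete", "none")) {
  stopifnot(inherits(aln, "hm_alignment"))
  n <- length(aln$seq)
  if (n < 4L) .stopf("Tajima's D requires n >= 4")
  haps <- collapse_haplotypes(aln, match.arg(gap_policy))
  st <- diversity_stats(haps)
  if (st$S == 0L) .stopf("Tajima's D is undefined: no segregating sites (S = 0)")
  D <- .tajima_d_value(n, st$S, st$mean_pairwise)
  n_replicates <- .check_count(n_replicates, "n_replicates")
  set.seed(.check_count(seed, "seed", min = 0L))
  sims <- vapply(seq_len(n_replicates), function(i) {
    r <- .sim_fixed_s(n, st$S)
    .tajima_d_value(n, r$S, r$pi)
  }, 0)
  p_lo <- mean(sims <= D)
  p_hi <- mean(sims >= D)
  p <- min(1, 2 * min(p_lo, p_hi))
  list(D = D, p = p, S = st$S, mean_pairwise = st$mean_pairwise,
       n = n, n_replicates = n_replicates)
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n),
# via the recurrence |s(n+1,k)| = |s(n,k-1)| + n |s(n,k)| in log space.
.log_stirling_env <- new.env(parent = emptyenv())
.log_stirling_row <- function(n) {
  key <- as.character(n)
  if (!is.null(.log_stirling_env[[key]])) return(.log_stirling_env[[key]])
  row <- 0  # n = 1: |s(1,1)| = 1
  if (n > 1L) for (i in 1L:(n - 1L)) {
    prev <- c(-Inf, row)                 # |s(i, k-1)|
    same <- c(row, -Inf) + log(i)        # i * |s(i, k)|
    nxt <- pmax(prev, same) + log1p(exp(-abs(prev - same)))
    nxt[is.nan(nxt)] <- -Inf
    row <- nxt
  }
  .log_stirling_env[[key]] <- row
  row
}

# log P(K = k | theta, n) under the Ewens sampling distribution, all k.
.log_ewens_k <- function(n, theta) {
  lrow <- .log_stirling_row(n)
  lnum <- lrow + seq_len(n) * log(theta)
  lden <- sum(log(theta + 0:(n - 1)))
  lnum - lden
}

# Fu's Fs from (n, k_obs, theta_hat). Both tails are evaluated in log space,
# so Fs = log S' - log(1 - S') is stable even when S' is within machine
# epsilon of 0 or 1.
.fu_fs_value <- function(n, k_obs, theta_hat) {
  lp <- .log_ewens_k(n, theta_hat)
  log_sp <- .logsumexp(lp[k_obs:n])      # log P(K >= k_obs)
  log_1msp <- if (k_obs > 1L) .logsumexp(lp[seq_len(k_obs - 1L)]) else -Inf
  log_sp - log_1msp
}

#' Fu's Fs with a coalescent p-value
#'
#' `Fs = ln(S'/(1-S'))` where `S' = P(K >= k_obs | theta_hat, n)` under the
#' Ewens sampling distribution, evaluated in log space through unsigned
#' Stirling numbers of the first kind; `theta_hat` is the observed mean
#' number of pairwise differences. The p-value is the fraction of neutral
#' coalescent replicates (at `theta_hat`) with a simulated Fs less than or
#' equal to the observed one (Fu's convention).
#'
#' @inheritParams tajimas_d
#' @return A list with `Fs`, `p`, `S_prime`, `k_obs`, `theta_hat`, `n`,
#'   `n_replicates`.
#' @export
fu_fs <- function(aln, n_replicates = 1000, seed = 1,
                  gap_policy = c("complete", "none")) {
  stopifnot(inherits(aln, "hm_alignment"))
  n <- length(aln$seq)
  if (n < 3L) .stopf("Fu's Fs requires n >= 3")
  haps <- collapse_haplotypes(aln, match.arg(gap_policy))
  st <- diversity_stats(haps)
  theta_hat <- st$mean_pairwise
  if (haps$H == 1L || theta_hat <= 0)
    .stopf("Fu's Fs is undefined: no sequence variation (single haplotype)")
  Fs <- .fu_fs_value(n, haps$H, theta_hat)
  n_replicates <- .check_count(n_replicates, "n_replicates")
  set.seed(.check_count(seed, "seed", min = 0L))
  sims <- vapply(seq_len(n_replicates), function(i) {
    r <- .sim_theta_stats(n, theta_hat)
    if (r$K == 1L || r$pi <= 0) return(Inf)  # no variation: maximally positive
    .fu_fs_value(n, r$K, r$pi)
  }, 0)
  p <- mean(sims <= Fs)
  list(Fs = Fs, p = p,
       S_prime = exp(Fs) / (1 + exp(Fs)),
       k_obs = haps$H, theta_hat = theta_hat, n = n,
       n_replicates = n_replicates)
}

#' Mismatch spectrum of an alignment
#'
#' Counts of unordered sample pairs differing at k retained sites.
#'
#' @inheritParams tajimas_d
#' @return An object of class `hm_mismatch`: integer counts named
#'   `0..k_max`, with attributes `n` (samples) and `pairs`.
#' @export
mismatch_spectrum <- function(aln, gap_policy = c("complete", "none")) {
  stopifnot(inherits(aln, "hm_alignment"))
  n <- length(aln$seq)
  if (n < 2L) .stopf("mismatch spectrum requires n >= 2")
  haps <- collapse_haplotypes(aln, match.arg(gap_policy))
  d <- .hap_dist(haps$haplotypes)
  cnt <- haps$counts
  kmax <- max(d)
  counts <- integer(kmax + 1L)
  H <- length(cnt)
  for (i in seq_len(H)) {
    counts[1L] <- counts[1L] + cnt[i] * (cnt[i] - 1) / 2
    if (i < H) for (j in (i + 1L):H) {
      k <- d[i, j]
      counts[k + 1L] <- counts[k + 1L] + cnt[i] * cnt[j]
    }
  }
  structure(setNames(as.integer(counts), 0:kmax),
            n = n, pairs = n * (n - 1) / 2, class = "hm_mismatch")
}

#' @export
print.hm_mismatch <- function(x, ...) {
  cat(sprintf("<hm_mismatch> n = %d samples, %d pairs, k_max = %d\n",
              attr(x, "n"), attr(x, "pairs"), length(x) - 1L))
  print(unclass(x)[seq_len(min(length(x), 25L))])
  invisible(x)
}

#' Expected mismatch probabilities under the sudden-expansion model
#'
#' Probability that a random pair differs at `k` sites when a population of
#' scaled size `theta0` jumped to `theta1` at `tau` mutational time units
#' before the present. Evaluated exactly through incomplete gamma integrals
#' of the piecewise-exponential pair-coalescence density. `theta1 = Inf` is
#' supported (no coalescence since the expansion).
#'
#' @param k integer vector of pairwise difference counts.
#' @param tau expansion time in mutational units (>= 0).
#' @param theta0,theta1 pre-/post-expansion scaled sizes (theta0 <= theta1).
#' @return Numeric vector of probabilities.
#' @export
mismatch_model_probs <- function(k, tau, theta0, theta1) {
  eps <- 1e-9
  fhat <- function(k, th) {
    if (!is.finite(th)) return(rep(0, length(k)))
    if (th < eps) return(as.numeric(k == 0))
    exp(k * log(th) - (k + 1) * log1p(th))
  }
  if (tau < eps) return(fhat(k, theta0))
  if (is.finite(theta1) && theta1 < eps) return(as.numeric(k == 0))
  # recent phase: coalescence before tau
  p_recent <- fhat(k, theta1) * pgamma(tau * (1 + 1 / theta1), k + 1)
  surv <- exp(-tau / theta1)  # theta1 = Inf -> 1
  if (theta0 < eps) {
    p_old <- surv * dpois(k, tau)
  } else {
    p_old <- surv * exp(tau / theta0) * fhat(k, theta0) *
      pgamma(tau * (1 + 1 / theta0), k + 1, lower.tail = FALSE)
  }
  p <- p_recent + p_old
  p[!is.finite(p)] <- 0
  pmax(p, 0)
}

# SSD between observed relative frequencies and model probabilities.
.mismatch_ssd <- function(x, tau, theta0, theta1) {
  k <- seq_along(x) - 1
  sum((x - mismatch_model_probs(k, tau, theta0, theta1))^2)
}

#' Harpending's raggedness index
#'
#' Sum of squared successive differences of the normalised mismatch
#' frequencies, with an implicit zero class appended beyond `k_max`.
#'
#' @param spec an `hm_mismatch` (or a bare vector of counts for k = 0..).
#' @return The raggedness index.
#' @export
raggedness_index <- function(spec) {
  x <- as.numeric(spec) / sum(spec)
  x <- c(x, 0)
  sum(diff(x)^2)
}

# Grid + Nelder-Mead SSD minimisation; theta0 <= theta1 by construction.
.fit_mismatch <- function(x, kmax) {
  mean_k <- sum((seq_along(x) - 1) * x)
  tau_grid <- seq(0, 2 * kmax, length.out = 33L)
  th0_grid <- c(0, 0.1, max(mean_k / 4, 0.5))
  th1_grid <- unique(pmin(c(max(mean_k, 1), 10 * max(mean_k, 1), 1000), 1e4))
  best <- list(ssd = Inf)
  for (tau in tau_grid) for (t0 in th0_grid) for (t1 in th1_grid) {
    if (t0 > t1) next
    s <- .mismatch_ssd(x, tau, t0, t1)
    if (s < best$ssd) best <- list(ssd = s, tau = tau, t0 = t0, t1 = t1)
  }
  # Nelder-Mead on transformed parameters (tau via logit on [0, 2 kmax],
  # theta0 and theta1 - theta0 on the log scale, capped at 1e4).
  tr <- function(y) {
    tau <- 2 * kmax * plogis(y[1L])
    t0 <- min(exp(y[2L]), 1e4)
    t1 <- min(t0 + exp(y[3L]), 1e4)
    c(tau, t0, t1)
  }
  y0 <- c(qlogis(min(max(best$tau / (2 * kmax), 1e-4), 1 - 1e-4)),
          log(max(best$t0, 1e-3)),
          log(max(best$t1 - best$t0, 1e-3)))
  opt <- optim(y0, function(y) {
    p <- tr(y)
    .mismatch_ssd(x, p[1L], p[2L], p[3L])
  }, method = "Nelder-Mead", control = list(maxit = 500L))
  par <- tr(opt$par)
  if (opt$value <= best$ssd) {
    list(tau = par[1L], theta0 = par[2L], theta1 = par[3L], ssd = opt$value)
  } else {
    list(tau = best$tau, theta0 = best$t0, theta1 = best$t1, ssd = best$ssd)
  }
}

#' Simulate a mismatch spectrum under the sudden-expansion model
#'
#' Draws one coalescent sample of size `n` under the sudden-expansion
#' history (scaled size `theta1` until `tau` mutational units ago, `theta0`
#' before) and returns its mismatch spectrum. This is the parametric
#' simulator used by the bootstrap in [fit_sudden_expansion()].
#'
#' @param n sample size (>= 2).
#' @param tau expansion time in mutational units.
#' @param theta0,theta1 pre-/post-expansion scaled sizes.
#' @param seed optional integer seed (NULL: use the current RNG state).
#' @return An `hm_mismatch`.
#' @export
sim_expansion_spectrum <- function(n, tau, theta0, theta1, seed = NULL) {
  n <- .check_count(n, "n", min = 2L)
  if (!is.null(seed)) set.seed(.check_count(seed, "seed", min = 0L))
  cnt <- .sim_expansion_spectrum(n, tau, theta0, theta1)
  structure(setNames(as.integer(cnt), seq_along(cnt) - 1L),
            n = n, pairs = n * (n - 1) / 2, class = "hm_mismatch")
}

#' Fit the sudden-expansion model to a mismatch spectrum
#'
#' Minimises the sum of squared deviations (SSD) between observed and model
#' mismatch probabilities by a coarse grid over the expansion time followed
#' by Nelder-Mead refinement. p-values for SSD and Harpending's raggedness
#' come from a parametric bootstrap: samples of the same size are simulated
#' under the fitted model, each bootstrap SSD is computed after refitting,
#' and p is the fraction of replicates with statistic >= observed.
#'
#' @param spec an `hm_mismatch` from [mismatch_spectrum()].
#' @param n_bootstrap bootstrap replicates (9000 by default; reduce for
#'   exploratory runs).
#' @param seed integer seed.
#' @return An object of class `hm_expansionfit`: list with `tau`, `theta0`,
#'   `theta1`, `SSD`, `Hri`, `p_SSD`, `p_Hri`, `n_bootstrap`, `n`,
#'   `degenerate`.
#' @export
fit_sudden_expansion <- function(spec, n_bootstrap = 9000, seed = 1) {
  stopifnot(inherits(spec, "hm_mismatch"))
  n <- attr(spec, "n")
  if (attr(spec, "pairs") < 3) .stopf("need at least 3 sample pairs")
  x <- as.numeric(spec) / sum(spec)
  kmax <- length(x) - 1L
  hri <- raggedness_index(spec)
  if (kmax == 0L) {
    warning("degenerate mismatch spectrum (all pairs identical); returning tau = 0 fit")
    return(structure(list(tau = 0, theta0 = 0, theta1 = 0, SSD = 0, Hri = hri,
                          p_SSD = 1, p_Hri = 1, n_bootstrap = 0L, n = n,
                          degenerate = TRUE),
                     class = "hm_expansionfit"))
  }
  n_bootstrap <- .check_count(n_bootstrap, "n_bootstrap", min = 0L)
  fit <- .fit_mismatch(x, kmax)
  set.seed(.check_count(seed, "seed", min = 0L))
  ssd_b <- hri_b <- numeric(n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    cb <- .sim_expansion_spectrum(n, fit$tau, fit$theta0, fit$theta1)
    xb <- cb / sum(cb)
    kb <- length(xb) - 1L
    if (kb == 0L) {
      ssd_b[b] <- 0
    } else {
      ssd_b[b] <- .fit_mismatch(xb, kb)$ssd
    }
    hri_b[b] <- raggedness_index(cb)
  }
  structure(list(tau = fit$tau, theta0 = fit$theta0, theta1 = fit$theta1,
                 SSD = fit$ssd, Hri = hri,
                 p_SSD = if (n_bootstrap) mean(ssd_b >= fit$ssd) else NA_real_,
                 p_Hri = if (n_bootstrap) mean(hri_b >= hri) else NA_real_,
                 n_bootstrap = n_bootstrap, n = n, degenerate = FALSE),
            class = "hm_expansionfit")
}

#' @export
print.hm_expansionfit <- function(x, ...) {
  cat("Sudden-expansion mismatch fit\n")
  cat(sprintf("  tau = %.3f  theta0 = %.3f  theta1 = %.3f\n",
              x$tau, x$theta0, x$theta1))
  cat(sprintf("  SSD = %.5f (p = %s)  Hri = %.5f (p = %s)  [%d bootstrap]\n",
              x$SSD, format(x$p_SSD, digits = 3), x$Hri,
              format(x$p_Hri, digits = 3), x$n_bootstrap))
  if (isTRUE(x$degenerate)) cat("  (degenerate spectrum: all pairs identical)\n")
  invisible(x)
}

#' Per-population diversity, neutrality and expansion summary table
#'
#' Runs the full sequence-statistics chain for each population label in the
#' alignment and returns one row per population (n, H, S, h, pi, Tajima's D
#' and p, Fu's Fs and p, SSD and p, raggedness and p).
#'
#' @param aln an [hm_alignment()] with population labels.
#' @param n_replicates neutrality-test replicates.
#' @param n_bootstrap mismatch bootstrap replicates.
#' @param seed integer seed.
#' @param file optional path: written as a TSV when given.
#' @return A data.frame (invisibly written to `file` when requested).
#' @export
population_summary <- function(aln, n_replicates = 1000, n_bootstrap = 1000,
                               seed = 1, file = NULL) {
  stopifnot(inherits(aln, "hm_alignment"))
  pops <- unique(aln$pop[!is.na(aln$pop)])
  if (!length(pops)) .stopf("alignment has no population labels")
  rows <- lapply(pops, function(p) {
    sub <- subset_population(aln, p)
    haps <- collapse_haplotypes(sub)
    st <- diversity_stats(haps)
    td <- tryCatch(tajimas_d(sub, n_replicates, seed),
                   error = function(e) list(D = NA_real_, p = NA_real_))
    fs <- tryCatch(fu_fs(sub, n_replicates, seed),
                   error = function(e) list(Fs = NA_real_, p = NA_real_))
    ef <- tryCatch(fit_sudden_expansion(mismatch_spectrum(sub), n_bootstrap, seed),
                   error = function(e) list(SSD = NA_real_, p_SSD = NA_real_,
                                            Hri = NA_real_, p_Hri = NA_real_))
    data.frame(population = p, n = st$n, H = st$H, S = st$S,
               h = st$h, pi = st$pi,
               D = td$D, p_D = td$p, Fs = fs$Fs, p_Fs = fs$p,
               SSD = ef$SSD, p_SSD = ef$p_SSD, Hri = ef$Hri, p_Hri = ef$p_Hri,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file))
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
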