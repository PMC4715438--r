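# Internal coalescent simulation machinery.
#
# Time scales:
#  - .kingman_branches(): standard n-coalescent with time in units where a
#    pair of lineages coalesces at rate 1 (E[pairwise coalescence time] = 1).
#    Mutations at rate theta/2 per lineage per unit time then give
#    E[pairwise differences] = theta.
#  - .expansion_branches(): time measured directly in mutational units x
#    (expected pairwise difference accumulated over x is x), so a branch of
#    duration dx carries Poisson(dx/2) mutations and a pair coalesces at
#    rate 1/theta while the scaled population size is theta.

# Simulate a Kingman genealogy. Returns branch lengths and, per branch, the
# set of descendant tips (integer vector) - enough to compute S, pi and
# haplotype counts without building sequences.
.kingman_branches <- function(n) {
  tips <- vector("list", 2L * n - 2L)
  lens <- numeric(2L * n - 2L)
  active <- as.list(seq_len(n))
  birth <- numeric(n)
  t <- 0
  b <- 0L
  k <- n
  while (k > 1L) {
    t <- t + rexp(1L, k * (k - 1) / 2)
    pair <- sample.int(k, 2L)
    i <- pair[1L]; j <- pair[2L]
    for (idx in c(i, j)) {
      b <- b + 1L
      tips[[b]] <- active[[idx]]
      lens[b] <- t - birth[idx]
    }
    merged <- c(active[[i]], active[[j]])
    keep <- setdiff(seq_len(k), c(i, j))
    active <- c(active[keep], list(merged))
    birth <- c(birth[keep], t)
    k <- k - 1L
  }
  list(lens = lens, tips = tips, n = n)
}

# Mean pairwise differences implied by per-branch mutation counts.
.pi_from_branches <- function(muts, tips, n) {
  if (!length(muts)) return(0)
  desc <- vapply(tips, length, 1L)
  sum(muts * desc * (n - desc)) / (n * (n - 1) / 2)
}

# Number of distinct haplotypes implied by per-branch mutation counts
# (infinite-sites: a tip's haplotype is the set of mutated branches above it).
.k_from_branches <- function(muts, tips, n) {
  hit <- which(muts > 0)
  if (!length(hit)) return(1L)
  m <- matrix(0L, n, length(hit))
  for (j in seq_along(hit)) m[tips[[hit[j]]], j] <- 1L
  nrow(unique(m))
}

# One neutral replicate conditioned on (n, S): S mutations thrown on the tree
# proportionally to branch length (Hudson's fixed-S scheme).
.sim_fixed_s <- function(n, S) {
  br <- .kingman_branches(n)
  muts <- as.vector(rmultinom(1L, S, br$lens))
  list(pi = .pi_from_branches(muts, br$tips, n), S = S)
}

# One neutral replicate at fixed theta (per-sequence scale).
.sim_theta_stats <- function(n, theta) {
  br <- .kingman_branches(n)
  muts <- rpois(length(br$lens), theta / 2 * br$lens)
  list(pi = .pi_from_branches(muts, br$tips, n),
       S = sum(muts),
       K = .k_from_branches(muts, br$tips, n))
}

# Genealogy under the sudden-expansion model: scaled size theta1 for
# x in [0, tau) looking backwards, theta0 beyond. Times in mutational units.
.expansion_branches <- function(n, tau, theta0, theta1) {
  eps <- 1e-10
  tips <- vector("list", 2L * n - 2L)
  lens <- numeric(2L * n - 2L)
  active <- as.list(seq_len(n))
  birth <- numeric(n)
  t <- 0
  b <- 0L
  k <- n
  recent <- TRUE
  while (k > 1L) {
    th <- if (recent) theta1 else theta0
    if (th < eps) {
      # instantaneous coalescence of everything at the current time
      dt <- 0
    } else {
      dt <- rexp(1L, k * (k - 1) / 2 / th)
    }
    if (recent && t + dt >= tau) {
      t <- tau
      recent <- FALSE
      next
    }
    t <- t + dt
    pair <- sample.int(k, 2L)
    i <- pair[1L]; j <- pair[2L]
    for (idx in c(i, j)) {
      b <- b + 1L
      tips[[b]] <- active[[idx]]
      lens[b] <- t - birth[idx]
    }
    merged <- c(active[[i]], active[[j]])
    keep <- setdiff(seq_len(k), c(i, j))
    active <- c(active[keep], list(merged))
    birth <- c(birth[keep], t)
    k <- k - 1L
  }
  list(lens = lens, tips = tips, n = n)
}

# Mismatch spectrum (counts over k = 0..max) of one expansion-model sample.
.sim_expansion_spectrum <- function(n, tau, theta0, theta1) {
  br <- .expansion_branches(n, tau, theta0, theta1)
  muts <- rpois(length(br$lens), br$lens / 2)
  d <- matrix(0, n, n)
  for (b in which(muts > 0)) {
    inn <- br$tips[[b]]
    out <- setdiff(seq_len(n), inn)
    d[inn, out] <- d[inn, out] + muts[b]
  }
  dv <- d[upper.tri(d)] + t(d)[upper.tri(d)]
  tabulate(dv + 1L, nbins = max(dv) + 1L)
}
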