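# Independent brute-force oracles used by the test suite. These deliberately
# re-derive each quantity from first principles, sharing no code with the
# package implementation.

# --- sequence statistics ----------------------------------------------------

# Complete-deletion site filter, independently coded.
oracle_retained <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m[, keep, drop = FALSE]
}

# All-pairs diversity statistics from raw sequences.
oracle_diversity <- function(seqs) {
  m <- oracle_retained(seqs)
  n <- nrow(m)
  L <- ncol(m)
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  red <- apply(m, 1, paste0, collapse = "")
  cnt <- table(red)
  p <- as.numeric(cnt) / n
  h <- n * (1 - sum(p^2)) / (n - 1)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) tot <- tot + sum(m[i, ] != m[j, ])
  pairs <- n * (n - 1) / 2
  list(S = S, h = h, pi = tot / (pairs * L), k_bar = tot / pairs,
       H = length(cnt))
}

# Textbook Tajima's D, written afresh from the published constants.
oracle_tajima_d <- function(seqs) {
  st <- oracle_diversity(seqs)
  n <- length(seqs)
  S <- st$S
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (st$k_bar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Ewens K-distribution by the Chinese-restaurant-process recursion
# (no Stirling numbers): f[k] after i customers.
oracle_ewens_k <- function(n, theta) {
  f <- c(1, rep(0, n - 1))  # after 1 customer, K = 1
  for (i in 1:(n - 1)) {
    g <- numeric(n)
    for (k in 1:i) {
      g[k] <- g[k] + f[k] * i / (theta + i)
      g[k + 1] <- g[k + 1] + f[k] * theta / (theta + i)
    }
    f <- g
  }
  f
}

oracle_fu_fs <- function(n, k_obs, theta) {
  f <- oracle_ewens_k(n, theta)
  sp <- sum(f[k_obs:n])
  log(sp / (1 - sp))
}

# --- graphs -----------------------------------------------------------------

# Union of all minimum spanning trees by exhaustive enumeration of
# spanning trees (n <= 7).
oracle_msn_edges <- function(d) {
  n <- nrow(d)
  pairs <- t(combn(n, 2))
  ne <- nrow(pairs)
  best <- Inf
  trees <- list()
  for (idx in combn(ne, n - 1, simplify = FALSE)) {
    parent <- 1:n
    ok <- TRUE
    for (e in idx) {
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      a <- find(pairs[e, 1]); b <- find(pairs[e, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (!ok) next
    w <- sum(d[pairs[idx, , drop = FALSE]])
    if (w < best - 1e-9) {
      best <- w
      trees <- list(idx)
    } else if (abs(w - best) <= 1e-9) {
      trees[[length(trees) + 1]] <- idx
    }
  }
  used <- sort(unique(unlist(trees)))
  cbind(pairs[used, 1], pairs[used, 2])
}

# Minimum spanning tree cost (Prim), independent implementation.
oracle_mst_cost <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  used <- 1
  cost <- 0
  while (length(used) < n) {
    rest <- setdiff(1:n, used)
    sub <- d[used, rest, drop = FALSE]
    cost <- cost + min(sub)
    j <- rest[(which.min(sub) - 1) %/% length(used) + 1]
    used <- c(used, j)
  }
  cost
}

hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# --- geometry ---------------------------------------------------------------

# Convex hull area via brute force: a point is a hull vertex iff it is not
# strictly inside any triangle of three other points; vertices are then
# ordered by angle around their centroid and the shoelace formula applied.
oracle_hull_area <- function(pts) {
  n <- nrow(pts)
  in_triangle <- function(p, a, b, c) {
    s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
    s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
    (s1 > 1e-12 & s2 > 1e-12 & s3 > 1e-12) |
      (s1 < -1e-12 & s2 < -1e-12 & s3 < -1e-12)
  }
  vertex <- rep(TRUE, n)
  for (p in 1:n) {
    others <- setdiff(1:n, p)
    for (tri in combn(others, 3, simplify = FALSE)) {
      if (in_triangle(pts[p, ], pts[tri[1], ], pts[tri[2], ], pts[tri[3], ])) {
        vertex[p] <- FALSE
        break
      }
    }
  }
  v <- pts[vertex, , drop = FALSE]
  ctr <- colMeans(v)
  v <- v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# --- misc -------------------------------------------------------------------

# Mean silhouette width for two groups on a score matrix.
silhouette_mean <- function(x, groups) {
  x <- as.matrix(x)
  d <- as.matrix(dist(x))
  sil <- vapply(seq_len(nrow(x)), function(i) {
    own <- groups == groups[i]
    a <- mean(d[i, own & seq_len(nrow(x)) != i])
    b <- min(vapply(unique(groups[!own]), function(g) mean(d[i, groups == g]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(sil)
}

# Pairwise sequence difference helper for raw alignments.
seq_diffs <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}
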