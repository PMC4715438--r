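# Median-joining haplotype network construction and export.

#' Hamming distance matrix between haplotypes
#'
#' @param haps an `hm_haplotypes` from [collapse_haplotypes()], or a
#'   character vector of equal-length haplotype strings.
#' @return A symmetric integer matrix of per-site differences.
#' @export
haplotype_distances <- function(haps) {
  hs <- if (inherits(haps, "hm_haplotypes")) haps$haplotypes else as.character(haps)
  if (length(hs) < 2L) .stopf("need at least 2 haplotypes")
  if (length(unique(nchar(hs))) != 1L) .stopf("haplotype lengths differ")
  d <- .hap_dist(hs)
  dimnames(d) <- list(hs, hs)
  d
}

# Minimax connection weights: m[i,j] = the smallest w such that i and j are
# connected using only edges of weight <= w (the weight at which they join
# in the build-by-increasing-weight process). Floyd-Warshall on max-edge
# path cost; node counts here are small.
.minimax <- function(d) {
  m <- d
  n <- nrow(d)
  for (k in seq_len(n)) {
    mk <- pmax(matrix(m[, k], n, n), matrix(m[k, ], n, n, byrow = TRUE))
    m <- pmin(m, mk)
  }
  diag(m) <- 0
  m
}

# Adjacency of the epsilon-relaxed minimum spanning network:
# edge (i,j) included iff d(i,j) <= minimax(i,j) + epsilon.
.msn_adjacency <- function(d, epsilon = 0) {
  mm <- .minimax(d)
  adj <- d <= mm + epsilon
  diag(adj) <- FALSE
  adj
}

# Total weight of a minimum spanning tree of distance matrix d (Prim).
.mst_cost <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(0)
  intree <- logical(n)
  intree[1L] <- TRUE
  best <- d[1L, ]
  cost <- 0
  for (step in seq_len(n - 1L)) {
    cand <- which(!intree)
    j <- cand[which.min(best[cand])]
    cost <- cost + best[j]
    intree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  cost
}

.network_object <- function(nodes, is_median, d, adj, counts, pop_comp,
                            epsilon, cost_trace) {
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  ed <- data.frame(from = nodes[edges[, 1L]], to = nodes[edges[, 2L]],
                   weight = d[edges], stringsAsFactors = FALSE)
  ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(nodes = nodes, is_median = is_median, edges = ed,
                 counts = counts, pop_composition = pop_comp,
                 epsilon = epsilon, cost = .mst_cost(d),
                 cost_trace = cost_trace),
            class = "hm_hapnet")
}

#' Minimum spanning network of haplotypes
#'
#' Union of all minimum spanning trees: an edge is included iff its two
#' endpoints are in different components when only strictly lighter edges
#' are considered (equivalently, its weight equals the minimax path weight).
#'
#' @param d symmetric distance matrix (e.g. [haplotype_distances()]).
#' @return An object of class `hm_hapnet` (no median vectors).
#' @export
minimum_spanning_network <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) .stopf("'d' must be a square matrix")
  nodes <- rownames(d) %||% paste0("H", seq_len(nrow(d)))
  adj <- .msn_adjacency(d, 0)
  .network_object(nodes, rep(FALSE, nrow(d)), d, adj,
                  counts = rep(NA_integer_, nrow(d)), pop_comp = NULL,
                  epsilon = 0, cost_trace = .mst_cost(d))
}

# Majority-consensus (quasi-median) of three equally long strings;
# three-way ties resolved to the lexicographically smallest state.
.quasi_median <- function(a, b, c) {
  am <- strsplit(c(a, b, c), "")
  m <- rbind(am[[1L]], am[[2L]], am[[3L]])
  res <- apply(m, 2L, function(col) {
    tb <- table(col)
    mx <- max(tb)
    if (mx >= 2L) names(tb)[which.max(tb)] else sort(col)[1L]
  })
  paste0(res, collapse = "")
}

#' Median-joining haplotype network
#'
#' Bandelt-style iteration: build the epsilon-relaxed minimum spanning
#' network, propose quasi-median (majority consensus) vectors for triplets
#' of connected nodes, add the candidate that most reduces the total network
#' (minimum spanning) cost, prune median vectors that no longer reduce the
#' cost, and repeat to a fixed point. All tie-breaking is lexicographic on
#' the haplotype strings, so the result is deterministic.
#'
#' @param haps an `hm_haplotypes` from [collapse_haplotypes()], or a
#'   character vector of distinct equal-length haplotype strings.
#' @param epsilon non-negative integer relaxation of the spanning network.
#' @return An object of class `hm_hapnet`: `nodes` (haplotype strings),
#'   `is_median`, `edges` (from, to, weight), `counts` and
#'   `pop_composition` for observed haplotypes, `cost` (minimum spanning
#'   cost of the final node set) and `cost_trace` (cost after each accepted
#'   median, non-increasing).
#' @examples
#' net <- median_joining(c("AAA", "TTA", "ATT"))
#' net$nodes
#' @export
median_joining <- function(haps, epsilon = 0) {
  epsilon <- .check_count(epsilon, "epsilon", min = 0L)
  if (inherits(haps, "hm_haplotypes")) {
    obs <- haps$haplotypes
    counts <- haps$counts
    pop_comp <- if (!all(is.na(haps$pop))) {
      tb <- table(factor(haps$membership, levels = seq_len(haps$H)), haps$pop)
      mat <- matrix(as.integer(tb), nrow = haps$H,
                    dimnames = list(obs, colnames(tb)))
      mat
    } else NULL
  } else {
    obs <- as.character(haps)
    if (anyDuplicated(obs)) .stopf("haplotype strings must be distinct")
    counts <- rep(1L, length(obs))
    pop_comp <- NULL
  }
  if (length(obs) < 2L) .stopf("need at least 2 haplotypes")
  if (length(unique(nchar(obs))) != 1L) .stopf("haplotype lengths differ")
  chars <- unique(unlist(strsplit(obs, "")))
  if (!all(chars %in% c("A", "C", "G", "T", "0", "1", "2", "3")))
    .stopf("haplotypes contain invalid characters: %s",
           paste(setdiff(chars, c("A", "C", "G", "T", "0", "1", "2", "3")), collapse = ","))

  nodes <- obs
  is_median <- rep(FALSE, length(obs))
  d <- .hap_dist(nodes)
  cost_trace <- .mst_cost(d)
  repeat {
    adj <- .msn_adjacency(d, epsilon)
    # candidate quasi-medians from connected triplets (>= 2 of 3 edges)
    n <- length(nodes)
    cands <- character(0)
    if (n >= 3L) {
      trip <- combn(n, 3L)
      for (c_i in seq_len(ncol(trip))) {
        i <- trip[1L, c_i]; j <- trip[2L, c_i]; k <- trip[3L, c_i]
        nlinks <- adj[i, j] + adj[i, k] + adj[j, k]
        if (nlinks >= 2L) {
          qm <- .quasi_median(nodes[i], nodes[j], nodes[k])
          if (!(qm %in% nodes)) cands <- c(cands, qm)
        }
      }
    }
    cands <- sort(unique(cands))
    cur_cost <- .mst_cost(d)
    best <- NULL
    best_cost <- cur_cost
    for (qm in cands) {
      dq <- .hap_dist(c(nodes, qm))
      cq <- .mst_cost(dq)
      if (cq < best_cost || (!is.null(best) && cq == best_cost && qm < best)) {
        best <- qm
        best_cost <- cq
      }
    }
    if (is.null(best)) break
    nodes <- c(nodes, best)
    is_median <- c(is_median, TRUE)
    d <- .hap_dist(nodes)
    cost_trace <- c(cost_trace, best_cost)
  }
  # prune medians whose removal does not increase the spanning cost
  repeat {
    removed <- FALSE
    cur_cost <- .mst_cost(d)
    meds <- which(is_median)
    meds <- meds[order(nodes[meds])]
    for (m in meds) {
      keep <- setdiff(seq_along(nodes), m)
      if (.mst_cost(d[keep, keep, drop = FALSE]) <= cur_cost) {
        nodes <- nodes[keep]
        is_median <- is_median[keep]
        d <- d[keep, keep, drop = FALSE]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  adj <- .msn_adjacency(d, epsilon)
  full_counts <- integer(length(nodes))
  full_counts[!is_median] <- counts[match(nodes[!is_median], obs)]
  net <- .network_object(nodes, is_median, d, adj, full_counts, pop_comp,
                         epsilon, cost_trace)
  net
}

#' @export
print.hm_hapnet <- function(x, ...) {
  cat(sprintf("<hm_hapnet> %d nodes (%d observed, %d median), %d edges, cost %g, epsilon %d\n",
              length(x$nodes), sum(!x$is_median), sum(x$is_median),
              nrow(x$edges), x$cost, x$epsilon))
  invisible(x)
}

.hapnet_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes,
                                                           median = as.integer(net$is_median),
                                                           count = net$counts))
  if (!is.null(net$pop_composition)) {
    for (p in colnames(net$pop_composition)) {
      v <- integer(length(net$nodes))
      idx <- match(rownames(net$pop_composition), net$nodes)
      v[idx] <- net$pop_composition[, p]
      g <- igraph::set_vertex_attr(g, paste0("pop_", p), value = v)
    }
  }
  g
}

#' Write a haplotype network to GML
#'
#' Node attributes carry the median flag, observed counts and (when
#' available) the per-population haplotype composition used for pie-chart
#' style displays.
#'
#' @param net an `hm_hapnet`.
#' @param file output GML path.
#' @return Invisibly, `file`.
#' @export
write_network_gml <- function(net, file) {
  stopifnot(inherits(net, "hm_hapnet"))
  igraph::write_graph(.hapnet_igraph(net), file, format = "gml")
  invisible(file)
}

#' Write a haplotype network edge list (TSV)
#'
#' Columns: node1, node2, weight, node1_median, node2_median.
#'
#' @param net an `hm_hapnet`.
#' @param file output TSV path.
#' @return Invisibly, `file`.
#' @export
write_network_edgelist <- function(net, file) {
  stopifnot(inherits(net, "hm_hapnet"))
  med <- setNames(net$is_median, net$nodes)
  out <- data.frame(node1 = net$edges$from, node2 = net$edges$to,
                    weight = net$edges$weight,
                    node1_median = med[net$edges$from],
                    node2_median = med[net$edges$to])
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
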