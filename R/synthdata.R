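# Synthetic-data generators: every downstream stage can be exercised
# without field data. All generators take explicit seeds and are
# reproducible (identical config => identical output).

#' Configuration for the sequence simulator
#'
#' Defaults emulate a three-population mitochondrial sample separated by
#' two barriers: recent divergence, modest gene flow and per-site diversity
#' in the range observed for closely related hummingbird species.
#'
#' @param n_pops number of populations (2 or 3).
#' @param n_per_pop haploid samples per population.
#' @param locus_length locus length in base pairs.
#' @param theta_per_site scaled per-site diversity (2 Ne u for a haploid
#'   maternally inherited locus).
#' @param divergence_generations generations since the populations split
#'   from a common ancestral deme.
#' @param migration_rate per-generation backwards migration probability:
#'   a scalar (applied to every ordered deme pair) or an `n_pops x n_pops`
#'   matrix with zero diagonal.
#' @param Ne deme size in (haploid) individuals; sets the generation scale
#'   for divergence and migration.
#' @param seed integer seed.
#' @return A validated list of class `hm_seqconfig`.
#' @export
sim_sequence_config <- function(n_pops = 3, n_per_pop = 50, locus_length = 1100,
                                theta_per_site = 0.005,
                                divergence_generations = 10000,
                                migration_rate = 1e-3, Ne = 1000, seed = 1) {
  n_pops <- .check_count(n_pops, "n_pops")
  if (!n_pops %in% c(2L, 3L)) .stopf("'n_pops' must be 2 or 3")
  n_per_pop <- .check_count(n_per_pop, "n_per_pop")
  locus_length <- .check_count(locus_length, "locus_length")
  theta_per_site <- .check_number(theta_per_site, "theta_per_site", min = 0)
  divergence_generations <- .check_number(divergence_generations,
                                          "divergence_generations", min = 0)
  Ne <- .check_count(Ne, "Ne", min = 2L)
  if (is.matrix(migration_rate)) {
    if (any(dim(migration_rate) != n_pops))
      .stopf("'migration_rate' matrix must be %d x %d", n_pops, n_pops)
    if (any(migration_rate < 0)) .stopf("'migration_rate' entries must be >= 0")
    mig <- migration_rate
    diag(mig) <- 0
  } else {
    m <- .check_number(migration_rate, "migration_rate", min = 0)
    mig <- matrix(m, n_pops, n_pops)
    diag(mig) <- 0
  }
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop,
                 locus_length = locus_length, theta_per_site = theta_per_site,
                 divergence_generations = divergence_generations,
                 migration = mig, Ne = Ne,
                 seed = .check_count(seed, "seed", min = 0L)),
            class = "hm_seqconfig")
}

# Structured discrete-generation coalescent. Exact Wright-Fisher parent
# sampling while the per-generation event probability is non-negligible,
# geometric waiting-time jumps otherwise. Returns edges (parent, child,
# length in generations) and the root id; tips are 1..n.
.structured_coalescent <- function(n_per_pop, n_pops, mig, Ne, t_div) {
  n <- n_per_pop * n_pops
  node_id <- seq_len(n)
  deme <- rep(seq_len(n_pops), each = n_per_pop)
  birth <- rep(0, n)
  next_id <- n + 1L
  edges <- list()
  t <- 0
  merged <- n_pops == 1L || t_div <= 0
  if (merged) deme[] <- 1L
  add_edge <- function(parent, child, len) {
    edges[[length(edges) + 1L]] <<- c(parent, child, len)
  }
  coalesce_group <- function(idx, time) {
    # idx: positions in the active vectors sharing one parent
    parent <- next_id
    next_id <<- next_id + 1L
    for (i in idx) add_edge(parent, node_id[i], time - birth[i])
    parent
  }
  while (length(node_id) > 1L) {
    k <- length(node_id)
    if (!merged && t >= t_div) {
      merged <- TRUE
      deme[] <- 1L
    }
    kd <- tabulate(deme, nbins = n_pops)
    p_coal <- sum(kd * (kd - 1) / 2) / Ne
    mig_rates <- if (merged) 0 else rowSums(mig)[deme]
    p_mig <- sum(mig_rates)
    p_tot <- p_coal + p_mig
    if (p_tot > 0.05) {
      # explicit Wright-Fisher generation: sample parents within demes,
      # lineages sharing a parent coalesce (multiple mergers allowed)
      t <- t + 1
      if (!merged) {
        for (i in seq_along(node_id)) {
          rates <- mig[deme[i], ]
          tot <- sum(rates)
          if (tot > 0 && runif(1) < tot) {
            deme[i] <- sample.int(n_pops, 1L, prob = rates)
          }
        }
        if (t >= t_div) { merged <- TRUE; deme[] <- 1L }
      }
      new_node <- integer(0); new_deme <- integer(0); new_birth <- numeric(0)
      for (d in sort(unique(deme))) {
        idx <- which(deme == d)
        par <- sample.int(Ne, length(idx), replace = TRUE)
        for (p in unique(par)) {
          grp <- idx[par == p]
          if (length(grp) == 1L) {
            new_node <- c(new_node, node_id[grp])
            new_deme <- c(new_deme, d)
            new_birth <- c(new_birth, birth[grp])
          } else {
            parent <- coalesce_group(grp, t)
            new_node <- c(new_node, parent)
            new_deme <- c(new_deme, d)
            new_birth <- c(new_birth, t)
          }
        }
      }
      node_id <- new_node; deme <- new_deme; birth <- new_birth
    } else if (p_tot > 0) {
      # geometric jump to the next event (at most one event per generation)
      g <- rgeom(1L, p_tot) + 1
      if (!merged && t + g > t_div) {
        t <- t_div
        next
      }
      t <- t + g
      if (runif(1) < p_coal / p_tot) {
        dprob <- kd * (kd - 1) / 2
        d <- sample.int(n_pops, 1L, prob = dprob)
        idx <- sample(which(deme == d), 2L)
        parent <- coalesce_group(idx, t)
        node_id[idx[1L]] <- parent
        birth[idx[1L]] <- t
        keep <- setdiff(seq_along(node_id), idx[2L])
        node_id <- node_id[keep]; deme <- deme[keep]; birth <- birth[keep]
      } else {
        i <- sample.int(k, 1L, prob = mig_rates)
        deme[i] <- sample.int(n_pops, 1L, prob = mig[deme[i], ])
      }
    } else {
      # no events possible until the demes merge
      t <- t_div
      merged <- TRUE
      deme[] <- 1L
    }
  }
  em <- do.call(rbind, edges)
  list(edges = data.frame(parent = em[, 1L], child = em[, 2L], len = em[, 3L]),
       root = node_id[1L], n = n)
}

# Evolve sequences down the tree: JC-style symmetric substitution, Poisson
# per-branch mutation counts at per-site rate u.
.evolve_sequences <- function(tree, L, u) {
  bases <- c("A", "C", "G", "T")
  n_nodes <- max(tree$edges$parent, tree$edges$child, tree$n)
  seqs <- vector("list", n_nodes)
  seqs[[tree$root]] <- sample(bases, L, replace = TRUE)
  kids <- split(seq_len(nrow(tree$edges)), tree$edges$parent)
  stack <- c(tree$root)
  while (length(stack)) {
    node <- stack[[1L]]
    stack <- stack[-1L]
    for (e in kids[[as.character(node)]]) {
      child <- tree$edges$child[e]
      s <- seqs[[node]]
      nmut <- rpois(1L, tree$edges$len[e] * u * L)
      if (nmut > 0) for (i in seq_len(nmut)) {
        site <- sample.int(L, 1L)
        s[site] <- sample(setdiff(bases, s[site]), 1L)
      }
      seqs[[child]] <- s
      stack <- c(stack, child)
    }
  }
  seqs
}

#' Simulate a labelled sequence alignment
#'
#' Haploid sequences from a structured coalescent (island model with a
#' split time): `n_pops` demes of size `Ne` exchange migrants at the
#' configured per-generation rates and merge into one ancestral deme
#' `divergence_generations` ago. Mutations are placed per branch as
#' Poisson draws at per-site rate `theta_per_site / (2 Ne)` with JC-style
#' symmetric substitution.
#'
#' @param config an [sim_sequence_config()].
#' @return An [hm_alignment()] with population labels `pop1..pop3`.
#' @export
sim_sequences <- function(config) {
  stopifnot(inherits(config, "hm_seqconfig"))
  set.seed(config$seed)
  tree <- .structured_coalescent(config$n_per_pop, config$n_pops,
                                 config$migration, config$Ne,
                                 config$divergence_generations)
  u <- config$theta_per_site / (2 * config$Ne)
  seqs <- .evolve_sequences(tree, config$locus_length, u)
  n <- tree$n
  pop <- rep(paste0("pop", seq_len(config$n_pops)), each = config$n_per_pop)
  ids <- paste0(pop, "_", rep(seq_len(config$n_per_pop), config$n_pops))
  hm_alignment(vapply(seqs[seq_len(n)], paste0, "", collapse = ""), ids, pop)
}

#' Configuration for the microsatellite simulator
#'
#' @param n_clusters number of genetic clusters.
#' @param n_per_cluster individuals per cluster (ignored when `admixture`
#'   is supplied).
#' @param n_loci number of unlinked loci (default 12).
#' @param alleles_per_locus alleles segregating per locus.
#' @param fst_target differentiation level in `[0, 1)` (Balding-Nichols
#'   Dirichlet divergence from shared ancestral frequencies).
#' @param admixture optional matrix (individuals x clusters) of per-individual
#'   mixing proportions, each row summing to 1.
#' @param missing_rate fraction of genotypes set to the missing code -9.
#' @param seed integer seed.
#' @return A validated list of class `hm_genoconfig`.
#' @export
sim_genotype_config <- function(n_clusters = 3, n_per_cluster = 50, n_loci = 12,
                                alleles_per_locus = 8, fst_target = 0.1,
                                admixture = NULL, missing_rate = 0.02, seed = 1) {
  n_clusters <- .check_count(n_clusters, "n_clusters")
  n_loci <- .check_count(n_loci, "n_loci")
  alleles_per_locus <- .check_count(alleles_per_locus, "alleles_per_locus", min = 2L)
  fst_target <- .check_number(fst_target, "fst_target", min = 0, max = 1,
                              strict_max = TRUE)
  missing_rate <- .check_number(missing_rate, "missing_rate", min = 0, max = 1,
                                strict_max = TRUE)
  if (!is.null(admixture)) {
    admixture <- as.matrix(admixture)
    if (ncol(admixture) != n_clusters)
      .stopf("'admixture' must have %d columns", n_clusters)
    if (any(admixture < 0) || any(abs(rowSums(admixture) - 1) > 1e-8))
      .stopf("admixture fractions per individual must be >= 0 and sum to 1")
  } else {
    n_per_cluster <- .check_count(n_per_cluster, "n_per_cluster")
  }
  structure(list(n_clusters = n_clusters, n_per_cluster = n_per_cluster,
                 n_loci = n_loci, alleles_per_locus = alleles_per_locus,
                 fst_target = fst_target, admixture = admixture,
                 missing_rate = missing_rate,
                 seed = .check_count(seed, "seed", min = 0L)),
            class = "hm_genoconfig")
}

#' Simulate diploid microsatellite genotypes
#'
#' Cluster allele frequencies follow the Balding-Nichols construction:
#' shared ancestral frequencies are drawn once per locus and each cluster's
#' frequencies are Dirichlet-distributed around them with concentration
#' `(1 - FST) / FST`, so the realised Weir-Cockerham FST tracks
#' `fst_target`. Each gene copy of an admixed individual first draws its
#' cluster of origin from the individual's admixture fractions. Missing
#' genotypes (both alleles) are coded -9.
#'
#' @param config an [sim_genotype_config()].
#' @return data.frame: `id`, `pop` (majority cluster), two columns per
#'   locus (`L1.a1`, `L1.a2`, ...).
#' @export
sim_microsats <- function(config) {
  stopifnot(inherits(config, "hm_genoconfig"))
  set.seed(config$seed)
  K <- config$n_clusters
  A <- config$alleles_per_locus
  Fst <- config$fst_target
  Q <- config$admixture
  if (is.null(Q)) {
    Q <- matrix(0, K * config$n_per_cluster, K)
    for (k in seq_len(K)) Q[(k - 1L) * config$n_per_cluster + seq_len(config$n_per_cluster), k] <- 1
  }
  n <- nrow(Q)
  rdirichlet <- function(alpha) {
    x <- rgamma(length(alpha), alpha, 1)
    if (sum(x) == 0) x[which.max(alpha)] <- 1
    x / sum(x)
  }
  out <- data.frame(id = paste0("ind", seq_len(n)),
                    pop = paste0("cluster", max.col(Q)),
                    stringsAsFactors = FALSE)
  for (l in seq_len(config$n_loci)) {
    anc <- rdirichlet(rep(1, A))
    freqs <- if (Fst == 0) {
      matrix(anc, K, A, byrow = TRUE)
    } else {
      t(vapply(seq_len(K), function(k) rdirichlet(anc * (1 - Fst) / Fst),
               numeric(A)))
    }
    draw <- function(i) {
      k <- sample.int(K, 1L, prob = Q[i, ])
      sample.int(A, 1L, prob = freqs[k, ])
    }
    a1 <- vapply(seq_len(n), draw, 1L)
    a2 <- vapply(seq_len(n), draw, 1L)
    miss <- runif(n) < config$missing_rate
    a1[miss] <- -9L
    a2[miss] <- -9L
    out[[paste0("L", l, ".a1")]] <- a1
    out[[paste0("L", l, ".a2")]] <- a2
  }
  out
}

#' Configuration for the landscape/climate simulator
#'
#' Two or more groups occupy disjoint longitude bands; per group,
#' background candidates are multivariate normal around a group centroid in
#' climate space, and occurrences follow the same distribution shifted by
#' `occupied_offset`. Default elevations reproduce the observed
#' highland-to-lowland gradient across the two barriers.
#'
#' @param n_vars number of bioclimatic variables (default 19).
#' @param group_centroids matrix (groups x n_vars) of background centroids.
#'   Default: two groups offset by 1.5 SD on the first two variables.
#' @param background_spread per-group SD scale (scalar or vector).
#' @param occupied_offset matrix (groups x n_vars) displacing occurrences
#'   from the background centroid (default 0).
#' @param n_occurrences,n_background_candidates per-group counts.
#' @param elevation_mean,elevation_sd per-group elevation parameters (m).
#' @param seed integer seed.
#' @return A validated list of class `hm_landconfig`.
#' @export
sim_landscape_config <- function(n_vars = 19,
                                 group_centroids = NULL,
                                 background_spread = 1,
                                 occupied_offset = NULL,
                                 n_occurrences = 100,
                                 n_background_candidates = 1000,
                                 elevation_mean = NULL, elevation_sd = NULL,
                                 seed = 1) {
  n_vars <- .check_count(n_vars, "n_vars", min = 2L)
  if (is.null(group_centroids)) {
    group_centroids <- matrix(0, 2L, n_vars)
    group_centroids[2L, 1:2] <- 1.5
  }
  group_centroids <- as.matrix(group_centroids)
  if (ncol(group_centroids) != n_vars) .stopf("'group_centroids' needs %d columns", n_vars)
  if (any(!is.finite(group_centroids))) .stopf("centroids must be finite")
  G <- nrow(group_centroids)
  spread <- rep_len(background_spread, G)
  if (any(spread <= 0)) .stopf("'background_spread' must be positive")
  if (is.null(occupied_offset)) occupied_offset <- matrix(0, G, n_vars)
  occupied_offset <- as.matrix(occupied_offset)
  if (any(dim(occupied_offset) != c(G, n_vars)))
    .stopf("'occupied_offset' must be %d x %d", G, n_vars)
  if (is.null(elevation_mean)) elevation_mean <- c(1375, 921, 542)[seq_len(min(G, 3L))]
  if (is.null(elevation_sd)) elevation_sd <- c(700, 526, 585)[seq_len(min(G, 3L))]
  elevation_mean <- rep_len(elevation_mean, G)
  elevation_sd <- rep_len(elevation_sd, G)
  structure(list(n_vars = n_vars, group_centroids = group_centroids,
                 background_spread = spread, occupied_offset = occupied_offset,
                 n_occurrences = .check_count(n_occurrences, "n_occurrences"),
                 n_background_candidates = .check_count(n_background_candidates,
                                                        "n_background_candidates"),
                 elevation_mean = elevation_mean, elevation_sd = elevation_sd,
                 seed = .check_count(seed, "seed", min = 0L)),
            class = "hm_landconfig")
}

#' Simulate occurrence and background climate tables
#'
#' @param config an [sim_landscape_config()].
#' @return A list with `occurrences` and `background` data.frames: `id`,
#'   `group`, `longitude`, `latitude`, `elevation`, `bio1..bio<n_vars>`.
#' @export
sim_landscape <- function(config) {
  stopifnot(inherits(config, "hm_landconfig"))
  set.seed(config$seed)
  G <- nrow(config$group_centroids)
  nv <- config$n_vars
  vars <- paste0("bio", seq_len(nv))
  lon_bands <- lapply(seq_len(G), function(g) c(-104, -76)[1L] + (g - 1L) * 28 / G + c(0, 28 / G))
  mk <- function(g, n, offset) {
    mu <- config$group_centroids[g, ] + offset
    X <- MASS::mvrnorm(n, mu, diag(config$background_spread[g]^2, nv))
    band <- lon_bands[[g]]
    data.frame(group = paste0("group", g),
               longitude = runif(n, band[1L], band[2L]),
               latitude = runif(n, 8, 25),
               elevation = rnorm(n, config$elevation_mean[g], config$elevation_sd[g]),
               setNames(as.data.frame(X), vars))
  }
  occ <- do.call(rbind, lapply(seq_len(G), function(g)
    mk(g, config$n_occurrences, config$occupied_offset[g, ])))
  bg <- do.call(rbind, lapply(seq_len(G), function(g)
    mk(g, config$n_background_candidates, rep(0, nv))))
  occ <- cbind(id = paste0("occ", seq_len(nrow(occ))), occ)
  bg <- cbind(id = paste0("bg", seq_len(nrow(bg))), bg)
  list(occurrences = occ, background = bg)
}

#' Configuration for the plumage cline simulator
#'
#' @param n_specimens number of specimens.
#' @param cline_midpoints two ordered longitudes (the barrier positions).
#' @param cline_scale logistic scale of each step (degrees longitude).
#' @param lon_margin how far the sampled range extends beyond the barriers.
#' @param noise_sd SD of the integer score noise per character.
#' @param seed integer seed.
#' @return A validated list of class `hm_plumconfig`.
#' @export
sim_plumage_config <- function(n_specimens = 145,
                               cline_midpoints = c(-94.5, -85.5),
                               cline_scale = 0.8, lon_margin = 9,
                               noise_sd = 0.3, seed = 1) {
  if (length(cline_midpoints) != 2L || diff(cline_midpoints) <= 0)
    .stopf("'cline_midpoints' must be two increasing (west -> east) longitudes")
  structure(list(n_specimens = .check_count(n_specimens, "n_specimens", min = 2L),
                 cline_midpoints = as.numeric(cline_midpoints),
                 cline_scale = .check_number(cline_scale, "cline_scale", min = 0,
                                             strict_min = TRUE),
                 lon_margin = .check_number(lon_margin, "lon_margin", min = 0,
                                            strict_min = TRUE),
                 noise_sd = .check_number(noise_sd, "noise_sd", min = 0),
                 seed = .check_count(seed, "seed", min = 0L)),
            class = "hm_plumconfig")
}

#' Simulate a clinal plumage table
#'
#' Specimens are spaced along the longitude range spanning both barriers;
#' the expected score of each character declines from its maximum at the
#' western extreme to 0 at the eastern extreme through two logistic steps
#' centred on the barrier longitudes, with optional integer score noise.
#'
#' @param config an [sim_plumage_config()].
#' @param scheme a plumage scheme (default [default_plumage_scheme()]).
#' @return data.frame: `id`, `longitude`, one state column per character.
#' @export
sim_plumage <- function(config, scheme = default_plumage_scheme()) {
  stopifnot(inherits(config, "hm_plumconfig"))
  .check_scheme(scheme)
  set.seed(config$seed)
  m <- config$cline_midpoints
  lon <- seq(m[1L] - config$lon_margin, m[2L] + config$lon_margin,
             length.out = config$n_specimens)
  f <- 1 - 0.5 * plogis((lon - m[1L]) / config$cline_scale) -
    0.5 * plogis((lon - m[2L]) / config$cline_scale)
  out <- data.frame(id = paste0("spec", seq_along(lon)), longitude = lon)
  for (ch in names(scheme)) {
    sc <- scheme[[ch]]
    mx <- max(sc)
    raw <- f * mx
    if (config$noise_sd > 0) raw <- raw + rnorm(length(lon), 0, config$noise_sd)
    score <- pmin(pmax(round(raw), 0L), mx)
    # map scores back to state names (first state carrying that score)
    state_of <- vapply(score, function(s) names(sc)[which(sc == s)[1L]], "")
    out[[ch]] <- state_of
  }
  out
}
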