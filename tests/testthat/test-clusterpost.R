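# Evanno DeltaK and genotype PCA post-processing.

make_lnp <- function(means, R = 10, sd = 10, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(means), function(K)
    data.frame(K = K, replicate = 1:R, lnP = means[K] + rnorm(R, 0, sd))))
}

test_that("DeltaK vanishes for linear lnP and finds a constructed elbow", {
  lin <- make_lnp(seq(-5000, -3000, by = 500), sd = 1, seed = 2)
  # inject exact linearity, keeping replicate scatter in sd only
  lin$lnP <- -5000 + 500 * (lin$K - 1) + rep(rnorm(10, 0, 1), 5)[
    (lin$K - 1) * 10 + lin$replicate]
  dk <- evanno_delta_k(lin)
  inner <- dk$summary$deltaK[!is.na(dk$summary$deltaK)]
  expect_true(all(inner < 1e-8))

  elbow <- make_lnp(c(-8000, -6000, -4000, -3950, -3900), sd = 20, seed = 3)
  dk2 <- evanno_delta_k(elbow)
  expect_equal(dk2$best_K, 3L)
  # hand recomputation at K = 3
  reps <- split(elbow$lnP, elbow$K)
  l2 <- mean(abs(reps[[4]] - 2 * reps[[3]] + reps[[2]]))
  expect_equal(dk2$summary$deltaK[3], l2 / sd(reps[[3]]))
})

test_that("DeltaK matches a spreadsheet-style recomputation on random tables", {
  tab <- make_lnp(c(-9000, -7500, -7000, -6900, -6850), R = 10, sd = 50, seed = 4)
  dk <- evanno_delta_k(tab)
  reps <- split(tab$lnP, tab$K)
  for (K in 2:4) {
    l2 <- mean(abs(reps[[K + 1]] - 2 * reps[[K]] + reps[[K - 1]]))
    expect_equal(dk$summary$deltaK[K], l2 / sd(reps[[K]]))
  }
  # invariant to adding a constant to every lnP
  tab2 <- tab; tab2$lnP <- tab2$lnP + 12345
  expect_equal(evanno_delta_k(tab2)$summary$deltaK, dk$summary$deltaK)
  # validation
  expect_error(evanno_delta_k(tab[tab$K <= 2, ]), "at least 3")
  const <- tab; const$lnP[const$K == 3] <- -7000
  expect_error(evanno_delta_k(const), "K = 3")
})

test_that("STRUCTURE logs are scraped into (K, replicate, lnP) triples", {
  files <- vapply(1:4, function(i) {
    f <- tempfile(fileext = ".out")
    K <- c(2, 2, 3, 3)[i]
    writeLines(c("STRUCTURE by Pritchard et al.",
                 sprintf("%d populations assumed", K),
                 "-------------------------",
                 sprintf("Estimated Ln Prob of Data   = %.1f", -5000 - i * 10)),
               f)
    f
  }, "")
  tab <- read_structure_lnp(files)
  expect_equal(tab$K, c(2L, 2L, 3L, 3L))
  expect_equal(tab$replicate, c(1, 2, 1, 2))
  expect_equal(tab$lnP, c(-5010, -5020, -5030, -5040))
})

test_that("STRUCTURE-format genotype files parse in both layouts", {
  one <- tempfile(fileext = ".str")
  writeLines(c("ind1 1 101 103 200 200",
               "ind2 1 101 101 200 202",
               "ind3 2 103 103 -9 -9"), one)
  g1 <- read_structure_genotypes(one, rows_per_individual = 1)
  expect_equal(names(g1), c("id", "pop", "L1.a1", "L1.a2", "L2.a1", "L2.a2"))
  expect_equal(g1$L1.a2, c(103, 101, 103))
  expect_equal(g1$L2.a1[3], -9)

  two <- tempfile(fileext = ".str")
  writeLines(c("ind1 1 101 200",
               "ind1 1 103 200",
               "ind2 2 101 -9",
               "ind2 2 101 -9"), two)
  g2 <- read_structure_genotypes(two, rows_per_individual = 2)
  expect_equal(g2$L1.a1, c(101, 101))
  expect_equal(g2$L1.a2, c(103, 101))
  expect_equal(g2$L2.a2, c(200, -9))
  # round trip through the package writer/reader
  f <- tempfile(fileext = ".tsv")
  write_genotypes(g1, f)
  expect_equal(read_genotypes(f), g1)
})

test_that("genotype PCA separates simulated clusters", {
  gm <- sim_microsats(sim_genotype_config(n_clusters = 2, n_per_cluster = 60,
                                          fst_target = 0.3, missing_rate = 0.02,
                                          seed = 9))
  p <- genotype_pca(gm, n_axes = 2)
  expect_gt(silhouette_mean(p$scores[, 1, drop = FALSE], p$pop), 0.5)
})

test_that("genotype PCA is deterministic, well-ordered and order-invariant", {
  gm <- sim_microsats(sim_genotype_config(n_clusters = 2, n_per_cluster = 20,
                                          fst_target = 0.2, missing_rate = 0.05,
                                          seed = 5))
  # duplicated individuals map to identical coordinates
  gm2 <- rbind(gm, gm[3, ])
  gm2$id <- make.unique(gm2$id)
  p2 <- genotype_pca(gm2)
  expect_equal(unname(p2$scores[3, ]), unname(p2$scores[nrow(gm2), ]))

  p <- genotype_pca(gm)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)

  # locus-order invariance (axes up to sign; here signs are fixed by the
  # largest-loading convention so scores should match up to that flip)
  p_r <- genotype_pca(gm[, c("id", "pop",
                             as.vector(rbind(paste0("L", 12:1, ".a1"),
                                             paste0("L", 12:1, ".a2"))))])
  k <- min(4, ncol(p$scores), ncol(p_r$scores))
  for (ax in seq_len(k)) {
    expect_equal(abs(unname(p$scores[, ax])), abs(unname(p_r$scores[, ax])),
                 tolerance = 1e-8)
  }
})

test_that("all-missing loci are dropped with a warning", {
  gm <- sim_microsats(sim_genotype_config(n_clusters = 2, n_per_cluster = 10,
                                          n_loci = 3, fst_target = 0.1,
                                          missing_rate = 0, seed = 2))
  gm$L2.a1 <- -9L
  gm$L2.a2 <- -9L
  expect_warning(p <- genotype_pca(gm), "L2")
  expect_equal(p$dropped_loci, "L2")
})
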