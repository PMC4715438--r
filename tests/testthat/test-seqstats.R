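# Diversity statistics, neutrality tests and the mismatch machinery.

toy5 <- hm_alignment(c("AAAAAAAAAA",
                       "AAAAAAAAAT",
                       "AAAAAAAATT",
                       "AAAACAAAAA",
                       "AAAACAAAAT"),
                     ids = paste0("s", 1:5))

test_that("haplotype collapsing matches a set-based oracle", {
  aln <- hm_alignment(c("ACGT", "ACGT", "ACGT"))
  h <- collapse_haplotypes(aln)
  expect_equal(h$H, 1L)
  expect_equal(h$counts, 3L)

  aln2 <- hm_alignment(c("AAAA", "TTTT", "AAAA", "TTTT"))
  h2 <- collapse_haplotypes(aln2)
  expect_equal(h2$H, 2L)
  expect_equal(h2$counts, c(2L, 2L))
  expect_equal(h2$haplotypes, c("AAAA", "TTTT"))  # first-occurrence order

  set.seed(42)
  seqs <- vapply(1:50, function(i)
    paste0(sample(c("A", "C"), 6, replace = TRUE), collapse = ""), "")
  h3 <- collapse_haplotypes(hm_alignment(seqs))
  expect_equal(h3$H, length(unique(seqs)))
  expect_equal(sum(h3$counts), 50L)
  expect_error(collapse_haplotypes(hm_alignment(character(0))), "non-empty")
})

test_that("alignments round-trip through FASTA with their population map", {
  aln <- sim_sequences(sim_sequence_config(n_pops = 2, n_per_pop = 6,
                                           locus_length = 120, seed = 13))
  fa <- tempfile(fileext = ".fa"); pm <- tempfile(fileext = ".csv")
  write_alignment(aln, fa, pm)
  back <- read_alignment(fa, pm)
  expect_equal(back$seq, aln$seq)
  expect_equal(back$ids, aln$ids)
  expect_equal(back$pop, aln$pop)
  expect_equal(subset_population(back, "pop2")$ids, aln$ids[aln$pop == "pop2"])
})

test_that("gap and ambiguity sites are removed under complete deletion", {
  aln <- hm_alignment(c("A-GTN", "ACGTN", "ACGAN"))
  h <- collapse_haplotypes(aln)
  expect_equal(h$L, 3L)  # columns 2 (gap) and 5 (N) dropped... column 1 kept
  expect_equal(h$retained_sites, c(1L, 3L, 4L))
})

test_that("diversity statistics match hand values and the all-pairs oracle", {
  flat <- hm_alignment(rep("ACGTACGT", 4))
  st <- diversity_stats(collapse_haplotypes(flat))
  expect_equal(st$S, 0L)
  expect_equal(st$h, 0)
  expect_equal(st$pi, 0)

  # n = 4, haplotype counts (2,1,1): h = (4/3)(1 - (0.25 + 0.0625 + 0.0625))
  aln <- hm_alignment(c("AAAA", "AAAA", "AAAT", "AATA"))
  st2 <- diversity_stats(collapse_haplotypes(aln))
  expect_equal(st2$h, (4 / 3) * (1 - (0.5^2 + 0.25^2 + 0.25^2)))

  two <- hm_alignment(c("AAAAAAAAAA", "TTAAAAAAAA"))
  expect_equal(diversity_stats(collapse_haplotypes(two))$pi, 0.2)

  expect_error(diversity_stats(collapse_haplotypes(hm_alignment("ACGT"))), "n < 2")

  for (s in 1:5) {
    set.seed(s)
    seqs <- vapply(1:15, function(i)
      paste0(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""), "")
    st <- diversity_stats(collapse_haplotypes(hm_alignment(seqs)))
    or <- oracle_diversity(seqs)
    expect_equal(st$S, or$S)
    expect_equal(st$h, or$h)
    expect_equal(st$pi, or$pi)
  }
})

test_that("diversity is invariant under sample reordering", {
  set.seed(9)
  seqs <- vapply(1:12, function(i)
    paste0(sample(c("A", "G"), 15, replace = TRUE), collapse = ""), "")
  a <- diversity_stats(collapse_haplotypes(hm_alignment(seqs)))
  b <- diversity_stats(collapse_haplotypes(hm_alignment(sample(seqs))))
  expect_equal(a$h, b$h)
  expect_equal(a$pi, b$pi)
  expect_equal(a$S, b$S)
})

test_that("Tajima's D agrees with an independent implementation", {
  expect_error(tajimas_d(hm_alignment(rep("ACGT", 5))), "undefined")
  td <- tajimas_d(toy5, n_replicates = 200, seed = 1)
  expect_equal(td$D, oracle_tajima_d(toy5$seq), tolerance = 1e-12)
  # seed reproducibility of the simulated p-value
  td2 <- tajimas_d(toy5, n_replicates = 200, seed = 1)
  expect_identical(td$p, td2$p)
  expect_true(td$p >= 0 && td$p <= 1)
})

test_that("neutral Tajima's D is centred near zero", {
  set.seed(4)
  ds <- vapply(1:500, function(i) {
    r <- hummintro:::.sim_theta_stats(30, 5)
    if (r$S == 0) return(NA_real_)
    hummintro:::.tajima_d_value(30, r$S, r$pi)
  }, 0)
  expect_gt(mean(ds, na.rm = TRUE), -0.3)
  expect_lt(mean(ds, na.rm = TRUE), 0.3)
})

test_that("Fu's S' matches direct Ewens enumeration and Fs behaves", {
  for (case in list(list(n = 6, k = 3, th = 2), list(n = 8, k = 5, th = 1.5),
                    list(n = 6, k = 6, th = 0.5))) {
    ours <- hummintro:::.fu_fs_value(case$n, case$k, case$th)
    theirs <- oracle_fu_fs(case$n, case$k, case$th)
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
  # many haplotypes at tiny theta -> strongly negative Fs
  expect_lt(hummintro:::.fu_fs_value(5, 5, 0.05), -5)

  aln <- hm_alignment(c("AAAA", "AAAT", "AATT", "ATTT", "TTTT", "AAAA"))
  f1 <- fu_fs(aln, n_replicates = 100, seed = 2)
  perm <- c(3, 1, 6, 2, 5, 4)
  f2 <- fu_fs(hm_alignment(aln$seq[perm]), n_replicates = 100, seed = 2)
  expect_equal(f1$Fs, f2$Fs)
  expect_error(fu_fs(hm_alignment(rep("AC", 4))), "undefined")
})

test_that("mismatch spectra count pairs correctly", {
  flat <- mismatch_spectrum(hm_alignment(rep("ACGT", 6)))
  expect_equal(as.integer(flat), 15L)
  expect_equal(names(flat), "0")

  # pairwise distances {1,1,2} -> spectrum {1:2, 2:1}
  tri <- mismatch_spectrum(hm_alignment(c("AAA", "AAT", "ATA")))
  expect_equal(as.integer(tri), c(0L, 2L, 1L))

  set.seed(3)
  seqs <- vapply(1:10, function(i)
    paste0(sample(c("A", "T"), 12, replace = TRUE), collapse = ""), "")
  sp <- mismatch_spectrum(hm_alignment(seqs))
  expect_equal(sum(sp), 45)
})

test_that("sudden-expansion model probabilities are a proper distribution", {
  p <- mismatch_model_probs(0:300, tau = 3, theta0 = 0.5, theta1 = 100)
  expect_equal(sum(p), 1, tolerance = 1e-8)
  expect_true(all(p >= 0))
  # theta0 = 0, theta1 = Inf: the pure Poisson(tau) wave
  expect_equal(mismatch_model_probs(0:20, 3, 0, Inf), dpois(0:20, 3),
               tolerance = 1e-12)
  # tau = 0 collapses to the theta0 equilibrium geometric
  th <- 2.5
  expect_equal(mismatch_model_probs(0:50, 0, th, 10),
               th^(0:50) / (1 + th)^(1:51), tolerance = 1e-12)
})

test_that("degenerate spectra yield a flagged tau = 0 fit", {
  sp <- mismatch_spectrum(hm_alignment(rep("ACGTACGT", 5)))
  expect_warning(fit <- fit_sudden_expansion(sp, n_bootstrap = 10, seed = 1),
                 "degenerate")
  expect_equal(fit$tau, 0)
  expect_equal(fit$SSD, 0)
  expect_true(fit$degenerate)
})

test_that("expansion fits are seed-reproducible", {
  sp <- sim_expansion_spectrum(30, 3, 0.5, 50, seed = 10)
  f1 <- fit_sudden_expansion(sp, n_bootstrap = 30, seed = 7)
  f2 <- fit_sudden_expansion(sp, n_bootstrap = 30, seed = 7)
  expect_identical(f1$p_SSD, f2$p_SSD)
  expect_identical(f1$p_Hri, f2$p_Hri)
  expect_true(f1$theta0 <= f1$theta1)
  expect_gte(f1$tau, 0)
})
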