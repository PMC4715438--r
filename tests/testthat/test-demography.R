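# Coalescent-to-demography conversions and the migration-era comparison.

# The published isolation-with-migration summary (thousands of individuals),
# survival-rate 0.30 column first, 0.52 column second.
table1_n <- list(
  bery_cyan = list(lo30 = c(45, 150, 12),  mean30 = c(96, 242, 95),
                   hi30 = c(180, 373, 275),
                   lo52 = c(35, 118, 10),  mean52 = c(76, 191, 75),
                   hi52 = c(142, 293, 217)),
  sauc_cyan = list(lo30 = c(89, 134, 11),  mean30 = c(195, 215, 116),
                   hi30 = c(387, 327, 294),
                   lo52 = c(70, 106, 9),   mean52 = c(153, 170, 91),
                   hi52 = c(305, 257, 231)),
  bery_sauc = list(lo30 = c(38, 102, 5),   mean30 = c(83, 220, 101),
                   hi30 = c(154, 431, 212),
                   lo52 = c(30, 80, 4),    mean52 = c(65, 173, 80),
                   hi52 = c(122, 339, 167)))

test_that("generation time follows T = a + s/(1 - s)", {
  expect_equal(round(generation_time(2, 0.30)$T, 2), 2.43)
  expect_equal(round(generation_time(2, 0.52)$T, 2), 3.08)
  expect_equal(generation_time(3, 0)$T, 3)
  expect_error(generation_time(2, 1), "s")
  # strictly increasing in both arguments
  for (i in 1:20) {
    a <- runif(1, 0.5, 5); s <- runif(1, 0, 0.9)
    expect_gt(generation_time(a + 0.1, s)$T, generation_time(a, s)$T)
    expect_gt(generation_time(a, s + 0.05)$T, generation_time(a, s)$T)
  }
})

test_that("divergence time and effective size scale inversely with the rate", {
  r <- rate_spec(1.45e-8, 1100)
  expect_equal(divergence_years(0, r), 0)
  expect_equal(divergence_years(1.595, rate_spec(1.595e-5 / 1100, 1100)), 1e5)
  r2 <- rate_spec(2 * 1.45e-8, 1100)
  expect_equal(divergence_years(3, r) / divergence_years(3, r2), 2)

  gen <- generation_time(2, 0.3)
  expect_equal(effective_size(0, r, gen), 0)
  # Ne ~ 1/T
  genB <- generation_time(4, 0.3)
  expect_equal(effective_size(5, r, gen) / effective_size(5, r, genB),
               genB$T / gen$T)
  # round trip to 10 significant digits
  q <- 3.14159
  ne <- effective_size(q, r, gen)
  expect_equal(ne * 4 * r$U * gen$T, q, tolerance = 1e-10)
  expect_error(rate_spec(0, 1100), "per_site_per_year")
})

test_that("rescaling between survival assumptions matches the printed table", {
  T30 <- generation_time(2, 0.30)$T
  T52 <- generation_time(2, 0.52)$T
  expect_equal(rescale_ne(96, T30, T52), 76)
  expect_equal(rescale_ne(242, T30, T52), 191)
  expect_equal(rescale_ne(95, T30, T52), 75)
  expect_equal(rescale_ne(123.4, 2.5, 2.5), 123)  # identity up to rounding
  expect_equal(rescale_ne(123.4, 2.5, 2.5, digits = 1), 123.4)

  # every printed cell is reproduced to within one unit in the last digit
  # (the two columns of the source table were rounded independently)
  for (pair in table1_n) {
    for (row in c("lo", "mean", "hi")) {
      got <- rescale_ne(pair[[paste0(row, "30")]], T30, T52)
      expect_true(all(abs(got - pair[[paste0(row, "52")]]) <= 1))
    }
  }
})

test_that("migration-rate conversions follow the MIGRATE conventions", {
  expect_equal(m_from_M(10.66, 5e-4), 5.33e-3)
  expect_equal(m_from_M(0, 5e-4), 0)
  expect_warning(lit <- m_from_M(10.66, 5e-4, mode = "paper-literal"), "literal")
  expect_equal(lit, 10.66 / 5e-4)
  expect_equal(nem_from_theta_M(1, 4), 1)
  expect_equal(nem_from_theta_M(0, 7), 0)
  th <- 0.83; M <- 12.61
  expect_equal(nem_from_theta_M(th, M) / (th / 4), M, tolerance = 1e-12)
})

test_that("the Mantel test matches exhaustive enumeration on 3x3 input", {
  A <- matrix(c(0, 1, 2, 3, 0, 4, 5, 6, 0), 3, 3, byrow = TRUE)
  self <- mantel_test(A, A, n_perm = 100)
  expect_equal(self$r, 1)
  expect_true(self$exact)
  scaled <- mantel_test(A, 3 * A, n_perm = 100)
  expect_equal(scaled$r, 1)

  set.seed(12)
  B <- matrix(runif(9), 3, 3); diag(B) <- 0
  got <- mantel_test(A, B, n_perm = 100)
  # brute-force oracle over all 6 label permutations
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  off <- !diag(TRUE, 3)
  r_obs <- cor(A[off], B[off])
  rs <- vapply(perms, function(p) cor(A[off], B[p, p][off]), 0)
  expect_equal(got$r, r_obs)
  expect_equal(got$p, mean(abs(rs) >= abs(r_obs) - 1e-12))
  expect_error(mantel_test(A, matrix(1, 3, 3)), "constant")
})

test_that("Mantel r agrees with vegan on symmetric matrices", {
  set.seed(20)
  x <- matrix(rnorm(20), 10, 2)
  y <- x + matrix(rnorm(20, sd = 0.5), 10, 2)
  A <- as.matrix(dist(x)); B <- as.matrix(dist(y))
  ours <- mantel_test(A, B, n_perm = 500, seed = 1)
  ref <- vegan::mantel(as.dist(A), as.dist(B), permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("Mantel null rejection is near the nominal level", {
  set.seed(99)
  rej <- vapply(1:500, function(i) {
    A <- matrix(runif(25), 5, 5); diag(A) <- 0
    B <- matrix(runif(25), 5, 5); diag(B) <- 0
    mantel_test(A, B, n_perm = 200, seed = i)$p <= 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("era comparison converts, correlates and reports ratios", {
  contemp <- matrix(c(0.98, 0.01, 0.01,
                      0.02, 0.97, 0.01,
                      0.07, 0.03, 0.90), 3, 3, byrow = TRUE,
                    dimnames = list(c("bery", "cyan", "sauc"),
                                    c("bery", "cyan", "sauc")))
  hist <- matrix(c(0, 10.66, 2.92,
                   4.47, 0, 1.96,
                   3.37, 12.61, 0), 3, 3, byrow = TRUE,
                 dimnames = dimnames(contemp))
  tabs <- migration_tables(contemp, hist, theta = c(0.5, 0.6, 0.7), mu = 5e-4)
  cmp <- compare_migration_eras(tabs, n_perm = 200, seed = 3)
  expect_s3_class(cmp, "hm_eracomparison")
  expect_true(abs(cmp$mantel$r) <= 1)
  off <- !diag(TRUE, 3)
  expect_equal(cmp$era_ratio[off], (hist * 5e-4 / contemp)[off])
  expect_equal(cmp$Nem[1, 2], nem_from_theta_M(0.5, 10.66))
  # conversion mode does not change r or p
  cmp2 <- compare_migration_eras(tabs, n_perm = 200, seed = 3,
                                 mode = "paper-literal")
  expect_equal(cmp$mantel$r, cmp2$mantel$r)
  expect_equal(cmp$mantel$p, cmp2$mantel$p)

  # identical eras: r = 1 at the smallest attainable p
  same <- migration_tables(contemp, contemp / 5e-4, mu = 5e-4)
  cs <- compare_migration_eras(same, n_perm = 100, seed = 1)
  expect_equal(cs$mantel$r, 1)
  # anti-ordered matrices correlate negatively
  anti <- matrix(c(0, 6, 5, 4, 0, 3, 2, 1, 0), 3, 3, byrow = TRUE)
  fwd <- matrix(c(0, 1, 2, 3, 0, 4, 5, 6, 0), 3, 3, byrow = TRUE)
  expect_lt(mantel_test(fwd, anti, 100)$r, 0)

  expect_error(migration_tables(contemp * 2, hist), "sum to 1")
})

test_that("matrix and parameter readers round-trip", {
  m <- matrix(c(0, 1.5, 2.5, 0.5, 0, 3.5, 4.5, 5.5, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(population = rownames(m), m, check.names = FALSE), f,
            row.names = FALSE)
  expect_equal(unname(read_migration_matrix(f)), unname(m))
  fi <- tempfile(fileext = ".csv")
  write.csv(data.frame(parameter = c("q1", "t"), mean = c(1.2, 0.8),
                       HPD95Lo = c(0.2, 0.1), HPD95Hi = c(3, 2)), fi,
            row.names = FALSE)
  expect_equal(read_ima_params(fi)$mean, c(1.2, 0.8))
})
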