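# Variable pruning, polygon geometry, background sampling and the
# divergence/conservatism test.

test_that("greedy variable pruning follows the correlation rule", {
  set.seed(2)
  n <- 50
  x1 <- rnorm(n)
  tab <- data.frame(v1 = x1, v2 = x1, v3 = rnorm(n),
                    v4 = 0.9 * x1 + 0.1 * rnorm(n), v5 = rnorm(n))
  kept <- select_uncorrelated_vars(tab, threshold = 0.7)
  expect_equal(kept[1], "v1")
  expect_false("v2" %in% kept)  # perfect correlate of the higher-priority v1
  expect_false("v4" %in% kept)
  expect_true(all(c("v3", "v5") %in% kept))
  # brute-force verification of the greedy rule
  verify <- character(0)
  for (v in names(tab)) {
    if (all(vapply(verify, function(k) abs(cor(tab[[v]], tab[[k]])) < 0.7, TRUE)))
      verify <- c(verify, v)
  }
  expect_identical(kept, verify)

  ind <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_setequal(select_uncorrelated_vars(ind, 0.99), c("a", "b", "c"))
  tab$const <- 1
  expect_warning(k2 <- select_uncorrelated_vars(tab), "constant")
  expect_false("const" %in% k2)
  # custom priority: later-listed duplicate wins
  expect_true("v2" %in% select_uncorrelated_vars(tab[, 1:3],
                                                 priority = c("v2", "v1", "v3")))
})

test_that("minimum convex polygons match brute-force hulls", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  hull <- minimum_convex_polygon(sq)
  expect_equal(nrow(hull), 4L)
  expect_false(any(hull[, 1] == 0.5 & hull[, 2] == 0.5))
  # counter-clockwise orientation: positive signed area
  x <- hull[, 1]; y <- hull[, 2]
  expect_gt(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2, 0)
  expect_equal(polygon_area(hull), 1)

  for (s in 1:3) {
    set.seed(s)
    pts <- cbind(runif(12), runif(12))
    hp <- minimum_convex_polygon(pts)
    expect_equal(polygon_area(hp), oracle_hull_area(pts), tolerance = 1e-10)
    expect_true(all(point_in_polygon(hp, pts)))
  }
  expect_error(minimum_convex_polygon(cbind(1:5, 2 * (1:5))), "degenerate|collinear")
})

test_that("background sampling is uniform inside the polygon", {
  hull <- minimum_convex_polygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  bg <- sample_background(hull, 1000, seed = 4)
  expect_true(all(point_in_polygon(hull, bg)))
  se <- sqrt(1 / 12 / 1000)
  expect_lt(abs(mean(bg$longitude) - 0.5), 3 * se)
  expect_lt(abs(mean(bg$latitude) - 0.5), 3 * se)
  expect_identical(sample_background(hull, 50, seed = 9),
                   sample_background(hull, 50, seed = 9))
  # climate attachment from the nearest synthetic record
  cf <- data.frame(longitude = c(0.25, 0.75), latitude = c(0.5, 0.5),
                   bio1 = c(10, 20))
  bg2 <- sample_background(hull, 200, climate_field = cf, seed = 5)
  expect_equal(bg2$bio1, ifelse(bg2$longitude < 0.5, 10, 20))
})

test_that("niche axes are fitted on backgrounds with fixed sign and ordering", {
  set.seed(6)
  n <- 200
  bg <- data.frame(bio1 = rnorm(n, sd = 5), bio2 = rnorm(n, sd = 1),
                   bio3 = rnorm(n, sd = 1))
  occ <- data.frame(bio1 = rnorm(40, sd = 5), bio2 = rnorm(40, sd = 1),
                    bio3 = rnorm(40, sd = 1))
  ax <- fit_niche_axes(occ, bg, c("bio1", "bio2", "bio3"), standardize = FALSE)
  expect_gt(abs(ax$loadings["bio1", 1]), 0.9)
  expect_true(all(diff(ax$explained) <= 1e-12))
  # the background mean projects to the origin
  ctr <- as.data.frame(t(colMeans(bg)))
  prj <- fit_niche_axes(ctr, bg, c("bio1", "bio2", "bio3"))$occ_scores
  expect_equal(unname(as.vector(prj)), rep(0, 3), tolerance = 1e-10)
})

test_that("the jackknife null matches a duplicate implementation", {
  set.seed(7)
  bgA <- rnorm(40); bgB <- rnorm(40) + 1
  null <- background_divergence_null(bgA, bgB, n_rep = 250, fraction = 0.75,
                                     seed = 13)
  # duplicate the sampling scheme with the same seed stream
  set.seed(13)
  mA <- ceiling(0.75 * 40); mB <- ceiling(0.75 * 40)
  reps <- vapply(1:250, function(i)
    abs(mean(sample(bgA, mA)) - mean(sample(bgB, mB))), 0)
  qs <- unname(quantile(reps, c(0.025, 0.975)))
  expect_equal(null$lo, qs[1])
  expect_equal(null$hi, qs[2])
  expect_gte(null$lo, 0)

  # fraction = 1 without replacement: every replicate equals the observed D
  n1 <- suppressWarnings(background_divergence_null(bgA, bgB, n_rep = 50,
                                                    fraction = 1, seed = 1))
  expect_equal(n1$lo, n1$hi)
  expect_equal(n1$lo, abs(mean(bgA) - mean(bgB)))
  expect_warning(background_divergence_null(bgA, bgB, n_rep = 50, seed = 1),
                 "unstable")
})

test_that("axis classification reproduces the published rule", {
  expect_equal(classify_axis(0.88, 1.25, 1.44), "conservatism")
  expect_equal(classify_axis(0.59, 0.05, 0.33), "divergence")
  expect_equal(classify_axis(0.30, 0.16, 0.53), "none")
  expect_error(classify_axis(1.10, 0.93, 0.17), "malformed")
})

test_that("the niche test is symmetric under group relabelling", {
  land <- sim_landscape(sim_landscape_config(n_vars = 6, n_occurrences = 60,
                                             n_background_candidates = 80,
                                             seed = 14))
  occ <- land$occurrences; bg <- land$background
  g1o <- occ[occ$group == "group1", ]; g2o <- occ[occ$group == "group2", ]
  g1b <- bg[bg$group == "group1", ]; g2b <- bg[bg$group == "group2", ]
  a <- niche_divergence_test(g1o, g1b, g2o, g2b, n_axes = 3, n_rep = 150, seed = 2)
  b <- niche_divergence_test(g2o, g2b, g1o, g1b, n_axes = 3, n_rep = 150, seed = 2)
  expect_equal(a$d_occ, b$d_occ)
  expect_equal(a$classification, b$classification)
})

test_that("axis-coordinate correlations behave as expected", {
  set.seed(15)
  n <- 60
  coords <- data.frame(longitude = runif(n, -100, -80),
                       latitude = runif(n, 8, 25))
  scores <- cbind(ax1 = coords$longitude, ax2 = rnorm(n))
  r <- axis_geo_correlation(scores, coords)
  expect_equal(r$r_longitude[1], 1)
  expect_lt(abs(r$r_longitude[2]), 0.5)
  # invariant to affine rescaling of the coordinates
  coords2 <- data.frame(longitude = 3 * coords$longitude + 7,
                        latitude = 0.5 * coords$latitude - 2)
  r2 <- axis_geo_correlation(scores, coords2)
  expect_equal(r$r_longitude, r2$r_longitude)
  expect_equal(r$r_latitude, r2$r_latitude)
  expect_warning(axis_geo_correlation(cbind(rep(1, n)), coords), "constant")
})

test_that("elevation comparison is a calibrated rank test", {
  # rank statistic invariant under monotone transformation
  set.seed(16)
  vals <- rexp(90)
  grp <- rep(c("a", "b", "c"), 30)
  e1 <- elevation_comparison(vals, grp)
  e2 <- elevation_comparison(log(vals + 1), grp)
  expect_equal(unname(e1$kruskal$statistic), unname(e2$kruskal$statistic))
  expect_equal(e1$dunn$z, e2$dunn$z)

  # null rejection near alpha
  set.seed(17)
  rej <- vapply(1:300, function(i) {
    v <- rnorm(45)
    elevation_comparison(v, rep(c("a", "b", "c"), each = 15))$kruskal$p.value <= 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)

  # strong shifts: all Dunn pairs significant in >= 90% of seeds
  hits <- vapply(1:20, function(i) {
    set.seed(400 + i)
    v <- c(rnorm(30, 0), rnorm(30, 2), rnorm(30, 4))
    all(elevation_comparison(v, rep(c("a", "b", "c"), each = 30))$dunn$p_adj < 0.05)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  expect_error(elevation_comparison(rep(1, 20), rep(c("a", "b"), 10)), "identical")
})

test_that("climate tables round-trip and are validated", {
  land <- sim_landscape(sim_landscape_config(n_vars = 4, n_occurrences = 10,
                                             n_background_candidates = 10,
                                             seed = 3))
  f <- tempfile(fileext = ".csv")
  write_climate_table(land$occurrences, f)
  back <- read_climate_table(f)
  expect_equal(back$bio1, land$occurrences$bio1)
  dup <- land$occurrences
  dup$id[2] <- dup$id[1]
  f2 <- tempfile(fileext = ".csv")
  write_climate_table(dup, f2)
  expect_error(read_climate_table(f2), "duplicated")
})
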