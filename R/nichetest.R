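# Background-vs-occupied niche divergence/conservatism testing on PCA axes
# with jackknife nulls, plus supporting geometry and variable selection.

#' Greedy selection of mutually uncorrelated variables
#'
#' Variables are scanned in priority order; one is kept iff its absolute
#' Pearson correlation with every already-kept variable is below the
#' threshold. Constant variables are excluded with a warning.
#'
#' @param table data.frame containing the candidate variables.
#' @param threshold correlation bound in (0, 1] (default 0.7).
#' @param priority ordered character vector of variable names to consider
#'   (default: all numeric columns in table order).
#' @return Character vector of kept variable names.
#' @export
select_uncorrelated_vars <- function(table, threshold = 0.7, priority = NULL) {
  threshold <- .check_number(threshold, "threshold", min = 0, max = 1, strict_min = TRUE)
  if (is.null(priority))
    priority <- names(table)[vapply(table, is.numeric, TRUE)]
  missing_vars <- setdiff(priority, names(table))
  if (length(missing_vars))
    .stopf("variables not in table: %s", paste(missing_vars, collapse = ", "))
  if (nrow(table) < 3L) .stopf("need >= 3 records")
  kept <- character(0)
  for (v in priority) {
    x <- table[[v]]
    if (sd(x) == 0) {
      warning("excluding constant variable: ", v)
      next
    }
    ok <- all(vapply(kept, function(k) abs(cor(x, table[[k]])) < threshold, TRUE))
    if (ok) kept <- c(kept, v)
  }
  kept
}

#' Minimum convex polygon (convex hull) of occurrence points
#'
#' @param points matrix or data.frame with longitude and latitude columns.
#' @return A matrix of hull vertices in counter-clockwise order, class
#'   `hm_polygon`.
#' @export
minimum_convex_polygon <- function(points) {
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  storage.mode(pts) <- "double"
  if (nrow(pts) < 3L) .stopf("need >= 3 points")
  idx <- chull(pts)              # clockwise order
  if (length(idx) < 3L) .stopf("degenerate (collinear) points: no polygon")
  hull <- pts[rev(idx), , drop = FALSE]  # counter-clockwise
  colnames(hull) <- c("longitude", "latitude")
  structure(hull, class = c("hm_polygon", "matrix"))
}

#' Test whether points fall inside (or on) a convex polygon
#'
#' @param poly an `hm_polygon` (counter-clockwise vertices).
#' @param points matrix/data.frame of (longitude, latitude).
#' @param tol boundary tolerance.
#' @return Logical vector.
#' @export
point_in_polygon <- function(poly, points, tol = 1e-9) {
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  v <- unclass(poly)
  nv <- nrow(v)
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(nv)) {
    a <- v[i, ]
    b <- v[if (i == nv) 1L else i + 1L, ]
    # counter-clockwise: interior is left of every directed edge
    crossp <- (b[1L] - a[1L]) * (pts[, 2L] - a[2L]) -
      (b[2L] - a[2L]) * (pts[, 1L] - a[1L])
    inside <- inside & (crossp >= -tol)
  }
  inside
}

#' Polygon area by the shoelace formula
#'
#' @param poly an `hm_polygon`.
#' @return Area in squared coordinate units.
#' @export
polygon_area <- function(poly) {
  v <- unclass(poly)
  x <- v[, 1L]; y <- v[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Sample uniform background points inside a polygon
#'
#' Rejection sampling from the bounding box; climate values are attached
#' from the nearest record of `climate_field` (Euclidean distance in the
#' coordinate plane), emulating raster extraction on synthetic data.
#'
#' @param poly an `hm_polygon`.
#' @param n number of points.
#' @param climate_field optional data.frame with `longitude`, `latitude`
#'   and climate columns to attach.
#' @param seed integer seed.
#' @return data.frame with `longitude`, `latitude` and any attached
#'   climate columns.
#' @export
sample_background <- function(poly, n, climate_field = NULL, seed = 1) {
  n <- .check_count(n, "n")
  if (polygon_area(poly) <= 0) .stopf("degenerate polygon: zero area")
  set.seed(.check_count(seed, "seed", min = 0L))
  v <- unclass(poly)
  xr <- range(v[, 1L]); yr <- range(v[, 2L])
  out <- matrix(NA_real_, 0L, 2L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cand <- cbind(runif(m, xr[1L], xr[2L]), runif(m, yr[1L], yr[2L]))
    keep <- point_in_polygon(poly, cand)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  res <- data.frame(longitude = out[, 1L], latitude = out[, 2L])
  if (!is.null(climate_field)) {
    cf <- as.data.frame(climate_field)
    vars <- setdiff(names(cf), c("id", "group", "longitude", "latitude"))
    nn <- vapply(seq_len(n), function(i) {
      which.min((cf$longitude - res$longitude[i])^2 +
                  (cf$latitude - res$latitude[i])^2)
    }, 1L)
    res <- cbind(res, cf[nn, vars, drop = FALSE], row.names = NULL)
  }
  res
}

#' Fit niche PCA axes on background points and project occurrences
#'
#' The PCA is fitted on the pooled background records (centred; and scaled
#' to unit variance by default, since bioclim variables are in
#' incommensurable units); occurrences are projected onto the same axes.
#' Axis signs are fixed so the largest-magnitude loading is positive.
#'
#' @param occurrences,backgrounds data.frames sharing the climate columns.
#' @param vars character vector of variable names to use.
#' @param standardize scale variables to unit variance (default TRUE).
#' @return A list of class `hm_nicheaxes`: `loadings`, `explained`,
#'   `occ_scores`, `bg_scores`.
#' @export
fit_niche_axes <- function(occurrences, backgrounds, vars, standardize = TRUE) {
  if (!all(vars %in% names(occurrences)) || !all(vars %in% names(backgrounds)))
    .stopf("variables missing from occurrence/background tables")
  B <- as.matrix(backgrounds[, vars, drop = FALSE])
  O <- as.matrix(occurrences[, vars, drop = FALSE])
  if (nrow(B) + nrow(O) < 3L) .stopf("need >= 3 records")
  if (length(vars) < 2L) .stopf("need >= 2 variables")
  pc <- prcomp(B, center = TRUE, scale. = standardize)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  bg_scores <- sweep(predict(pc, backgrounds[, vars, drop = FALSE]), 2L, flip, `*`)
  occ_scores <- sweep(predict(pc, occurrences[, vars, drop = FALSE]), 2L, flip, `*`)
  structure(list(loadings = loadings,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 occ_scores = occ_scores, bg_scores = bg_scores),
            class = "hm_nicheaxes")
}

#' Jackknife null distribution of background divergence on one axis
#'
#' Per replicate, `ceiling(fraction * n)` points per group are drawn
#' without replacement (with replacement when `replace = TRUE`) and the
#' absolute difference of group mean scores is recorded; the null interval
#' is the (alpha/2, 1 - alpha/2) pair of empirical quantiles.
#'
#' @param bgA,bgB numeric axis scores for the two backgrounds (>= 10 each).
#' @param n_rep replicates (default 1000; < 100 warns).
#' @param fraction resample share in (0, 1].
#' @param seed integer seed.
#' @param alpha two-sided level (default 0.05).
#' @param replace resample with replacement (bootstrap mode).
#' @return A list with `lo`, `hi`, `d_bg` (observed background divergence)
#'   and `replicates`.
#' @export
background_divergence_null <- function(bgA, bgB, n_rep = 1000, fraction = 0.75,
                                       seed = 1, alpha = 0.05, replace = FALSE) {
  if (length(bgA) < 10L || length(bgB) < 10L)
    .stopf("need >= 10 background points per group")
  fraction <- .check_number(fraction, "fraction", min = 0, max = 1, strict_min = TRUE)
  n_rep <- .check_count(n_rep, "n_rep")
  if (n_rep < 100L) warning("n_rep < 100: unstable null quantiles")
  set.seed(.check_count(seed, "seed", min = 0L))
  mA <- ceiling(fraction * length(bgA))
  mB <- ceiling(fraction * length(bgB))
  reps <- vapply(seq_len(n_rep), function(i) {
    abs(mean(sample(bgA, mA, replace = replace)) -
          mean(sample(bgB, mB, replace = replace)))
  }, 0)
  qs <- unname(quantile(reps, c(alpha / 2, 1 - alpha / 2), type = 7))
  list(lo = qs[1L], hi = qs[2L], d_bg = abs(mean(bgA) - mean(bgB)),
       replicates = reps)
}

#' Classify one axis as divergence, conservatism or none
#'
#' Divergence iff the occupied divergence exceeds the null upper bound;
#' conservatism iff it falls below the null lower bound; none otherwise.
#'
#' @param d_occ observed occupied divergence score.
#' @param lo,hi null interval bounds (lo <= hi).
#' @return `"divergence"`, `"conservatism"` or `"none"`.
#' @examples
#' classify_axis(0.88, 1.25, 1.44)  # conservatism
#' classify_axis(0.59, 0.05, 0.33)  # divergence
#' @export
classify_axis <- function(d_occ, lo, hi) {
  if (lo > hi) .stopf("malformed null interval: lo > hi")
  if (d_occ > hi) "divergence" else if (d_occ < lo) "conservatism" else "none"
}

#' Background-vs-occupied niche divergence test
#'
#' Fits PCA axes on the pooled backgrounds of the two groups, projects
#' occurrences, and for each requested axis compares the occupied
#' divergence `|mean occ-score A - mean occ-score B|` with a jackknife null
#' of the background divergence.
#'
#' @param occA,bgA,occB,bgB data.frames of occurrence and background
#'   records for groups A and B (shared climate columns).
#' @param vars climate variable names (default: `bio*` columns).
#' @param n_axes number of PCA axes to test (default 4).
#' @param n_rep,fraction,alpha,replace passed to
#'   [background_divergence_null()].
#' @param seed integer seed.
#' @param standardize passed to [fit_niche_axes()].
#' @return A data.frame of class `hm_nichetest`: one row per axis with
#'   `axis`, `d_occ`, `d_bg`, `lo`, `hi`, `classification`, `explained`.
#'   The fitted axes are attached as attribute `axes`.
#' @export
niche_divergence_test <- function(occA, bgA, occB, bgB, vars = NULL,
                                  n_axes = 4, n_rep = 1000, fraction = 0.75,
                                  alpha = 0.05, seed = 1, replace = FALSE,
                                  standardize = TRUE) {
  if (is.null(vars)) {
    vars <- grep("^bio", names(bgA), value = TRUE)
    if (!length(vars)) .stopf("no bio* columns found; supply 'vars'")
  }
  occ <- rbind(occA[, vars, drop = FALSE], occB[, vars, drop = FALSE])
  bg <- rbind(bgA[, vars, drop = FALSE], bgB[, vars, drop = FALSE])
  axes <- fit_niche_axes(occ, bg, vars, standardize)
  n_axes <- min(.check_count(n_axes, "n_axes"), ncol(axes$bg_scores))
  nA_occ <- nrow(occA); nA_bg <- nrow(bgA)
  occ_grp <- rep(c("A", "B"), c(nA_occ, nrow(occB)))
  bg_grp <- rep(c("A", "B"), c(nA_bg, nrow(bgB)))
  rows <- lapply(seq_len(n_axes), function(ax) {
    so <- axes$occ_scores[, ax]
    sb <- axes$bg_scores[, ax]
    d_occ <- abs(mean(so[occ_grp == "A"]) - mean(so[occ_grp == "B"]))
    null <- background_divergence_null(sb[bg_grp == "A"], sb[bg_grp == "B"],
                                       n_rep = n_rep, fraction = fraction,
                                       seed = seed + ax, alpha = alpha,
                                       replace = replace)
    data.frame(axis = ax, d_occ = d_occ, d_bg = null$d_bg,
               lo = null$lo, hi = null$hi,
               classification = classify_axis(d_occ, null$lo, null$hi),
               explained = axes$explained[ax], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "axes") <- axes
  class(out) <- c("hm_nichetest", "data.frame")
  out
}

#' Correlation of niche axis scores with latitude and longitude
#'
#' @param axes an `hm_nicheaxes` from [fit_niche_axes()] (occurrence scores
#'   are used), or a numeric matrix of scores.
#' @param coords data.frame with `longitude` and `latitude` for the same
#'   records.
#' @return data.frame: `axis`, `r_latitude`, `r_longitude` (NA with a
#'   warning when scores are constant).
#' @export
axis_geo_correlation <- function(axes, coords) {
  scores <- if (inherits(axes, "hm_nicheaxes")) axes$occ_scores else as.matrix(axes)
  if (nrow(scores) != nrow(coords)) .stopf("scores and coords differ in length")
  if (nrow(scores) < 3L) .stopf("need >= 3 occurrences")
  rows <- lapply(seq_len(ncol(scores)), function(ax) {
    s <- scores[, ax]
    if (sd(s) == 0) {
      warning("constant scores on axis ", ax, ": correlation undefined")
      return(data.frame(axis = ax, r_latitude = NA_real_, r_longitude = NA_real_))
    }
    data.frame(axis = ax,
               r_latitude = cor(s, coords$latitude),
               r_longitude = cor(s, coords$longitude))
  })
  do.call(rbind, rows)
}

#' Elevation comparison across groups (Kruskal-Wallis + Dunn)
#'
#' Kruskal-Wallis rank test with tie correction followed by Dunn's pairwise
#' z comparisons with Bonferroni adjustment.
#'
#' @param values numeric vector of elevations.
#' @param groups group labels (>= 2 groups, >= 2 samples each).
#' @return A list of class `hm_elevtest`: `kruskal` (htest), `dunn`
#'   (data.frame with `group1`, `group2`, `z`, `p`, `p_adj`).
#' @export
elevation_comparison <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) .stopf("need >= 2 groups")
  if (any(table(groups) < 2L)) .stopf("need >= 2 samples per group")
  if (length(unique(values)) == 1L) .stopf("degenerate test: all values identical")
  kw <- kruskal.test(values, groups)
  N <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- combn(lev, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    n1 <- sum(groups == g1); n2 <- sum(groups == g2)
    z <- (mean(rk[groups == g1]) - mean(rk[groups == g2])) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n1 + 1 / n2))
    data.frame(group1 = g1, group2 = g2, z = z,
               p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  dunn <- do.call(rbind, rows)
  dunn$p_adj <- pmin(1, dunn$p * nrow(dunn))  # Bonferroni
  structure(list(kruskal = kw, dunn = dunn), class = "hm_elevtest")
}

#' @export
print.hm_elevtest <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.3f, df = %d, p = %.4g\n",
              unname(x$kruskal$statistic), unname(x$kruskal$parameter),
              x$kruskal$p.value))
  print(x$dunn, digits = 4)
  invisible(x)
}
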