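# Conversion of coalescent-scaled inference output to demographic units and
# comparison of contemporary vs historical migration.

#' Per-locus mutation rate specification
#'
#' @param per_site_per_year substitution rate per site per year (use
#'   `per_site_per_my / 1e6` for rates quoted per million years).
#' @param locus_length locus length in base pairs.
#' @return A list of class `hm_ratespec` with `u` (per site per year),
#'   `locus_length` and `U = u * locus_length` (per locus per year).
#' @examples
#' rate_spec(0.0145e-6, 1100)$U
#' @export
rate_spec <- function(per_site_per_year, locus_length) {
  u <- .check_number(per_site_per_year, "per_site_per_year", min = 0, strict_min = TRUE)
  L <- .check_count(locus_length, "locus_length")
  structure(list(u = u, locus_length = L, U = u * L), class = "hm_ratespec")
}

#' Average generation time from age at maturity and adult survival
#'
#' `T = a + s / (1 - s)` where `a` is the age at first breeding (years) and
#' `s` the annual adult survival rate.
#'
#' @param a age at maturity in years (> 0).
#' @param s adult annual survival in `[0, 1)`.
#' @return A list of class `hm_gentime` with `a`, `s`, `T` (years).
#' @examples
#' generation_time(2, 0.30)$T  # 2.43 after rounding
#' @export
generation_time <- function(a, s) {
  a <- .check_number(a, "a", min = 0, strict_min = TRUE)
  s <- .check_number(s, "s", min = 0, max = 1, strict_max = TRUE)
  structure(list(a = a, s = s, T = a + s / (1 - s)), class = "hm_gentime")
}

#' Divergence time in years from a mutation-scaled time
#'
#' `t = t_scaled / U` where `U` is the per-locus per-year mutation rate.
#'
#' @param t_scaled mutation-scaled divergence time (>= 0).
#' @param rate an [rate_spec()].
#' @return Time in years.
#' @export
divergence_years <- function(t_scaled, rate) {
  stopifnot(inherits(rate, "hm_ratespec"))
  t_scaled <- .check_number(t_scaled, "t_scaled", min = 0)
  if (rate$U <= 0) .stopf("per-locus rate U must be positive")
  t_scaled / rate$U
}

#' Effective population size from a mutation-scaled size
#'
#' `Ne = q / (inheritance_scalar * U * T)`: the scaled size `q` divided by
#' the inheritance scalar times the per-generation per-locus rate. The
#' default scalar 4 follows the usual theta = 4 Ne mu convention of
#' isolation-with-migration software; 2 is available for strict maternal
#' haploid accounting.
#'
#' @param q mutation-scaled population size (>= 0).
#' @param rate an [rate_spec()].
#' @param gen a [generation_time()].
#' @param inheritance_scalar 4 (default) or 2.
#' @return Effective number of individuals.
#' @export
effective_size <- function(q, rate, gen, inheritance_scalar = 4) {
  stopifnot(inherits(rate, "hm_ratespec"), inherits(gen, "hm_gentime"))
  q <- .check_number(q, "q", min = 0)
  k <- .check_number(inheritance_scalar, "inheritance_scalar", min = 0, strict_min = TRUE)
  den <- k * rate$U * gen$T
  if (den <= 0) .stopf("zero denominator: check rate and generation time")
  q / den
}

#' Rescale an effective size between generation-time assumptions
#'
#' Effective sizes converted with generation time `T_old` are re-expressed
#' under `T_new` as `N * T_old / T_new`, rounded half away from zero to the
#' precision of the input.
#'
#' @param N effective size (any unit, e.g. thousands of individuals).
#' @param T_old,T_new generation times in years (> 0).
#' @param digits decimal places of the input table (0 for integer tables).
#' @return Rescaled N at the input's precision.
#' @examples
#' rescale_ne(96, generation_time(2, 0.30)$T, generation_time(2, 0.52)$T)  # 76
#' @export
rescale_ne <- function(N, T_old, T_new, digits = 0) {
  T_old <- .check_number(T_old, "T_old", min = 0, strict_min = TRUE)
  T_new <- .check_number(T_new, "T_new", min = 0, strict_min = TRUE)
  .round_half_away(N * T_old / T_new, digits)
}

#' Migration fraction from a mutation-scaled migration rate
#'
#' MIGRATE reports `M = m / mu`, so the per-generation migration fraction is
#' `m = M * mu`. A paper-literal mode dividing by mu instead is kept behind
#' `mode = "paper-literal"` and warns, since it yields fractions above 1;
#' correlation-based comparisons are unaffected by the choice.
#'
#' @param M scaled migration rate (scalar or matrix, >= 0).
#' @param mu per-generation mutation rate (> 0).
#' @param mode `"migrate"` (default, m = M * mu) or `"paper-literal"`
#'   (m = M / mu).
#' @return Migration fraction(s), same shape as `M`.
#' @export
m_from_M <- function(M, mu, mode = c("migrate", "paper-literal")) {
  mode <- match.arg(mode)
  if (any(M < 0, na.rm = TRUE)) .stopf("'M' must be >= 0")
  mu <- .check_number(mu, "mu", min = 0, strict_min = TRUE)
  if (mode == "paper-literal") {
    warning("paper-literal mode divides M by mu; resulting 'fractions' exceed 1")
    return(M / mu)
  }
  M * mu
}

#' Migrants per generation from theta and M
#'
#' `Nem = theta * M / 4` under the `theta = 4 Ne mu`, `M = m / mu`
#' conventions.
#'
#' @param theta mutation-scaled size (>= 0).
#' @param M mutation-scaled migration rate (>= 0).
#' @return Effective migrants per generation.
#' @export
nem_from_theta_M <- function(theta, M) {
  if (any(theta < 0, na.rm = TRUE) || any(M < 0, na.rm = TRUE))
    .stopf("'theta' and 'M' must be >= 0")
  theta * M / 4
}

#' Mantel test for square (possibly asymmetric) matrices
#'
#' Pearson correlation over corresponding off-diagonal cells; the null is
#' generated by permuting row and column labels of the second matrix
#' simultaneously (appropriate for asymmetric migration matrices). When the
#' number of distinct label permutations does not exceed `n_perm`, the exact
#' enumeration is used and flagged. The p-value is two-tailed.
#'
#' @param matA,matB square numeric matrices of the same size (>= 3 x 3).
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @return A list of class `hm_mantel` with `r`, `p`, `n_perm`,
#'   `exact` (logical).
#' @export
mantel_test <- function(matA, matB, n_perm = 5000, seed = 1) {
  if (!is.matrix(matA) || !is.matrix(matB)) .stopf("inputs must be matrices")
  n <- nrow(matA)
  if (n < 3L || any(dim(matA) != n) || any(dim(matB) != n))
    .stopf("matrices must be square, same shape, >= 3 x 3")
  off <- !diag(TRUE, n)
  a <- matA[off]
  if (sd(a) == 0 || sd(matB[off]) == 0)
    .stopf("undefined correlation: constant off-diagonal values")
  r_obs <- cor(a, matB[off])
  n_perm <- .check_count(n_perm, "n_perm")
  exact <- factorial(n) <= n_perm
  if (exact) {
    perms <- .perms(n)
    rs <- vapply(perms, function(p) cor(a, matB[p, p][off]), 0)
    p <- mean(abs(rs) >= abs(r_obs) - 1e-12)
  } else {
    set.seed(.check_count(seed, "seed", min = 0L))
    rs <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      cor(a, matB[p, p][off])
    }, 0)
    # include the identity permutation in the null set
    p <- (sum(abs(rs) >= abs(r_obs) - 1e-12) + 1) / (n_perm + 1)
  }
  structure(list(r = r_obs, p = p, n_perm = n_perm, exact = exact),
            class = "hm_mantel")
}

#' @export
print.hm_mantel <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p, if (x$exact) "exact enumeration" else "sampled", x$n_perm))
  invisible(x)
}

#' Bundle contemporary and historical migration tables
#'
#' @param contemporary square matrix of recent migration proportions
#'   (rows = recipient populations; diagonal = non-migrant fraction; rows
#'   must sum to 1 within 0.01).
#' @param historical square matrix of mutation-scaled migration rates
#'   `M = m / mu` (diagonal ignored).
#' @param theta optional vector of scaled sizes (4 Ne mu) per population.
#' @param mu microsatellite per-generation mutation rate (default 5e-4).
#' @return A list of class `hm_migtables`.
#' @export
migration_tables <- function(contemporary, historical, theta = NULL, mu = 5e-4) {
  if (!is.matrix(contemporary) || !is.matrix(historical) ||
      any(dim(contemporary) != dim(historical)))
    .stopf("contemporary and historical must be square matrices of the same size")
  if (any(contemporary < 0, na.rm = TRUE) || any(historical < 0, na.rm = TRUE))
    .stopf("migration entries must be >= 0")
  rs <- rowSums(contemporary)
  if (any(abs(rs - 1) > 0.01))
    .stopf("contemporary rows must sum to 1 (+/- 0.01); got %s",
           paste(round(rs, 3), collapse = ", "))
  mu <- .check_number(mu, "mu", min = 0, strict_min = TRUE)
  structure(list(contemporary = contemporary, historical = historical,
                 theta = theta, mu = mu), class = "hm_migtables")
}

#' Compare contemporary and historical migration eras
#'
#' Converts the historical scaled rates to per-generation fractions,
#' correlates them with the contemporary fractions by [mantel_test()] and
#' reports per-pair era ratios (historical / contemporary) plus, when theta
#' values are supplied, the implied migrants per generation.
#'
#' @param tables an [migration_tables()].
#' @param n_perm,seed passed to [mantel_test()].
#' @param mode conversion mode for [m_from_M()].
#' @return A list of class `hm_eracomparison` with `mantel`, `m_hist`,
#'   `m_contemp`, `era_ratio` and optionally `Nem`.
#' @export
compare_migration_eras <- function(tables, n_perm = 5000, seed = 1,
                                   mode = c("migrate", "paper-literal")) {
  stopifnot(inherits(tables, "hm_migtables"))
  mode <- match.arg(mode)
  m_hist <- suppressWarnings(m_from_M(tables$historical, tables$mu, mode))
  diag(m_hist) <- NA
  m_contemp <- tables$contemporary
  mt <- mantel_test(m_contemp, {h <- m_hist; diag(h) <- 0; h}, n_perm, seed)
  ratio <- m_hist / m_contemp
  diag(ratio) <- NA
  out <- list(mantel = mt, m_hist = m_hist, m_contemp = m_contemp,
              era_ratio = ratio, mode = mode)
  if (!is.null(tables$theta)) {
    # row d = recipient, column o = donor: Nem into d along column rates
    Nem <- tables$historical * NA
    for (d in seq_len(nrow(Nem))) for (o in seq_len(ncol(Nem)))
      if (d != o) Nem[d, o] <- nem_from_theta_M(tables$theta[d], tables$historical[d, o])
    out$Nem <- Nem
  }
  structure(out, class = "hm_eracomparison")
}

#' @export
print.hm_eracomparison <- function(x, ...) {
  cat("Contemporary vs historical migration\n")
  print(x$mantel)
  cat("Era ratios (historical m / contemporary m):\n")
  print(round(x$era_ratio, 3))
  invisible(x)
}

#' Read an IMa-style parameter table
#'
#' CSV with columns `parameter, mean, HPD95Lo, HPD95Hi`.
#'
#' @param file path to the CSV.
#' @return A data.frame.
#' @export
read_ima_params <- function(file) {
  x <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("parameter", "mean", "HPD95Lo", "HPD95Hi")
  if (!all(need %in% names(x)))
    .stopf("expected columns: %s", paste(need, collapse = ", "))
  x
}

#' Read a square migration matrix with population headers
#'
#' CSV whose first column holds recipient population names and whose
#' remaining columns are donor populations.
#'
#' @param file path to the CSV.
#' @return A numeric matrix with dimnames.
#' @export
read_migration_matrix <- function(file) {
  x <- read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- x[[1L]]
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) .stopf("migration matrix must be square")
  m
}
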