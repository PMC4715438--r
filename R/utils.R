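# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    .stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

.check_number <- function(x, name, min = -Inf, max = Inf,
                          strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    .stopf("'%s' must be a single finite number", name)
  if (x < min || (strict_min && x <= min)) .stopf("'%s' must be %s %g", name,
                                                  if (strict_min) ">" else ">=", min)
  if (x > max || (strict_max && x >= max)) .stopf("'%s' must be %s %g", name,
                                                  if (strict_max) "<" else "<=", max)
  as.numeric(x)
}

.logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# All permutations of 1..n as a list of integer vectors (n small).
.perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- vector("list", factorial(n))
  i <- 0L
  for (k in seq_len(n)) {
    for (p in .perms(n - 1L)) {
      i <- i + 1L
      rest <- seq_len(n)[-k]
      out[[i]] <- c(k, rest[p])
    }
  }
  out
}

# Rounding half away from zero at `digits` decimal places.
.round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
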