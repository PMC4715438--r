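# Ten-character plumage colour index and clinal summaries.

#' Default ten-character plumage scoring scheme
#'
#' Four primary diagnostic characters (rufous patch on the secondaries,
#' rufous patch on the primaries, belly colouration, tail colouration)
#' scored 0-3 and six auxiliary characters scored 0-2, for a total range of
#' 0 (steely-blue extreme) to 24 (berylline extreme). Fully overridable:
#' any list of named integer state-score vectors with per-character minima
#' of 0 is accepted by the scoring functions.
#'
#' @return Named list of 10 characters; each element is a named integer
#'   vector mapping state names to scores.
#' @examples
#' sum(vapply(default_plumage_scheme(), max, 0L))  # 24
#' @export
default_plumage_scheme <- function() {
  four <- c(absent = 0L, trace = 1L, partial = 2L, extensive = 3L)
  belly <- c(emerald_green = 0L, mixed_green = 1L, greenish_gold = 2L,
             golden_green = 3L)
  tail <- c(steel_blue = 0L, blue_purple = 1L, purple_rufous = 2L,
            rufous_brown = 3L)
  three <- c(saucerottei_like = 0L, intermediate = 1L, beryllina_like = 2L)
  list(secondary_wing_patch = four,
       primary_wing_patch = four,
       belly_colour = belly,
       tail_colour = tail,
       crown_sheen = three,
       throat_colour = three,
       rump_tinge = three,
       uppertail_coverts = three,
       wing_covert_edging = three,
       undertail_coverts = three)
}

.check_scheme <- function(scheme) {
  if (!is.list(scheme) || !length(scheme) || is.null(names(scheme)))
    .stopf("scheme must be a named list of state-score vectors")
  for (ch in names(scheme)) {
    sc <- scheme[[ch]]
    if (is.null(names(sc)) || anyDuplicated(names(sc)))
      .stopf("character '%s': state names must be unique", ch)
    if (min(sc) != 0L) .stopf("character '%s': minimum score must be 0", ch)
  }
  invisible(scheme)
}

#' Score one specimen on the plumage colour index
#'
#' @param states named character vector or list giving one state per
#'   scheme character.
#' @param scheme a scoring scheme (default [default_plumage_scheme()]).
#' @return The summed integer index.
#' @examples
#' sch <- default_plumage_scheme()
#' states <- vapply(sch, function(s) names(s)[which.max(s)], "")
#' score_plumage(states, sch)  # 24
#' @export
score_plumage <- function(states, scheme = default_plumage_scheme()) {
  .check_scheme(scheme)
  states <- unlist(states)
  total <- 0L
  for (ch in names(scheme)) {
    if (!ch %in% names(states)) .stopf("missing character: %s", ch)
    st <- states[[ch]]
    if (!st %in% names(scheme[[ch]]))
      .stopf("unknown state '%s' for character '%s'", st, ch)
    total <- total + scheme[[ch]][[st]]
  }
  as.integer(total)
}

#' Score a plumage table and append numeric per-character scores
#'
#' @param records data.frame with one column per scheme character holding
#'   state names (plus any id/longitude columns, which are preserved).
#' @param scheme a scoring scheme.
#' @return The input with `score_<character>` columns and an `index`
#'   column appended.
#' @export
score_plumage_table <- function(records, scheme = default_plumage_scheme()) {
  .check_scheme(scheme)
  out <- records
  total <- integer(nrow(records))
  for (ch in names(scheme)) {
    if (!ch %in% names(records)) .stopf("missing character: %s", ch)
    st <- as.character(records[[ch]])
    bad <- !st %in% names(scheme[[ch]])
    if (any(bad))
      .stopf("unknown state '%s' for character '%s'", st[bad][1L], ch)
    sc <- scheme[[ch]][st]
    out[[paste0("score_", ch)]] <- as.integer(sc)
    total <- total + as.integer(sc)
  }
  out$index <- total
  out
}

#' Clinal profile of the colour index against longitude
#'
#' Equal-width longitude bins with per-bin mean, sd and n of the index,
#' plus profiles of the four primary diagnostic characters when present.
#'
#' @param records a scored plumage data.frame (see
#'   [score_plumage_table()]) with `longitude` and `index` columns.
#' @param n_bins number of equal-width longitude bins.
#' @return A list of class `hm_cline`: `index` data.frame (bin, mid, mean,
#'   sd, n) and `characters`, a named list of the same per character.
#' @export
cline_profile <- function(records, n_bins = 8) {
  n_bins <- .check_count(n_bins, "n_bins")
  if (!all(c("longitude", "index") %in% names(records)))
    .stopf("records need 'longitude' and 'index' columns")
  rng <- range(records$longitude)
  if (diff(rng) <= 0) .stopf("zero-width longitude range")
  brk <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  bin <- cut(records$longitude, brk, include.lowest = TRUE, labels = FALSE)
  prof <- function(v) {
    rows <- lapply(seq_len(n_bins), function(b) {
      x <- v[bin == b]
      data.frame(bin = b, mid = (brk[b] + brk[b + 1L]) / 2,
                 mean = if (length(x)) mean(x) else NA_real_,
                 sd = if (length(x) > 1L) sd(x) else if (length(x)) 0 else NA_real_,
                 n = length(x))
    })
    do.call(rbind, rows)
  }
  chars <- intersect(paste0("score_", c("secondary_wing_patch",
                                        "primary_wing_patch",
                                        "belly_colour", "tail_colour")),
                     names(records))
  structure(list(index = prof(records$index),
                 characters = setNames(lapply(chars, function(cn) prof(records[[cn]])),
                                       sub("^score_", "", chars))),
            class = "hm_cline")
}

#' @export
print.hm_cline <- function(x, ...) {
  cat("Colour-index cline (per-longitude-bin mean +/- sd):\n")
  print(x$index, digits = 3)
  invisible(x)
}

#' Read a plumage trait table (CSV)
#'
#' @param file CSV with `id`, `longitude` and ten character-state columns.
#' @return data.frame.
#' @export
read_plumage_table <- function(file) read.csv(file, stringsAsFactors = FALSE)

#' Write a plumage trait table (CSV)
#'
#' @param records data.frame.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_plumage_table <- function(records, file) {
  write.csv(records, file, row.names = FALSE)
  invisible(file)
}
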