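# Occurrence / background climate table IO.

#' Read an occurrence or background climate table (CSV)
#'
#' Expected columns: `id`, `group`, `longitude`, `latitude`, `elevation`,
#' then the bioclimatic variables (`bio1..bio19` by convention).
#'
#' @param file CSV path.
#' @return data.frame.
#' @export
read_climate_table <- function(file) {
  x <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("id", "group", "longitude", "latitude")
  if (!all(need %in% names(x)))
    .stopf("climate table must contain columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(x$id)) .stopf("duplicated ids in climate table")
  if (any(!is.finite(x$longitude)) || any(!is.finite(x$latitude)))
    .stopf("non-finite coordinates in climate table")
  x
}

#' Write an occurrence or background climate table (CSV)
#'
#' @param table data.frame.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_climate_table <- function(table, file) {
  write.csv(table, file, row.names = FALSE)
  invisible(file)
}
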