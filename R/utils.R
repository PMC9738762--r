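#' Write a provenance / ground-truth manifest as JSON
#'
#' @param x a manifest list (seeds, settings, planted truth records).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a manifest written by [write_manifest()]
#'
#' @param path JSON path.
#' @return the manifest list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a table as TSV
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
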