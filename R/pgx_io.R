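#' Dose-response panel of IC50 values
#'
#' Container for a drug x cell-line matrix of half-maximal inhibitory
#' concentrations (IC50, nM) with optional cell-line annotations, the input
#' shape of large pharmacogenomic screens (GDSC-style: hundreds of compounds
#' across >1000 cancer cell lines).
#'
#' @param ic50 numeric matrix, drugs in rows, cell lines in columns, values in
#'   nM. `NA` marks a missing measurement. Non-positive values are coerced to
#'   `NA` with a warning (IC50 must be positive to be log-transformable).
#' @param drug_ids,cell_line_ids character identifiers; defaults taken from
#'   `dimnames(ic50)`. Must be unique.
#' @param measure_kind `"IC50"` or `"AUC"`.
#' @param annotations optional `data.frame` with columns `cell_line_id`,
#'   `tissue`, and optionally `subtype`; every annotated line must appear in
#'   `cell_line_ids`.
#' @return An object of class `dose_response_panel`: a list with elements
#'   `ic50` (named matrix), `drug_ids`, `cell_line_ids`, `measure_kind`,
#'   `annotations`.
#' @export
dose_response_panel <- function(ic50, drug_ids = rownames(ic50),
                                cell_line_ids = colnames(ic50),
                                measure_kind = c("IC50", "AUC"),
                                annotations = NULL) {
  measure_kind <- match.arg(measure_kind)
  ic50 <- as.matrix(ic50)
  storage.mode(ic50) <- "double"
  if (is.null(drug_ids) || is.null(cell_line_ids)) {
    stop("drug_ids and cell_line_ids are required (set dimnames or pass them)")
  }
  drug_ids <- as.character(drug_ids)
  cell_line_ids <- as.character(cell_line_ids)
  if (nrow(ic50) != length(drug_ids) || ncol(ic50) != length(cell_line_ids)) {
    stop("ic50 dimensions do not match identifier lengths")
  }
  if (nrow(ic50) == 0L || ncol(ic50) == 0L) stop("empty IC50 matrix")
  if (anyDuplicated(drug_ids)) stop("duplicate drug identifiers")
  if (anyDuplicated(cell_line_ids)) stop("duplicate cell-line identifiers")
  bad <- which(!is.na(ic50) & (ic50 <= 0 | !is.finite(ic50)))
  if (length(bad)) {
    warning(sprintf("%d non-positive/non-finite IC50 entries coerced to missing",
                    length(bad)))
    ic50[bad] <- NA_real_
  }
  dimnames(ic50) <- list(drug_ids, cell_line_ids)
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    stopifnot(all(c("cell_line_id", "tissue") %in% names(annotations)))
    if (!"subtype" %in% names(annotations)) annotations$subtype <- NA_character_
    unknown <- setdiff(annotations$cell_line_id, cell_line_ids)
    if (length(unknown)) {
      stop("annotated lines absent from panel: ", paste(unknown, collapse = ", "))
    }
  }
  structure(
    list(ic50 = ic50, drug_ids = drug_ids, cell_line_ids = cell_line_ids,
         measure_kind = measure_kind, annotations = annotations),
    class = "dose_response_panel"
  )
}

#' @export
print.dose_response_panel <- function(x, ...) {
  cat(sprintf("<dose_response_panel> %d drugs x %d cell lines (%s, nM), %d missing\n",
              nrow(x$ic50), ncol(x$ic50), x$measure_kind, sum(is.na(x$ic50))))
  if (!is.null(x$annotations)) {
    tab <- table(tolower(x$annotations$tissue))
    cat("tissues:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a dose-response panel from a delimited table
#'
#' The first column holds identifiers; remaining columns are numeric IC50
#' values with blanks or `NA` for missing. Non-positive and non-numeric body
#' entries are recorded as missing with a warning that reports the count.
#'
#' @param path file path (CSV; use `sep = "\t"` for TSV).
#' @param orientation `"drugs_rows"` (default) if drugs are rows, or
#'   `"lines_rows"` if cell lines are rows.
#' @param unit input concentration unit; `"uM"` values are converted to nM.
#' @param annotations optional annotation `data.frame` (see
#'   [dose_response_panel()]) or path to an annotation CSV with columns
#'   `cell_line_id`, `tissue`, `subtype`.
#' @param sep field separator.
#' @inheritParams dose_response_panel
#' @return A [dose_response_panel()].
#' @export
read_panel <- function(path, orientation = c("drugs_rows", "lines_rows"),
                       unit = c("nM", "uM"), annotations = NULL,
                       measure_kind = "IC50", sep = ",") {
  orientation <- match.arg(orientation)
  unit <- match.arg(unit)
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  m <- as.matrix(raw)
  suppressWarnings(storage.mode(m) <- "double")
  n_nonnum <- sum(is.na(m)) - sum(is.na(as.matrix(raw)))
  if (n_nonnum > 0) {
    warning(sprintf("%d non-numeric entries treated as missing", n_nonnum))
  }
  if (orientation == "lines_rows") m <- t(m)
  if (unit == "uM") m <- m * 1000
  if (is.character(annotations) && length(annotations) == 1L) {
    annotations <- utils::read.csv(annotations, stringsAsFactors = FALSE)
  }
  dose_response_panel(m, measure_kind = measure_kind, annotations = annotations)
}

#' Write a dose-response panel to CSV
#'
#' Inverse of [read_panel()]: `read_panel(write_panel(p, f))` reproduces `p`
#' (identifiers bit-exact, values to stored precision). Missing entries are
#' written as empty cells.
#'
#' @param panel a [dose_response_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "dose_response_panel"))
  df <- data.frame(drug_id = panel$drug_ids, panel$ic50,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, qmethod = "double",
                     na = "", quote = TRUE)
  invisible(path)
}

#' Filter a panel to cell lines of given tissues
#'
#' Retains exactly the cell lines whose annotated tissue is in `include`
#' (case-insensitive exact match, no fuzzy matching); the drug set is
#' unchanged. The per-tissue retained counts are attached as attribute
#' `tissue_counts` and reported via `message()`.
#'
#' @param panel an annotated [dose_response_panel()].
#' @param include non-empty character vector of tissue labels.
#' @return The filtered panel, with attribute `tissue_counts` (named integer).
#' @export
filter_by_tissue <- function(panel, include) {
  stopifnot(inherits(panel, "dose_response_panel"))
  if (is.null(panel$annotations)) stop("panel has no tissue annotations")
  if (length(include) == 0L) stop("include set is empty")
  ann <- panel$annotations
  keep_ids <- ann$cell_line_id[tolower(ann$tissue) %in% tolower(include)]
  keep <- panel$cell_line_ids %in% keep_ids
  if (!any(keep)) {
    stop("no cell line retained for tissues: ", paste(include, collapse = ", "))
  }
  kept_ann <- ann[ann$cell_line_id %in% panel$cell_line_ids[keep], , drop = FALSE]
  counts <- table(tolower(kept_ann$tissue))
  message("retained ", sum(keep), " lines: ",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  out <- dose_response_panel(panel$ic50[, keep, drop = FALSE],
                             measure_kind = panel$measure_kind,
                             annotations = kept_ann)
  attr(out, "tissue_counts") <- stats::setNames(as.integer(counts), names(counts))
  out
}

#' Worked-example tissue annotation table
#'
#' Builds a synthetic cell-line annotation table mirroring the genitourinary
#' subset of a GDSC-style panel: breast (52), cervix (14), endometrium (11),
#' ovary (45), prostate (8), testis (3) and vulva (3) lines — 136 in all —
#' plus lung and skin distractor lines that an inclusion filter should drop.
#'
#' @param n_lung,n_skin number of distractor lines per excluded tissue.
#' @return `data.frame` with columns `cell_line_id`, `tissue`, `subtype`.
#' @export
example_tissue_annotations <- function(n_lung = 20L, n_skin = 15L) {
  counts <- c(breast = 52L, cervix = 14L, endometrium = 11L, ovary = 45L,
              prostate = 8L, testis = 3L, vulva = 3L,
              lung = as.integer(n_lung), skin = as.integer(n_skin))
  tissue <- rep(names(counts), counts)
  data.frame(
    cell_line_id = sprintf("CL_%s_%02d", toupper(substr(tissue, 1, 4)),
                           unlist(lapply(counts, seq_len))),
    tissue = tissue,
    subtype = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Read a drug annotation table
#'
#' @param path CSV with columns `drug_id`, `target`, `target_pathway`.
#' @return `data.frame` with those columns; `drug_id` must be unique.
#' @export
read_drug_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("drug_id", "target", "target_pathway") %in% names(ann)))
  if (anyDuplicated(ann$drug_id)) stop("duplicate drug_id in annotations")
  ann
}
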