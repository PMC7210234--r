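#' Construct a lot-measurement table
#'
#' A lot table is the long-format container for per-lot continuous quality
#' attribute measurements of the two products under comparison: the candidate
#' biosimilar (\code{product = "test"}) and the licensed originator
#' (\code{product = "reference"}). Each row is one measurement of one
#' attribute on one manufactured lot.
#'
#' Invariants enforced at construction: every value is finite, the key
#' (product, lot_id, attribute) is unique, and each attribute is reported in
#' a single unit. Missing values are rejected rather than imputed; the
#' downstream similarity procedures have no imputation step.
#'
#' @param measurements data frame with columns \code{product} (\code{"test"}
#'   or \code{"reference"}), \code{lot_id}, \code{attribute}, \code{value}
#'   (finite numeric), \code{unit}.
#' @param provenance free-text description of where the data came from.
#' @return An object of class \code{lot_table}: the validated data frame with
#'   a \code{provenance} attribute.
#' @examples
#' lots <- lot_table(data.frame(
#'   product   = c("test", "test", "reference"),
#'   lot_id    = c("T01", "T02", "R01"),
#'   attribute = "HM_pct",
#'   value     = c(2.4, 2.6, 8.0),
#'   unit      = "%"))
#' summarize_attribute(lots, "HM_pct", "test")
#' @export
lot_table <- function(measurements, provenance = "") {
  required <- c("product", "lot_id", "attribute", "value", "unit")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols) > 0L) {
    stop("lot table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- as.data.frame(measurements)[, required]
  m$product <- as.character(m$product)
  m$lot_id <- as.character(m$lot_id)
  m$attribute <- as.character(m$attribute)
  m$unit <- as.character(m$unit)
  bad_product <- setdiff(unique(m$product), c("test", "reference"))
  if (length(bad_product) > 0L) {
    stop("product must be 'test' or 'reference'; found: ",
         paste(bad_product, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(m$value) || anyNA(m$value) || any(!is.finite(m$value))) {
    bad <- which(!is.numeric(m$value) | is.na(m$value) | !is.finite(m$value))
    stop("non-finite or missing value in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- paste(m$product, m$lot_id, m$attribute, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- m[duplicated(key), , drop = FALSE]
    stop("duplicate (product, lot_id, attribute) measurement(s): ",
         paste(sprintf("%s/%s/%s", dup$product, dup$lot_id, dup$attribute),
               collapse = "; "), call. = FALSE)
  }
  units <- tapply(m$unit, m$attribute, function(u) length(unique(u)))
  if (any(units > 1L)) {
    stop("attribute(s) reported in more than one unit: ",
         paste(names(units)[units > 1L], collapse = ", "), call. = FALSE)
  }
  rownames(m) <- NULL
  structure(m, provenance = provenance, class = c("lot_table", "data.frame"))
}

#' Read a lot table from delimited text
#'
#' Reads a comma-delimited, UTF-8, "."-decimal lot-measurement file with a
#' header row. Column names can be remapped through \code{schema} when the
#' source file uses different headers.
#'
#' @param source path to (or connection for) the CSV file.
#' @param schema named character vector mapping the canonical column names
#'   \code{product}, \code{lot_id}, \code{attribute}, \code{value},
#'   \code{unit} to the column names present in the file.
#' @param provenance provenance string stored on the result; defaults to the
#'   file path.
#' @return A \code{\link{lot_table}}.
#' @export
read_lot_table <- function(source,
                           schema = c(product = "product", lot_id = "lot_id",
                                      attribute = "attribute", value = "value",
                                      unit = "unit"),
                           provenance = NULL) {
  canonical <- c("product", "lot_id", "attribute", "value", "unit")
  schema <- schema[canonical]
  if (anyNA(schema)) {
    stop("schema must map all of: ", paste(canonical, collapse = ", "),
         call. = FALSE)
  }
  raw <- utils::read.csv(source, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0L) {
    stop("input is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- raw[, unname(schema)]
  names(out) <- canonical
  val <- suppressWarnings(as.numeric(out$value))
  bad <- which(is.na(val) | !is.finite(val))
  if (length(bad) > 0L) {
    stop("non-numeric or missing value in data row(s): ",
         paste(bad, collapse = ", "), " (value '",
         paste(out$value[bad], collapse = "', '"), "')", call. = FALSE)
  }
  out$value <- val
  if (is.null(provenance)) {
    provenance <- if (is.character(source)) source else "connection"
  }
  lot_table(out, provenance = provenance)
}

#' Write a lot table to CSV
#'
#' Values can be rounded to a per-attribute number of decimal places, mirroring
#' the precision at which assay results are reported; by default full precision
#' is written so that a write/read round trip is lossless.
#'
#' @param table a \code{\link{lot_table}}.
#' @param path output file path.
#' @param digits optional named integer vector (names = attributes) of decimal
#'   places to round to on output; attributes not named are written at full
#'   precision.
#' @return \code{path}, invisibly.
#' @export
write_lot_table <- function(table, path, digits = NULL) {
  stopifnot(inherits(table, "lot_table"))
  out <- as.data.frame(table)
  if (!is.null(digits)) {
    hit <- out$attribute %in% names(digits)
    out$value[hit] <- round(out$value[hit], digits[out$attribute[hit]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-product summary statistics for one attribute
#'
#' Computes the lot count, mean, sample standard deviation (n - 1
#' denominator), minimum and maximum for one product's lots of one attribute.
#' The reference-product sample SD computed here is the anchor of both the
#' tier-1 equivalence margin and the tier-2 quality range, which treat the
#' reference lots as a sample from the originator's batch process. For a
#' single lot the SD is reported as 0 (a one-point sample has no spread).
#'
#' @param table a \code{\link{lot_table}}.
#' @param attribute attribute name.
#' @param product \code{"test"} or \code{"reference"}.
#' @return An object of class \code{summary_stats}: list with \code{n},
#'   \code{mean}, \code{sd}, \code{min}, \code{max}, \code{attribute},
#'   \code{product}, \code{unit}.
#' @export
summarize_attribute <- function(table, attribute, product) {
  stopifnot(inherits(table, "lot_table"))
  if (!attribute %in% table$attribute) {
    stop("unknown attribute: ", attribute, call. = FALSE)
  }
  sel <- table$attribute == attribute & table$product == product
  if (!any(sel)) {
    stop("no lots for product '", product, "' and attribute '", attribute, "'",
         call. = FALSE)
  }
  x <- table$value[sel]
  structure(list(
    n = length(x),
    mean = mean(x),
    sd = if (length(x) > 1L) stats::sd(x) else 0,
    min = min(x),
    max = max(x),
    attribute = attribute,
    product = product,
    unit = table$unit[sel][1L]
  ), class = "summary_stats")
}

#' Render summary statistics as "mean (min-max)"
#'
#' The conventional display for lot summaries in analytical similarity
#' reports, e.g. \code{"2.5 (2.2-2.9)"}.
#'
#' @param stats a \code{summary_stats} object.
#' @param digits decimal places for display (default 1).
#' @param dash range separator (en dash by default).
#' @return A single string.
#' @export
format_mean_range <- function(stats, digits = 1, dash = "–") {
  fmt <- function(v) formatC(round(v, digits), format = "f", digits = digits)
  sprintf("%s (%s%s%s)", fmt(stats$mean), fmt(stats$min), dash, fmt(stats$max))
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("%s [%s], n = %d lots: %s %s  (sd %.4g)\n",
              x$attribute, x$product, x$n, format_mean_range(x),
              x$unit, x$sd))
  invisible(x)
}

#' @export
print.lot_table <- function(x, ...) {
  cat(sprintf("Lot table: %d measurements, %d attribute(s), %d test / %d reference lot(s)\n",
              nrow(x), length(unique(x$attribute)),
              length(unique(x$lot_id[x$product == "test"])),
              length(unique(x$lot_id[x$product == "reference"]))))
  if (nzchar(attr(x, "provenance") %||% "")) {
    cat("Provenance:", attr(x, "provenance"), "\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attribute metadata table
#'
#' Validates the per-attribute metadata consumed by criticality scoring and
#' tier assignment: the RRF impact and uncertainty scores and the
#' assay-nature flags. One row describes one (attribute, assay) pair; the
#' same attribute measured by two methods occupies two rows and may land in
#' different tiers.
#'
#' @param defs data frame with columns \code{attribute}, \code{assay},
#'   \code{impact}, \code{uncertainty}, and logical flags \code{moa_direct}
#'   (readout directly reflects the primary mechanism of action),
#'   \code{quantitative}, \code{qualitative_assay}, \code{trace_analyte}
#'   (analyte present in trace amounts), \code{one_sided} (impurity-style
#'   attribute bounded above only); optional \code{unit}.
#' @return Validated data frame of class \code{attribute_definitions}.
#' @export
attribute_definitions <- function(defs) {
  required <- c("attribute", "assay", "impact", "uncertainty", "moa_direct",
                "quantitative", "qualitative_assay", "trace_analyte",
                "one_sided")
  missing_cols <- setdiff(required, names(defs))
  if (length(missing_cols) > 0L) {
    stop("attribute definitions missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- as.data.frame(defs)
  if (!"unit" %in% names(d)) d$unit <- ""
  for (fl in c("moa_direct", "quantitative", "qualitative_assay",
               "trace_analyte", "one_sided")) {
    d[[fl]] <- as.logical(d[[fl]])
    if (anyNA(d[[fl]])) stop("flag column '", fl, "' has missing values",
                             call. = FALSE)
  }
  both <- d$qualitative_assay & d$quantitative
  if (any(both)) {
    stop("assay flagged both qualitative and quantitative: ",
         paste(d$attribute[both], collapse = ", "), call. = FALSE)
  }
  key <- paste(d$attribute, d$assay, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (attribute, assay) definition(s)", call. = FALSE)
  }
  rownames(d) <- NULL
  structure(d, class = c("attribute_definitions", "data.frame"))
}

#' Read attribute metadata from CSV
#'
#' @param path CSV file with the columns documented in
#'   \code{\link{attribute_definitions}}.
#' @return An \code{attribute_definitions} table.
#' @export
read_attribute_definitions <- function(path) {
  attribute_definitions(utils::read.csv(path, stringsAsFactors = FALSE))
}
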