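#' Render a similarity report
#'
#' \code{format = "csv"} writes the flat report table preceded by commented
#' header lines (\code{# key: value}) echoing the configuration used, for
#' auditability; \code{format = "markdown"} renders a table whose summary
#' cells use the conventional \code{"mean (min-max)"} display. Both formats
#' carry identical decision content.
#'
#' @param report a \code{similarity_report} from \code{\link{run_similarity}}.
#' @param format \code{"csv"} or \code{"markdown"}.
#' @param path optional output file; when \code{NULL} the document is
#'   returned as a character vector of lines.
#' @param digits decimal places for markdown summary cells.
#' @return The document lines, invisibly when written to \code{path}.
#' @export
render_report <- function(report, format = c("csv", "markdown"), path = NULL,
                          digits = 1) {
  format <- match.arg(format)
  stopifnot(inherits(report, "similarity_report"))
  cfg <- attr(report, "config")
  lines <- if (format == "csv") {
    header <- c(
      sprintf("# k1: %g", cfg$k1),
      sprintf("# alpha: %g", cfg$alpha),
      sprintf("# variance_mode: %s", cfg$variance_mode),
      sprintf("# k2: %g", cfg$k2),
      sprintf("# pass_fraction: %g", cfg$pass_fraction)
    )
    tc <- textConnection("csv_out", "w", local = TRUE)
    utils::write.csv(as.data.frame(report), tc, row.names = FALSE)
    close(tc)
    c(header, csv_out)
  } else {
    render_markdown(report, digits)
  }
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

render_markdown <- function(report, digits = 1) {
  fmt <- function(v) formatC(round(v, digits), format = "f", digits = digits)
  mr <- function(mean, min, max) {
    ifelse(is.na(mean), "", sprintf("%s (%s–%s)", fmt(mean), fmt(min),
                                    fmt(max)))
  }
  stat_cell <- function(i) {
    r <- report[i, ]
    if (r$decision == "not evaluated") return("no data")
    switch(as.character(r$tier),
      "1" = sprintf("diff %s, CI (%s, %s), margin ±%s",
                    fmt(r$mean_diff), fmt(r$ci_low), fmt(r$ci_high),
                    fmt(r$margin)),
      "2" = sprintf("range [%s, %s], %s%% of lots inside",
                    fmt(r$qr_low), fmt(r$qr_high),
                    formatC(100 * r$fraction_inside, format = "f",
                            digits = 0)),
      "3" = sprintf("range overlap %.2f", r$range_overlap))
  }
  decision_cell <- function(d) {
    switch(d,
           pass = "Pass", fail = "Fail", similar = "Similar",
           lower = "Lower in test product",
           higher = "Higher in test product",
           `not evaluated` = "Not evaluated", d)
  }
  ann <- vapply(report$annotation, function(a)
    switch(a, star = "\\*", hash = "#", ""), character(1))
  rows <- vapply(seq_len(nrow(report)), function(i) {
    r <- report[i, ]
    paste("|", paste(c(
      r$attribute, r$assay, paste0(r$tier, ann[i]),
      mr(r$test_mean, r$test_min, r$test_max),
      mr(r$ref_mean, r$ref_min, r$ref_max),
      stat_cell(i), decision_cell(r$decision)
    ), collapse = " | "), "|")
  }, character(1))
  c("| Quality attribute | Method | Tier | Test mean (range) | Reference mean (range) | Statistics | Similarity assessment |",
    "|---|---|---|---|---|---|---|",
    rows)
}

#' Write a risk/tier table to CSV
#'
#' @param tiers a \code{tier_table} from \code{\link{assign_tiers}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_tier_table <- function(tiers, path) {
  utils::write.csv(as.data.frame(tiers), path, row.names = FALSE)
  invisible(path)
}

#' Read back the decision content of a rendered CSV report
#'
#' Skips the commented configuration header and returns the report table;
#' used to verify that rendered documents round-trip their decisions.
#'
#' @param path CSV report path.
#' @return A data frame.
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
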