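#' Tier-1 equivalence test (two one-sided tests)
#'
#' Tests equivalence of the test-product mean to the reference-product mean
#' against a margin proportional to the reference batch-to-batch variability.
#' The two one-sided tests (TOST) at one-sided size \code{alpha} are carried
#' out through the equivalent two-sided \eqn{100(1-2\alpha)\%} confidence
#' interval for the mean difference: similarity passes when that interval
#' lies strictly inside \eqn{(-k_1 s_R, +k_1 s_R)}, where \eqn{s_R} is the
#' reference sample SD. With the defaults \code{k1 = 1.5},
#' \code{alpha = 0.05}, this is the familiar "90% CI within (-1.5 SD,
#' +1.5 SD)" tier-1 rule.
#'
#' The interval uses the Welch construction by default (unequal variances,
#' Satterthwaite degrees of freedom); \code{variance_mode = "pooled"} gives
#' the classical equal-variance two-sample interval. The margin is always
#' anchored to the reference lots alone, never to pooled or test-product
#' variability.
#'
#' @param test numeric vector of test-product lot values (>= 3).
#' @param ref numeric vector of reference-product lot values (>= 3).
#' @param k1 margin multiplier (margin = \code{k1 * sd(ref)}).
#' @param alpha one-sided test size; the interval has confidence
#'   \code{1 - 2*alpha}.
#' @param variance_mode \code{"welch"} or \code{"pooled"}.
#' @param margin optional explicit margin half-width. By default the margin
#'   is \code{k1 * sd(ref)}, estimated from the reference lots; supplying a
#'   fixed value (e.g. \code{k1} times a known process SD in an
#'   operating-characteristics study) removes the margin-estimation noise,
#'   which otherwise inflates the pass probability at the margin above
#'   \code{alpha} even for large lot counts.
#' @param attribute optional attribute label carried into the result.
#' @return An object of class \code{equivalence_result}: list with
#'   \code{mean_diff}, \code{ci_low}, \code{ci_high}, \code{se}, \code{df},
#'   \code{sd_ref}, \code{margin}, \code{k1}, \code{alpha},
#'   \code{variance_mode}, \code{n_test}, \code{n_ref}, \code{pass}.
#' @examples
#' tost_equivalence(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
#' @export
tost_equivalence <- function(test, ref, k1 = 1.5, alpha = 0.05,
                             variance_mode = c("welch", "pooled"),
                             margin = NULL,
                             attribute = NA_character_) {
  variance_mode <- match.arg(variance_mode)
  n1 <- length(test); n2 <- length(ref)
  if (n1 < 3L || n2 < 3L) {
    stop("insufficient lots: need at least 3 per product (got ", n1,
         " test, ", n2, " reference)", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)",
                                       call. = FALSE)
  sd_ref <- stats::sd(ref)
  if (sd_ref == 0) {
    stop("reference lots have zero standard deviation; margin is degenerate",
         call. = FALSE)
  }
  v1 <- stats::var(test); v2 <- stats::var(ref)
  if (variance_mode == "welch") {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  mean_diff <- mean(test) - mean(ref)
  tq <- stats::qt(1 - alpha, df)
  ci_low <- mean_diff - tq * se
  ci_high <- mean_diff + tq * se
  if (is.null(margin)) margin <- k1 * sd_ref
  structure(list(
    attribute = attribute,
    mean_diff = mean_diff, ci_low = ci_low, ci_high = ci_high,
    se = se, df = df, sd_ref = sd_ref, margin = margin,
    k1 = k1, alpha = alpha, variance_mode = variance_mode,
    n_test = n1, n_ref = n2,
    pass = (ci_low > -margin) && (ci_high < margin)
  ), class = "equivalence_result")
}

#' Tier-2 quality-range comparison
#'
#' Builds the quality range reference mean \eqn{\pm k_2 s_R} from the
#' reference lots and counts how many test lots fall inside it (closed
#' interval: a lot exactly on a bound counts as inside). Similarity passes
#' when the inside fraction reaches \code{pass_fraction}; with the defaults
#' \code{k2 = 3}, \code{pass_fraction = 0.9} this is the "90% of test lots
#' within mean +/- 3 SD of the reference" tier-2 rule. The threshold applies
#' exactly, so with 6 test lots all 6 must be inside (5/6 is about 83%).
#'
#' For impurity-style attributes bounded above only, \code{sidedness =
#' "upper"} uses the one-sided range \eqn{(-\infty, \bar x_R + k_2 s_R]}.
#'
#' @param test numeric vector of test-product lot values (>= 1).
#' @param ref numeric vector of reference-product lot values (>= 3).
#' @param k2 range multiplier.
#' @param pass_fraction minimum inside fraction, compared as
#'   \code{fraction_inside >= pass_fraction}.
#' @param sidedness \code{"two"} or \code{"upper"}.
#' @param attribute optional attribute label carried into the result.
#' @return An object of class \code{quality_range_result}: list with
#'   \code{qr_low}, \code{qr_high}, \code{n_inside}, \code{n_test},
#'   \code{fraction_inside}, \code{k2}, \code{pass_fraction},
#'   \code{sidedness}, \code{sd_ref}, \code{pass}.
#' @examples
#' quality_range(c(2, 3, 9), c(1, 2, 3, 4, 5))
#' @export
quality_range <- function(test, ref, k2 = 3, pass_fraction = 0.9,
                          sidedness = c("two", "upper"),
                          attribute = NA_character_) {
  sidedness <- match.arg(sidedness)
  if (length(ref) < 3L) stop("need at least 3 reference lots", call. = FALSE)
  if (length(test) < 1L) stop("need at least 1 test lot", call. = FALSE)
  sd_ref <- stats::sd(ref)
  if (sd_ref == 0) {
    stop("reference lots have zero standard deviation; quality range is degenerate",
         call. = FALSE)
  }
  m_ref <- mean(ref)
  qr_high <- m_ref + k2 * sd_ref
  qr_low <- if (sidedness == "upper") -Inf else m_ref - k2 * sd_ref
  inside <- test >= qr_low & test <= qr_high
  n_inside <- sum(inside)
  fraction_inside <- n_inside / length(test)
  structure(list(
    attribute = attribute,
    qr_low = qr_low, qr_high = qr_high,
    n_inside = n_inside, n_test = length(test),
    fraction_inside = fraction_inside,
    k2 = k2, pass_fraction = pass_fraction, sidedness = sidedness,
    sd_ref = sd_ref,
    pass = fraction_inside >= pass_fraction
  ), class = "quality_range_result")
}

#' Tier-3 descriptive range comparison
#'
#' A reproducible numeric stand-in for the visual side-by-side comparison
#' used for the lowest-risk attributes. Reports both products' lot summaries,
#' the overlap of their observed ranges (intersection length divided by union
#' length), and a categorical flag: \code{"lower"} when the test range lies
#' entirely below the reference range, \code{"higher"} when entirely above,
#' \code{"similar"} otherwise (i.e. whenever the ranges touch or overlap).
#'
#' @param test numeric vector of test-product lot values (>= 1).
#' @param ref numeric vector of reference-product lot values (>= 1).
#' @param attribute optional attribute label carried into the result.
#' @return An object of class \code{descriptive_comparison}: list with
#'   \code{test_summary}, \code{ref_summary} (both \code{summary_stats}-like
#'   lists), \code{range_overlap} in [0, 1], and \code{flag}.
#' @examples
#' tier3_compare(c(2.2, 2.5, 2.9), c(6.7, 8.0, 8.4))$flag  # "lower"
#' @export
tier3_compare <- function(test, ref, attribute = NA_character_) {
  if (length(test) < 1L || length(ref) < 1L) {
    stop("need at least 1 lot per product", call. = FALSE)
  }
  summ <- function(x) list(n = length(x), mean = mean(x),
                           sd = if (length(x) > 1L) stats::sd(x) else 0,
                           min = min(x), max = max(x))
  ts <- summ(test); rs <- summ(ref)
  inter <- max(0, min(ts$max, rs$max) - max(ts$min, rs$min))
  union_len <- max(ts$max, rs$max) - min(ts$min, rs$min)
  # both ranges degenerate to the same point -> complete overlap
  range_overlap <- if (union_len == 0) 1 else inter / union_len
  flag <- if (ts$max < rs$min) "lower"
          else if (ts$min > rs$max) "higher"
          else "similar"
  structure(list(attribute = attribute,
                 test_summary = structure(c(ts, list(attribute = attribute,
                                                     product = "test",
                                                     unit = "")),
                                          class = "summary_stats"),
                 ref_summary = structure(c(rs, list(attribute = attribute,
                                                    product = "reference",
                                                    unit = "")),
                                         class = "summary_stats"),
                 range_overlap = range_overlap, flag = flag),
            class = "descriptive_comparison")
}

#' Run the tiered similarity assessment
#'
#' Applies the tier-appropriate procedure to every (attribute, assay) row of
#' a tier table: tier 1 gets \code{\link{tost_equivalence}}, tier 2
#' \code{\link{quality_range}}, tier 3 \code{\link{tier3_compare}}. Rows
#' whose attribute has no lot data for both products are reported as
#' \code{"not evaluated"} rather than raising an error. Report rows follow
#' the order of the tier table.
#'
#' @param lots a \code{\link{lot_table}}.
#' @param tiers data frame with at least \code{attribute}, \code{assay},
#'   \code{tier} (and optionally \code{annotation}, \code{risk_rank},
#'   \code{one_sided}); typically a \code{tier_table} from
#'   \code{\link{assign_tiers}}, possibly joined with a per-attribute
#'   \code{one_sided} flag for upper-sided tier-2 ranges.
#' @param config configuration list; see \code{\link{default_config}}.
#' @return An object of class \code{similarity_report}: a data frame with one
#'   row per tier-table row (columns: attribute, assay, tier, annotation,
#'   lot counts, per-product mean/sd/min/max, the tier-specific statistics,
#'   and \code{decision}), with attributes \code{config} (echo),
#'   \code{results} (the underlying result objects) and \code{counts}
#'   (decision tallies).
#' @export
run_similarity <- function(lots, tiers, config = default_config()) {
  stopifnot(inherits(lots, "lot_table"))
  validate_config(config)
  need <- c("attribute", "assay", "tier")
  if (!all(need %in% names(tiers))) {
    stop("tier table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  results <- vector("list", nrow(tiers))
  rows <- vector("list", nrow(tiers))
  for (i in seq_len(nrow(tiers))) {
    at <- tiers$attribute[i]
    tier <- as.integer(tiers$tier[i])
    test <- lots$value[lots$attribute == at & lots$product == "test"]
    ref <- lots$value[lots$attribute == at & lots$product == "reference"]
    row <- data.frame(
      attribute = at, assay = tiers$assay[i], tier = tier,
      annotation = if ("annotation" %in% names(tiers))
        tiers$annotation[i] else "none",
      n_test = length(test), n_ref = length(ref),
      test_mean = NA_real_, test_sd = NA_real_,
      test_min = NA_real_, test_max = NA_real_,
      ref_mean = NA_real_, ref_sd = NA_real_,
      ref_min = NA_real_, ref_max = NA_real_,
      mean_diff = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      margin = NA_real_, qr_low = NA_real_, qr_high = NA_real_,
      fraction_inside = NA_real_, range_overlap = NA_real_,
      decision = "not evaluated", stringsAsFactors = FALSE
    )
    if (length(test) >= 1L && length(ref) >= 1L) {
      row$test_mean <- mean(test); row$ref_mean <- mean(ref)
      row$test_sd <- if (length(test) > 1) stats::sd(test) else 0
      row$ref_sd <- if (length(ref) > 1) stats::sd(ref) else 0
      row$test_min <- min(test); row$test_max <- max(test)
      row$ref_min <- min(ref); row$ref_max <- max(ref)
      res <- tryCatch(
        switch(as.character(tier),
          "1" = tost_equivalence(test, ref, k1 = config$k1,
                                 alpha = config$alpha,
                                 variance_mode = config$variance_mode,
                                 attribute = at),
          "2" = quality_range(test, ref, k2 = config$k2,
                              pass_fraction = config$pass_fraction,
                              sidedness = if (isTRUE(as.logical(
                                tiers$one_sided[i]))) "upper" else "two",
                              attribute = at),
          "3" = tier3_compare(test, ref, attribute = at),
          stop("unknown tier: ", tier, call. = FALSE)
        ),
        error = function(e) e
      )
      if (!inherits(res, "error")) {
        results[[i]] <- res
        if (tier == 1L) {
          row$mean_diff <- res$mean_diff
          row$ci_low <- res$ci_low; row$ci_high <- res$ci_high
          row$margin <- res$margin
          row$decision <- if (res$pass) "pass" else "fail"
        } else if (tier == 2L) {
          row$qr_low <- res$qr_low; row$qr_high <- res$qr_high
          row$fraction_inside <- res$fraction_inside
          row$decision <- if (res$pass) "pass" else "fail"
        } else {
          row$range_overlap <- res$range_overlap
          row$decision <- res$flag
        }
      } else {
        row$decision <- "not evaluated"
      }
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows %||% list())
  if (is.null(out)) {
    out <- data.frame(attribute = character(), assay = character(),
                      tier = integer(), annotation = character(),
                      n_test = integer(), n_ref = integer(),
                      test_mean = numeric(), test_sd = numeric(),
                      test_min = numeric(), test_max = numeric(),
                      ref_mean = numeric(), ref_sd = numeric(),
                      ref_min = numeric(), ref_max = numeric(),
                      mean_diff = numeric(), ci_low = numeric(),
                      ci_high = numeric(), margin = numeric(),
                      qr_low = numeric(), qr_high = numeric(),
                      fraction_inside = numeric(), range_overlap = numeric(),
                      decision = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  counts <- table(factor(out$decision,
                         levels = c("pass", "fail", "similar", "lower",
                                    "higher", "not evaluated")))
  structure(out, config = config, results = results,
            counts = as.list(counts),
            class = c("similarity_report", "data.frame"))
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(
    "Equivalence (TOST, %s): diff %.4g, %d%% CI (%.4g, %.4g), margin +/-%.4g -> %s\n",
    x$variance_mode, x$mean_diff, round(100 * (1 - 2 * x$alpha)),
    x$ci_low, x$ci_high, x$margin, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' @export
print.quality_range_result <- function(x, ...) {
  cat(sprintf(
    "Quality range (%s-sided): [%.4g, %.4g], %d/%d lots inside (%.1f%%) -> %s\n",
    x$sidedness, x$qr_low, x$qr_high, x$n_inside, x$n_test,
    100 * x$fraction_inside, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' @export
print.descriptive_comparison <- function(x, ...) {
  cat(sprintf(
    "Descriptive comparison: test %s vs reference %s; range overlap %.3f -> %s\n",
    format_mean_range(x$test_summary), format_mean_range(x$ref_summary),
    x$range_overlap, x$flag))
  invisible(x)
}

#' @export
print.similarity_report <- function(x, ...) {
  counts <- attr(x, "counts")
  cat(sprintf("Similarity report: %d attribute/assay rows\n", nrow(x)))
  cat(sprintf("  pass %d | fail %d | similar %d | lower %d | higher %d | not evaluated %d\n",
              counts$pass, counts$fail, counts$similar, counts$lower,
              counts$higher, counts$`not evaluated`))
  print.data.frame(as.data.frame(x)[, c("attribute", "assay", "tier",
                                        "decision")])
  invisible(x)
}
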