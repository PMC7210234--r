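#' RRF risk score
#'
#' The risk ranking and filtering (RRF) criticality score of a quality
#' attribute: the product of an ordinal impact score (consequence of the
#' attribute drifting, for safety or efficacy) and an ordinal uncertainty
#' score (how well that consequence is understood). Both scores must come
#' from the configured ordinal scales.
#'
#' @param impact impact score.
#' @param uncertainty uncertainty score.
#' @param config configuration list providing \code{impact_scale} and
#'   \code{uncertainty_scale}; see \code{\link{default_config}}.
#' @return The numeric risk score, \code{impact * uncertainty}. Vectorized.
#' @examples
#' risk_score(16, 3)  # 48
#' @export
risk_score <- function(impact, uncertainty, config = default_config()) {
  check_scale(impact, config$impact_scale, "impact")
  check_scale(uncertainty, config$uncertainty_scale, "uncertainty")
  impact * uncertainty
}

check_scale <- function(x, scale, what) {
  bad <- !x %in% scale
  if (any(bad)) {
    stop(what, " score(s) ", paste(unique(x[bad]), collapse = ", "),
         " not on the allowed scale {", paste(scale, collapse = ", "), "}",
         call. = FALSE)
  }
  invisible(x)
}

#' Rank a risk score as High / Moderate / Low
#'
#' @param score numeric risk score(s).
#' @param config configuration list providing \code{rank_cutpoints}.
#' @return Character vector of ranks.
#' @export
risk_rank <- function(score, config = default_config()) {
  cp <- config$rank_cutpoints
  ifelse(score >= cp[["High"]], "High",
         ifelse(score >= cp[["Moderate"]], "Moderate", "Low"))
}

#' Classify attributes as CQA or not
#'
#' Applies the RRF filter: an attribute is a critical quality attribute (CQA)
#' when its risk score reaches the configured cutoff, or when it is on the
#' mandatory-CQA list (by default the process-related impurities, which are
#' treated as critical on toxicity/immunogenicity grounds even when their
#' uncertainty score is low).
#'
#' @param defs an \code{\link{attribute_definitions}} table (or data frame
#'   with \code{attribute}, \code{assay}, \code{impact}, \code{uncertainty}).
#' @param config configuration list; see \code{\link{default_config}}.
#' @return A data frame of class \code{risk_assessment} with columns
#'   \code{attribute}, \code{assay}, \code{impact}, \code{uncertainty},
#'   \code{risk_score}, \code{risk_rank}, \code{is_cqa}.
#' @export
classify_cqa <- function(defs, config = default_config()) {
  score <- risk_score(defs$impact, defs$uncertainty, config)
  out <- data.frame(
    attribute = defs$attribute,
    assay = defs$assay,
    impact = defs$impact,
    uncertainty = defs$uncertainty,
    risk_score = score,
    risk_rank = risk_rank(score, config),
    is_cqa = score >= config$cqa_cutoff |
      defs$attribute %in% config$mandatory_cqa,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("risk_assessment", "data.frame"))
}

#' Assign one attribute/assay pair to a similarity tier
#'
#' Tier assignment rules, applied in order:
#' \enumerate{
#'   \item Tier 1 — the attribute's readout directly reflects the primary
#'     mechanism of action (\code{moa_direct}); assessed by equivalence
#'     testing.
#'   \item An explicit per-row override in \code{config$tier_overrides}, if
#'     present, wins over the general rule below.
#'   \item Tier 2 — High or Moderate risk rank, quantitative readout, and
#'     neither a qualitative assay nor a trace-level analyte; assessed by the
#'     quality-range rule.
#'   \item Tier 3 otherwise — lowest-risk attributes, plus any attribute whose
#'     assay is qualitative (annotation \code{"star"}) or whose analyte is
#'     present only in trace amounts (annotation \code{"hash"}), regardless of
#'     risk rank; assessed descriptively.
#' }
#'
#' @param defn a one-row \code{\link{attribute_definitions}} slice (or list
#'   with the same fields).
#' @param risk_rank \code{"High"}, \code{"Moderate"} or \code{"Low"}.
#' @param config configuration list (for the override table).
#' @return A list of class \code{tier_assignment}: \code{attribute},
#'   \code{assay}, \code{tier} (integer 1/2/3), \code{annotation}
#'   (\code{"none"}, \code{"star"}, \code{"hash"}), \code{rationale}.
#' @examples
#' defn <- list(attribute = "Free thiols", assay = "fluorescent kit",
#'              moa_direct = FALSE, quantitative = TRUE,
#'              qualitative_assay = FALSE, trace_analyte = TRUE)
#' assign_tier(defn, "High")$tier  # 3, annotation "hash"
#' @export
assign_tier <- function(defn, risk_rank, config = default_config()) {
  risk_rank <- match.arg(risk_rank, c("High", "Moderate", "Low"))
  if (isTRUE(defn$qualitative_assay) && isTRUE(defn$quantitative)) {
    stop("attribute '", defn$attribute,
         "': assay cannot be both qualitative and quantitative", call. = FALSE)
  }
  annotation <- "none"
  if (isTRUE(defn$moa_direct)) {
    tier <- 1L
    rationale <- "direct impact on primary mechanism of action"
  } else {
    ov <- config$tier_overrides
    hit <- !is.null(ov) && nrow(ov) > 0 &&
      any(ov$attribute == defn$attribute & ov$assay == defn$assay)
    if (hit) {
      tier <- as.integer(ov$tier[ov$attribute == defn$attribute &
                                   ov$assay == defn$assay][1L])
      rationale <- "per-attribute override"
    } else if (risk_rank %in% c("High", "Moderate") &&
               isTRUE(defn$quantitative) &&
               !isTRUE(defn$trace_analyte) &&
               !isTRUE(defn$qualitative_assay)) {
      tier <- 2L
      rationale <- sprintf("%s risk, quantitative assay", risk_rank)
    } else {
      tier <- 3L
      rationale <- if (isTRUE(defn$qualitative_assay)) {
        "qualitative assay"
      } else if (isTRUE(defn$trace_analyte)) {
        "trace-level analyte"
      } else {
        "low risk"
      }
    }
    if (tier == 3L) {
      if (isTRUE(defn$qualitative_assay)) annotation <- "star"
      if (isTRUE(defn$trace_analyte)) annotation <- "hash"
    }
  }
  structure(list(attribute = defn$attribute, assay = defn$assay,
                 tier = tier, annotation = annotation,
                 rationale = rationale),
            class = "tier_assignment")
}

#' Risk-assess and tier a whole attribute panel
#'
#' Runs \code{\link{classify_cqa}} and \code{\link{assign_tier}} over every
#' (attribute, assay) row of a metadata table.
#'
#' @param defs an \code{\link{attribute_definitions}} table.
#' @param config configuration list.
#' @return A data frame of class \code{tier_table}: one row per
#'   (attribute, assay) with columns \code{attribute}, \code{assay},
#'   \code{impact}, \code{uncertainty}, \code{risk_score}, \code{risk_rank},
#'   \code{is_cqa}, \code{tier}, \code{annotation}, \code{rationale}.
#' @export
assign_tiers <- function(defs, config = default_config()) {
  risk <- classify_cqa(defs, config)
  rows <- lapply(seq_len(nrow(defs)), function(i) {
    ta <- assign_tier(as.list(defs[i, , drop = FALSE]), risk$risk_rank[i],
                      config)
    data.frame(tier = ta$tier, annotation = ta$annotation,
               rationale = ta$rationale, stringsAsFactors = FALSE)
  })
  out <- cbind(as.data.frame(risk), do.call(rbind, rows))
  rownames(out) <- NULL
  structure(out, class = c("tier_table", "data.frame"))
}

#' Bundled adalimumab attribute panel
#'
#' The worked attribute panel shipped with the package: the quality
#' attributes, assays, assay-nature flags and published risk ranks / tiers of
#' an adalimumab biosimilar similarity exercise, one row per
#' (attribute, assay) pair. The columns \code{published_risk},
#' \code{published_tier} and \code{published_annotation} record the published
#' assessment and are used only for cross-checking; \code{\link{assign_tiers}}
#' recomputes tiers from the flags and scores alone.
#'
#' @return A list with \code{definitions} (an
#'   \code{\link{attribute_definitions}} table) and \code{published} (data
#'   frame of published risk ranks, tiers and annotations, same row order).
#' @export
adalimumab_panel <- function() {
  path <- system.file("extdata", "adalimumab_attribute_panel.csv",
                      package = "biosimtier", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  defs <- attribute_definitions(raw[, c("attribute", "assay", "impact",
                                        "uncertainty", "moa_direct",
                                        "quantitative", "qualitative_assay",
                                        "trace_analyte", "one_sided", "unit")])
  published <- raw[, c("attribute", "assay", "published_risk",
                       "published_tier", "published_annotation")]
  list(definitions = defs, published = published)
}

#' @export
print.tier_assignment <- function(x, ...) {
  ann <- switch(x$annotation, star = "*", hash = "#", "")
  cat(sprintf("%s [%s]: tier %d%s (%s)\n", x$attribute, x$assay, x$tier, ann,
              x$rationale))
  invisible(x)
}
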