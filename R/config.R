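#' Default run configuration
#'
#' Collects every tunable constant of the pipeline with its default. The
#' statistical defaults are the ones conventional in tiered analytical
#' similarity exercises: a tier-1 equivalence margin of 1.5 reference SDs
#' supported by a 90% confidence interval (two one-sided tests at
#' \eqn{\alpha = 0.05}), and a tier-2 quality range of reference mean
#' \eqn{\pm} 3 SDs that must contain at least 90% of the test lots.
#'
#' The RRF ordinal scales default to impact \{2, 4, 12, 16, 20\} and
#' uncertainty \{1, 2, 3, 5, 7\}; the risk score is their product. Risk-rank
#' cut-points and the CQA cutoff act on that score. All of it is plain
#' configuration: pass a modified list anywhere a \code{config} argument is
#' accepted, or store it as JSON (see \code{\link{read_run_config}}).
#'
#' @return A named list with components:
#' \describe{
#'   \item{k1}{tier-1 margin multiplier (margin = k1 x reference SD), 1.5.}
#'   \item{alpha}{one-sided size of each of the two one-sided tests, 0.05
#'     (interval confidence 1 - 2 alpha = 90\%).}
#'   \item{variance_mode}{"welch" (default) or "pooled" interval construction.}
#'   \item{k2}{tier-2 quality-range multiplier, 3.}
#'   \item{pass_fraction}{minimum fraction of test lots inside the quality
#'     range, 0.9, applied as fraction >= 0.9 exactly.}
#'   \item{impact_scale, uncertainty_scale}{allowed ordinal scores.}
#'   \item{rank_cutpoints}{named numeric: minimum risk score for High and for
#'     Moderate rank; anything below is Low.}
#'   \item{cqa_cutoff}{minimum risk score for CQA status.}
#'   \item{mandatory_cqa}{attribute names always classified as CQAs
#'     irrespective of score (process-related impurities by default).}
#'   \item{tier_overrides}{data frame (attribute, assay, tier) of per-row tier
#'     assignments that take precedence over the general rule.}
#' }
#' @export
default_config <- function() {
  list(
    k1 = 1.5,
    alpha = 0.05,
    variance_mode = "welch",
    k2 = 3,
    pass_fraction = 0.9,
    impact_scale = c(2, 4, 12, 16, 20),
    uncertainty_scale = c(1, 2, 3, 5, 7),
    rank_cutpoints = c(High = 40, Moderate = 16),
    cqa_cutoff = 40,
    mandatory_cqa = c("DNA", "HCP", "Protein A"),
    tier_overrides = data.frame(
      attribute = c("Sub-micron particles", "Sub-visible particles"),
      assay = c("DLS", "MFI"),
      tier = c(3L, 3L),
      stringsAsFactors = FALSE
    )
  )
}

#' Read a run configuration from JSON
#'
#' Any key present in the file replaces the corresponding default from
#' \code{\link{default_config}}; keys not present keep their defaults.
#' \code{tier_overrides} may be given as an array of objects with fields
#' \code{attribute}, \code{assay}, \code{tier}.
#'
#' @param path JSON file path.
#' @return A full configuration list.
#' @export
read_run_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (key in names(user)) {
    value <- user[[key]]
    if (key == "rank_cutpoints") value <- unlist(value)
    if (key == "tier_overrides") value <- as.data.frame(value)
    cfg[[key]] <- value
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$k1) || cfg$k1 < 0) stop("k1 must be >= 0", call. = FALSE)
  if (!is.numeric(cfg$k2) || cfg$k2 < 0) stop("k2 must be >= 0", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 0.5) {
    stop("alpha must lie in (0, 0.5)", call. = FALSE)
  }
  if (cfg$pass_fraction < 0 || cfg$pass_fraction > 1) {
    stop("pass_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!all(c("High", "Moderate") %in% names(cfg$rank_cutpoints))) {
    stop("rank_cutpoints must name High and Moderate minima", call. = FALSE)
  }
  invisible(cfg)
}

#' Write a configuration to JSON
#'
#' @param cfg configuration list as from \code{\link{default_config}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
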