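# Molecular quantification from qPCR cycle thresholds: ChIP-qPCR percent
# input and relative expression by the 2^-ddCt method.  Both are exact
# closed forms; technical duplicates are averaged on the Ct scale before any
# exponentiation.

#' ChIP-qPCR percent input
#'
#' `100 * 2^-dCt` with `dCt = Ct[ChIP] - (Ct[input] - log2(dilution))`: the
#' immunoprecipitated DNA as a percentage of the dilution-corrected input
#' chromatin.
#'
#' @param ct_chip,ct_input Cycle thresholds of the ChIP and input reactions.
#' @param dilution_factor Input dilution factor (>= 1).
#' @return Percent input.  Vectorized over all arguments.
#' @export
#' @examples
#' percent_input(25, 20, dilution_factor = 100)
percent_input <- function(ct_chip, ct_input, dilution_factor = 1) {
  if (any(!is.finite(ct_chip)) || any(!is.finite(ct_input))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  if (any(dilution_factor < 1)) {
    stop("dilution_factor must be >= 1", call. = FALSE)
  }
  dct <- ct_chip - (ct_input - log2(dilution_factor))
  100 * 2^(-dct)
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((Ct[target,sample] - Ct[hk,sample]) - (Ct[target,ref] - Ct[hk,ref]))`,
#' the fold change of a target gene in a sample relative to a reference
#' condition, normalized to a housekeeping gene.  No amplification-efficiency
#' correction is applied.
#'
#' @param ct_target_s,ct_hk_s Target and housekeeping Ct in the sample.
#' @param ct_target_r,ct_hk_r Target and housekeeping Ct in the reference.
#' @return Fold change.  Vectorized over all arguments.
#' @export
#' @examples
#' ddct_fold_change(20, 18, 22, 18) # two cycles earlier -> fourfold
ddct_fold_change <- function(ct_target_s, ct_hk_s, ct_target_r, ct_hk_r) {
  cts <- list(ct_target_s, ct_hk_s, ct_target_r, ct_hk_r)
  if (any(vapply(cts, function(x) any(!is.finite(x)), TRUE))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  2^(-((ct_target_s - ct_hk_s) - (ct_target_r - ct_hk_r)))
}

#' Summarize qPCR replicates per condition
#'
#' Technical duplicates are first averaged on the Ct scale (arithmetic mean
#' per condition/replicate/role); the quantification formula is then applied
#' per biological replicate and conditions are summarized as mean and SEM on
#' the computed scale.
#'
#' @param records Data frame of Ct records with columns `condition`,
#'   `replicate`, `role`, `ct` and (for inputs) `dilution_factor`.  Roles are
#'   `"chip"`/`"input"` in `"percent_input"` mode and
#'   `"target_gene"`/`"housekeeping"` in `"ddct"` mode.
#' @param mode `"percent_input"` or `"ddct"`.
#' @param reference Reference condition label (required for `"ddct"`); the
#'   reference delta-Ct is the mean over its replicates.
#' @return Data frame with one row per condition: `condition`, `n`, `mean`,
#'   `sem` (`NA` with a warning for single-replicate conditions).
#' @export
summarize_replicates <- function(records, mode = c("percent_input", "ddct"),
                                 reference = NULL) {
  mode <- match.arg(mode)
  needed <- c("condition", "replicate", "role", "ct")
  if (!all(needed %in% names(records))) {
    stop("records need columns condition, replicate, role, ct", call. = FALSE)
  }
  # technical duplicates: average Ct per condition/replicate/role
  agg <- stats::aggregate(ct ~ condition + replicate + role, records, mean)
  if (mode == "percent_input") {
    if (!"dilution_factor" %in% names(records)) {
      stop("percent_input mode needs a dilution_factor column", call. = FALSE)
    }
    dil <- stats::aggregate(dilution_factor ~ condition + replicate,
                            records[records$role == "input", ], mean)
    wide <- merge(
      agg[agg$role == "chip", c("condition", "replicate", "ct")],
      agg[agg$role == "input", c("condition", "replicate", "ct")],
      by = c("condition", "replicate"), suffixes = c("_chip", "_input")
    )
    wide <- merge(wide, dil, by = c("condition", "replicate"))
    wide$value <- percent_input(wide$ct_chip, wide$ct_input,
                                wide$dilution_factor)
  } else {
    if (is.null(reference)) stop("ddct mode needs a reference condition",
                                 call. = FALSE)
    wide <- merge(
      agg[agg$role == "target_gene", c("condition", "replicate", "ct")],
      agg[agg$role == "housekeeping", c("condition", "replicate", "ct")],
      by = c("condition", "replicate"), suffixes = c("_target", "_hk")
    )
    wide$dct <- wide$ct_target - wide$ct_hk
    ref_dct <- mean(wide$dct[wide$condition == reference])
    if (!is.finite(ref_dct)) {
      stop(sprintf("reference condition '%s' not found", reference),
           call. = FALSE)
    }
    wide$value <- 2^(-(wide$dct - ref_dct))
  }
  out <- do.call(rbind, lapply(split(wide, wide$condition), function(d) {
    data.frame(
      condition = d$condition[1L], n = nrow(d), mean = mean(d$value),
      sem = if (nrow(d) >= 2L) stats::sd(d$value) / sqrt(nrow(d))
            else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  if (any(out$n < 2L)) warning("single-replicate condition: SEM undefined")
  out
}
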