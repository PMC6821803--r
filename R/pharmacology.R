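# Treatment / washout analysis: network metrics of a well recorded under a
# sequence of conditions are expressed relative to its own non-treated (NT)
# baseline, and condition groups are tabulated as mean +/- SEM.

#' Condition series for one well
#'
#' Segment-wise metrics of a single well across a pharmacology experiment.
#' The non-treated baseline segment must be present (condition `"NT"`)
#' before any normalization is possible.
#'
#' @param well_id Well identifier.
#' @param condition Character vector of condition labels per segment
#'   (`"NT"`, `"NBQX"`, `"D-AP5"`, `"MK-801"`, `"Naspm"`, ...).
#' @param t_offset Numeric vector of segment times in minutes from treatment
#'   (the NT baseline may use a negative or zero offset); must be
#'   non-decreasing.
#' @param metrics Data frame of per-segment network metrics (one row per
#'   segment, columns as in [summarize_well()]).
#' @return An object of class `condition_series`.
#' @export
condition_series <- function(well_id, condition, t_offset, metrics) {
  stopifnot(is.data.frame(metrics), nrow(metrics) == length(condition),
            length(condition) == length(t_offset))
  if (!"NT" %in% condition) {
    stop("a non-treated (NT) baseline segment is required", call. = FALSE)
  }
  if (is.unsorted(t_offset)) {
    stop("t_offset must be increasing", call. = FALSE)
  }
  structure(
    list(well_id = as.character(well_id), condition = as.character(condition),
         t_offset = as.numeric(t_offset), metrics = metrics),
    class = "condition_series"
  )
}

#' Normalize a metric to the non-treated baseline
#'
#' Each segment's value is divided by the well's NT value, so the NT segment
#' maps to exactly 1 and full suppression to 0.
#'
#' @param series A [condition_series()].
#' @param field Metric column name, e.g. `"nb_rate"`.
#' @return Data frame with columns `t_offset`, `condition`, `ratio`.
#' @export
normalize_to_baseline <- function(series, field) {
  stopifnot(inherits(series, "condition_series"))
  if (!field %in% names(series$metrics)) {
    stop(sprintf("unknown metric field '%s'", field), call. = FALSE)
  }
  v <- series$metrics[[field]]
  nt <- v[series$condition == "NT"][1L]
  if (!is.finite(nt) || nt <= 0) {
    stop(sprintf("well %s: NT baseline of '%s' is zero or undefined",
                 series$well_id, field), call. = FALSE)
  }
  data.frame(t_offset = series$t_offset, condition = series$condition,
             ratio = v / nt, stringsAsFactors = FALSE)
}

#' Normalized recovery at a given time after treatment
#'
#' Piecewise-linear interpolation of the baseline-normalized trajectory of
#' the treated segments at time `t` minutes after treatment.
#'
#' @param series A [condition_series()].
#' @param field Metric column name.
#' @param t Time in minutes; must lie within the recorded treated range.
#' @return Normalized ratio at `t` (1 = full recovery to baseline).
#' @export
recovery_fraction <- function(series, field, t) {
  norm <- normalize_to_baseline(series, field)
  seg <- norm[norm$condition != "NT", , drop = FALSE]
  if (nrow(seg) < 1L) stop("no treated segments", call. = FALSE)
  if (t < min(seg$t_offset) || t > max(seg$t_offset)) {
    stop(sprintf("t = %g min outside recorded range [%g, %g]",
                 t, min(seg$t_offset), max(seg$t_offset)), call. = FALSE)
  }
  if (nrow(seg) == 1L) return(seg$ratio)
  stats::approx(seg$t_offset, seg$ratio, xout = t, ties = mean)$y
}

#' Tabulate a metric across condition groups
#'
#' Per-group mean, SEM and n, plus all pairwise mean differences.  No
#' hypothesis tests are computed.
#'
#' @param groups Named list mapping condition label to a data frame of well
#'   metrics (as from [summarize_well()]), or a single metric table with a
#'   `condition` column.
#' @param field Metric column name.
#' @return List with `summary` (condition, n, mean, sem; SEM is `NA` with a
#'   flag for groups of size < 2) and `differences` (condition_a,
#'   condition_b, mean_diff).
#' @export
compare_conditions <- function(groups, field) {
  if (is.data.frame(groups)) {
    stopifnot("condition" %in% names(groups))
    groups <- split(groups, groups$condition)
  }
  if (length(groups) < 2L) stop("need at least 2 condition groups",
                                call. = FALSE)
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]][[field]]
    v <- v[is.finite(v)]
    data.frame(
      condition = g, n = length(v), mean = mean(v),
      sem = if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  if (any(summ$n < 2L)) {
    warning("groups of size < 2: SEM undefined for those groups")
  }
  pairs <- utils::combn(summ$condition, 2L)
  diffs <- data.frame(
    condition_a = pairs[1L, ], condition_b = pairs[2L, ],
    mean_diff = summ$mean[match(pairs[1L, ], summ$condition)] -
      summ$mean[match(pairs[2L, ], summ$condition)],
    stringsAsFactors = FALSE
  )
  list(summary = summ, differences = diffs)
}
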