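# Secondary screen: per-dose suppression profiles in tumor vs control cell
# lines, and the three-way selectivity / efficacy / off-target triage.

#' Percent suppression from a luminescent viability reading
#'
#' `100 * (1 - rlu / median(vehicle_rlu))`: 0% at vehicle level, 100% at
#' complete viability loss, negative under growth stimulation.
#'
#' @param rlu luminescence reading(s).
#' @param vehicle_rlu vehicle-well readings (median must be > 0).
#' @return suppression percent.
#' @export
suppression_from_viability <- function(rlu, vehicle_rlu) {
  mv <- stats::median(vehicle_rlu)
  if (!is.finite(mv) || mv <= 0) stop("vehicle median rlu must be > 0")
  100 * (1 - rlu / mv)
}

#' Percent suppression from an imaging metric
#'
#' Control-based normalized effect of the chosen imaging metric: vehicle
#' anchored at 0%, positive control at 100%.
#'
#' @param x raw imaging metric value(s) (AUC or final-timepoint fraction).
#' @param vehicle_values,positive_values control metric values.
#' @return suppression percent.
#' @export
suppression_from_imaging <- function(x, vehicle_values, positive_values) {
  normalize_control_based(x, vehicle_values, positive_values)
}

#' Construct a dose profile
#'
#' @param compound_id,cell_line,metric_kind identifiers.
#' @param doses_nM ascending dose ladder (nM).
#' @param suppression_percent suppression at each dose (capped above at
#'   100).
#' @return list of class `dose_profile`.
#' @export
dose_profile <- function(compound_id, cell_line, metric_kind,
                         doses_nM, suppression_percent) {
  if (length(doses_nM) != length(suppression_percent) ||
      length(doses_nM) == 0) {
    stop("doses and suppression values must be matched and non-empty")
  }
  ord <- order(doses_nM)
  doses_nM <- doses_nM[ord]
  suppression_percent <- pmin(suppression_percent[ord], 100)
  if (any(diff(doses_nM) <= 0)) stop("doses must be strictly increasing")
  structure(list(compound_id = compound_id, cell_line = cell_line,
                 metric_kind = metric_kind, doses_nM = doses_nM,
                 suppression_percent = suppression_percent),
            class = "dose_profile")
}

.check_matched_profiles <- function(tumor, control) {
  if (length(tumor$doses_nM) != length(control$doses_nM) ||
      any(abs(tumor$doses_nM - control$doses_nM) >
            1e-9 * pmax(tumor$doses_nM, 1))) {
    stop("dose-ladder mismatch between tumor and control profiles")
  }
  if (!identical(tumor$metric_kind, control$metric_kind)) {
    stop("metric kind mismatch between profiles")
  }
  invisible(TRUE)
}

#' Selectivity filter: tumor-vs-control suppression difference
#'
#' Passes when `tumor - control` suppression exceeds `delta` percentage
#' points (strictly) at `min_doses` or more doses; the exceedance doses need
#' not be adjacent.
#'
#' @param tumor,control `dose_profile`s on the same ladder and metric.
#' @param delta required difference in percentage points (default 40).
#' @param min_doses minimum number of exceedance doses (default 2).
#' @return logical.
#' @export
selectivity_filter <- function(tumor, control, delta = 40, min_doses = 2) {
  .check_matched_profiles(tumor, control)
  diffs <- tumor$suppression_percent - control$suppression_percent
  sum(diffs > delta) >= min_doses
}

#' Efficacy filter: suppression at the highest dose in the tumor line
#'
#' Passes when tumor suppression at the maximal dose is strictly greater
#' than `cutoff` percent.
#'
#' @param tumor a `dose_profile`.
#' @param cutoff percent (default 50).
#' @return logical.
#' @export
efficacy_filter <- function(tumor, cutoff = 50) {
  n <- length(tumor$suppression_percent)
  if (n == 0) stop("empty profile")
  tumor$suppression_percent[n] > cutoff
}

#' Off-target safety filter: suppression at the highest dose in the control
#' line
#'
#' Passes when control suppression at the maximal dose is strictly less than
#' `cutoff` percent.
#'
#' @param control a `dose_profile`.
#' @param cutoff percent (default 50).
#' @return logical.
#' @export
safety_filter <- function(control, cutoff = 50) {
  n <- length(control$suppression_percent)
  if (n == 0) stop("empty profile")
  control$suppression_percent[n] < cutoff
}

#' Triage a secondary screen
#'
#' Applies the three filters (selectivity, efficacy, off-target safety) to
#' every candidate with tumor and control profiles for the requested metric.
#' Replicate wells per (compound, cell line, dose) are aggregated by median
#' before filtering.
#'
#' @param profiles long data.frame: `compound_id`, `cell_line`,
#'   `metric_kind`, `dose_nM`, `suppression_percent` (one row per
#'   replicate-dose).
#' @param metric_kind metric to triage on.
#' @param tumor_line,control_line cell-line identifiers.
#' @param delta,min_doses selectivity parameters.
#' @param efficacy_cutoff,safety_cutoff percent cutoffs.
#' @return data.frame, one row per compound ordered by `compound_id`, with
#'   `selectivity_pass`, `efficacy_pass`, `safety_pass`, `overall` and the
#'   per-dose tumor-minus-control difference columns `diff_d1..diff_dk`.
#' @export
triage <- function(profiles, metric_kind, tumor_line, control_line,
                   delta = 40, min_doses = 2,
                   efficacy_cutoff = 50, safety_cutoff = 50) {
  p <- profiles[profiles$metric_kind == metric_kind, , drop = FALSE]
  if (nrow(p) == 0) stop("no profiles for metric kind ", metric_kind)
  agg <- stats::aggregate(suppression_percent ~ compound_id + cell_line +
                            dose_nM, data = p, FUN = stats::median)
  ids <- sort(unique(agg$compound_id))
  rows <- lapply(ids, function(id) {
    tu <- agg[agg$compound_id == id & agg$cell_line == tumor_line, ]
    co <- agg[agg$compound_id == id & agg$cell_line == control_line, ]
    if (nrow(tu) == 0 || nrow(co) == 0) {
      stop("missing tumor or control profile for compound ", id)
    }
    tup <- dose_profile(id, tumor_line, metric_kind, tu$dose_nM,
                        tu$suppression_percent)
    cop <- dose_profile(id, control_line, metric_kind, co$dose_nM,
                        co$suppression_percent)
    sel <- selectivity_filter(tup, cop, delta = delta,
                              min_doses = min_doses)
    eff <- efficacy_filter(tup, cutoff = efficacy_cutoff)
    saf <- safety_filter(cop, cutoff = safety_cutoff)
    diffs <- tup$suppression_percent - cop$suppression_percent
    out <- data.frame(compound_id = id, metric_kind = metric_kind,
                      selectivity_pass = sel, efficacy_pass = eff,
                      safety_pass = saf, overall = sel && eff && saf,
                      stringsAsFactors = FALSE)
    for (j in seq_along(diffs)) out[[paste0("diff_d", j)]] <- diffs[j]
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
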