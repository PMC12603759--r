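# Primary screen: death-fraction kinetics, AUC / final-timepoint metrics,
# normalization, robust Z-scores and hit calling.

#' Pooled dead/dying-cell fraction for one well at one timepoint
#'
#' Counts are summed across imaging fields before the ratio is taken, so a
#' degenerate single field cannot produce an infinite fraction.
#'
#' @param draq7_counts dead-stain object counts, one per field.
#' @param tracker_counts live-stain object counts, one per field.
#' @return pooled fraction `sum(draq7) / sum(tracker)`.
#' @export
well_death_fraction <- function(draq7_counts, tracker_counts) {
  if (length(draq7_counts) != length(tracker_counts) ||
      length(draq7_counts) == 0) {
    stop("need matched, non-empty field counts")
  }
  tt <- sum(tracker_counts)
  if (tt == 0) {
    stop("undefined death fraction: pooled tracker count is 0 [QC]")
  }
  sum(draq7_counts) / tt
}

#' Death-fraction time series for one well
#'
#' @param ds a `screen_dataset`.
#' @param plate_id,well well identity (canonical well label).
#' @param timepoints required schedule in hours; a missing timepoint is an
#'   error (no interpolation).
#' @return list with `plate_id`, `well`, `timepoints`, `fractions`, class
#'   `death_series`.
#' @export
death_series <- function(ds, plate_id, well,
                         timepoints = c(0, 24, 48, 72)) {
  well <- parse_well(well)
  img <- ds$imaging
  rows <- img[img$plate_id == plate_id & img$well == well, , drop = FALSE]
  present <- sort(unique(rows$timepoint_h))
  miss <- setdiff(timepoints, present)
  if (length(miss) > 0) {
    stop("incomplete series for ", plate_id, " ", well,
         ": missing timepoint(s) ", paste(miss, collapse = ", "))
  }
  tp <- sort(timepoints)
  fr <- vapply(tp, function(t) {
    r <- rows[rows$timepoint_h == t, ]
    well_death_fraction(r$draq7_count, r$tracker_count)
  }, numeric(1))
  structure(list(plate_id = plate_id, well = well, timepoints = tp,
                 fractions = fr),
            class = "death_series")
}

#' Trapezoidal area under a death-fraction time course
#'
#' No baseline subtraction by default; set `baseline_subtract = TRUE` to
#' subtract the t = 0 fraction first.
#'
#' @param fractions death fractions, or a `death_series` object.
#' @param timepoints hours, strictly increasing (ignored when a series
#'   object is given).
#' @param baseline_subtract subtract the first fraction before integrating.
#' @return AUC in fraction-hours.
#' @export
auc_trapezoid <- function(fractions, timepoints = NULL,
                          baseline_subtract = FALSE) {
  if (inherits(fractions, "death_series")) {
    timepoints <- fractions$timepoints
    fractions <- fractions$fractions
  }
  if (length(fractions) < 2 || length(fractions) != length(timepoints)) {
    stop("need >= 2 matched (timepoint, fraction) pairs")
  }
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  if (baseline_subtract) fractions <- fractions - fractions[1]
  n <- length(fractions)
  sum(diff(timepoints) * (fractions[-1] + fractions[-n]) / 2)
}

#' Effect relative to vehicle (robust-mean anchored)
#'
#' @param x raw metric value(s).
#' @param vehicle_values raw metric over vehicle wells (>= 2 required).
#' @return `x - median(vehicle_values)`.
#' @export
effect_vs_vehicle <- function(x, vehicle_values) {
  if (length(vehicle_values) < 2) stop("need >= 2 vehicle wells")
  x - stats::median(vehicle_values)
}

#' Control-based normalization to percent effect
#'
#' Anchors the vehicle robust mean (median) at 0% and the positive-control
#' robust mean at 100%.
#'
#' @param x raw metric value(s).
#' @param vehicle_values,positive_values control metric values.
#' @return percent effect.
#' @export
normalize_control_based <- function(x, vehicle_values, positive_values) {
  if (length(vehicle_values) == 0 || length(positive_values) == 0) {
    stop("both control sets must be non-empty")
  }
  mv <- stats::median(vehicle_values)
  mp <- stats::median(positive_values)
  if (mp == mv) stop("zero control window: control robust means are equal")
  100 * (x - mv) / (mp - mv)
}

#' Robust Z-scores over a test population
#'
#' `z = (x - median(x)) / (1.4826 * MAD(x))`. A zero MAD falls back to
#' IQR / 1.349; if that is also zero the population is degenerate and an
#' error is raised.
#'
#' @param x metric values over library compounds (>= 8 required).
#' @return numeric vector of robust Z-scores.
#' @export
robust_zscores <- function(x) {
  if (length(x) < 8) stop("need >= 8 library values for a robust Z-score")
  med <- stats::median(x)
  s <- stats::mad(x, center = med, constant = 1.4826)
  if (s == 0) {
    s <- stats::IQR(x) / 1.349
    if (s == 0) stop("degenerate population: robust spread is zero")
  }
  (x - med) / s
}

#' Call hits by robust Z-score threshold
#'
#' Hits satisfy `robust_z < threshold` (strict); a score exactly at the
#' threshold is not a hit.
#'
#' @param zscores named numeric vector (names = compound ids) or data.frame
#'   with columns `compound_id`, `robust_z`.
#' @param threshold hit threshold (default -3).
#' @param metric_kind label propagated to the output.
#' @return data.frame `compound_id`, `metric_kind`, `robust_z`, `is_hit`,
#'   `threshold`, sorted by ascending z.
#' @export
call_hits <- function(zscores, threshold = -3, metric_kind = NA_character_) {
  if (is.data.frame(zscores)) {
    out <- data.frame(compound_id = zscores$compound_id,
                      robust_z = zscores$robust_z,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(compound_id = if (is.null(names(zscores)))
      as.character(seq_along(zscores)) else names(zscores),
      robust_z = as.numeric(zscores), stringsAsFactors = FALSE)
  }
  out$metric_kind <- metric_kind
  out$is_hit <- out$robust_z < threshold
  out$threshold <- threshold
  out <- out[order(out$robust_z), c("compound_id", "metric_kind",
                                    "robust_z", "is_hit", "threshold")]
  rownames(out) <- NULL
  out
}

#' Per-well screening metrics for a dataset
#'
#' Computes, for every non-empty annotated well, the AUC and final-timepoint
#' death-fraction metrics (and the CTG metric when luminescence is present).
#'
#' @param ds a `screen_dataset`.
#' @param timepoints imaging schedule.
#' @return long data.frame: `plate_id`, `well`, `role`, `compound_id`,
#'   `metric_kind`, `raw_value`.
#' @export
well_metrics <- function(ds, timepoints = c(0, 24, 48, 72)) {
  ann <- ds$annotations
  ann <- ann[ann$role != "empty", , drop = FALSE]
  img <- ds$imaging
  # pool fields, then pivot wells x timepoints for vectorized AUC
  pooled <- stats::aggregate(
    cbind(draq7_count, tracker_count) ~ plate_id + well + timepoint_h,
    data = img, FUN = sum)
  if (any(pooled$tracker_count == 0)) {
    bad <- pooled[pooled$tracker_count == 0, ]
    stop("undefined death fraction (pooled tracker count 0) at: ",
         paste(bad$plate_id, bad$well, bad$timepoint_h, collapse = "; "))
  }
  pooled$fraction <- pooled$draq7_count / pooled$tracker_count
  tp <- sort(timepoints)
  key <- paste(pooled$plate_id, pooled$well, sep = "\r")
  wells <- unique(key)
  fmat <- matrix(NA_real_, nrow = length(wells), ncol = length(tp),
                 dimnames = list(wells, tp))
  fmat[cbind(match(key, wells), match(pooled$timepoint_h, tp))] <-
    pooled$fraction
  if (anyNA(fmat)) {
    miss <- wells[rowSums(is.na(fmat)) > 0]
    stop("incomplete timepoint series for well(s): ",
         paste(gsub("\r", " ", miss), collapse = ", "))
  }
  dt <- diff(tp)
  auc <- as.vector(((fmat[, -ncol(fmat), drop = FALSE] +
                       fmat[, -1, drop = FALSE]) / 2) %*% dt)
  final <- fmat[, ncol(fmat)]
  ids <- do.call(rbind, strsplit(wells, "\r", fixed = TRUE))
  per_well <- data.frame(plate_id = ids[, 1], well = ids[, 2],
                         auc = auc, final_timepoint = final,
                         stringsAsFactors = FALSE)
  per_well <- merge(ann[c("plate_id", "well", "role", "compound_id")],
                    per_well, by = c("plate_id", "well"))
  out <- rbind(
    data.frame(plate_id = per_well$plate_id, well = per_well$well,
               role = per_well$role, compound_id = per_well$compound_id,
               metric_kind = "auc", raw_value = per_well$auc,
               stringsAsFactors = FALSE),
    data.frame(plate_id = per_well$plate_id, well = per_well$well,
               role = per_well$role, compound_id = per_well$compound_id,
               metric_kind = "final_timepoint",
               raw_value = per_well$final_timepoint,
               stringsAsFactors = FALSE))
  if (!is.null(ds$luminescence)) {
    lum <- merge(ds$luminescence, ann[c("plate_id", "well", "role",
                                        "compound_id")],
                 by = c("plate_id", "well"))
    out <- rbind(out, data.frame(
      plate_id = lum$plate_id, well = lum$well, role = lum$role,
      compound_id = lum$compound_id, metric_kind = "ctg",
      raw_value = lum$rlu, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Score a primary screen and call hits
#'
#' Full primary-screen chain: per-well metrics, vehicle-anchored effects,
#' normalization under the chosen scheme, orientation, robust Z-scores per
#' plate population, and threshold hit calls.
#'
#' For death-fraction metrics stronger killing raises the raw value; under
#' the default `"killing_negative"` orientation the effect is negated so
#' that killers land at negative Z and the `Z < threshold` selection applies
#' directly. `"raw"` keeps the natural sign.
#'
#' @param ds a `screen_dataset`.
#' @param metric_kinds metrics to score (`"auc"`, `"final_timepoint"`, and
#'   `"ctg"` when luminescence is present).
#' @param scheme `"test_population"` (effects scaled to vehicle = 0) or
#'   `"control_based"` (vehicle = 0, positive control = 100).
#' @param orientation `"killing_negative"` (default) or `"raw"`.
#' @param scope `"per_plate"` (default) or `"pooled"` Z-score population.
#' @param threshold robust-Z hit threshold, default -3.
#' @param timepoints imaging schedule.
#' @return data.frame with per-compound `raw_value`, `effect`, `robust_z`,
#'   `is_hit` per metric kind.
#' @export
primary_screen_hits <- function(ds,
                                metric_kinds = c("auc", "final_timepoint"),
                                scheme = c("test_population",
                                           "control_based"),
                                orientation = c("killing_negative", "raw"),
                                scope = c("per_plate", "pooled"),
                                threshold = -3,
                                timepoints = c(0, 24, 48, 72)) {
  scheme <- match.arg(scheme)
  orientation <- match.arg(orientation)
  scope <- match.arg(scope)
  wm <- well_metrics(ds, timepoints = timepoints)
  out <- list()
  for (mk in metric_kinds) {
    m <- wm[wm$metric_kind == mk, , drop = FALSE]
    if (nrow(m) == 0) stop("no measurements for metric kind ", mk)
    groups <- if (scope == "per_plate") unique(m$plate_id) else "all"
    for (g in groups) {
      sub <- if (scope == "per_plate") m[m$plate_id == g, ] else m
      veh <- sub$raw_value[sub$role == "vehicle"]
      pos <- sub$raw_value[sub$role == "positive_control"]
      lib <- sub[sub$role == "library", , drop = FALSE]
      eff <- if (scheme == "control_based") {
        normalize_control_based(lib$raw_value, veh, pos)
      } else {
        effect_vs_vehicle(lib$raw_value, veh)
      }
      # CTG rlu falls with killing; imaging death fractions rise with it.
      killing_raises_raw <- mk %in% c("auc", "final_timepoint")
      if (orientation == "killing_negative" && killing_raises_raw) {
        eff <- -eff
      }
      z <- robust_zscores(eff)
      out[[length(out) + 1L]] <- data.frame(
        compound_id = lib$compound_id, plate_id = lib$plate_id,
        well = lib$well, metric_kind = mk, raw_value = lib$raw_value,
        effect = eff, robust_z = z, is_hit = z < threshold,
        threshold = threshold, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$metric_kind, res$robust_z), ]
  rownames(res) <- NULL
  res
}
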