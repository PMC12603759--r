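# Four-parameter logistic (variable slope) dose-response fitting and ICx
# extraction, with a median-effect fit as an independent cross-check.

# log10 molar dose from nM
.log10_molar <- function(dose_nM) log10(dose_nM) - 9

# inhibitor convention: hill > 0 gives viability decreasing with dose
# (equivalent to the log(inhibitor)-vs-response variable-slope model with a
# negative slope factor)
.fourpl <- function(log_dose_M, bottom, top, log_ic50, hill) {
  bottom + (top - bottom) / (1 + 10^((log_dose_M - log_ic50) * hill))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Model: `y(d) = bottom + (top - bottom) / (1 + 10^((log10 d -
#' log_ic50) * hill))` with `d` in molar and `hill > 0` for an inhibitor
#' (viability non-increasing in dose), fitted by bounded
#' Levenberg-Marquardt least squares over all replicate points (no
#' pre-averaging). Multi-start over hill in {0.5, 1, 2}; the best residual
#' sum of squares wins, ties broken by smallest |hill|.
#'
#' @param dose_nM doses in nM, strictly positive, >= 4 distinct values.
#' @param response viability percent (normalized to vehicle), one per point.
#' @param preset `"default"` (top in [50, 150], bottom in [-10, 60]) or
#'   `"constrained_0_100"` (bottom fixed 0, top fixed 100).
#' @param lower,upper optional named bound overrides for
#'   `bottom`, `top`, `log_ic50`, `hill`.
#' @return object of class `fit_4pl` with `bottom`, `top`, `log_ic50`
#'   (log10 molar), `hill`, `rss`, `converged`, `n_points`.
#' @export
fit_4pl <- function(dose_nM, response,
                    preset = c("default", "constrained_0_100"),
                    lower = NULL, upper = NULL) {
  preset <- match.arg(preset)
  if (length(dose_nM) != length(response)) stop("length mismatch")
  if (any(dose_nM <= 0)) stop("doses must be > 0")
  if (length(unique(dose_nM)) < 4) stop("need >= 4 distinct doses")
  if (stats::sd(response) == 0) stop("responses are all equal; nothing to fit")
  ld <- .log10_molar(dose_nM)
  lo <- c(bottom = -10, top = 50, log_ic50 = min(ld) - 3, hill = 0.05)
  hi <- c(bottom = 60, top = 150, log_ic50 = max(ld) + 3, hill = 20)
  if (preset == "constrained_0_100") {
    lo["bottom"] <- hi["bottom"] <- 0
    lo["top"] <- hi["top"] <- 100
  }
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)
  pnames <- c("bottom", "top", "log_ic50", "hill")
  free <- lo < hi
  clamp <- function(v) pmin(pmax(v, lo), hi)
  resid_fn <- function(p) {
    full <- lo
    full[free] <- p
    response - .fourpl(ld, full["bottom"], full["top"], full["log_ic50"],
                       full["hill"])
  }
  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    start <- clamp(c(bottom = min(response), top = max(response),
                     log_ic50 = stats::median(unique(ld)), hill = h0))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start[free], lower = lo[free],
                         upper = hi[free], fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    full <- lo
    full[free] <- fit$par
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 &&
           abs(full["hill"]) < abs(best$hill))) {
      best <- list(bottom = unname(full["bottom"]),
                   top = unname(full["top"]),
                   log_ic50 = unname(full["log_ic50"]),
                   hill = unname(full["hill"]), rss = rss)
    }
  }
  if (is.null(best)) stop("4PL fit failed to converge from all starts")
  structure(c(best, list(converged = TRUE, n_points = length(response))),
            class = "fit_4pl")
}

#' @export
print.fit_4pl <- function(x, ...) {
  cat(sprintf(paste0("4PL fit: bottom=%.3f top=%.3f log10(IC50 [M])=%.4f ",
                     "hill=%.3f rss=%.4g (n=%d)\n"),
              x$bottom, x$top, x$log_ic50, x$hill, x$rss, x$n_points))
  invisible(x)
}

#' Evaluate a fitted 4PL curve
#'
#' @param fit a `fit_4pl`.
#' @param dose_nM dose(s) in nM, > 0.
#' @return predicted viability percent.
#' @export
predict_4pl <- function(fit, dose_nM) {
  if (any(dose_nM <= 0)) stop("dose must be > 0")
  .fourpl(.log10_molar(dose_nM), fit$bottom, fit$top, fit$log_ic50,
          fit$hill)
}

#' Dose achieving a target effect level (ICx / Dx)
#'
#' Absolute mode solves for the dose where the fraction affected
#' `fa(d) = 1 - y(d)/100` equals `level`; relative mode solves
#' `y(d) = top - level * (top - bottom)` (span-relative). Both invert the
#' 4PL in closed form. When the requested level lies beyond the curve's
#' plateaus, `reachable` is FALSE and the dose is NA -- distinct from a fit
#' failure.
#'
#' @param fit a converged `fit_4pl`.
#' @param level effect fraction in (0, 1); e.g. 0.5 for IC50, 0.75, 0.9.
#' @param mode `"absolute"` (default; Chou-Talalay Dx convention) or
#'   `"relative"`.
#' @return list `level`, `dose_nM`, `mode`, `reachable`.
#' @export
icx <- function(fit, level = 0.5, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  if (!isTRUE(fit$converged)) stop("ICx requires a converged fit")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  y_target <- if (mode == "absolute") 100 * (1 - level) else
    fit$top - level * (fit$top - fit$bottom)
  lo <- min(fit$bottom, fit$top)
  hi <- max(fit$bottom, fit$top)
  if (y_target <= lo || y_target >= hi) {
    return(list(level = level, dose_nM = NA_real_, mode = mode,
                reachable = FALSE))
  }
  # invert: 10^((log d - log_ic50) * hill) = (top - y) / (y - bottom)
  r <- (fit$top - y_target) / (y_target - fit$bottom)
  log_d <- fit$log_ic50 + log10(r) / fit$hill
  list(level = level, dose_nM = 10^(log_d + 9), mode = mode,
       reachable = TRUE)
}

#' Median-effect fit (independent Dx cross-check)
#'
#' Linear regression of `log10(fa / (1 - fa))` on `log10(dose)` after
#' excluding saturated points (fa outside (0, 1)); returns the median-effect
#' dose `Dm = 10^(-intercept / slope)` in the input dose units and slope
#' `m`. Provided as an independent oracle for doses derived from the 4PL
#' fit.
#'
#' @param dose_nM doses in nM.
#' @param response viability percent.
#' @return list `Dm_nM`, `m`, `n_used`, `n_excluded`.
#' @export
fit_median_effect <- function(dose_nM, response) {
  fa <- 1 - response / 100
  keep <- fa > 0 & fa < 1 & dose_nM > 0
  n_excluded <- sum(!keep)
  if (sum(keep) < 3) stop("need >= 3 points with fa strictly in (0, 1)")
  x <- log10(dose_nM[keep])
  y <- log10(fa[keep] / (1 - fa[keep]))
  co <- stats::coef(stats::lm(y ~ x))
  m <- unname(co[2])
  Dm <- 10^(-unname(co[1]) / m)
  list(Dm_nM = Dm, m = m, n_used = sum(keep), n_excluded = n_excluded)
}
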