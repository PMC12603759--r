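# Drug-combination interaction: Chou-Talalay combination index, Loewe
# additivity and highest-single-agent expected-effect surfaces.
#
# All synergy computations operate on the fraction-affected scale expressed
# in percent: fa = 100 - viability%.

#' Chou-Talalay combination index
#'
#' `CI = D1/Dx1 + D2/Dx2`, where D1/D2 are the combination doses achieving
#' an effect and Dx1/Dx2 the single-agent doses achieving the same effect.
#'
#' @param D1,D2 combination doses (>= 0).
#' @param Dx1,Dx2 single-agent equi-effective doses (> 0).
#' @return combination index.
#' @export
ci_value <- function(D1, Dx1, D2, Dx2) {
  if (any(Dx1 <= 0) || any(Dx2 <= 0)) stop("Dx doses must be > 0")
  if (any(D1 < 0) || any(D2 < 0)) stop("combination doses must be >= 0")
  D1 / Dx1 + D2 / Dx2
}

.CI_BANDS <- data.frame(
  band = c("strong_synergism", "synergism", "moderate_slight_synergism",
           "nearly_additive", "slight_moderate_antagonism",
           "strong_antagonism"),
  stringsAsFactors = FALSE)

#' Classify a combination index into interaction bands
#'
#' Bands: strong synergism CI < 0.3; synergism 0.3-0.7; moderate to slight
#' synergism 0.7-0.9; nearly additive 0.9-1.1; slight to moderate
#' antagonism 1.1-1.45; strong antagonism CI > 1.45. Boundary closure is
#' fixed as left-closed at 0.3, 0.7 and 0.9 and right-closed at 1.1 and
#' 1.45, so every non-negative CI maps to exactly one band.
#'
#' @param ci combination index value(s), >= 0.
#' @return character vector of band labels.
#' @export
classify_ci <- function(ci) {
  if (any(ci < 0)) stop("CI must be non-negative")
  out <- character(length(ci))
  out[ci < 0.3] <- "strong_synergism"
  out[ci >= 0.3 & ci < 0.7] <- "synergism"
  out[ci >= 0.7 & ci < 0.9] <- "moderate_slight_synergism"
  out[ci >= 0.9 & ci <= 1.1] <- "nearly_additive"
  out[ci > 1.1 & ci <= 1.45] <- "slight_moderate_antagonism"
  out[ci > 1.45] <- "strong_antagonism"
  out
}

# fraction affected (percent) of a fitted single agent at dose d (nM);
# d = 0 returns the zero-dose limit 100 - top.
.fa_percent <- function(fit, dose_nM) {
  ifelse(dose_nM <= 0, 100 - fit$top, 100 - predict_4pl(fit, pmax(dose_nM, .Machine$double.xmin)))
}

# dose (nM) at which agent reaches fraction-affected E percent (closed-form
# 4PL inversion); 0 when the effect is at/below the zero-dose level, Inf
# when the plateau prevents reaching E.
.dose_for_fa <- function(fit, E) {
  y <- 100 - E
  lo <- min(fit$bottom, fit$top)
  hi <- max(fit$bottom, fit$top)
  if (y >= hi) return(0)
  if (y <= lo) return(Inf)
  r <- (fit$top - y) / (y - fit$bottom)
  10^(fit$log_ic50 + log10(r) / fit$hill + 9)
}

#' Combination index along a fixed-ratio design
#'
#' Fits a 4PL to the combination's viability along the drug-1 dose axis,
#' then for each effect level x takes D1 from the combination fit's ICx,
#' D2 = ratio * D1, and Dx1/Dx2 from the single-agent fits, giving
#' `CI = D1/Dx1 + D2/Dx2` with its interaction band. An unreachable ICx at
#' some level yields an NA row for that level, not a global failure.
#'
#' @param dose1_nM combination's drug-1 doses (nM).
#' @param response combination viability percent at those doses.
#' @param ratio constant d2/d1 dose ratio of the design.
#' @param fit1,fit2 converged single-agent `fit_4pl`s (drug 1, drug 2).
#' @param levels effect levels (fractions affected), default 0.5/0.75/0.9.
#' @param preset passed to [fit_4pl()] for the combination fit.
#' @return data.frame: `effect_level`, `D1`, `D2`, `Dx1`, `Dx2`, `ci`,
#'   `band`, `reachable`.
#' @export
combination_ci <- function(dose1_nM, response, ratio, fit1, fit2,
                           levels = c(0.5, 0.75, 0.9),
                           preset = "default") {
  if (!isTRUE(fit1$converged) || !isTRUE(fit2$converged)) {
    stop("single-agent fits must be converged")
  }
  if (ratio < 0) stop("ratio must be >= 0")
  combo_fit <- fit_4pl(dose1_nM, response, preset = preset)
  rows <- lapply(levels, function(x) {
    d1 <- icx(combo_fit, level = x, mode = "absolute")
    dx1 <- icx(fit1, level = x, mode = "absolute")
    dx2 <- icx(fit2, level = x, mode = "absolute")
    if (ratio == 0) {
      # drug 2 absent: CI degenerates to D1/Dx1
      if (d1$reachable && dx1$reachable) {
        ci <- d1$dose_nM / dx1$dose_nM
        return(data.frame(effect_level = x, D1 = d1$dose_nM, D2 = 0,
                          Dx1 = dx1$dose_nM, Dx2 = NA_real_, ci = ci,
                          band = classify_ci(ci), reachable = TRUE,
                          stringsAsFactors = FALSE))
      }
    } else if (d1$reachable && dx1$reachable && dx2$reachable) {
      D1 <- d1$dose_nM
      D2 <- ratio * D1
      ci <- ci_value(D1, dx1$dose_nM, D2, dx2$dose_nM)
      return(data.frame(effect_level = x, D1 = D1, D2 = D2,
                        Dx1 = dx1$dose_nM, Dx2 = dx2$dose_nM, ci = ci,
                        band = classify_ci(ci), reachable = TRUE,
                        stringsAsFactors = FALSE))
    }
    data.frame(effect_level = x, D1 = NA_real_, D2 = NA_real_,
               Dx1 = NA_real_, Dx2 = NA_real_, ci = NA_real_,
               band = NA_character_, reachable = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Loewe-additivity expected effect of a dose pair
#'
#' Solves `d1 / D1(E) + d2 / D2(E) = 1` for the effect E (fraction affected,
#' percent), where `Di(E)` inverts agent i's fitted curve. Solved by
#' bracketed bisection over the jointly attainable effect range (tolerance
#' 1e-8 in effect). When one agent's plateau prevents reaching E its dose
#' requirement is infinite and its reciprocal term is 0. If even the
#' attainable maximum leaves the dose sum above 1, the expected effect is
#' capped at that maximum and flagged via the `"capped"` attribute.
#'
#' @param d1,d2 doses in nM (>= 0).
#' @param fit1,fit2 converged monotone `fit_4pl`s.
#' @return expected effect (fraction affected, percent).
#' @export
loewe_expected <- function(d1, d2, fit1, fit2) {
  if (!isTRUE(fit1$converged) || !isTRUE(fit2$converged)) {
    stop("fits must be converged")
  }
  if (d1 < 0 || d2 < 0) stop("doses must be >= 0")
  if (d1 == 0 && d2 == 0) return(0)
  if (d2 == 0) return(.fa_percent(fit1, d1))
  if (d1 == 0) return(.fa_percent(fit2, d2))
  # attainable fraction-affected caps (percent) at infinite dose
  cap1 <- 100 - fit1$bottom
  cap2 <- 100 - fit2$bottom
  cap <- max(cap1, cap2)
  g <- function(E) {
    t1 <- d1 / .dose_for_fa(fit1, E)   # 0 when unreachable (Inf dose)
    t2 <- d2 / .dose_for_fa(fit2, E)
    t1 + t2 - 1
  }
  lo <- 1e-9
  hi <- cap - 1e-9
  if (hi <= lo) return(0)
  if (g(hi) > 0) {
    return(structure(hi, capped = TRUE))
  }
  if (g(lo) < 0) return(0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-8) break
  }
  (lo + hi) / 2
}

#' Highest-single-agent expected effect of a dose pair
#'
#' `max(effect1(d1), effect2(d2))` on the fraction-affected percent scale.
#'
#' @param d1,d2 doses in nM (>= 0).
#' @param fit1,fit2 converged `fit_4pl`s.
#' @return expected effect percent.
#' @export
hsa_expected <- function(d1, d2, fit1, fit2) {
  if (!isTRUE(fit1$converged) || !isTRUE(fit2$converged)) {
    stop("fits must be converged")
  }
  if (d1 < 0 || d2 < 0) stop("doses must be >= 0")
  max(if (d1 == 0) 0 else .fa_percent(fit1, d1),
      if (d2 == 0) 0 else .fa_percent(fit2, d2))
}

#' Observed-vs-expected synergy surface over a dose matrix
#'
#' Computes the model-expected effect for every (d1, d2) cell, the per-cell
#' delta (observed minus expected), and summary statistics: mean delta and
#' the peak delta with its cell coordinates.
#'
#' @param observed matrix of observed effects (fraction affected, percent);
#'   rows indexed by `doses1`, columns by `doses2`.
#' @param doses1,doses2 dose grids in nM (may include 0).
#' @param fit1,fit2 converged single-agent `fit_4pl`s.
#' @param model `"loewe"` or `"hsa"`.
#' @return object of class `synergy_matrix`: list with `observed`,
#'   `expected`, `delta`, `model`, `doses1`, `doses2`, `summary`.
#' @export
synergy_matrix <- function(observed, doses1, doses2, fit1, fit2,
                           model = c("loewe", "hsa")) {
  model <- match.arg(model)
  observed <- as.matrix(observed)
  if (nrow(observed) != length(doses1) || ncol(observed) != length(doses2)) {
    stop("observed matrix dimensions must match the dose grids")
  }
  expected <- matrix(NA_real_, nrow(observed), ncol(observed))
  for (i in seq_along(doses1)) {
    for (j in seq_along(doses2)) {
      expected[i, j] <- if (model == "loewe") {
        as.numeric(loewe_expected(doses1[i], doses2[j], fit1, fit2))
      } else {
        hsa_expected(doses1[i], doses2[j], fit1, fit2)
      }
    }
  }
  delta <- observed - expected
  peak <- which(delta == max(delta), arr.ind = TRUE)[1, ]
  structure(list(
    observed = observed, expected = expected, delta = delta,
    model = model, doses1 = doses1, doses2 = doses2,
    summary = list(mean_delta = mean(delta),
                   peak_delta = max(delta),
                   peak_cell = c(row = unname(peak["row"]),
                                 col = unname(peak["col"])))),
    class = "synergy_matrix")
}

#' @export
print.synergy_matrix <- function(x, ...) {
  cat(sprintf(
    "synergy_matrix (%s): %dx%d grid, mean delta %.3f, peak %.3f at (%d, %d)\n",
    x$model, nrow(x$observed), ncol(x$observed),
    x$summary$mean_delta, x$summary$peak_delta,
    x$summary$peak_cell["row"], x$summary$peak_cell["col"]))
  invisible(x)
}
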