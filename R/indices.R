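# Glucose/insulin-derived indices from the five-point OGTT.
#
# Unit conventions (fixed, recorded in every panel's units_note):
#   * HOMA-IR uses fasting glucose in mmol/L:  fG * fI / 22.5
#   * Matsuda, disposition index, HIRI and MISI use glucose in mg/dL
#     (conversion factor exactly 18.0) and insulin in mU/L.
# Consequence: HIRI = HOMA-IR * 22.5 * 18.0 = HOMA-IR * 405 exactly, since
# both are built from the same fasting sample.

MGDL_PER_MMOL <- 18.0
HOMA_DENOM <- 22.5
UNITS_NOTE <- paste(
  "glucose mmol/L (HOMA-IR) or mg/dL via factor 18.0 (Matsuda, DI, HIRI, MISI);",
  "insulin mU/L; times min")

#' Convert plasma glucose from mmol/L to mg/dL
#'
#' Uses the fixed conversion factor 18.0 mg/dL per mmol/L.
#'
#' @param g Glucose concentration(s) in mmol/L; all positive.
#' @return `g * 18.0`, in mg/dL.
#' @examples
#' glucose_to_mgdl(5)     # 90
#' glucose_to_mgdl(11.98) # 215.64
#' @export
glucose_to_mgdl <- function(g) {
  g <- as.numeric(g)
  if (length(g) == 0L || anyNA(g) || any(g <= 0))
    stop("glucose must be positive (mmol/L)")
  g * MGDL_PER_MMOL
}

#' Trapezoidal area under a sampled concentration curve
#'
#' Area under the straight-line interpolation of `values` against `times`,
#' restricted to a window whose endpoints must be sampling times (no
#' extrapolation and no interpolation of window endpoints).
#'
#' @param times Sampling times (minutes), strictly increasing.
#' @param values Concentrations at each time.
#' @param window Length-2 numeric `c(t_lo, t_hi)` with `t_lo <= t_hi`; both
#'   must be sampling times. A degenerate window (`t_lo == t_hi`) has area 0.
#' @return The trapezoidal area (concentration x minutes).
#' @examples
#' trapezoid_auc(c(0, 30), c(10, 20), c(0, 30)) # 450
#' @export
trapezoid_auc <- function(times, values, window) {
  times <- as.numeric(times); values <- as.numeric(values)
  stopifnot(length(times) == length(values), length(times) >= 1L,
            !anyNA(times), !anyNA(values), length(window) == 2L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(window %in% times))
    stop("window endpoints must be sampling times; no extrapolation is performed")
  if (window[1L] > window[2L]) stop("window must satisfy t_lo <= t_hi")
  keep <- times >= window[1L] & times <= window[2L]
  t <- times[keep]; v <- values[keep]
  if (length(t) < 2L) return(0)
  sum(diff(t) * (v[-length(v)] + v[-1L]) / 2)
}

#' HOMA-IR fasting insulin-resistance index
#'
#' `fG * fI / 22.5` with fasting glucose in mmol/L and fasting insulin in
#' mU/L (dimensionless by convention).
#'
#' @param fg Fasting plasma glucose, mmol/L (> 0).
#' @param fi Fasting plasma insulin, mU/L (> 0).
#' @return HOMA-IR.
#' @examples
#' homa_ir(4.5, 5) # 1
#' @export
homa_ir <- function(fg, fi) {
  fg <- as.numeric(fg); fi <- as.numeric(fi)
  if (anyNA(fg) || anyNA(fi) || any(fg <= 0) || any(fi <= 0))
    stop("fasting glucose and insulin must be positive")
  fg * fi / HOMA_DENOM
}

#' Hepatic insulin resistance index (HIRI)
#'
#' The fasting glucose-insulin product `fG * fI`, with glucose expressed in
#' mg/dL: `glucose_to_mgdl(fg) * fi`. Identically `homa_ir(fg, fi) * 405`
#' (405 = 22.5 x 18.0), since the two indices share the fasting sample and
#' differ only in the glucose unit and normalization.
#'
#' @inheritParams homa_ir
#' @return HIRI, in (mg/dL) x (mU/L).
#' @examples
#' hiri(1 / 18, 1) # 1
#' @export
hiri <- function(fg, fi) {
  glucose_to_mgdl(fg) * as.numeric(fi)
}

#' Matsuda whole-body insulin sensitivity index
#'
#' `10000 / sqrt(fG' * fI * mG' * mI)` where primed glucose quantities are in
#' mg/dL, `fG'`/`fI` are the fasting values and `mG'`/`mI` the arithmetic
#' means over all five OGTT samples. Requires the full five-point curve.
#'
#' @param curve A full [ogtt_curve()].
#' @return The (dimensionless) Matsuda index; higher is more insulin
#'   sensitive.
#' @export
matsuda <- function(curve) {
  assert_full_curve(curve)
  gp <- glucose_to_mgdl(curve$glucose)
  10000 / sqrt(gp[1L] * curve$insulin[1L] * mean(gp) * mean(curve$insulin))
}

#' Disposition index (beta-cell function scaled by insulin sensitivity)
#'
#' The early (0-30 min) insulin-to-glucose trapezoidal AUC ratio, with
#' glucose in mg/dL, multiplied by the Matsuda index. Low values indicate
#' impaired beta-cell function.
#'
#' @param curve A full [ogtt_curve()].
#' @return The (dimensionless) disposition index.
#' @export
disposition_index <- function(curve) {
  assert_full_curve(curve)
  auc_i <- trapezoid_auc(curve$times, curve$insulin, c(0, 30))
  auc_g <- trapezoid_auc(curve$times, glucose_to_mgdl(curve$glucose), c(0, 30))
  (auc_i / auc_g) * matsuda(curve)
}

#' Muscle insulin sensitivity index (MISI)
#'
#' The OGTT glucose slope normalized by mean insulin, `(dG/dt) / mI`, with
#' glucose in mg/dL and `mI` the mean insulin over all five samples. The
#' slope endpoints are not fixed by the defining ratio, so two documented
#' conventions are provided:
#'
#' * `"span_slope"` (default): `100 * (G'_min - G'_max) / dt / mI` where
#'   `G'_max`/`G'_min` are the curve maximum/minimum and `dt` the positive
#'   duration between their times. Always <= 0; large negative values mean a
#'   steep glucose span relative to the circulating insulin, i.e. worse
#'   muscle insulin sensitivity.
#' * `"peak_decay"`: classic decay-rate variant, `100 * (G'_peak - G'_nadir)
#'   / (t_nadir - t_peak) / mI` using the minimum *after* the peak; positive
#'   when glucose falls from its peak, 0 (with a warning) when the peak is
#'   the last sample.
#'
#' A flat curve returns 0 with a warning under either convention.
#'
#' @param curve A full [ogtt_curve()].
#' @param convention `"span_slope"` or `"peak_decay"`.
#' @return Signed MISI value (per-minute glucose change in mg/dL per mU/L of
#'   mean insulin, scaled by 100).
#' @export
misi <- function(curve, convention = c("span_slope", "peak_decay")) {
  assert_full_curve(curve)
  convention <- match.arg(convention)
  gp <- glucose_to_mgdl(curve$glucose)
  mi <- mean(curve$insulin)
  if (max(gp) == min(gp)) {
    warning("flat glucose curve: MISI undefined, returning 0")
    return(0)
  }
  if (convention == "span_slope") {
    i_max <- which.max(gp); i_min <- which.min(gp)
    dt <- abs(curve$times[i_min] - curve$times[i_max])
    100 * (gp[i_min] - gp[i_max]) / dt / mi
  } else {
    i_max <- which.max(gp)
    if (i_max == length(gp)) {
      warning("glucose peaks at the last sample: no decay phase, returning 0")
      return(0)
    }
    tail_idx <- i_max:length(gp)
    i_min <- tail_idx[which.min(gp[tail_idx])]
    100 * (gp[i_max] - gp[i_min]) / (curve$times[i_min] - curve$times[i_max]) / mi
  }
}

#' Compute the full index panel for one OGTT curve
#'
#' Evaluates all five indices (Matsuda, disposition index, HIRI, MISI,
#' HOMA-IR) on a full five-point curve under the package's fixed unit
#' conventions.
#'
#' @param curve A full [ogtt_curve()].
#' @param convention MISI convention, see [misi()].
#' @return An object of class `"index_panel"`: a list with elements
#'   `participant_id`, `visit`, `matsuda`, `disposition`, `hiri`, `misi`,
#'   `homa_ir`, `misi_convention` and `units_note`.
#' @export
compute_panel <- function(curve, convention = c("span_slope", "peak_decay")) {
  assert_full_curve(curve)
  convention <- match.arg(convention)
  fg <- curve$glucose[1L]; fi <- curve$insulin[1L]
  structure(
    list(participant_id = curve$participant_id, visit = curve$visit,
         matsuda = matsuda(curve),
         disposition = disposition_index(curve),
         hiri = hiri(fg, fi),
         misi = misi(curve, convention),
         homa_ir = homa_ir(fg, fi),
         misi_convention = convention,
         units_note = UNITS_NOTE),
    class = "index_panel")
}

#' @export
print.index_panel <- function(x, digits = 4, ...) {
  cat(sprintf("Index panel: participant %s, %s (MISI convention: %s)\n",
              x$participant_id, x$visit, x$misi_convention))
  vals <- c(Matsuda = x$matsuda, `Disposition index` = x$disposition,
            HIRI = x$hiri, MISI = x$misi, `HOMA-IR` = x$homa_ir)
  print(signif(vals, digits))
  cat("Units:", x$units_note, "\n")
  invisible(x)
}

#' Compute index panels for a list of OGTT curves
#'
#' Vectorized front end to [compute_panel()]. Partial curves (missing some
#' post-load samples) contribute only the fasting-sample indices (HOMA-IR,
#' HIRI); their Matsuda, disposition and MISI entries are `NA`.
#'
#' @param curves A list of [ogtt_curve()] objects (as returned by
#'   [read_ogtt_csv()] or [generate_cohort()]).
#' @inheritParams compute_panel
#' @return A data frame with one row per curve: `participant_id`, `visit`,
#'   `matsuda`, `disposition`, `hiri`, `misi`, `homa_ir`, `full_panel`.
#' @export
compute_indices <- function(curves, convention = c("span_slope", "peak_decay")) {
  convention <- match.arg(convention)
  stopifnot(length(curves) >= 1L)
  rows <- lapply(curves, function(cv) {
    if (!inherits(cv, "ogtt_curve")) stop("curves must be 'ogtt_curve' objects")
    fg <- cv$glucose[1L]; fi <- cv$insulin[1L]
    if (cv$full_panel) {
      p <- compute_panel(cv, convention)
      data.frame(participant_id = cv$participant_id, visit = cv$visit,
                 matsuda = p$matsuda, disposition = p$disposition,
                 hiri = p$hiri, misi = p$misi, homa_ir = p$homa_ir,
                 full_panel = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(participant_id = cv$participant_id, visit = cv$visit,
                 matsuda = NA_real_, disposition = NA_real_,
                 hiri = hiri(fg, fi), misi = NA_real_,
                 homa_ir = homa_ir(fg, fi),
                 full_panel = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "units_note") <- UNITS_NOTE
  attr(out, "misi_convention") <- convention
  out
}
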