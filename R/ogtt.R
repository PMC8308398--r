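#' @keywords internal
"_PACKAGE"

# Canonical five-point OGTT sampling grid (minutes after the glucose drink)
# and the three study visits. These are fixed by the sampling protocol the
# index formulas assume; they are not configurable.
CANONICAL_TIMES <- c(0, 30, 60, 90, 120)
VISIT_LEVELS <- c("baseline", "month3", "month6")
SUBTYPE_LEVELS <- c("healthy", "HIR", "MIR", "CIR", "IB", "IB-HIR", "IB-MIR", "IB-CIR")
STATUS_LEVELS <- c("T2D", "reversal", "remission")
DRUG_CLASSES <- c("metformin", "SU_derivative", "insulin", "GLP1_agonist",
                  "other_glucose_lowering")

#' Construct a single participant-visit OGTT curve
#'
#' Bundles one participant-visit's timed plasma glucose and insulin samples.
#' A *full* curve samples exactly the canonical grid t = 0, 30, 60, 90,
#' 120 min and supports the whole index panel; a *partial* curve (a subset of
#' the canonical grid that includes the fasting sample) is accepted but only
#' supports the fasting-sample indices (HOMA-IR, HIRI).
#'
#' @param participant_id Opaque participant identifier (coerced to character).
#' @param visit One of `"baseline"`, `"month3"`, `"month6"`.
#' @param times Sampling times in minutes; strictly increasing, starting at 0,
#'   and a subset of the canonical grid \{0, 30, 60, 90, 120\}.
#' @param glucose Plasma glucose in mmol/L at each time; all positive.
#' @param insulin Plasma insulin in mU/L at each time; all positive.
#'
#' @return An object of class `"ogtt_curve"`: a list with the validated
#'   fields plus `full_panel`, `TRUE` when all five canonical times are
#'   present.
#' @examples
#' ogtt_curve("P1", "baseline",
#'            times = c(0, 30, 60, 90, 120),
#'            glucose = c(12.0, 15.1, 18.2, 20.0, 21.4),
#'            insulin = c(23.9, 31.0, 38.5, 45.2, 51.0))
#' @export
ogtt_curve <- function(participant_id, visit, times, glucose, insulin) {
  participant_id <- as.character(participant_id)
  stopifnot(length(participant_id) == 1L, nzchar(participant_id))
  visit <- match.arg(as.character(visit), VISIT_LEVELS)
  times <- as.numeric(times)
  glucose <- as.numeric(glucose)
  insulin <- as.numeric(insulin)
  n <- length(times)
  if (n < 1L) stop("an OGTT curve needs at least the fasting (t = 0) sample")
  if (length(glucose) != n || length(insulin) != n)
    stop("glucose and insulin must have one value per sampling time")
  if (anyNA(times) || anyNA(glucose) || anyNA(insulin))
    stop("missing values are not allowed in an OGTT curve")
  if (any(diff(times) <= 0))
    stop("sampling times must be strictly increasing")
  if (times[1L] != 0)
    stop("the first sampling time must be the fasting sample at t = 0 min")
  if (!all(times %in% CANONICAL_TIMES))
    stop("sampling times must lie on the canonical grid {",
         paste(CANONICAL_TIMES, collapse = ", "), "} min")
  if (any(glucose <= 0) || any(insulin <= 0))
    stop("glucose and insulin concentrations must be positive")
  structure(
    list(participant_id = participant_id, visit = visit,
         times = times, glucose = glucose, insulin = insulin,
         full_panel = length(times) == 5L),
    class = "ogtt_curve")
}

#' @export
print.ogtt_curve <- function(x, ...) {
  cat(sprintf("OGTT curve: participant %s, %s (%s)\n",
              x$participant_id, x$visit,
              if (x$full_panel) "full five-point panel" else "partial curve"))
  print(data.frame(time_min = x$times,
                   glucose_mmol_l = x$glucose,
                   insulin_mu_l = x$insulin), row.names = FALSE)
  invisible(x)
}

is_full_curve <- function(curve) {
  inherits(curve, "ogtt_curve") && isTRUE(curve$full_panel)
}

assert_full_curve <- function(curve) {
  if (!inherits(curve, "ogtt_curve")) stop("not an 'ogtt_curve' object")
  if (!curve$full_panel)
    stop("this index needs the full five-point curve (t = 0, 30, 60, 90, 120 min); ",
         "participant ", curve$participant_id, ", ", curve$visit,
         " has only t = {", paste(curve$times, collapse = ", "), "}")
  invisible(curve)
}
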