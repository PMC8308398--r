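# Eight-subtype classification ("diabetyping") from index cutoffs, and
# Youden-J calibration of those cutoffs on a labeled reference cohort.
#
# Impairment directions are fixed: HIRI above its cutoff flags hepatic
# insulin resistance; MISI below its cutoff flags muscle insulin resistance;
# disposition index below its cutoff flags impaired beta-cell function.
# Boundary equality always resolves to the healthy side, so "healthy" is the
# closed cell of the partition.

#' Cutoff configuration for subtype classification
#'
#' @param hiri HIRI cutoff; values strictly above flag hepatic insulin
#'   resistance.
#' @param misi MISI cutoff; values strictly below flag muscle insulin
#'   resistance.
#' @param disposition Disposition-index cutoff; values strictly below flag
#'   impaired beta-cell function.
#' @param provenance Free-text note recording which cohort or procedure
#'   produced these cutoffs.
#' @return An object of class `"cutoff_config"`.
#' @seealso [diabetype()] to calibrate cutoffs from a reference cohort;
#'   [read_cutoffs_json()] / [write_cutoffs_json()] for file round-trips.
#' @export
cutoff_config <- function(hiri, misi, disposition, provenance = "user-supplied") {
  vals <- c(hiri = hiri, misi = misi, disposition = disposition)
  if (!is.numeric(vals) || length(vals) != 3L || !all(is.finite(vals)))
    stop("all three cutoffs must be finite numbers")
  structure(list(hiri = as.numeric(hiri), misi = as.numeric(misi),
                 disposition = as.numeric(disposition),
                 provenance = as.character(provenance)[1L]),
            class = "cutoff_config")
}

#' @export
print.cutoff_config <- function(x, ...) {
  cat("Subtype cutoffs:\n")
  cat(sprintf("  HIRI              > %g  => hepatic insulin resistance\n", x$hiri))
  cat(sprintf("  MISI              < %g  => muscle insulin resistance\n", x$misi))
  cat(sprintf("  Disposition index < %g  => impaired beta-cell function\n", x$disposition))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Subtype label from the three impairment flags
#'
#' Pure function of the flags: the insulin-resistance stem is `HIR`
#' (hepatic only), `MIR` (muscle only), `CIR` (combined, both) or empty, and
#' impaired beta-cell function prepends `IB`; no flags at all is `healthy`.
#' Exactly eight labels are reachable.
#'
#' @param hepatic_ir,muscle_ir,impaired_bcf Logical vectors (recycled to a
#'   common length).
#' @return A factor with levels `healthy, HIR, MIR, CIR, IB, IB-HIR, IB-MIR,
#'   IB-CIR`.
#' @examples
#' subtype_label(TRUE, FALSE, TRUE) # IB-HIR
#' @export
subtype_label <- function(hepatic_ir, muscle_ir, impaired_bcf) {
  n <- max(length(hepatic_ir), length(muscle_ir), length(impaired_bcf))
  h <- rep_len(as.logical(hepatic_ir), n)
  m <- rep_len(as.logical(muscle_ir), n)
  b <- rep_len(as.logical(impaired_bcf), n)
  if (anyNA(h) || anyNA(m) || anyNA(b)) stop("flags must be TRUE/FALSE")
  stem <- ifelse(h & m, "CIR", ifelse(h, "HIR", ifelse(m, "MIR", "")))
  lab <- ifelse(b, ifelse(stem == "", "IB", paste0("IB-", stem)),
                ifelse(stem == "", "healthy", stem))
  factor(lab, levels = SUBTYPE_LEVELS)
}

#' Classify index panels into the eight pathophysiological subtypes
#'
#' Applies the strict cutoff comparisons (`hiri > cutoff`, `misi < cutoff`,
#' `disposition < cutoff`; equality is never an impairment) and derives the
#' subtype label from the resulting flags. HOMA-IR and the Matsuda index are
#' carried in panels but do not enter the decision.
#'
#' @param panel An `"index_panel"` object, or a data frame with numeric
#'   columns `hiri`, `misi`, `disposition` (e.g. from [compute_indices()]).
#' @param cutoffs A [cutoff_config()] (or a fitted [diabetype()] object,
#'   whose cutoffs are used).
#' @return For a single panel, a list of class `"subtype_call"` with the
#'   three flags and the `label`; for a data frame, a data frame with
#'   `participant_id`/`visit` (when present), the flags and `label` (rows
#'   with any missing index get an `NA` label).
#' @examples
#' cfg <- cutoff_config(hiri = 1500, misi = -4, disposition = 1)
#' classify_subtype(data.frame(hiri = 4779, misi = -2.1, disposition = 0.15), cfg)
#' @export
classify_subtype <- function(panel, cutoffs) {
  if (inherits(cutoffs, "diabetype")) cutoffs <- cutoffs$cutoffs
  if (!inherits(cutoffs, "cutoff_config")) stop("cutoffs must be a 'cutoff_config'")
  if (inherits(panel, "index_panel")) {
    h <- panel$hiri > cutoffs$hiri
    m <- panel$misi < cutoffs$misi
    b <- panel$disposition < cutoffs$disposition
    return(structure(list(participant_id = panel$participant_id,
                          visit = panel$visit,
                          hepatic_ir = h, muscle_ir = m, impaired_bcf = b,
                          label = subtype_label(h, m, b)),
                     class = "subtype_call"))
  }
  if (!is.data.frame(panel) ||
      !all(c("hiri", "misi", "disposition") %in% names(panel)))
    stop("panel must be an 'index_panel' or a data frame with columns hiri, misi, disposition")
  h <- panel$hiri > cutoffs$hiri
  m <- panel$misi < cutoffs$misi
  b <- panel$disposition < cutoffs$disposition
  ok <- !(is.na(h) | is.na(m) | is.na(b))
  lab <- factor(rep(NA_character_, nrow(panel)), levels = SUBTYPE_LEVELS)
  if (any(ok)) lab[ok] <- subtype_label(h[ok], m[ok], b[ok])
  out <- data.frame(hepatic_ir = h, muscle_ir = m, impaired_bcf = b,
                    stringsAsFactors = FALSE)
  out$label <- lab
  keep <- intersect(c("participant_id", "visit"), names(panel))
  if (length(keep)) out <- cbind(panel[keep], out)
  out
}

#' @export
print.subtype_call <- function(x, ...) {
  cat(sprintf("Subtype call: participant %s, %s -> %s\n",
              x$participant_id, x$visit, as.character(x$label)))
  cat(sprintf("  hepatic IR: %s | muscle IR: %s | impaired BCF: %s\n",
              x$hepatic_ir, x$muscle_ir, x$impaired_bcf))
  invisible(x)
}

# Youden-J optimal threshold for a single index.
# direction "greater": diseased predicted when x > c; "less": when x < c.
# Candidates are midpoints between consecutive sorted unique values; ties in
# J resolve to the midpoint of the tied candidates. Returns list(cutoff, j,
# sensitivity, specificity, degenerate).
youden_cutoff <- function(x, diseased, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  ok <- is.finite(x) & !is.na(diseased)
  x <- x[ok]; d <- as.logical(diseased)[ok]
  if (!any(d) || all(d)) stop("both classes must be present to calibrate a cutoff")
  ux <- sort(unique(x))
  if (length(ux) < 2L) {
    warning("index is constant across the reference cohort; cutoff set to the pooled median")
    return(list(cutoff = stats::median(x), j = 0, sensitivity = NA_real_,
                specificity = NA_real_, degenerate = TRUE))
  }
  cand <- (ux[-length(ux)] + ux[-1L]) / 2
  sens <- vapply(cand, function(cc) {
    if (direction == "greater") mean(x[d] > cc) else mean(x[d] < cc)
  }, numeric(1))
  spec <- vapply(cand, function(cc) {
    if (direction == "greater") mean(x[!d] <= cc) else mean(x[!d] >= cc)
  }, numeric(1))
  j <- sens + spec - 1
  jmax <- max(j)
  if (jmax <= 0) {
    warning("index does not separate the classes (best Youden J <= 0); ",
            "cutoff set to the pooled median")
    return(list(cutoff = stats::median(x), j = jmax, sensitivity = NA_real_,
                specificity = NA_real_, degenerate = TRUE))
  }
  tied <- cand[j == jmax]
  cutoff <- (min(tied) + max(tied)) / 2
  if (jmax < 0.2)
    warning(sprintf("weak class separation (Youden J = %.3f)", jmax))
  best <- which(j == jmax)[1L]
  list(cutoff = cutoff, j = jmax, sensitivity = sens[best],
       specificity = spec[best], degenerate = FALSE)
}

#' Calibrate subtype cutoffs on a labeled reference cohort
#'
#' Fits one threshold per classifying index (HIRI, MISI, disposition index)
#' by maximizing Youden's J (sensitivity + specificity - 1) for separating
#' T2D from healthy reference panels, in the fixed impairment direction of
#' each index. Candidate thresholds are the midpoints between consecutive
#' sorted unique index values; ties in J resolve to the midpoint of the tied
#' candidates, so perfectly separated classes yield the midpoint of the
#' separating gap. An index that fails to separate the classes (best J <= 0,
#' e.g. shuffled labels) falls back to the pooled median with a warning.
#'
#' @param x A data frame with numeric columns `hiri`, `misi`, `disposition`
#'   (extra columns are ignored), or a formula like
#'   `status ~ hiri + misi + disposition` with `data`.
#' @param status Character/factor of `"healthy"` / `"T2D"` labels, one per
#'   row of `x` (default method only).
#' @param min_per_class Minimum panels required in each class (default 20).
#' @param ... Passed between methods.
#' @return An object of class `"diabetype"`: a list with `cutoffs` (a
#'   [cutoff_config()]), per-index calibration statistics `stats`
#'   (Youden J, sensitivity, specificity at the chosen cutoff), class sizes
#'   `n`, the reference panels `reference`, and the matched `call`. Supports
#'   `print()`, `summary()`, `coef()`, `predict()` and `plot()`.
#' @examples
#' set.seed(1)
#' ref <- data.frame(
#'   hiri = c(rnorm(25, 800, 120), rnorm(25, 4800, 600)),
#'   misi = c(rnorm(25, -2, 0.4), rnorm(25, -9, 1.5)),
#'   disposition = c(rnorm(25, 2.5, 0.4), rnorm(25, 0.2, 0.08)))
#' fit <- diabetype(ref, rep(c("healthy", "T2D"), each = 25))
#' coef(fit)
#' predict(fit, data.frame(hiri = 5000, misi = -3, disposition = 0.2))
#' @export
diabetype <- function(x, ...) UseMethod("diabetype")

#' @rdname diabetype
#' @export
diabetype.default <- function(x, status, min_per_class = 20L, ...) {
  if (!is.data.frame(x) || !all(c("hiri", "misi", "disposition") %in% names(x)))
    stop("x must be a data frame with columns hiri, misi, disposition")
  status <- as.character(status)
  if (length(status) != nrow(x)) stop("one status per reference panel is required")
  if (!all(status %in% c("healthy", "T2D")))
    stop("status must be 'healthy' or 'T2D'")
  d <- status == "T2D"
  n_h <- sum(!d); n_t <- sum(d)
  if (n_h == 0L || n_t == 0L) stop("both classes must be present")
  if (n_h < min_per_class || n_t < min_per_class)
    stop("at least ", min_per_class, " panels per class are required (got ",
         n_h, " healthy, ", n_t, " T2D)")
  fits <- list(
    hiri = youden_cutoff(x$hiri, d, "greater"),
    misi = youden_cutoff(x$misi, d, "less"),
    disposition = youden_cutoff(x$disposition, d, "less"))
  stats_df <- data.frame(
    index = names(fits),
    cutoff = vapply(fits, `[[`, numeric(1), "cutoff"),
    youden_j = vapply(fits, `[[`, numeric(1), "j"),
    sensitivity = vapply(fits, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(fits, `[[`, numeric(1), "specificity"),
    degenerate = vapply(fits, `[[`, logical(1), "degenerate"),
    row.names = NULL, stringsAsFactors = FALSE)
  cutoffs <- cutoff_config(
    hiri = fits$hiri$cutoff, misi = fits$misi$cutoff,
    disposition = fits$disposition$cutoff,
    provenance = sprintf(
      "Youden-J calibration on %d healthy / %d T2D reference panels", n_h, n_t))
  structure(list(cutoffs = cutoffs, stats = stats_df,
                 n = c(healthy = n_h, T2D = n_t),
                 reference = cbind(x[c("hiri", "misi", "disposition")],
                                   status = status),
                 call = match.call()),
            class = "diabetype")
}

#' @rdname diabetype
#' @param formula A formula whose left-hand side names the status column of
#'   `data` and whose right-hand side uses the index columns, e.g.
#'   `status ~ hiri + misi + disposition` (or `status ~ .`).
#' @param data Data frame holding the reference panels for the formula
#'   method.
#' @export
diabetype.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  status <- mf[[1L]]
  rhs <- mf[-1L]
  need <- c("hiri", "misi", "disposition")
  if (!all(need %in% names(rhs)))
    stop("the right-hand side must provide hiri, misi and disposition")
  out <- diabetype.default(rhs[need], status, ...)
  out$call <- match.call()
  out
}

#' @export
print.diabetype <- function(x, ...) {
  cat("Diabetyping cutoff calibration\n")
  cat("Call: "); print(x$call)
  cat(sprintf("Reference cohort: %d healthy, %d T2D panels\n",
              x$n[["healthy"]], x$n[["T2D"]]))
  print(x$cutoffs)
  invisible(x)
}

#' @export
coef.diabetype <- function(object, ...) {
  c(hiri = object$cutoffs$hiri, misi = object$cutoffs$misi,
    disposition = object$cutoffs$disposition)
}

#' @export
summary.diabetype <- function(object, ...) {
  res <- object$stats
  # training-set reclassification: healthy panels should carry no flag on
  # each index, T2D panels should carry the flag
  ref <- object$reference
  d <- ref$status == "T2D"
  acc <- c(
    hiri = mean((ref$hiri > object$cutoffs$hiri) == d),
    misi = mean((ref$misi < object$cutoffs$misi) == d),
    disposition = mean((ref$disposition < object$cutoffs$disposition) == d))
  res$train_accuracy <- acc[res$index]
  structure(list(call = object$call, n = object$n, stats = res,
                 cutoffs = object$cutoffs),
            class = "summary.diabetype")
}

#' @export
print.summary.diabetype <- function(x, digits = 4, ...) {
  cat("Diabetyping cutoff calibration\n")
  cat("Call: "); print(x$call)
  cat(sprintf("Reference cohort: %d healthy, %d T2D panels\n\n",
              x$n[["healthy"]], x$n[["T2D"]]))
  st <- x$stats
  st[-1] <- lapply(st[-1], function(col) if (is.numeric(col)) signif(col, digits) else col)
  print(st, row.names = FALSE)
  cat("\nProvenance:", x$cutoffs$provenance, "\n")
  invisible(x)
}

#' @export
#' @rdname diabetype
#' @param object A fitted `"diabetype"` object.
#' @param newdata Data frame of index panels to classify (columns `hiri`,
#'   `misi`, `disposition`; `participant_id`/`visit` carried through).
predict.diabetype <- function(object, newdata, ...) {
  if (missing(newdata)) newdata <- object$reference
  classify_subtype(newdata, object$cutoffs)
}

#' @export
plot.diabetype <- function(x, ...) {
  ref <- x$reference
  cuts <- coef(x)
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  for (idx in c("hiri", "misi", "disposition")) {
    vals <- split(ref[[idx]], ref$status)
    graphics::stripchart(vals, vertical = TRUE, method = "jitter",
                         pch = 16, cex = 0.6,
                         col = c("#2b8cbe", "#e34a33"),
                         main = idx, ylab = idx, ...)
    graphics::abline(h = cuts[[idx]], lty = 2)
  }
  invisible(x)
}

#' Per-visit subtype counts and visit-to-visit transitions
#'
#' Tabulates subtype calls per visit (missing calls reported separately) and
#' counts each adjacent visit-to-visit transition, mirroring an alluvial
#' flow of subtypes over the study.
#'
#' @param calls Data frame with columns `participant_id`, `visit` and
#'   `label` (subtype label, `NA` for a visit where the subtype could not be
#'   determined). Visits a participant never appears under are also counted
#'   as missing.
#' @param visits Visit ordering; defaults to the three study visits.
#' @return An object of class `"subtype_flow"`: a list with `per_visit`
#'   (labels x visits count matrix with a trailing `missing` row) and
#'   `transitions` (one from x to count matrix, including `missing`, per
#'   adjacent visit pair).
#' @export
subtype_flow <- function(calls, visits = VISIT_LEVELS) {
  stopifnot(is.data.frame(calls),
            all(c("participant_id", "visit", "label") %in% names(calls)))
  if (anyDuplicated(calls[c("participant_id", "visit")]))
    stop("at most one subtype call per participant and visit")
  bad <- !is.na(calls$label) & !(as.character(calls$label) %in% SUBTYPE_LEVELS)
  if (any(bad)) stop("unknown subtype label(s): ",
                     paste(unique(calls$label[bad]), collapse = ", "))
  ids <- unique(as.character(calls$participant_id))
  lev <- c(SUBTYPE_LEVELS, "missing")
  # label of participant id at visit v, "missing" when absent or NA
  label_at <- function(v) {
    m <- calls[calls$visit == v, ]
    lab <- as.character(m$label[match(ids, as.character(m$participant_id))])
    lab[is.na(lab)] <- "missing"
    factor(lab, levels = lev)
  }
  by_visit <- lapply(visits, label_at)
  names(by_visit) <- visits
  per_visit <- vapply(by_visit, table, integer(length(lev)))
  transitions <- list()
  if (length(visits) >= 2L) {
    for (k in seq_len(length(visits) - 1L)) {
      nm <- paste(visits[k], "->", visits[k + 1L])
      transitions[[nm]] <- table(from = by_visit[[k]], to = by_visit[[k + 1L]])
    }
  }
  structure(list(per_visit = per_visit, transitions = transitions,
                 n = length(ids)),
            class = "subtype_flow")
}

#' @export
print.subtype_flow <- function(x, ...) {
  cat(sprintf("Subtype flow over %d participants\n\nPer-visit counts:\n", x$n))
  print(x$per_visit)
  for (nm in names(x$transitions)) {
    cat("\nTransitions", nm, ":\n")
    tr <- x$transitions[[nm]]
    print(tr[rowSums(tr) > 0, colSums(tr) > 0, drop = FALSE])
  }
  invisible(x)
}
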