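# Remission / reversal adjudication from HbA1c, fasting glucose and
# structured glucose-lowering medication records.
#
# Thresholds (strict boundary semantics, applied exactly as written):
#   remission: fasting glucose <= 6.9 mmol/L AND HbA1c < 48 mmol/mol AND no
#              glucose-lowering medication at the visit;
#   reversal:  HbA1c <= 53 mmol/mol AND fasting glucose < 8.0 mmol/L with
#              reduced (or fully stopped) medication, OR HbA1c < 48 AND
#              fasting glucose <= 6.9 with unchanged medication.
# Remission takes precedence over reversal.

REMISSION_FPG <- 6.9   # mmol/L, inclusive
REMISSION_HBA1C <- 48  # mmol/mol, exclusive
REVERSAL_HBA1C <- 53   # mmol/mol, inclusive
REVERSAL_FPG <- 8.0    # mmol/L, exclusive
MED_RELATIONS <- c("stopped_all", "reduced", "equal", "increased")

#' Glucose-lowering medication state at one visit
#'
#' A set of glucose-lowering drug classes with daily doses. At most one item
#' per drug class; doses are only comparable within an identical
#' (class, unit) pair. Blood-pressure and lipid drugs are outside this
#' container by design: only glucose-lowering classes enter the remission /
#' reversal adjudication.
#'
#' @param visit One of `"baseline"`, `"month3"`, `"month6"`.
#' @param drug_class Character vector of classes among `metformin`,
#'   `SU_derivative`, `insulin`, `GLP1_agonist`, `other_glucose_lowering`
#'   (empty for a medication-free visit).
#' @param daily_dose Positive daily dose per item.
#' @param dose_unit Dose unit string per item (e.g. `"mg"`, `"IU"`).
#' @return An object of class `"medication_state"`.
#' @examples
#' medication_state("baseline", c("metformin", "SU_derivative"),
#'                  c(2000, 80), c("mg", "mg"))
#' medication_state("month3") # medication-free
#' @export
medication_state <- function(visit, drug_class = character(),
                             daily_dose = numeric(), dose_unit = character()) {
  visit <- match.arg(as.character(visit), VISIT_LEVELS)
  drug_class <- as.character(drug_class)
  daily_dose <- as.numeric(daily_dose)
  dose_unit <- as.character(dose_unit)
  n <- length(drug_class)
  if (length(daily_dose) != n || length(dose_unit) != n)
    stop("drug_class, daily_dose and dose_unit must have equal lengths")
  if (n > 0L) {
    bad <- !(drug_class %in% DRUG_CLASSES)
    if (any(bad)) stop("unknown drug class(es): ",
                       paste(unique(drug_class[bad]), collapse = ", "))
    if (anyDuplicated(drug_class)) stop("at most one item per drug class")
    if (anyNA(daily_dose) || any(daily_dose <= 0))
      stop("daily doses must be positive")
  }
  structure(list(visit = visit,
                 items = data.frame(drug_class = drug_class,
                                    daily_dose = daily_dose,
                                    dose_unit = dose_unit,
                                    stringsAsFactors = FALSE)),
            class = "medication_state")
}

#' @export
print.medication_state <- function(x, ...) {
  cat(sprintf("Medication state (%s): ", x$visit))
  if (nrow(x$items) == 0L) cat("no glucose-lowering medication\n")
  else {
    cat("\n")
    print(x$items, row.names = FALSE)
  }
  invisible(x)
}

n_medications <- function(state) nrow(state$items)

#' Compare a visit's medication state against the reference visit
#'
#' Orders two glucose-lowering medication states on the reduction lattice:
#'
#' * `stopped_all`: the current visit is medication-free while the reference
#'   was not;
#' * `reduced`: the current classes are a proper subset of the reference
#'   classes with no remaining dose raised, or the classes are identical
#'   with every dose at most the reference and at least one strictly lower;
#' * `equal`: identical classes, doses and units (including both
#'   medication-free);
#' * `increased`: anything else — any new class, any raised dose, and mixed
#'   changes (one dose up, another down), which are classified conservatively
#'   as increased.
#'
#' @param baseline Reference [medication_state()] (normally the trial start).
#' @param current The [medication_state()] to compare.
#' @return One of `"stopped_all"`, `"reduced"`, `"equal"`, `"increased"`.
#' @examples
#' b <- medication_state("baseline", c("metformin", "SU_derivative", "insulin"),
#'                       c(2000, 80, 40), c("mg", "mg", "IU"))
#' compare_medication(b, medication_state("month3", "metformin", 2000, "mg"))
#' @export
compare_medication <- function(baseline, current) {
  stopifnot(inherits(baseline, "medication_state"),
            inherits(current, "medication_state"))
  b <- baseline$items; k <- current$items
  shared <- intersect(b$drug_class, k$drug_class)
  for (cl in shared) {
    if (b$dose_unit[b$drug_class == cl] != k$dose_unit[k$drug_class == cl])
      stop("dose unit mismatch for ", cl, " ('",
           b$dose_unit[b$drug_class == cl], "' vs '",
           k$dose_unit[k$drug_class == cl],
           "'); doses are only comparable within one unit")
  }
  if (nrow(k) == 0L && nrow(b) > 0L) return("stopped_all")
  new_class <- length(setdiff(k$drug_class, b$drug_class)) > 0L
  if (new_class) return("increased")
  bd <- b$daily_dose[match(shared, b$drug_class)]
  kd <- k$daily_dose[match(shared, k$drug_class)]
  any_up <- any(kd > bd)
  any_down <- any(kd < bd)
  classes_equal <- setequal(b$drug_class, k$drug_class)
  if (any_up) return("increased")
  if (!classes_equal) return("reduced")            # proper subset, no dose raised
  if (any_down) return("reduced")                  # same classes, some dose lower
  "equal"
}

#' Adjudicate per-visit diabetes status
#'
#' Applies the remission / reversal definitions to one visit's labs and
#' medication. Remission is checked first: fasting glucose <= 6.9 mmol/L,
#' HbA1c < 48 mmol/mol and *no* glucose-lowering medication at the visit.
#' Otherwise reversal: HbA1c <= 53 and fasting glucose < 8.0 with reduced or
#' fully stopped medication, or HbA1c < 48 and fasting glucose <= 6.9 with
#' unchanged medication. Otherwise T2D. All boundaries are honored exactly
#' as written (e.g. HbA1c = 48 with no medication is *not* remission).
#'
#' @param labs A list or one-row data frame with `hba1c` (mmol/mol) and
#'   `fpg` (mmol/L), both positive.
#' @param relation Medication relation versus the reference visit, as
#'   returned by [compare_medication()].
#' @param current The current visit's [medication_state()] (needed because
#'   remission requires an empty state, which `relation` alone does not
#'   determine).
#' @return An object of class `"status_call"`: list with `status`
#'   (`"T2D"`, `"reversal"` or `"remission"`) and `med_relation`.
#' @examples
#' classify_status(list(hba1c = 32, fpg = 5.5), "stopped_all",
#'                 medication_state("month3"))
#' @export
classify_status <- function(labs, relation, current) {
  hba1c <- as.numeric(labs$hba1c)
  fpg <- as.numeric(labs$fpg)
  if (length(hba1c) != 1L || length(fpg) != 1L ||
      is.na(hba1c) || is.na(fpg) || hba1c <= 0 || fpg <= 0)
    stop("labs must provide one positive hba1c (mmol/mol) and fpg (mmol/L)")
  relation <- match.arg(relation, MED_RELATIONS)
  stopifnot(inherits(current, "medication_state"))
  med_free <- n_medications(current) == 0L
  status <-
    if (fpg <= REMISSION_FPG && hba1c < REMISSION_HBA1C && med_free) {
      "remission"
    } else if ((hba1c <= REVERSAL_HBA1C && fpg < REVERSAL_FPG &&
                relation %in% c("reduced", "stopped_all")) ||
               (hba1c < REMISSION_HBA1C && fpg <= REMISSION_FPG &&
                relation == "equal")) {
      "reversal"
    } else {
      "T2D"
    }
  structure(list(status = factor(status, levels = STATUS_LEVELS),
                 med_relation = relation),
            class = "status_call")
}

#' @export
print.status_call <- function(x, ...) {
  cat(sprintf("Status: %s (medication %s)\n",
              as.character(x$status), x$med_relation))
  invisible(x)
}

#' Adjudicate status for a whole cohort
#'
#' Joins visit-level labs with medication records and runs
#' [compare_medication()] + [classify_status()] per participant-visit,
#' comparing each follow-up visit's medication against the reference visit
#' (the trial start by default). Every participant needs a medication record
#' at the reference visit; an explicitly medication-free visit is encoded as
#' a single `drug_class = "none"` row so that it is distinguishable from a
#' missing record.
#'
#' @param labs Data frame with columns `participant_id`, `visit`,
#'   `hba1c_mmol_mol`, `fpg_mmol_l`.
#' @param medication Data frame with columns `participant_id`, `visit`,
#'   `drug_class`, `daily_dose`, `dose_unit`; `drug_class = "none"` (dose
#'   fields ignored) marks a medication-free visit.
#' @param reference_visit Visit the medication comparison is referenced to
#'   (default `"baseline"`).
#' @return Data frame with one row per labs row: `participant_id`, `visit`,
#'   `status`, `med_relation`.
#' @export
adjudicate_status <- function(labs, medication, reference_visit = "baseline") {
  stopifnot(is.data.frame(labs),
            all(c("participant_id", "visit", "hba1c_mmol_mol", "fpg_mmol_l")
                %in% names(labs)),
            is.data.frame(medication),
            all(c("participant_id", "visit", "drug_class") %in% names(medication)))
  reference_visit <- match.arg(reference_visit, VISIT_LEVELS)
  med_state <- function(id, visit) {
    m <- medication[medication$participant_id == id & medication$visit == visit, ,
                    drop = FALSE]
    if (nrow(m) == 0L) return(NULL)  # record genuinely missing
    m <- m[m$drug_class != "none", , drop = FALSE]
    medication_state(visit, m$drug_class, m$daily_dose, m$dose_unit)
  }
  rows <- lapply(seq_len(nrow(labs)), function(i) {
    id <- as.character(labs$participant_id[i])
    visit <- as.character(labs$visit[i])
    base <- med_state(id, reference_visit)
    if (is.null(base))
      stop("no ", reference_visit, " medication record for participant ", id,
           "; encode a medication-free visit with drug_class = 'none'")
    cur <- if (visit == reference_visit) base else med_state(id, visit)
    if (is.null(cur))
      stop("no ", visit, " medication record for participant ", id)
    rel <- compare_medication(base, cur)
    call <- classify_status(list(hba1c = labs$hba1c_mmol_mol[i],
                                 fpg = labs$fpg_mmol_l[i]),
                            rel, cur)
    data.frame(participant_id = id, visit = visit,
               status = as.character(call$status),
               med_relation = call$med_relation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$status <- factor(out$status, levels = STATUS_LEVELS)
  out
}

#' Per-visit status counts
#'
#' Counts T2D / reversal / remission calls per visit. Requires one call per
#' participant per visit present in `calls`; counts per visit sum to the
#' number of participants seen at that visit.
#'
#' @param calls Data frame with columns `participant_id`, `visit`, `status`
#'   (as from [adjudicate_status()]).
#' @param visits Visit ordering; defaults to the three study visits.
#' @return A status x visit integer matrix of class `"status_counts"`.
#' @export
status_counts <- function(calls, visits = VISIT_LEVELS) {
  stopifnot(is.data.frame(calls),
            all(c("participant_id", "visit", "status") %in% names(calls)))
  if (anyDuplicated(calls[c("participant_id", "visit")]))
    stop("at most one status call per participant and visit")
  st <- factor(as.character(calls$status), levels = STATUS_LEVELS)
  if (anyNA(st)) stop("unknown status value(s)")
  vs <- factor(as.character(calls$visit), levels = visits)
  if (anyNA(vs)) stop("unknown visit value(s)")
  out <- table(status = st, visit = vs)
  class(out) <- c("status_counts", class(out))
  out
}

#' @export
print.status_counts <- function(x, ...) {
  cat("Per-visit diabetes status counts:\n")
  y <- x
  class(y) <- "table"
  print(y)
  invisible(x)
}
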