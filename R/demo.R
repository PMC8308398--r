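# End-to-end demo pipeline: simulate -> write/read CSV -> indices ->
# calibrate -> classify -> adjudicate -> summarize, from a single seed.

#' Run the whole pipeline on a seeded synthetic cohort
#'
#' Simulates a study-like cohort, writes its CSV inputs, reads them back
#' through the package's own readers, computes index panels, calibrates
#' cutoffs on an independent synthetic reference cohort, classifies
#' subtypes, adjudicates remission/reversal, and writes all summary tables.
#' Every output is a pure function of `(seed, n, archetype mix)`; rerunning
#' with the same arguments reproduces the output tree bit-for-bit.
#'
#' @param seed Integer root seed.
#' @param out_dir Output directory (created if needed).
#' @param n Cohort size (default 15, a small pilot scale).
#' @param archetype_mix Archetype proportions, see [cohort_spec()].
#' @param quiet Suppress the per-stage record-count log (written to
#'   `stderr`).
#' @return Invisibly, a list with the fitted `diabetype` object, the panels,
#'   subtype calls, status calls, `subtype_flow`, `status_counts`, visit
#'   summaries and the vector of written file paths.
#' @export
run_demo <- function(seed = 1L, out_dir = tempfile("diabetyper-demo-"),
                     n = 15L,
                     archetype_mix = c(`IB-HIR` = 0.8, IB = 0.1, `IB-CIR` = 0.1),
                     quiet = FALSE) {
  log_msg <- function(...) if (!quiet) message("[demo] ", sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  spec <- cohort_spec(n = n, archetype_mix = archetype_mix,
                      seed = as.integer(seed))
  cohort <- generate_cohort(spec)
  log_msg("simulated %d participants (%d curves, %d lab rows, %d medication rows)",
          n, length(cohort$curves), nrow(cohort$labs), nrow(cohort$medication))
  write_ogtt_csv(cohort$curves, p("ogtt.csv"))
  utils::write.csv(cohort$labs, p("labs.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$medication, p("medication.csv"), row.names = FALSE,
                   quote = FALSE)

  curves <- read_ogtt_csv(p("ogtt.csv"))
  panels <- compute_indices(curves)
  write_index_csv(panels, p("index_panels.csv"))
  log_msg("computed %d index panels", nrow(panels))

  ref <- simulate_reference_panels(n_per_class = 200,
                                   seed = participant_seed(seed, 10007L))
  fit <- diabetype(ref[c("hiri", "misi", "disposition")], ref$status)
  write_cutoffs_json(fit, p("cutoffs.json"))
  log_msg("calibrated cutoffs on %d reference panels (HIRI %.0f, MISI %.2f, DI %.3f)",
          nrow(ref), fit$cutoffs$hiri, fit$cutoffs$misi, fit$cutoffs$disposition)

  calls <- predict(fit, panels)
  utils::write.csv(calls, p("subtype_calls.csv"), row.names = FALSE, quote = FALSE)
  flow <- subtype_flow(calls)
  utils::write.csv(as.data.frame.matrix(flow$per_visit), p("subtype_counts.csv"),
                   quote = FALSE)
  log_msg("classified %d participant-visits", nrow(calls))

  labs <- read_labs_csv(p("labs.csv"))
  meds <- read_medication_csv(p("medication.csv"))
  status <- adjudicate_status(labs, meds)
  utils::write.csv(status, p("status_calls.csv"), row.names = FALSE, quote = FALSE)
  counts <- status_counts(status)
  utils::write.csv(as.data.frame.matrix(unclass(counts)), p("status_counts.csv"),
                   quote = FALSE)
  log_msg("adjudicated status for %d participant-visits", nrow(status))

  long <- stats::reshape(
    cohort$labs[c("participant_id", "visit", "hba1c_mmol_mol", "fpg_mmol_l",
                  "fasting_insulin_mu_l", "body_weight_kg")],
    direction = "long",
    varying = c("hba1c_mmol_mol", "fpg_mmol_l", "fasting_insulin_mu_l",
                "body_weight_kg"),
    v.names = "value", timevar = "variable",
    times = c("hba1c_mmol_mol", "fpg_mmol_l", "fasting_insulin_mu_l",
              "body_weight_kg"),
    idvar = c("participant_id", "visit"))
  rownames(long) <- NULL
  summaries <- summarize_visits(long)
  utils::write.csv(summaries, p("visit_summaries.csv"), row.names = FALSE,
                   quote = FALSE)
  changes <- do.call(rbind, lapply(
    c("hba1c_mmol_mol", "fpg_mmol_l", "body_weight_kg"), function(v)
      rbind(paired_change(long, v, c("baseline", "month3")),
            paired_change(long, v, c("baseline", "month6")))))
  utils::write.csv(changes, p("paired_changes.csv"), row.names = FALSE,
                   quote = FALSE)
  log_msg("wrote summaries to %s", out_dir)

  invisible(list(fit = fit, panels = panels, subtype_calls = calls,
                 status_calls = status, flow = flow, status_counts = counts,
                 summaries = summaries, paired_changes = changes,
                 files = list.files(out_dir, full.names = TRUE)))
}
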