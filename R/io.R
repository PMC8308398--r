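# CSV / JSON interchange. CSV is RFC-4180, UTF-8, '.' decimal; JSON only for
# the cutoff configuration. Visits are plain strings; no date arithmetic.

read_checked_csv <- function(path, required, comment.char = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = comment.char)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  df
}

as_numeric_strict <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad))
    stop("malformed numeric value in ", path, ", column '", col, "', data row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(x[bad]), collapse = ", "))
  out
}

#' Read long-format OGTT measurements from CSV
#'
#' Expects columns `participant_id`, `visit`, `time_min`, `glucose_mmol_l`,
#' `insulin_mu_l`, one row per sample. Rows with sampling times off the
#' canonical grid \{0, 30, 60, 90, 120\} min are rejected with a per-row
#' warning (and reported in the `rejected` attribute); duplicate
#' (participant, visit, time) rows and malformed numerics are hard errors
#' naming the offending rows. Participant-visits missing some canonical
#' times yield flagged partial curves (usable for the fasting-sample
#' indices only).
#'
#' @param path Path to the CSV file.
#' @return A list of [ogtt_curve()] objects, with attribute `rejected` (data
#'   frame of dropped non-canonical rows, if any).
#' @export
read_ogtt_csv <- function(path) {
  req <- c("participant_id", "visit", "time_min", "glucose_mmol_l", "insulin_mu_l")
  df <- read_checked_csv(path, req)
  for (col in c("time_min", "glucose_mmol_l", "insulin_mu_l"))
    df[[col]] <- as_numeric_strict(as.character(df[[col]]), col, path)
  bad_t <- !(df$time_min %in% CANONICAL_TIMES)
  rejected <- df[bad_t, , drop = FALSE]
  if (any(bad_t)) {
    warning("rejected ", sum(bad_t), " row(s) with non-canonical sampling times ",
            "(data rows ", paste(which(bad_t), collapse = ", "), ")")
    df <- df[!bad_t, , drop = FALSE]
  }
  key <- paste(df$participant_id, df$visit, df$time_min, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (participant, visit, time) rows in ", path, ": data rows ",
         paste(dup, collapse = ", "))
  }
  groups <- split(df, paste(df$participant_id, df$visit, sep = "\r"), drop = TRUE)
  curves <- lapply(groups, function(g) {
    g <- g[order(g$time_min), ]
    ogtt_curve(g$participant_id[1L], g$visit[1L], g$time_min,
               g$glucose_mmol_l, g$insulin_mu_l)
  })
  names(curves) <- NULL
  ord <- order(vapply(curves, `[[`, character(1), "participant_id"),
               match(vapply(curves, `[[`, character(1), "visit"), VISIT_LEVELS))
  curves <- curves[ord]
  attr(curves, "rejected") <- rejected
  curves
}

#' Write OGTT curves to long-format CSV
#'
#' Inverse of [read_ogtt_csv()]: writing then reading gives back identical
#' curves.
#'
#' @param curves List of [ogtt_curve()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ogtt_csv <- function(curves, path) {
  rows <- lapply(curves, function(cv)
    data.frame(participant_id = cv$participant_id, visit = cv$visit,
               time_min = cv$times, glucose_mmol_l = cv$glucose,
               insulin_mu_l = cv$insulin, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write computed index panels to CSV
#'
#' One row per participant-visit, preceded by a `#`-comment header recording
#' the unit conventions.
#'
#' @param panels Data frame from [compute_indices()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_index_csv <- function(panels, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  note <- attr(panels, "units_note")
  if (is.null(note)) note <- UNITS_NOTE
  writeLines(paste("# units:", note), con)
  utils::write.csv(panels, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read index panels written by [write_index_csv()]
#'
#' @param path CSV path.
#' @return Data frame of index panels.
#' @export
read_index_csv <- function(path) {
  read_checked_csv(path, c("participant_id", "visit", "matsuda", "disposition",
                           "hiri", "misi", "homa_ir"),
                   comment.char = "#")
}

#' Read / write a cutoff configuration as JSON
#'
#' The JSON object has fields `hiri`, `misi`, `disposition` (numbers) and
#' `provenance` (string).
#'
#' @param path JSON path.
#' @return `read_cutoffs_json()`: a [cutoff_config()];
#'   `write_cutoffs_json()`: `path`, invisibly.
#' @export
read_cutoffs_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("hiri", "misi", "disposition")
  if (!all(need %in% names(x)))
    stop("cutoff JSON must contain fields hiri, misi, disposition")
  cutoff_config(x$hiri, x$misi, x$disposition,
                provenance = if (is.null(x$provenance)) "unspecified" else x$provenance)
}

#' @rdname read_cutoffs_json
#' @param cutoffs A [cutoff_config()] (or fitted [diabetype()] object).
#' @export
write_cutoffs_json <- function(cutoffs, path) {
  if (inherits(cutoffs, "diabetype")) cutoffs <- cutoffs$cutoffs
  stopifnot(inherits(cutoffs, "cutoff_config"))
  jsonlite::write_json(list(hiri = cutoffs$hiri, misi = cutoffs$misi,
                            disposition = cutoffs$disposition,
                            provenance = cutoffs$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read visit-level labs from CSV
#'
#' Requires columns `participant_id`, `visit`, `hba1c_mmol_mol`,
#' `fpg_mmol_l`; extra clinical columns are kept.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_labs_csv <- function(path) {
  df <- read_checked_csv(path, c("participant_id", "visit",
                                 "hba1c_mmol_mol", "fpg_mmol_l"))
  for (col in setdiff(names(df), c("participant_id", "visit")))
    df[[col]] <- as_numeric_strict(as.character(df[[col]]), col, path)
  bad <- !(df$visit %in% VISIT_LEVELS)
  if (any(bad)) stop("unknown visit value(s) in ", path, ": ",
                     paste(unique(df$visit[bad]), collapse = ", "))
  df
}

#' Read medication records from CSV
#'
#' Requires columns `participant_id`, `visit`, `drug_class`, `daily_dose`,
#' `dose_unit`. Every participant-visit that was observed must appear;
#' `drug_class = "none"` marks an explicitly medication-free visit.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_medication_csv <- function(path) {
  df <- read_checked_csv(path, c("participant_id", "visit", "drug_class",
                                 "daily_dose", "dose_unit"))
  df$daily_dose <- as_numeric_strict(as.character(df$daily_dose), "daily_dose", path)
  bad <- !(df$drug_class %in% c(DRUG_CLASSES, "none"))
  if (any(bad)) stop("unknown drug class(es) in ", path, ": ",
                     paste(unique(df$drug_class[bad]), collapse = ", "))
  df
}
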