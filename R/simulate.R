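# Seeded synthetic OGTT cohort generator.
#
# One participant-visit curve comes from a discrete glucose balance on a
# 5-minute grid,
#
#   G(t+dt) = G(t) + dt * [ absorption(t) - disposal_rate * I(t) * (G(t) - Gb) ]
#
# with a fixed absorption input over the first 60 minutes and a basal
# glucose floor Gb (a fraction of the fasting value; at the default fraction
# of 1 the excursion decays back toward the fasting level). Insulin responds
# to the positive glucose excursion exc(t) = (G(t) - G0)+ in two phases,
# both scaled by the archetype's beta-cell gain,
#
#   I(t) = fI + gain * [ F(t) * sat(exc, K1) + s2 * (1 - F(t)) * sat(exc, K2) ],
#
# where F(t) falls linearly from 1 at t <= 30 min to 0 at t >= 60 min and
# sat(x, K) = x / (1 + x / K) saturates the response. A failing beta cell
# loses the early (first-phase) response - the classical secretory signature
# of impaired beta-cell function - and with it most of the late compensation,
# which is what lets the early insulin-to-glucose AUC ratio (the
# disposition-index numerator) read out the gain.
#
# The grid contains the five canonical sampling times, where multiplicative
# lognormal measurement noise (coefficient of variation noise_cv) is applied
# to both traces. This is deliberately not a validated physiological model
# (no minimal-model fitting, no incretin effect): it is the simplest
# mechanism that gives the OGTT indices the monotone dependence on the
# archetype parameters the classifier assumes.

SIM_DT <- 5              # minutes, difference-equation step
SIM_ABSORPTION_MIN <- 60 # minutes of glucose input after the drink
SIM_FLOOR_FRAC <- 1.0    # basal glucose floor as a fraction of fasting glucose
SIM_SAT_K1 <- 1.5        # mmol/L, half-saturation of the first-phase response
SIM_SAT_K2 <- 2.5        # mmol/L, half-saturation of the second-phase response
SIM_PHASE2_FRAC <- 0.18  # second-phase gain as a fraction of the first-phase gain

# Archetype parameter levels. Fasting levels for the hepatic flag are
# anchored to an advanced-T2D cohort scale (fasting glucose ~12 mmol/L,
# fasting insulin ~23 mU/L; the combined-IR prototype carries a lower
# fasting insulin, reflecting failing basal hypersecretion, and reaches a
# 2-h glucose near 20 mmol/L); the healthy levels sit in the normoglycemic
# range (fasting glucose < 6.1 mmol/L in expectation). `clearance` is the
# effective insulin-dependent disposal at the archetype fasting insulin;
# disposal_rate = clearance / fasting insulin mean, so the disposal term
# disposal_rate * I(t) * (G - Gb) has a comparable scale across
# fasting-insulin levels. Beta-cell-impaired prototypes without the muscle
# flag get a compensated (higher per-insulin) clearance so that their
# effective glucose decay stays in the normal-disposal range despite the
# absent insulin response: each archetype is an index-space prototype, not a
# patient model.
SIM_BETA_NORMAL <- 90
SIM_BETA_IMPAIRED <- 1.5
SIM_CLEAR_NORMAL <- 0.045
SIM_CLEAR_MUSCLE <- 0.002
SIM_CLEAR_COMPENSATION <- 4

#' Archetype specification for the synthetic OGTT generator
#'
#' Builds the generator parameters for one of the eight subtype archetypes.
#' Each impairment flag of the label switches one parameter group to its
#' impaired level: hepatic insulin resistance raises the fasting
#' glucose-insulin level, muscle insulin resistance lowers the
#' insulin-dependent disposal rate, impaired beta-cell function lowers the
#' gain of the (two-phase) insulin response. Two interactions keep the
#' prototypes in their index-space cells: the combined-IR prototypes carry a
#' lower fasting insulin than the isolated hepatic ones (failing basal
#' hypersecretion), and beta-cell-impaired prototypes without muscle
#' involvement get a compensated, higher per-insulin clearance so their
#' glucose decay stays in the normal-disposal range despite the absent
#' insulin response. Any field can be overridden through `...`.
#'
#' @param label One of `healthy, HIR, MIR, CIR, IB, IB-HIR, IB-MIR, IB-CIR`.
#' @param noise_cv Multiplicative measurement-noise coefficient of variation
#'   applied per sample (default 0.05).
#' @param ... Named overrides for any spec field (`fg_mean`, `fg_sd`,
#'   `fi_mean`, `fi_sd`, `beta_cell_gain`, `disposal_rate`,
#'   `absorption_rate`, `absorption_minutes`, `basal_floor_frac`,
#'   `noise_cv`).
#' @return An object of class `"archetype_spec"`.
#' @examples
#' archetype_spec("IB-HIR")
#' @export
archetype_spec <- function(label, noise_cv = 0.05, ...) {
  label <- match.arg(as.character(label), SUBTYPE_LEVELS)
  hep <- label %in% c("HIR", "CIR", "IB-HIR", "IB-CIR")
  mus <- label %in% c("MIR", "CIR", "IB-MIR", "IB-CIR")
  bcf <- label %in% c("IB", "IB-HIR", "IB-MIR", "IB-CIR")
  fi_mean <- if (hep && mus) 14 else if (hep) 23 else 9
  clearance <- if (mus) SIM_CLEAR_MUSCLE else
    SIM_CLEAR_NORMAL * (if (bcf) SIM_CLEAR_COMPENSATION else 1)
  spec <- list(
    label = label,
    fg_mean = if (hep) 11.7 else 5.2, fg_sd = if (hep) 1.10 else 0.30,
    fi_mean = fi_mean,
    fi_sd = if (hep && mus) 1.8 else if (hep) 2.2 else 1.35,
    beta_cell_gain = if (bcf) SIM_BETA_IMPAIRED else SIM_BETA_NORMAL,
    disposal_rate = clearance / fi_mean,
    absorption_rate = 0.18,   # mmol/L per min over the absorption window
    absorption_minutes = SIM_ABSORPTION_MIN,
    basal_floor_frac = SIM_FLOOR_FRAC,
    noise_cv = noise_cv)
  dots <- list(...)
  bad <- setdiff(names(dots), names(spec))
  if (length(bad)) stop("unknown archetype field(s): ", paste(bad, collapse = ", "))
  spec[names(dots)] <- dots
  with(spec, stopifnot(fg_mean > 0, fg_sd > 0, fi_mean > 0, fi_sd > 0,
                       beta_cell_gain > 0, disposal_rate > 0,
                       absorption_rate > 0, absorption_minutes > 0,
                       basal_floor_frac > 0, basal_floor_frac <= 1,
                       noise_cv >= 0))
  structure(spec, class = "archetype_spec")
}

#' @export
print.archetype_spec <- function(x, ...) {
  cat(sprintf("Archetype '%s': fG ~ N(%.1f, %.2f) mmol/L, fI ~ N(%.1f, %.2f) mU/L,\n",
              x$label, x$fg_mean, x$fg_sd, x$fi_mean, x$fi_sd))
  cat(sprintf("  beta-cell gain %.2f, disposal rate %.5f /min per mU/L, noise CV %.0f%%\n",
              x$beta_cell_gain, x$disposal_rate, 100 * x$noise_cv))
  invisible(x)
}

# positive truncated normal draw
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}

# mean-preserving multiplicative lognormal noise
lnoise <- function(x, cv) {
  if (cv == 0) return(x)
  sdlog <- sqrt(log(1 + cv^2))
  x * exp(stats::rnorm(length(x), -sdlog^2 / 2, sdlog))
}

sat <- function(x, k) x / (1 + x / k)

# first-phase weight: 1 up to 30 min, ramping to 0 by 60 min
phase1_weight <- function(t) pmin(pmax((60 - t) / 30, 0), 1)

sim_insulin <- function(arch, t, exc, fi) {
  fi + arch$beta_cell_gain *
    (phase1_weight(t) * sat(exc, SIM_SAT_K1) +
       SIM_PHASE2_FRAC * (1 - phase1_weight(t)) * sat(exc, SIM_SAT_K2))
}

# noise-free glucose/insulin trajectories on the 5-minute grid
sim_trajectory <- function(arch, fg, fi) {
  grid <- seq(0, 120, by = SIM_DT)
  gb <- arch$basal_floor_frac * fg
  g <- numeric(length(grid)); g[1] <- fg
  for (k in seq_len(length(grid) - 1L)) {
    ins <- sim_insulin(arch, grid[k], max(g[k] - fg, 0), fi)
    a <- if (grid[k] < arch$absorption_minutes) arch$absorption_rate else 0
    g[k + 1L] <- g[k] + SIM_DT * (a - arch$disposal_rate * ins * max(g[k] - gb, 0))
    if (g[k + 1L] <= 0)
      stop("archetype parameters drove glucose non-positive at t = ",
           grid[k + 1L], " min")
  }
  ins <- sim_insulin(arch, grid, pmax(g - fg, 0), fi)
  list(times = grid, glucose = g, insulin = ins)
}

#' Generate one synthetic OGTT curve from an archetype
#'
#' Draws the fasting state (unless supplied), integrates the glucose balance
#' on a 5-minute grid, reads off the five canonical sampling times and
#' applies multiplicative lognormal measurement noise. Uses (and advances)
#' R's current random-number stream.
#'
#' @param arch An [archetype_spec()].
#' @param participant_id,visit Identifiers stored on the returned curve.
#' @param fg,fi Optional fixed fasting glucose (mmol/L) / insulin (mU/L);
#'   drawn from the archetype's fasting distribution when `NULL`.
#' @param noise_cv Measurement-noise CV; defaults to the archetype's.
#' @return An [ogtt_curve()].
#' @examples
#' set.seed(1)
#' generate_curve(archetype_spec("healthy"))
#' @export
generate_curve <- function(arch, participant_id = "sim", visit = "baseline",
                           fg = NULL, fi = NULL, noise_cv = arch$noise_cv) {
  stopifnot(inherits(arch, "archetype_spec"))
  if (is.null(fg)) fg <- rnorm_pos(1L, arch$fg_mean, arch$fg_sd)
  if (is.null(fi)) fi <- rnorm_pos(1L, arch$fi_mean, arch$fi_sd)
  tr <- sim_trajectory(arch, fg, fi)
  idx <- match(CANONICAL_TIMES, tr$times)
  g <- lnoise(tr$glucose[idx], noise_cv)
  i <- lnoise(tr$insulin[idx], noise_cv)
  ogtt_curve(participant_id, visit, CANONICAL_TIMES, pmax(g, 1e-6), pmax(i, 1e-6))
}

#' Cohort specification for the synthetic generator
#'
#' @param n Number of participants (>= 1).
#' @param archetype_mix Named numeric vector of archetype proportions
#'   (names among the eight subtype labels; must sum to 1).
#' @param visit_effects Named list with one entry per follow-up visit, each
#'   a numeric vector of multipliers `c(fg, fi, beta, disposal)` applied to
#'   the archetype's fasting glucose, fasting insulin, beta-cell gain and
#'   disposal rate. The defaults emulate a lifestyle-intervention pattern:
#'   a strong 3-month improvement followed by a partial relapse of the
#'   fasting state at 6 months while insulin sensitivity keeps improving.
#' @param noise_cv Measurement-noise CV per sample.
#' @param seed Integer root seed; every draw flows from per-participant
#'   seeds derived from it, so any subset of participants is reproducible
#'   independent of generation order.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n, archetype_mix = c(`IB-HIR` = 0.8, IB = 0.1, `IB-CIR` = 0.1),
                        visit_effects = list(
                          month3 = c(fg = 0.73, fi = 0.73, beta = 2.2, disposal = 1.5),
                          month6 = c(fg = 0.87, fi = 0.58, beta = 1.7, disposal = 2.0)),
                        noise_cv = 0.05, seed = 1L) {
  n <- as.integer(n)
  stopifnot(n >= 1L, is.numeric(archetype_mix), length(archetype_mix) >= 1L)
  if (is.null(names(archetype_mix)) ||
      !all(names(archetype_mix) %in% SUBTYPE_LEVELS))
    stop("archetype_mix must be named with subtype labels")
  if (abs(sum(archetype_mix) - 1) > 1e-8) stop("archetype proportions must sum to 1")
  if (any(archetype_mix < 0)) stop("archetype proportions must be non-negative")
  stopifnot(all(names(visit_effects) %in% VISIT_LEVELS))
  for (v in names(visit_effects))
    stopifnot(all(c("fg", "fi", "beta", "disposal") %in% names(visit_effects[[v]])),
              all(visit_effects[[v]] > 0))
  structure(list(n = n, archetype_mix = archetype_mix,
                 visit_effects = visit_effects, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# derived per-participant seed, kept below 2^31
participant_seed <- function(root, i) {
  as.integer((as.numeric(root) * 48271 + i * 7919) %% 2147483587)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a full synthetic longitudinal cohort
#'
#' For each participant: an archetype drawn from the mix, a person-level
#' fasting state, and for each of the three visits an OGTT curve (visit
#' effect multipliers applied to the archetype), visit labs (HbA1c derived
#' from the curve's mean glucose by a fixed affine map with additive noise;
#' fasting glucose and insulin read off the curve; body weight with a
#' visit-level loss pattern) and glucose-lowering medication records that
#' de-escalate when the simulated labs improve past configurable thresholds.
#' Fully reproducible from the root seed; each participant has an
#' independent derived stream.
#'
#' @param spec A [cohort_spec()].
#' @param hba1c_coef Affine map `c(intercept, slope, sd)` from mean OGTT
#'   glucose (mmol/L) to HbA1c (mmol/mol) plus additive Gaussian noise. The
#'   defaults put the fully impaired fasting archetypes near the
#'   HbA1c ~ 67 mmol/mol scale of an advanced-T2D cohort.
#' @param med_rules De-escalation thresholds: insulin and SU derivatives are
#'   stopped at a follow-up when HbA1c < `stop_injectable_hba1c`; all
#'   glucose-lowering medication stops when HbA1c < `stop_all_hba1c` and
#'   fasting glucose <= `stop_all_fpg`; otherwise metformin is halved when
#'   HbA1c <= `halve_metformin_hba1c`.
#' @return An object of class `"synthetic_cohort"`: list with `curves` (list
#'   of [ogtt_curve()]), `labs`, `medication`, `archetypes` data frames and
#'   the `spec`.
#' @export
generate_cohort <- function(spec,
                            hba1c_coef = c(intercept = 11, slope = 4.3, sd = 2),
                            med_rules = c(stop_injectable_hba1c = 58,
                                          stop_all_hba1c = 48, stop_all_fpg = 6.9,
                                          halve_metformin_hba1c = 53)) {
  stopifnot(inherits(spec, "cohort_spec"))
  mix <- spec$archetype_mix
  visits <- VISIT_LEVELS
  # baseline regimen categories with pilot-like frequencies
  regimens <- list(
    c("insulin", "SU_derivative", "metformin"),
    c("insulin", "GLP1_agonist", "metformin"),
    c("insulin", "metformin"),
    c("SU_derivative", "metformin"),
    "metformin",
    character())
  reg_prob <- c(2, 1, 3, 5, 3, 1) / 15
  doses <- c(metformin = 2000, SU_derivative = 80, insulin = 40, GLP1_agonist = 1.5,
             other_glucose_lowering = 1)
  units <- c(metformin = "mg", SU_derivative = "mg", insulin = "IU",
             GLP1_agonist = "mg", other_glucose_lowering = "unit")

  one_participant <- function(i) with_seed(participant_seed(spec$seed, i), {
    id <- sprintf("S%03d", i)
    label <- sample(names(mix), 1L, prob = mix)
    base_arch <- archetype_spec(label, noise_cv = spec$noise_cv)
    fg0 <- rnorm_pos(1L, base_arch$fg_mean, base_arch$fg_sd)
    fi0 <- rnorm_pos(1L, base_arch$fi_mean, base_arch$fi_sd)
    weight0 <- rnorm_pos(1L, 102.6, 13)
    healthy <- label == "healthy"
    regimen <- if (healthy) character() else
      regimens[[sample(length(regimens), 1L, prob = reg_prob)]]
    wt_mult <- c(baseline = 1, month3 = 0.902, month6 = 0.894)
    curves <- list(); labs <- list(); meds <- list()
    for (v in visits) {
      eff <- if (v == "baseline") c(fg = 1, fi = 1, beta = 1, disposal = 1) else
        spec$visit_effects[[v]]
      arch <- archetype_spec(label, noise_cv = spec$noise_cv,
                             beta_cell_gain = base_arch$beta_cell_gain * eff[["beta"]],
                             disposal_rate = base_arch$disposal_rate * eff[["disposal"]])
      cv <- generate_curve(arch, id, v, fg = fg0 * eff[["fg"]], fi = fi0 * eff[["fi"]])
      curves[[v]] <- cv
      mean_g <- mean(cv$glucose)
      hba1c <- max(hba1c_coef[["intercept"]] + hba1c_coef[["slope"]] * mean_g +
                     stats::rnorm(1L, 0, hba1c_coef[["sd"]]), 10)
      fpg <- cv$glucose[1L]
      labs[[v]] <- data.frame(
        participant_id = id, visit = v,
        hba1c_mmol_mol = hba1c, fpg_mmol_l = fpg,
        fasting_insulin_mu_l = cv$insulin[1L],
        body_weight_kg = weight0 * wt_mult[[v]] + stats::rnorm(1L, 0, 0.5),
        stringsAsFactors = FALSE)
      # medication: baseline regimen held at baseline, de-escalated at
      # follow-ups when the simulated labs cross the rule thresholds
      cur <- regimen
      dose_mult <- stats::setNames(rep(1, length(cur)), cur)
      if (v != "baseline" && length(cur)) {
        if (hba1c < med_rules[["stop_injectable_hba1c"]])
          cur <- setdiff(cur, c("insulin", "SU_derivative"))
        if (hba1c < med_rules[["stop_all_hba1c"]] &&
            fpg <= med_rules[["stop_all_fpg"]]) {
          cur <- character()
        } else if (hba1c <= med_rules[["halve_metformin_hba1c"]] &&
                   "metformin" %in% cur) {
          dose_mult[["metformin"]] <- 0.5
        }
      }
      meds[[v]] <- if (length(cur) == 0L) {
        data.frame(participant_id = id, visit = v, drug_class = "none",
                   daily_dose = NA_real_, dose_unit = NA_character_,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(participant_id = id, visit = v, drug_class = cur,
                   daily_dose = unname(doses[cur] * dose_mult[cur]),
                   dose_unit = unname(units[cur]), stringsAsFactors = FALSE)
      }
    }
    list(curves = curves, labs = do.call(rbind, labs),
         meds = do.call(rbind, meds),
         arch = data.frame(participant_id = id, archetype = label,
                           stringsAsFactors = FALSE))
  })

  parts <- lapply(seq_len(spec$n), one_participant)
  structure(list(
    curves = unlist(lapply(parts, `[[`, "curves"), recursive = FALSE, use.names = FALSE),
    labs = do.call(rbind, lapply(parts, `[[`, "labs")),
    medication = do.call(rbind, lapply(parts, `[[`, "meds")),
    archetypes = do.call(rbind, lapply(parts, `[[`, "arch")),
    spec = spec), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic OGTT cohort: %d participants x %d visits (seed %d)\n",
              x$spec$n, length(VISIT_LEVELS), x$spec$seed))
  print(table(x$archetypes$archetype))
  invisible(x)
}

#' Simulate a labeled reference cohort for cutoff calibration
#'
#' Generates baseline index panels for a healthy class (the `healthy`
#' archetype) and a diseased class (the fully impaired `IB-CIR` archetype),
#' labeled for [diabetype()]. Using the fully impaired archetype as the
#' diseased calibration class puts each per-index Youden threshold in the
#' gap between that index's normal and impaired generator levels.
#'
#' @param n_per_class Panels per class.
#' @param seed Root seed (the two classes use derived sub-seeds).
#' @param noise_cv Measurement-noise CV.
#' @param convention MISI convention passed to [compute_indices()].
#' @return Data frame of panels with a `status` column (`healthy` / `T2D`).
#' @export
simulate_reference_panels <- function(n_per_class = 200, seed = 1L,
                                      noise_cv = 0.05,
                                      convention = "span_slope") {
  make <- function(label, status, sub) with_seed(participant_seed(seed, sub), {
    arch <- archetype_spec(label, noise_cv = noise_cv)
    curves <- lapply(seq_len(n_per_class), function(i)
      generate_curve(arch, sprintf("%s%03d", status, i)))
    p <- compute_indices(curves, convention = convention)
    p$status <- status
    p
  })
  rbind(make("healthy", "healthy", 1L), make("IB-CIR", "T2D", 2L))
}
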