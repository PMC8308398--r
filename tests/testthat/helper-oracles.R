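# Independent literal transcriptions of the index formulas, written in a
# deliberately different style (explicit loops, pracma::trapz where
# available) so they can serve as oracles for the package implementation.

oracle_homa <- function(fg, fi) (fg * fi) / 22.5

oracle_hiri <- function(fg, fi) (fg * 18) * fi

oracle_matsuda <- function(glucose_mmol, insulin) {
  fg <- glucose_mmol[1] * 18
  fi <- insulin[1]
  mg <- sum(glucose_mmol * 18) / length(glucose_mmol)
  mi <- sum(insulin) / length(insulin)
  10000 / sqrt(fg * fi * mg * mi)
}

oracle_auc <- function(times, values, lo, hi) {
  keep <- times >= lo & times <= hi
  if (sum(keep) < 2) return(0)
  if (requireNamespace("pracma", quietly = TRUE)) {
    pracma::trapz(times[keep], values[keep])
  } else {
    t <- times[keep]; v <- values[keep]
    a <- 0
    for (k in 2:length(t)) a <- a + (t[k] - t[k - 1]) * (v[k] + v[k - 1]) / 2
    a
  }
}

oracle_di <- function(times, glucose_mmol, insulin) {
  auc_i <- oracle_auc(times, insulin, 0, 30)
  auc_g <- oracle_auc(times, glucose_mmol * 18, 0, 30)
  (auc_i / auc_g) * oracle_matsuda(glucose_mmol, insulin)
}

oracle_misi_span <- function(times, glucose_mmol, insulin) {
  gp <- glucose_mmol * 18
  i_max <- 1; i_min <- 1
  for (k in seq_along(gp)) {
    if (gp[k] > gp[i_max]) i_max <- k
    if (gp[k] < gp[i_min]) i_min <- k
  }
  if (gp[i_max] == gp[i_min]) return(0)
  mi <- sum(insulin) / length(insulin)
  100 * (gp[i_min] - gp[i_max]) / abs(times[i_min] - times[i_max]) / mi
}

# random plausible five-point curve (positive, not flat)
random_curve <- function(id = "R1", visit = "baseline") {
  fg <- runif(1, 4, 14)
  g <- fg * exp(cumsum(c(0, rnorm(4, 0.05, 0.15))))
  fi <- runif(1, 4, 35)
  i <- fi * exp(cumsum(c(0, rnorm(4, 0.1, 0.3))))
  ogtt_curve(id, visit, c(0, 30, 60, 90, 120), g, i)
}

fixture_path <- function(f) {
  p <- system.file("extdata", f, package = "diabetyper")
  if (!nzchar(p)) p <- file.path("../../inst/extdata", f)
  p
}
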