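make_curve <- function(glucose, insulin, id = "T1") {
  ogtt_curve(id, "baseline", c(0, 30, 60, 90, 120), glucose, insulin)
}

test_that("glucose unit conversion uses factor 18 and rejects non-positive input", {
  expect_equal(glucose_to_mgdl(11.98), 215.64)
  expect_equal(glucose_to_mgdl(5), 90)
  expect_error(glucose_to_mgdl(0), "positive")
  expect_error(glucose_to_mgdl(-3), "positive")
})

test_that("trapezoidal AUC matches hand values and is linear and additive", {
  t5 <- c(0, 30, 60, 90, 120)
  expect_equal(trapezoid_auc(c(0, 30), c(10, 20), c(0, 30)), 450)
  expect_equal(trapezoid_auc(t5, rep(7, 5), c(0, 30)), 30 * 7)
  expect_equal(trapezoid_auc(t5, c(3, 9, 2, 8, 5), c(60, 60)), 0)
  expect_error(trapezoid_auc(t5, 1:5, c(0, 45)), "sampling times")
  expect_error(trapezoid_auc(t5, 1:5, c(30, 0)), "t_lo <= t_hi")

  set.seed(42)
  for (rep in 1:20) {
    v1 <- runif(5, 1, 50); v2 <- runif(5, 1, 50); a <- runif(1, 0.1, 5)
    # linear in values
    expect_equal(trapezoid_auc(t5, a * v1 + v2, c(0, 120)),
                 a * trapezoid_auc(t5, v1, c(0, 120)) +
                   trapezoid_auc(t5, v2, c(0, 120)))
    # additive over adjacent windows
    expect_equal(trapezoid_auc(t5, v1, c(0, 60)) + trapezoid_auc(t5, v1, c(60, 120)),
                 trapezoid_auc(t5, v1, c(0, 120)))
    # agrees with the reference integrator
    expect_equal(trapezoid_auc(t5, v1, c(0, 120)), oracle_auc(t5, v1, 0, 120))
  }
})

test_that("HOMA-IR and HIRI reproduce hand-computed fasting values", {
  expect_equal(homa_ir(11.98, 23.9), 11.98 * 23.9 / 22.5)
  expect_equal(homa_ir(4.5, 5), 1)
  expect_equal(homa_ir(22.5, 1), 1)
  expect_error(homa_ir(0, 5), "positive")

  expect_equal(hiri(1 / 18, 1), 1)
  # HIRI is the same fasting product as HOMA-IR under the mg/dL convention
  expect_equal(hiri(11.98, 23.9), homa_ir(11.98, 23.9) * 22.5 * 18)
})

test_that("Matsuda index matches hand evaluations and scales as 1/k^2", {
  flat <- make_curve(rep(100 / 18, 5), rep(10, 5))
  expect_equal(matsuda(flat), 10, tolerance = 1e-12)

  # curve with fG' 215.6, fI 23.9, mG' 280, mI 40
  g <- c(215.6, 280, 320, 300, 284.4) / 18
  i <- c(23.9, 40, 50, 46.1, 40)
  expect_equal(mean(g) * 18, 280)
  expect_equal(mean(i), 40)
  expect_equal(matsuda(make_curve(g, i)),
               10000 / sqrt(215.6 * 23.9 * 280 * 40), tolerance = 1e-12)
  expect_equal(matsuda(make_curve(g, i)), 1.316, tolerance = 1e-3)

  set.seed(7)
  for (rep in 1:10) {
    cv <- random_curve()
    k <- runif(1, 0.5, 3)
    scaled <- make_curve(cv$glucose * k, cv$insulin * k)
    expect_equal(matsuda(scaled), matsuda(cv) / k^2, tolerance = 1e-10)
    expect_equal(hiri(cv$glucose[1] * k, cv$insulin[1] * k),
                 hiri(cv$glucose[1], cv$insulin[1]) * k^2)
  }
})

test_that("disposition index follows its AUC-ratio construction", {
  flat <- make_curve(rep(100 / 18, 5), rep(10, 5))
  expect_equal(disposition_index(flat), 1, tolerance = 1e-12)

  set.seed(11)
  cv <- random_curve()
  # scaling the whole insulin trace by k multiplies the early AUC ratio by k
  # and the Matsuda index by 1/k (both insulin factors sit under the square
  # root), so the disposition index is invariant under insulin rescaling
  doubled <- make_curve(cv$glucose, cv$insulin * 2)
  expect_equal(disposition_index(doubled), disposition_index(cv),
               tolerance = 1e-10)

  # insulin numerically identical to the mg/dL glucose trace: ratio is 1
  same <- make_curve(cv$glucose, cv$glucose * 18)
  expect_equal(disposition_index(same), matsuda(same), tolerance = 1e-12)
})

test_that("MISI conventions give the documented signs and hand values", {
  rising <- make_curve(c(215, 260, 305, 350, 395) / 18, rep(40, 5))
  expect_equal(misi(rising), 100 * (215 - 395) / 120 / 40)
  expect_equal(misi(rising), -3.75)

  flat <- make_curve(rep(5, 5), rep(10, 5))
  expect_warning(v <- misi(flat), "flat")
  expect_equal(v, 0)

  # decaying from a 30-min peak: classic decay convention is positive
  decay <- make_curve(c(90, 180, 150, 120, 100) / 18, rep(20, 5))
  expect_gt(misi(decay, "peak_decay"), 0)
  expect_lt(misi(decay, "span_slope"), 0)
  expect_equal(misi(decay, "peak_decay"), 100 * (180 - 100) / 90 / 20)

  # peak at the last sample: no decay phase under the decay convention
  expect_warning(v2 <- misi(rising, "peak_decay"), "decay")
  expect_equal(v2, 0)
})

test_that("all five indices agree with literal-transcription oracles on random curves", {
  set.seed(123)
  for (rep in 1:200) {
    cv <- random_curve()
    p <- compute_panel(cv)
    expect_equal(p$homa_ir, oracle_homa(cv$glucose[1], cv$insulin[1]),
                 tolerance = 1e-9)
    expect_equal(p$hiri, oracle_hiri(cv$glucose[1], cv$insulin[1]),
                 tolerance = 1e-9)
    expect_equal(p$matsuda, oracle_matsuda(cv$glucose, cv$insulin),
                 tolerance = 1e-9)
    expect_equal(p$disposition, oracle_di(cv$times, cv$glucose, cv$insulin),
                 tolerance = 1e-9)
    expect_equal(p$misi, oracle_misi_span(cv$times, cv$glucose, cv$insulin),
                 tolerance = 1e-9)
  }
})

test_that("compute_panel keeps the HIRI/HOMA-IR identity and compute_indices flags partial curves", {
  set.seed(5)
  for (rep in 1:50) {
    p <- compute_panel(random_curve())
    expect_equal(p$hiri, p$homa_ir * 22.5 * 18, tolerance = 1e-9)
  }
  curves <- list(
    random_curve("A"),
    ogtt_curve("B", "baseline", c(0, 30, 60, 120), c(8, 10, 12, 11),
               c(15, 22, 28, 30)))
  idx <- compute_indices(curves)
  expect_equal(idx$full_panel, c(TRUE, FALSE))
  expect_true(is.na(idx$matsuda[2]) && is.na(idx$misi[2]) && is.na(idx$disposition[2]))
  expect_equal(idx$homa_ir[2], 8 * 15 / 22.5)
  expect_equal(idx$hiri[2], 8 * 18 * 15)
})
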