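test_that("the eight flag combinations map to the eight labels exhaustively", {
  grid <- expand.grid(h = c(FALSE, TRUE), m = c(FALSE, TRUE), b = c(FALSE, TRUE))
  labels <- subtype_label(grid$h, grid$m, grid$b)
  expect_setequal(as.character(labels),
                  c("healthy", "HIR", "MIR", "CIR", "IB", "IB-HIR", "IB-MIR", "IB-CIR"))
  expect_equal(length(unique(labels)), 8L)
  # spot checks of the naming rule
  expect_equal(as.character(subtype_label(TRUE, FALSE, TRUE)), "IB-HIR")
  expect_equal(as.character(subtype_label(TRUE, TRUE, FALSE)), "CIR")
  expect_equal(as.character(subtype_label(FALSE, FALSE, FALSE)), "healthy")
  # label is a pure function of flags: CIR stem iff both IR flags
  for (r in seq_len(nrow(grid))) {
    lab <- as.character(subtype_label(grid$h[r], grid$m[r], grid$b[r]))
    expect_equal(grepl("CIR", lab), grid$h[r] && grid$m[r])
    expect_equal(grepl("IB", lab), grid$b[r])
  }
})

test_that("boundary equality always resolves to the healthy side", {
  cfg <- cutoff_config(hiri = 2000, misi = -5, disposition = 0.5)
  at_cut <- data.frame(hiri = 2000, misi = -5, disposition = 0.5)
  call <- classify_subtype(at_cut, cfg)
  expect_false(call$hepatic_ir)
  expect_false(call$muscle_ir)
  expect_false(call$impaired_bcf)
  expect_equal(as.character(call$label), "healthy")
  # an epsilon past each cutoff flips exactly that flag
  eps <- 1e-9
  worse <- data.frame(hiri = 2000 + eps, misi = -5 - eps, disposition = 0.5 - eps)
  call2 <- classify_subtype(worse, cfg)
  expect_true(call2$hepatic_ir && call2$muscle_ir && call2$impaired_bcf)
  expect_equal(as.character(call2$label), "IB-CIR")
})

test_that("classification is monotone in each index's impairment direction", {
  cfg <- cutoff_config(hiri = 2000, misi = -5, disposition = 0.5)
  n_flags <- function(df) {
    cl <- classify_subtype(df, cfg)
    cl$hepatic_ir + cl$muscle_ir + cl$impaired_bcf
  }
  set.seed(31)
  for (rep in 1:100) {
    p <- data.frame(hiri = runif(1, 100, 6000), misi = runif(1, -20, 0),
                    disposition = runif(1, 0, 3))
    base_flags <- n_flags(p)
    worse_h <- transform(p, hiri = hiri + runif(1, 0, 3000))
    worse_m <- transform(p, misi = misi - runif(1, 0, 10))
    worse_d <- transform(p, disposition = disposition - runif(1, 0, disposition))
    expect_gte(n_flags(worse_h), base_flags)
    expect_gte(n_flags(worse_m), base_flags)
    expect_gte(n_flags(worse_d), base_flags)
  }
})

test_that("Youden calibration finds the gap midpoint for separated classes", {
  # perfectly separated: cutoff must be the midpoint of the separating gap
  ref <- data.frame(
    hiri = c(seq(500, 900, length.out = 25), seq(3000, 5000, length.out = 25)),
    misi = c(seq(-3, -1, length.out = 25), seq(-20, -10, length.out = 25)),
    disposition = c(seq(1.5, 3, length.out = 25), seq(0.05, 0.4, length.out = 25)))
  fit <- diabetype(ref, rep(c("healthy", "T2D"), each = 25))
  expect_equal(unname(coef(fit)[["hiri"]]), (900 + 3000) / 2)
  expect_equal(unname(coef(fit)[["misi"]]), (-3 + -10) / 2)
  expect_equal(unname(coef(fit)[["disposition"]]), (0.4 + 1.5) / 2)
  expect_true(all(fit$stats$youden_j == 1))
  # training panels reclassify perfectly per index
  s <- summary(fit)
  expect_true(all(s$stats$train_accuracy == 1))
})

test_that("shuffled labels yield near-zero J with a warning; degenerate index falls back to the median", {
  set.seed(99)
  x <- data.frame(hiri = rnorm(60, 1000, 200), misi = rnorm(60, -5, 1),
                  disposition = rnorm(60, 1, 0.2))
  status <- sample(rep(c("healthy", "T2D"), each = 30))
  w <- capture_warnings(fit <- diabetype(x, status))
  expect_true(any(grepl("J", w)))
  expect_true(all(fit$stats$youden_j < 0.5))

  const <- data.frame(hiri = rep(1000, 60), misi = rnorm(60, -5, 1),
                      disposition = c(rnorm(30, 2, 0.1), rnorm(30, 0.2, 0.1)))
  w2 <- capture_warnings(fit2 <- diabetype(const, rep(c("healthy", "T2D"), each = 30)))
  expect_true(any(grepl("constant", w2)))
  expect_equal(fit2$cutoffs$hiri, 1000)
  expect_true(fit2$stats$degenerate[fit2$stats$index == "hiri"])
})

test_that("calibration rejects single-class and undersized references", {
  x <- data.frame(hiri = rnorm(50, 1000), misi = rnorm(50, -5),
                  disposition = rnorm(50, 1))
  expect_error(diabetype(x, rep("T2D", 50)), "both classes")
  expect_error(diabetype(x, rep(c("healthy", "T2D"), c(45, 5))), "at least 20")
  expect_error(diabetype(x, rep(c("healthy", "sick"), each = 25)), "healthy")
})

test_that("the formula interface matches the default method", {
  set.seed(12)
  ref <- data.frame(
    hiri = c(rnorm(30, 800, 100), rnorm(30, 4000, 500)),
    misi = c(rnorm(30, -2, 0.5), rnorm(30, -15, 3)),
    disposition = c(rnorm(30, 2, 0.3), rnorm(30, 0.2, 0.05)),
    status = rep(c("healthy", "T2D"), each = 30))
  f1 <- diabetype(ref[1:3], ref$status)
  f2 <- diabetype(status ~ hiri + misi + disposition, data = ref)
  expect_equal(coef(f1), coef(f2))
  pred <- predict(f2, data.frame(hiri = 4000, misi = -14, disposition = 0.2))
  expect_equal(as.character(pred$label), "IB-CIR")
})

test_that("calibrated cutoffs agree with pROC's Youden-optimal threshold", {
  skip_if_not_installed("pROC")
  set.seed(77)
  x <- c(rnorm(40, 0, 1), rnorm(40, 2.2, 1))
  d <- rep(c(0, 1), each = 40)
  ref <- data.frame(hiri = x, misi = -x, disposition = -x)
  fit <- diabetype(ref, ifelse(d == 1, "T2D", "healthy"))
  roc <- pROC::roc(d, x, direction = "<", quiet = TRUE)
  best <- pROC::coords(roc, "best", best.method = "youden", ret = "threshold")
  expect_equal(unname(coef(fit)[["hiri"]]), best$threshold[1], tolerance = 1e-8)
})

test_that("subtype_flow tabulates per-visit counts, transitions and missing visits", {
  # nobody changes: transition matrices are diagonal
  calls <- expand.grid(participant_id = paste0("P", 1:4),
                       visit = c("baseline", "month3", "month6"),
                       stringsAsFactors = FALSE)
  calls$label <- rep(c("IB-HIR", "IB", "CIR", "healthy"), 3)
  fl <- subtype_flow(calls)
  for (tr in fl$transitions) {
    off_diag <- tr; diag(off_diag) <- 0
    expect_true(all(off_diag == 0))
  }
  expect_equal(unname(fl$per_visit["IB-HIR", ]), c(1, 1, 1))

  # a participant absent at one visit is counted as missing
  calls2 <- calls[!(calls$participant_id == "P2" & calls$visit == "month3"), ]
  fl2 <- subtype_flow(calls2)
  expect_equal(unname(fl2$per_visit["missing", "month3"]), 1)
  expect_equal(sum(fl2$per_visit[, "month3"]), 4)

  expect_error(subtype_flow(rbind(calls, calls[1, ])), "one subtype call")
})
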