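test_that("noiseless decay fits are self-consistent and match the grid oracle", {
  t <- default_grid
  f1 <- fitDecay(2^(-t / 5), t)
  expect_equal(f1$half_life, 5, tolerance = 1e-6)
  expect_equal(f1$eff, 1, tolerance = 1e-6)
  expect_equal(f1$r_squared, 1, tolerance = 1e-9)

  y <- 0.8 * 2^(-t / 3) + 0.2
  f2 <- fitDecay(y, t)
  expect_equal(f2$half_life, 3, tolerance = 1e-4)
  expect_equal(f2$eff, 0.8, tolerance = 1e-4)
  oracle <- grid_oracle_ss(y, t, thRange = c(0.1, 60))
  expect_lte(f2$ss_res, oracle$ss + 1e-8)
})

test_that("optimizer never loses to the exhaustive grid search", {
  t <- default_grid
  set.seed(7)
  for (i in 1:40) {
    th <- rlnorm(1, log(4), 0.8)
    eff <- runif(1, 0.3, 1)
    y <- (eff * 2^(-t / th) + 1 - eff) * exp(rnorm(length(t), 0, 0.1))
    y <- y / y[1]
    f <- fitDecay(y, t)
    expect_lte(f$ss_res, grid_oracle_ss(y, t)$ss + 1e-8)
  }
})

test_that("degenerate series are reported unfit", {
  f <- fitDecay(c(1, 1, 1, 1), c(0, 1, 2, 3))
  expect_false(f$converged)
  expect_true(is.na(f$r_squared))
  expect_identical(classifyFit(f, meanRawSignal = 1)$status, "unfit")
})

test_that("series contracts are enforced", {
  expect_error(fitDecay(c(1, 0.5), c(0, 1)), class = "tuChase_insufficient_data")
  expect_error(fitDecay(c(1, NA, 0.2), c(0, 1, 2)), class = "tuChase_data")
  expect_error(fitDecay(c(1, 0.7, 0.5), c(1, 2, 3)), class = "tuChase_input")
  expect_error(fitSynthesis(c(1), c(0)), class = "tuChase_insufficient_data")
  expect_error(fitDecayFixedEff(c(1, 0.5, 0.2), c(0, 1, 2), eff = 1.2),
               class = "tuChase_invalid_parameter")
})

test_that("fixed-efficiency fits expose the naive-model bias", {
  t <- default_grid
  y_pure <- 2^(-t / 5)
  expect_equal(fitDecayFixedEff(y_pure, t, eff = 1)$half_life, 5,
               tolerance = 1e-6)

  y_ineff <- 0.8 * 2^(-t / 5) + 0.2
  naive <- fitDecayFixedEff(y_ineff, t, eff = 1)
  expect_gt(naive$half_life, 5)
  # independent 1-D oracle: dense grid minimization of the naive SS
  ths <- exp(seq(log(0.1), log(600), length.out = 20000))
  ss <- vapply(ths, function(th) sum((y_ineff - 2^(-t / th))^2), numeric(1))
  expect_equal(naive$half_life, ths[which.min(ss)], tolerance = 1e-3)
  expect_lte(naive$ss_res, min(ss) + 1e-8)

  matched <- fitDecayFixedEff(y_ineff, t, eff = 0.8)
  expect_equal(matched$half_life, 5, tolerance = 1e-4)
})

test_that("the free-efficiency model never fits worse than the clamped one", {
  t <- default_grid
  set.seed(13)
  for (i in 1:20) {
    th <- rlnorm(1, log(4), 0.7)
    eff <- rbeta(1, 20, 2)
    y <- (eff * 2^(-t / th) + 1 - eff) * exp(rnorm(length(t), 0, 0.08))
    y <- y / y[1]
    full <- fitDecay(y, t)
    clamped <- fitDecayFixedEff(y, t, eff = 1)
    expect_gte(full$r_squared, clamped$r_squared - 1e-12)
  }
})

test_that("synthesis fits are ordinary least squares", {
  f <- fitSynthesis(c(0, 1, 2), c(0, 1, 2))
  expect_equal(f$ks, 1)
  expect_equal(f$offset, 0)
  expect_equal(f$r_squared, 1)

  flat <- fitSynthesis(c(1, 1), c(0, 2))
  expect_equal(flat$ks, 0)
  expect_equal(flat$offset, 1)

  t4 <- 0:3
  y4 <- 1 - 2^(-t4 / 10)
  f4 <- fitSynthesis(y4, t4)
  # closed-form OLS slope on the four analytic points
  expect_equal(f4$ks, sum((t4 - mean(t4)) * (y4 - mean(y4))) /
                 sum((t4 - mean(t4))^2), tolerance = 1e-12)
  expect_equal(f4$ks, 0.0625725239, tolerance = 1e-8)
  expect_lt(abs(f4$ks - log(2) / 10) / (log(2) / 10), 0.10)
})

test_that("fit classification applies the reporting thresholds", {
  t <- default_grid
  base <- fitDecay(0.9 * 2^(-t / 4) + 0.1, t)
  ok <- classifyFit(set_r2(base, 0.96), meanRawSignal = 1)
  expect_identical(ok$status, "ok")
  expect_true(ok$high_quality)
  poor <- classifyFit(set_r2(base, 0.79), meanRawSignal = 1)
  expect_identical(poor$status, "poor_fit")
  border <- classifyFit(set_r2(base, 0.90), meanRawSignal = 1)
  expect_identical(border$status, "ok")
  expect_false(border$high_quality)
  # expression filter precedes everything else
  low <- classifyFit(set_r2(base, 0.99), meanRawSignal = 1e-6)
  expect_identical(low$status, "low_expression")
  expect_true(is.na(low$half_life))
})

test_that("fitTranscriptome runs the pipeline row-wise and counts statuses", {
  p <- sampleTrueParams(10, seed = 21)
  ce <- simulateDecayTimecourse(p, simulationDesign(noiseSigma = 0,
                                                    channel = "decay"))
  fits <- fitTranscriptome(ce)
  expect_equal(nrow(fits), 10)
  expect_true(all(fits$status == "ok"))
  expect_equal(metadata(fits)$statusCounts$ok, 10)
  expect_equal(as.data.frame(fits)$half_life, p$true_half_life,
               tolerance = 1e-4)
  expect_equal(as.data.frame(fits)$eff, p$true_eff, tolerance = 1e-3)

  # mixture with constant (information-free) series
  Y <- rbind(decaying = decay_curve(default_grid, 1, 4, 0.9),
             flat1 = rep(2, 6), flat2 = rep(0.5, 6))
  mixed <- fitTranscriptome(make_ce(Y))
  expect_equal(metadata(mixed)$statusCounts$unfit, 2)
  expect_equal(metadata(mixed)$statusCounts$ok, 1)
})

test_that("fits are invariant to row order and id relabeling", {
  p <- sampleTrueParams(8, seed = 31)
  ce <- simulateDecayTimecourse(p, simulationDesign(noiseSigma = 0.05,
                                                    channel = "decay", seed = 32))
  fits <- as.data.frame(fitTranscriptome(ce))
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6, 9)  # keep the spike row last
  ce_perm <- ChaseExperiment(assay(ce, "signal")[perm, ],
                             timepoints = timepoints(ce), spikeId = "rcc1_Xl",
                             channel = "decay")
  fits_perm <- as.data.frame(fitTranscriptome(ce_perm))
  m <- merge(fits, fits_perm, by = "transcript_id")
  expect_equal(m$half_life.x, m$half_life.y)
  expect_equal(m$eff.x, m$eff.y)
})

test_that("naive fits are biased upward relative to the efficiency model", {
  p <- sampleTrueParams(40, seed = 41)
  p$true_eff <- pmin(p$true_eff, 0.95)  # everyone genuinely below eff = 1
  ce <- simulateDecayTimecourse(p, simulationDesign(noiseSigma = 0.03,
                                                    channel = "decay", seed = 42))
  Y <- transcriptSignal(t0Normalize(spikeNormalize(ce)))
  t <- timepoints(ce)
  th_model <- vapply(seq_len(nrow(Y)),
                     function(i) fitDecay(Y[i, ], t)$half_life, numeric(1))
  th_naive <- vapply(seq_len(nrow(Y)),
                     function(i) fitDecayFixedEff(Y[i, ], t, eff = 1)$half_life,
                     numeric(1))
  expect_gt(mean(th_naive), mean(th_model))
  expect_gt(mean(th_naive > th_model), 0.9)
})

test_that("low-noise transcriptome recovery is accurate in the typical range", {
  p <- sampleTrueParams(300, seed = 51)
  ce <- simulateDecayTimecourse(p, simulationDesign(noiseSigma = 0.01,
                                                    channel = "decay", seed = 52))
  fits <- as.data.frame(fitTranscriptome(ce))
  rel <- abs(fits$half_life - p$true_half_life) / p$true_half_life
  expect_gt(mean(rel <= 0.10, na.rm = TRUE), 0.95)
  expect_lt(median(abs(fits$eff - p$true_eff), na.rm = TRUE), 0.02)
})
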