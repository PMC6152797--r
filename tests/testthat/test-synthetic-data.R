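test_that("sampleTrueParams respects its contracts", {
  empty <- sampleTrueParams(0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("transcript_id", "true_half_life", "true_abundance",
                        "true_eff", "steady_state"))

  a <- sampleTrueParams(1000, seed = 7)
  b <- sampleTrueParams(1000, seed = 7)
  expect_identical(a, b)
  c <- sampleTrueParams(1000, seed = 8)
  expect_false(identical(a, c))

  expect_true(all(a$true_half_life > 0))
  expect_true(all(a$true_abundance > 0))
  expect_true(all(a$true_eff > 0 & a$true_eff <= 1))
  expect_false(anyDuplicated(a$transcript_id) > 0)

  expect_error(sampleTrueParams(-1), class = "tuChase_invalid_parameter")
  expect_error(sampleTrueParams(10, medianHalfLife = 0),
               class = "tuChase_invalid_parameter")
  expect_error(sampleTrueParams(10, effShape1 = -2),
               class = "tuChase_invalid_parameter")
})

test_that("sampled half-life marginal matches its lognormal target", {
  p <- sampleTrueParams(10000, medianHalfLife = 3.6, sdlogHalfLife = 0.7,
                        seed = 11)
  expect_lt(abs(median(p$true_half_life) - 3.6) / 3.6, 0.05)
  # skewed, order-of-magnitude spread
  expect_gt(quantile(p$true_half_life, 0.99) / quantile(p$true_half_life, 0.01),
            10)
})

test_that("noiseless decay channel evaluates the model exactly", {
  p <- data.frame(transcript_id = c("a", "b"),
                  true_half_life = c(5, 4.8), true_abundance = c(2, 1),
                  true_eff = c(1, 0.9), steady_state = TRUE)
  d <- simulationDesign(timepoints = c(0, 4.8, 5), noiseSigma = 0,
                        channel = "decay", seed = 1)
  ce <- simulateDecayTimecourse(p, d)
  sig <- transcriptSignal(ce)
  expect_equal(sig["a", "t0"], 2)              # t = 0 anchor is A
  expect_equal(sig["a", "t5"], 1.0)            # A * 2^-1, half-life definition
  expect_equal(sig["b", "t4.8"], 0.9 * 0.5 + 0.1)  # eff-modified curve
  expect_equal(spikeSignal(ce), rep(1, 3))
})

test_that("noiseless decay signal is decreasing and bounded", {
  p <- sampleTrueParams(20, seed = 3)
  ce <- simulateDecayTimecourse(p, simulationDesign(noiseSigma = 0,
                                                    channel = "decay"))
  sig <- transcriptSignal(ce)
  for (i in seq_len(nrow(sig))) {
    expect_true(all(diff(sig[i, ]) < 0))
    expect_true(all(sig[i, ] <= p$true_abundance[i] + 1e-12))
    expect_true(all(sig[i, ] >=
                      p$true_abundance[i] * (1 - p$true_eff[i]) - 1e-12))
  }
})

test_that("synthesis channel starts at zero, saturates, and is monotone", {
  p <- data.frame(transcript_id = "a", true_half_life = 5,
                  true_abundance = 1, true_eff = 1, steady_state = TRUE)
  d <- simulationDesign(timepoints = c(0, 1, 2, 5, 500), noiseSigma = 0,
                        channel = "synthesis", seed = 1)
  ce <- simulateSynthesisTimecourse(p, d)
  y <- as.numeric(transcriptSignal(ce))
  expect_equal(y[1], 0)
  expect_true(all(diff(y) >= 0))
  expect_equal(y[5], 1, tolerance = 1e-6)  # plateau at A for eff = 1
})

test_that("decay and synthesis channels conserve the pool at eff = 1", {
  p <- sampleTrueParams(10, seed = 5)
  p$true_eff <- 1
  dd <- simulationDesign(noiseSigma = 0, channel = "decay", seed = 2)
  ds <- simulationDesign(noiseSigma = 0, channel = "synthesis", seed = 2)
  U <- transcriptSignal(simulateDecayTimecourse(p, dd))
  L <- transcriptSignal(simulateSynthesisTimecourse(p, ds))
  expect_equal(unname(U + L),
               matrix(p$true_abundance, nrow(U), ncol(U)),
               tolerance = 1e-12)
})

test_that("simulation is seed-reproducible and seed-sensitive", {
  p <- sampleTrueParams(25, seed = 1)
  d1 <- simulationDesign(noiseSigma = 0.1, channel = "decay", seed = 99)
  d2 <- simulationDesign(noiseSigma = 0.1, channel = "decay", seed = 100)
  expect_identical(assay(simulateDecayTimecourse(p, d1), "signal"),
                   assay(simulateDecayTimecourse(p, d1), "signal"))
  expect_false(identical(assay(simulateDecayTimecourse(p, d1), "signal"),
                         assay(simulateDecayTimecourse(p, d2), "signal")))
})

test_that("channel/design mismatches and bad params are rejected", {
  p <- sampleTrueParams(3, seed = 1)
  expect_error(
    simulateDecayTimecourse(p, simulationDesign(channel = "synthesis")),
    class = "tuChase_unsupported_design")
  expect_error(
    simulateSynthesisTimecourse(p, simulationDesign(channel = "decay")),
    class = "tuChase_unsupported_design")
  p$steady_state <- FALSE
  expect_error(simulateDecayTimecourse(p, simulationDesign(channel = "decay")),
               class = "tuChase_unsupported_design")
  expect_error(simulationDesign(timepoints = c(1, 2, 3)))   # must start at 0
  expect_error(simulationDesign(timepoints = c(0, 2, 2)))   # strictly increasing
  expect_error(simulationDesign(noiseSigma = -0.1))
})

test_that("optional Poisson counting layer is seeded and preserves scale", {
  p <- sampleTrueParams(10, seed = 2)
  d <- simulationDesign(noiseSigma = 0.05, channel = "decay", seed = 5,
                        poissonScale = 100)
  ce1 <- simulateDecayTimecourse(p, d)
  ce2 <- simulateDecayTimecourse(p, d)
  expect_identical(assay(ce1, "signal"), assay(ce2, "signal"))
  sig <- transcriptSignal(ce1)
  expect_true(all(sig >= 0))
  expect_true(all(abs(sig * 100 - round(sig * 100)) < 1e-9))
})

test_that("naive exponential fits overestimate half-life, worse as eff drops", {
  bias <- inefficiencyBias(effs = c(1, 0.9, 0.8, 0.6), halfLife = 5)
  expect_equal(bias$naive_half_life[1], 5, tolerance = 1e-6)
  expect_true(all(bias$bias[-1] > 0))
  expect_true(all(diff(bias$naive_half_life) > 0))  # monotone in falling eff
})
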