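# Small in-code fixtures shared across test files.

default_grid <- c(0, 2, 4, 8, 16, 32)

decay_curve <- function(t, A, Th, eff) A * (eff * 2^(-t / Th) + (1 - eff))

# Build a ChaseExperiment from a transcript signal matrix plus a unit spike.
make_ce <- function(Y, t = default_grid, spike = rep(1, length(t)),
                    channel = "decay", ...) {
  if (is.null(rownames(Y))) rownames(Y) <- paste0("tx", seq_len(nrow(Y)))
  sig <- rbind(Y, spikein = spike)
  ChaseExperiment(sig, timepoints = t, spikeId = "spikein",
                  channel = channel, ...)
}

# Independent 2-D grid-search oracle for the decay model: exhaustive scan
# over a log-spaced Th grid crossed with an eff grid, no profiling shared
# with the implementation under test.
grid_oracle_ss <- function(y, t, thRange = c(0.1, 600), effRange = c(0.01, 1),
                           nTh = 400, nEff = 200) {
  ths <- exp(seq(log(thRange[1]), log(thRange[2]), length.out = nTh))
  effs <- seq(effRange[1], effRange[2], length.out = nEff)
  yc <- y - 1
  best <- Inf
  best_th <- NA_real_
  best_eff <- NA_real_
  for (th in ths) {
    xc <- 2^(-t / th) - 1
    a <- sum(xc * xc)
    b <- sum(yc * xc)
    cc <- sum(yc * yc)
    ss <- cc - 2 * effs * b + effs^2 * a
    i <- which.min(ss)
    if (ss[i] < best) {
      best <- ss[i]
      best_th <- th
      best_eff <- effs[i]
    }
  }
  list(ss = best, half_life = best_th, eff = best_eff)
}

# Brute-force exact two-sided signed-rank p-value: enumerate all 2^n sign
# assignments of the absolute differences.
enum_signed_rank_p <- function(control, treated) {
  d <- treated - control
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  W_all <- signs %*% r
  p_le <- mean(W_all <= W_obs + 1e-9)
  p_ge <- mean(W_all >= W_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

set_r2 <- function(fit, r2) {
  fit$r_squared <- r2
  fit
}
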