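# brute-force oracle for the dF/F baseline: per-sample loops
oracle_dff <- function(soma, npil, t1, t2, fr, coeff = 0.7) {
  f <- soma - coeff * npil
  n <- length(f)
  w1 <- max(1, round(t1 * fr)); if (w1 %% 2 == 0) w1 <- w1 + 1
  half <- (w1 - 1) / 2
  sm <- vapply(seq_len(n), function(i)
    mean(f[max(1, i - half):min(n, i + half)]), numeric(1))
  w2 <- round(t2 * fr)
  f0 <- vapply(seq_len(n), function(i)
    min(sm[max(1, i - w2 + 1):i]), numeric(1))
  eps <- 1e-6 * quantile(f, 0.95, names = FALSE)
  if (!is.finite(eps) || eps <= 0) eps <- 1e-6
  (f - f0) / pmax(f0, eps)
}

test_that("compute_dff matches the neuropil-correction and baseline rules", {
  n <- 200; fr <- 5
  # constant traces: corrected F = 6.5, dff identically 0
  soma <- matrix(10, 1, n); npil <- matrix(5, 1, n)
  d <- compute_dff(soma, npil, preprocess_config(), fr)
  expect_equal(as.numeric(d), rep(0, n))
  # step trace: dff ~ 1 at the plateau while the old baseline persists
  soma2 <- matrix(10, 1, n); soma2[1, 101:n] <- 20
  d2 <- compute_dff(soma2, NULL, preprocess_config(t1 = 1, t2 = 15), fr)
  o2 <- oracle_dff(soma2[1, ], 0 * soma2[1, ], 1, 15, fr)
  expect_equal(as.numeric(d2), o2, tolerance = 1e-10)
  expect_equal(d2[1, 120], 1, tolerance = 0.05)
  # random trace against the brute-force oracle
  set.seed(11)
  soma3 <- matrix(50 + cumsum(rnorm(n)) + rexp(n), 1, n)
  npil3 <- matrix(20 + rnorm(n), 1, n)
  d3 <- compute_dff(soma3, npil3, preprocess_config(), fr)
  expect_equal(as.numeric(d3), oracle_dff(soma3[1, ], npil3[1, ], 1, 15, fr),
               tolerance = 1e-10)
})

test_that("compute_dff handles degenerate input and scales", {
  n <- 120; fr <- 6
  z <- matrix(0, 1, n)
  expect_warning(d <- compute_dff(z, z, preprocess_config(), fr),
                 "baseline floor")
  expect_equal(as.numeric(d), rep(0, n))
  # scale invariance: k * (soma, npil) leaves dff unchanged
  set.seed(3)
  soma <- matrix(50 + rexp(n, 0.2), 1, n); npil <- matrix(30 + rnorm(n), 1, n)
  d1 <- compute_dff(soma, npil, preprocess_config(), fr)
  d2 <- compute_dff(3.7 * soma, 3.7 * npil, preprocess_config(), fr)
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-9)
  expect_error(compute_dff(soma, npil, preprocess_config(t1 = 0.01, t2 = 0.05),
                           fr),
               "configuration error")
})

test_that("bin_activity: uniform signal gives uniform rate and exact occupancy", {
  rec <- simple_session(n_laps = 6, dff = matrix(3, 2, 600))
  b <- bin_activity(rec, rec$envs$familiar, preprocess_config(),
                    signal_kind = "dff")
  expect_equal(dim(b$rate), c(6, 100, 2))
  occ_pos <- b$occupancy > 0
  expect_true(all(abs(b$rate[, , 1][occ_pos] - 3) < 1e-12))
  expect_equal(sum(b$p_i), 1)
})

test_that("a stationary bout leaves occupancy unchanged", {
  rec <- simple_session(n_laps = 6, dff = matrix(1, 1, 600))
  b0 <- bin_activity(rec, rec$envs$familiar, preprocess_config(), "dff")
  # splice a 60 s stationary bout (velocity 0.2 < 1 cm/s) into bin 40 of lap 3
  j <- which(rec$lap == 3 &
               vrplace:::position_to_bin(rec$position, 100, 100) == 40)[1]
  k <- 300; dt <- 0.2
  ins <- function(x, v) c(x[1:j], rep(v, k), x[(j + 1):length(x)])
  rec2 <- rec
  rec2$time <- c(rec$time[1:j], rec$time[j] + (1:k) * dt,
                 rec$time[(j + 1):600] + k * dt)
  rec2$position <- ins(rec$position, rec$position[j])
  rec2$velocity <- ins(rec$velocity, 0.2)
  rec2$lap <- as.integer(ins(rec$lap, 3))
  rec2$env <- ins(rec$env, "familiar")
  rec2$dff <- matrix(1, 1, 600 + k)
  b1 <- bin_activity(rec2, rec2$envs$familiar, preprocess_config(), "dff")
  expect_equal(b1$occupancy, b0$occupancy, tolerance = 1e-12)
})

test_that("bin_activity matches a brute-force per-sample accumulation", {
  set.seed(21)
  sim <- cached_sim("tele_small",
                    scenario_config("teleportation", seed = 7, n_cells = 12,
                                    n_laps_fam = 10, n_laps_nov = 10))
  rec <- sim$rec
  env <- rec$envs$familiar
  cfg <- preprocess_config()
  b <- bin_activity(rec, env, cfg, "deconv")
  # oracle: loop over every retained sample
  dt <- c(diff(rec$time), 1 / rec$frame_rate_hz)
  bins <- vrplace:::position_to_bin(rec$position, env$track_length, env$n_bins)
  num <- array(0, dim(b$rate)); occ <- matrix(0, b$n_laps, env$n_bins)
  for (s in seq_along(rec$time)) {
    if (rec$env[s] != env$name) next
    if (rec$velocity[s] < cfg$speed_floor) next
    l <- match(rec$lap[s], b$lap_ids)
    if (is.na(l)) next
    occ[l, bins[s]] <- occ[l, bins[s]] + dt[s]
    num[l, bins[s], ] <- num[l, bins[s], ] + rec$deconv[, s]  # counts
  }
  expect_equal(b$occupancy, occ, tolerance = 1e-12)
  rate_o <- num / ifelse(array(occ, dim(num)) > 0, array(occ, dim(num)), NA)
  expect_equal(b$rate, rate_o, tolerance = 1e-12)
  # total retained time is invariant to the bin count
  b50 <- bin_activity(rec, environment_spec(env$name, env$track_length,
                                            n_bins = 50L,
                                            reward_bins = env$reward_bins,
                                            tunnel_bins = 1L),
                      cfg, "deconv")
  expect_equal(sum(b50$occupancy), sum(b$occupancy), tolerance = 1e-9)
})

test_that("bin_activity is equivariant to circular relabeling of bins", {
  rec <- simple_session(n_laps = 6, n_cells = 1)
  set.seed(5)
  rec$dff <- matrix(rexp(600), 1, 600)
  env <- rec$envs$familiar
  b <- bin_activity(rec, env, preprocess_config(), "dff")
  shift_cm <- 30  # exactly 30 bins on this 100 cm / 100 bin track
  rec2 <- rec
  rec2$position <- (rec$position + shift_cm) %% env$track_length
  # rotating positions must not change lap completeness: disable the drop
  cfg <- preprocess_config(drop_partial_laps = FALSE)
  b1 <- bin_activity(rec, env, cfg, "dff")
  b2 <- bin_activity(rec2, env, cfg, "dff")
  rot <- ((seq_len(100) - 1 + 30) %% 100) + 1
  expect_equal(b2$rate[, rot, 1], b1$rate[, , 1], tolerance = 1e-12)
  expect_equal(b2$occupancy[, rot], b1$occupancy, tolerance = 1e-12)
})

test_that("deconv fallback uses the positive part of the dF/F derivative", {
  rec <- simple_session(n_laps = 6, n_cells = 1)
  rec$dff <- matrix(sin(seq_len(600) / 10), 1, 600)
  expect_message(b <- bin_activity(rec, rec$envs$familiar, preprocess_config(),
                                   "deconv"),
                 "positive part")
  expect_true(all(b$rate >= 0, na.rm = TRUE))
})
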