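test_that("pv_matrix: self-comparison, shape, symmetry, independence", {
  set.seed(41)
  r <- array(rexp(9 * 100 * 30), c(9, 100, 30))
  b <- binned_from_rate(r)
  pm <- pv_matrix(b, b, laps_ref = 1:3, laps_other = 1:3)
  expect_equal(dim(pm$matrix), c(100, 100))
  expect_equal(diag(pm$matrix), rep(1, 100))
  expect_equal(pm$diag_mean, 1)
  expect_true(all(pm$matrix <= 1 + 1e-12 & pm$matrix >= -1 - 1e-12,
                  na.rm = TRUE))
  # swap symmetry up to transposition
  pm12 <- pv_matrix(b, b, laps_ref = 1:3, laps_other = 4:6)
  pm21 <- pv_matrix(b, b, laps_ref = 4:6, laps_other = 1:3)
  expect_equal(pm12$matrix, t(pm21$matrix), tolerance = 1e-12)
  # statistically independent populations decorrelate
  r2 <- array(rexp(9 * 100 * 30), c(9, 100, 30))
  pi2 <- pv_matrix(b, binned_from_rate(r2))
  expect_lt(abs(pi2$diag_mean), 0.1)
  # zero-variance PV excluded, diag_mean needs >= min_finite entries
  r3 <- r; r3[1:3, 1:60, ] <- 5
  pm3 <- pv_matrix(binned_from_rate(r3), b, laps_ref = 1:3, laps_other = 1:3)
  expect_true(all(is.na(pm3$matrix[1:60, ])))
  expect_true(is.na(pm3$diag_mean))  # only 40 finite diagonal bins
})

test_that("pv_timecourse variants track stability and remapping", {
  set.seed(42)
  n_cells <- 40
  # stable noiseless population: every diag_mean is 1
  stable <- planted_rate_tensor(15, 100, sample(100, n_cells, replace = TRUE),
                                width_bins = 4, amp = 2)
  bs <- binned_from_rate(stable)
  tc <- pv_timecourse(bs, bs, "final_familiar")
  expect_true(all(abs(tc$diag_mean - 1) < 1e-9))
  # abrupt global remap: familiar reference drops to ~0 on novel laps
  remap <- planted_rate_tensor(15, 100, sample(100, n_cells, replace = TRUE),
                               width_bins = 4, amp = 2, noise_sd = 0.3)
  bn <- binned_from_rate(remap)
  tc2 <- pv_timecourse(bs, bn, "final_familiar")
  fam_rows <- tc2$env == bs$env & tc2$start_lap <= 13
  expect_true(all(tc2$diag_mean[tc2$env == "env" & seq_len(nrow(tc2)) <= 5] > 0.6))
  # novel_late: reference laps 13-15 vs earlier intervals
  tc3 <- pv_timecourse(bs, bn, "novel_late")
  expect_equal(tc3$start_lap, c(1, 4, 7, 10))
  # offset7 pairs laps 1-3 with 8-10
  tc4 <- pv_timecourse(bn, variant = "offset7")
  expect_equal(tc4$start_lap[1], 1)
  expect_equal(nrow(tc4), 2)  # 1-3 vs 8-10, 4-6 vs 11-13
  # too few laps: skipped with message
  expect_message(
    sk <- pv_timecourse(binned_from_rate(stable[1:5, , , drop = FALSE]),
                        variant = "novel_late"),
    "skipped")
  expect_true(isTRUE(attr(sk, "skipped")))
})

test_that("group_activity z-scores lapwise rates and recovers a planted drop", {
  set.seed(43)
  n_laps <- 12; n_cells <- 30
  centers <- sample(100, n_cells, replace = TRUE)
  r_fam <- planted_rate_tensor(n_laps, 100, centers, width_bins = 5, amp = 2,
                               noise_sd = 0.02)
  r_nov <- r_fam * 0.5   # "both" cells halve their rate in the novel env
  bf <- binned_from_rate(r_fam); bn <- binned_from_rate(r_nov)
  pcc <- fake_pcc(rep(TRUE, n_cells))
  ga <- group_activity(bf, bn, pcc, pcc)
  expect_equal(ga$both_drop_frac, 0.5, tolerance = 0.02)
  expect_setequal(unique(ga$series$group), "both")
  # stationary statistics: z-scored group means ~ 0 on both halves
  ga0 <- group_activity(bf, bf, pcc, pcc)
  expect_lt(max(abs(tapply(ga0$series$mean_z, ga0$series$env, mean))), 0.3)
  # empty group raises a message, series still produced for others
  expect_message(
    ga2 <- group_activity(bf, bn, fake_pcc(rep(TRUE, n_cells)),
                          fake_pcc(rep(FALSE, n_cells))),
    "empty group")
  expect_setequal(unique(ga2$series$group), "familiar_only")
})

test_that("in_out_ratio: uniform activity is 1; planted ramps rise", {
  b <- binned_from_rate(array(2, c(8, 100, 3)))
  io <- in_out_ratio(b)
  expect_equal(io$ratio, rep(1, 8))
  expect_equal(round(io$n_cells), rep(3, 8))
  # in-field rate ramping over laps: increasing ratio, positive slope
  n_laps <- 10
  r <- planted_rate_tensor(n_laps, 100, c(30, 60), width_bins = 3, amp = 1,
                           base = 0.5)
  for (l in seq_len(n_laps)) r[l, , ] <- 0.5 + (r[l, , ] - 0.5) * l / n_laps
  io2 <- in_out_ratio(binned_from_rate(r))
  slope <- coef(lm(io2$ratio ~ io2$lap))[2]
  expect_gt(slope, 0)
  expect_true(all(diff(io2$ratio) > 0))
})

test_that("com_shift: stable fields sit at 0; planted drift is recovered", {
  n_laps <- 15; n_bins <- 100; tl <- 377; bin_cm <- tl / n_bins
  mkfield <- function(drift_cm_per_lap) {
    r <- array(0.02, c(n_laps, n_bins, 1))
    for (l in seq_len(n_laps)) {
      center <- (200 + drift_cm_per_lap * (l - 1)) %% tl
      cb <- vrplace:::position_to_bin(center, tl, n_bins)
      d <- vrplace:::circ_dist_bins(seq_len(n_bins), cb, n_bins)
      r[l, , 1] <- r[l, , 1] + 2 * exp(-d^2 / (2 * 4^2))
    }
    r
  }
  fld <- list(list(cell = 1, environment = "env", peak_bin = 53, start = 40,
                   end = 66, size_cm = 27 * bin_cm, active_laps = 1:n_laps,
                   onset_lap = 1))
  cs0 <- com_shift(binned_from_rate(mkfield(0), tl), fld)
  expect_true(all(abs(cs0$per_field$com_offset_cm) < 1e-6))
  csd <- com_shift(binned_from_rate(mkfield(-1), tl), fld)
  sl <- coef(lm(com_offset_cm ~ laps_since_onset, csd$per_field))[2]
  expect_equal(unname(sl), -1, tolerance = 0.2)
  # equivariance under circular rotation of the track
  r <- mkfield(0)
  rot <- ((seq_len(n_bins) - 1 - 50) %% n_bins) + 1
  fld_rot <- fld
  fld_rot[[1]][c("peak_bin", "start", "end")] <-
    lapply(fld[[1]][c("peak_bin", "start", "end")],
           function(b) ((b + 50 - 1) %% n_bins) + 1)
  cs_rot <- com_shift(binned_from_rate(r[, rot, , drop = FALSE], tl), fld_rot)
  expect_equal(cs_rot$per_field$com_offset_cm, cs0$per_field$com_offset_cm,
               tolerance = 1e-6)
})

test_that("field_size_by_lap: constant fields are 1; widening fields grow", {
  n_laps <- 12; n_bins <- 100; tl <- 377
  r <- planted_rate_tensor(n_laps, n_bins, 50, width_bins = 5, amp = 2)
  fld <- list(list(cell = 1, environment = "env", peak_bin = 50, start = 35,
                   end = 65, size_cm = 31 * tl / n_bins,
                   active_laps = 1:n_laps, onset_lap = 1))
  fs <- field_size_by_lap(binned_from_rate(r, tl), fld)
  expect_equal(fs$per_field$size_norm, rep(1, n_laps))
  # widening: sigma grows with lap
  r2 <- array(0.02, c(n_laps, n_bins, 1))
  d <- vrplace:::circ_dist_bins(seq_len(n_bins), 50, n_bins)
  for (l in seq_len(n_laps))
    r2[l, , 1] <- 0.02 + 2 * exp(-d^2 / (2 * (2 + 0.5 * l)^2))
  fs2 <- field_size_by_lap(binned_from_rate(r2, tl), fld)
  expect_gt(coef(lm(size_norm ~ lap, fs2$per_field))[2], 0)
  expect_true(all(diff(fs2$per_field$size_bins) >= 0))
})
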