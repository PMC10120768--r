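# rate tensor whose single cell fires a fixed distance behind a (possibly
# per-lap shifting) landmark bin
object_locked_tensor <- function(n_laps, n_bins, landmark_bins,
                                 offset_bins = 1, amp = 3, base = 0.05) {
  r <- array(base, c(n_laps, n_bins, 1))
  for (l in seq_len(n_laps)) {
    cb <- ((landmark_bins[l] - offset_bins - 1) %% n_bins) + 1
    d <- vrplace:::circ_dist_bins(seq_len(n_bins), cb, n_bins)
    r[l, , 1] <- r[l, , 1] + amp * exp(-d^2 / (2 * 1.2^2))
  }
  r
}

slot_bins_default <- function() {
  vrplace:::position_to_bin(160 + (0:5) * 31.5, 377, 100L)
}

test_that("align_activity extracts the 4-bin window and follows landmarks", {
  cfg <- object_tuning_config()
  n_laps <- 10
  # fixed landmark, fixed field: aligned rows identical across laps
  r <- object_locked_tensor(n_laps, 100, rep(50, n_laps))
  b <- binned_from_rate(r)
  al <- align_activity(b, 1, 50, cfg)
  expect_equal(dim(al), c(n_laps, 4))
  expect_true(all(apply(al, 2, function(x) diff(range(x)) < 1e-12)))
  # shifting landmark with an object-locked cell: aligned traces still
  # identical across laps despite shifting positions
  set.seed(61)
  lm_bins <- sample(slot_bins_default(), n_laps, replace = TRUE)
  r2 <- object_locked_tensor(n_laps, 100, lm_bins)
  al2 <- align_activity(binned_from_rate(r2), 1, lm_bins, cfg)
  expect_true(all(apply(al2, 2, function(x) diff(range(x)) < 1e-12)))
  # and the peak sits one bin behind the landmark (window index 2 of
  # (b-2, b-1, b, b+1))
  expect_equal(which.max(colMeans(al2)), 2L, ignore_attr = TRUE)
  # landmark in the tunnel is rejected
  expect_error(align_activity(b, 1, 1, cfg, tunnel_bins = c(1:4, 97:100)),
               "tunnel")
})

test_that("shuffle_null has 1000 draws and matches a brute-force oracle", {
  set.seed(62)
  n_laps <- 8
  r <- array(rexp(n_laps * 100), c(n_laps, 100, 1))
  b <- binned_from_rate(r)
  slots <- slot_bins_default()
  cfg <- object_tuning_config(n_shuffles = 1000)
  null <- shuffle_null(b, 1, slots, cfg, seed = 7)
  expect_equal(length(null$win_means), 1000)
  expect_equal(dim(null$bin_means), c(1000, 4))
  # brute-force re-run with the same seed: plain loops, no shared code path
  set.seed(7)
  draws <- matrix(sample.int(6, n_laps * 1000, replace = TRUE), n_laps, 1000)
  win_o <- numeric(1000); bin_o <- matrix(0, 1000, 4)
  for (dd in 1:1000) {
    vals <- matrix(NA_real_, n_laps, 4)
    for (l in seq_len(n_laps)) {
      sb <- slots[draws[l, dd]]
      wb <- ((sb + 1 - (4:1)) %% 100) + 1  # (b-2, b-1, b, b+1)
      vals[l, ] <- r[l, wb, 1]
    }
    bin_o[dd, ] <- colMeans(vals)
    win_o[dd] <- mean(vals)
  }
  expect_equal(null$win_means, win_o, tolerance = 1e-12)
  expect_equal(quantile(null$bin_means[, 2], 0.975),
               quantile(bin_o[, 2], 0.975), tolerance = 1e-12)
  # spatially uniform cell: null concentrates at the cell's mean
  bu <- binned_from_rate(array(2, c(n_laps, 100, 1)))
  nu <- shuffle_null(bu, 1, slots, cfg, seed = 3)
  expect_true(all(abs(nu$win_means - 2) < 1e-12))
})

test_that("classify_tuning separates object- from position-locked cells", {
  set.seed(63)
  n_laps <- 14
  env <- vrplace:::make_env_geometry("object_env", 377, c(20L, 70L),
                                     with_zones = TRUE,
                                     lap_object_table =
                                       generate_object_table(n_laps, TRUE))
  slots <- slot_bins_default()
  tab <- env$lap_object_table
  # object-locked cell follows object 2 across its shifting slots
  lm_bins <- slots[tab[, 2]]
  r_obj <- object_locked_tensor(n_laps, 100, lm_bins) +
    array(abs(rnorm(n_laps * 100, 0, 0.05)), c(n_laps, 100, 1))
  cls_o <- classify_tuning(binned_from_rate(r_obj), env,
                           object_tuning_config(n_shuffles = 500), seed = 1)
  expect_equal(cls_o$table$category, "object")
  # position-locked cell at a slot: in the shifting configuration some
  # object occupies its slot on many laps, so object alignment may also
  # pass; at minimum it must be position-tuned
  r_pos <- object_locked_tensor(n_laps, 100, rep(slots[3], n_laps)) +
    array(abs(rnorm(n_laps * 100, 0, 0.05)), c(n_laps, 100, 1))
  cls_p <- classify_tuning(binned_from_rate(r_pos), env,
                           object_tuning_config(n_shuffles = 500), seed = 2)
  expect_true(cls_p$table$tuned_position)
  # fixed configuration: a position-locked cell at an occupied slot is "both"
  tab_fix <- matrix(rep(c(3L, 1L, 5L, 6L), each = n_laps), n_laps)
  env_fix <- vrplace:::make_env_geometry("object_env", 377, c(20L, 70L),
                                         with_zones = TRUE,
                                         lap_object_table = tab_fix)
  cls_b <- classify_tuning(binned_from_rate(r_pos), env_fix,
                           object_tuning_config(n_shuffles = 500), seed = 3)
  expect_equal(cls_b$table$category, "both")
})

test_that("classification is invariant to global rescaling of activity", {
  set.seed(64)
  n_laps <- 12
  env <- vrplace:::make_env_geometry("object_env", 377, c(20L, 70L),
                                     with_zones = TRUE,
                                     lap_object_table =
                                       generate_object_table(n_laps, TRUE))
  r <- object_locked_tensor(n_laps, 100, rep(slot_bins_default()[4], n_laps)) +
    array(abs(rnorm(n_laps * 100, 0, 0.05)), c(n_laps, 100, 1))
  c1 <- classify_tuning(binned_from_rate(r), env,
                        object_tuning_config(n_shuffles = 300), seed = 5)
  c2 <- classify_tuning(binned_from_rate(r * 12.5), env,
                        object_tuning_config(n_shuffles = 300), seed = 5)
  expect_equal(c1$table$category, c2$table$category)
  expect_equal(c1$slot_pass, c2$slot_pass)
  expect_equal(c1$slot_z, c2$slot_z, tolerance = 1e-9)
})
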