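test_that("spatial information matches closed forms", {
  # uniform rates: SI = 0
  b <- binned_from_rate(array(1.3, c(6, 100, 1)))
  expect_equal(spatial_information(b, 1, n_shuffles = 5, seed = 1)$si, 0)
  # two equal-occupancy bins, rates (2, 0): SI = 0.5*2*log2(2/1) = 1 bit/s
  r <- array(0, c(6, 2, 1)); r[, 1, 1] <- 2
  b2 <- binned_from_rate(r, track_length = 10)
  si2 <- spatial_information(b2, 1, n_shuffles = 100, seed = 2)
  expect_equal(si2$si, 1.0)
  expect_length(si2$shuffle, 100)
  # rate form scales linearly in a way fixed by the closed form:
  # k*(2,0) -> SI = k * (1 + log2(k) contribution); at k=2: 0.5*4*log2(4/2)=2
  r4 <- r * 2
  expect_equal(spatial_information(binned_from_rate(r4, 10), 1,
                                   n_shuffles = 2, seed = 1)$si, 2.0)
  # zero rate: SI defined as 0 with a flag
  s0 <- spatial_information(binned_from_rate(array(0, c(5, 4, 1)), 10), 1,
                            n_shuffles = 3, seed = 1)
  expect_equal(s0$si, 0)
  expect_equal(s0$flag, "zero_rate")
})

test_that("sparsity matches closed forms", {
  expect_equal(sparsity(binned_from_rate(array(2, c(5, 100, 1))), 1), 1)
  n <- 25
  r <- array(0, c(5, n, 1)); r[, 7, 1] <- 3
  expect_equal(sparsity(binned_from_rate(r, 100), 1), 1 / n)
  expect_true(is.na(sparsity(binned_from_rate(array(0, c(5, n, 1)), 100), 1)))
})

test_that("detect_fields applies the three-step criterion", {
  n_laps <- 20; n_bins <- 100; bin_cm <- 3.77
  tl <- n_bins * bin_cm
  mkb <- function(width_cm, active = NULL, center = 50) {
    r <- planted_rate_tensor(n_laps, n_bins, center,
                             width_bins = width_cm / bin_cm,
                             amp = 2, base = 0.02, shape = "cosine",
                             hash_amp = 0.3,
                             active_laps = if (is.null(active)) NULL else
                               list(active))
    binned_from_rate(r, track_length = tl)
  }
  expect_length(detect_fields(binned_from_rate(array(0, c(n_laps, n_bins, 1)),
                                               tl), 1), 0)
  # reliable ~40 cm field accepted with correct peak and size bounds
  f40 <- detect_fields(mkb(40), 1)
  expect_length(f40, 1)
  expect_equal(f40[[1]]$peak_bin, 50)
  expect_true(f40[[1]]$size_cm >= 20 && f40[[1]]$size_cm <= 150)
  expect_equal(f40[[1]]$onset_lap, 1)
  expect_equal(f40[[1]]$active_laps, 1:20)
  # same field active on only 3 of 20 laps: rejected at step 2
  # (brute-force oracle: count laps whose in-field peak beats 3.5x baseline)
  b3 <- mkb(40, active = c(2, 9, 15))
  r <- b3$rate[, , 1]
  q <- quantile(r, c(0.05, 0.5)); baseline <- q[2] - q[1]
  n_active <- sum(apply(r[, 45:55], 1, max) > 3.5 * baseline)
  expect_equal(n_active, 3)
  expect_lt(n_active, max(ceiling(20 / 3), 5))
  expect_length(detect_fields(b3, 1), 0)
  # 15 cm field: candidate found (beats 3.5x median) but eliminated at step 3
  b15 <- mkb(15)
  sm <- vrplace:::hann_smooth_circular(colMeans(b15$rate[, , 1]), 5)
  expect_gt(max(sm), 3.5 * median(sm))
  expect_length(detect_fields(b15, 1), 0)
  # > 150 cm field: eliminated at step 3
  expect_length(detect_fields(mkb(170), 1), 0)
  # fewer than 5 laps: skipped with a message
  expect_message(
    out <- detect_fields(binned_from_rate(array(1, c(4, n_bins, 1)), tl), 1),
    "fewer than 5 laps")
  expect_length(out, 0)
})

test_that("detect_fields is equivariant to circular rotation (incl. the seam)", {
  n_laps <- 15; n_bins <- 100; tl <- 377
  r <- planted_rate_tensor(n_laps, n_bins, 60, width_bins = 12, amp = 2,
                           shape = "cosine", hash_amp = 0.3)
  b <- binned_from_rate(r, tl)
  f0 <- detect_fields(b, 1)
  expect_length(f0, 1)
  for (shift in c(37, 40 - 60 + 1)) {  # second shift puts the peak at bin 1
    rot <- ((seq_len(n_bins) - 1 - shift) %% n_bins) + 1
    b2 <- binned_from_rate(r[, rot, , drop = FALSE], tl)
    f2 <- detect_fields(b2, 1)
    expect_length(f2, 1)
    expect_equal((f2[[1]]$peak_bin - shift - 1) %% n_bins + 1, f0[[1]]$peak_bin)
    expect_equal(f2[[1]]$size_cm, f0[[1]]$size_cm)
  }
})

test_that("classify_pcc recovers planted fields and rejects nulls", {
  set.seed(99)
  n_laps <- 18; n_bins <- 100; tl <- 377
  centers <- c(10, 25, 40, 55, 70, 85, rep(NA, 14))
  r <- planted_rate_tensor(n_laps, n_bins, centers, width_bins = 5, amp = 2,
                           base = 0.05, noise_sd = 0.05)
  b <- binned_from_rate(r, tl)
  res <- classify_pcc(b, seed = 4)
  expect_s3_class(res$table, "data.frame")
  expect_true(all(res$table$is_pcc[1:6]))
  expect_true(all(abs(res$table$peak_bin[1:6] - centers[1:6]) <= 1))
  # flat noisy cells should essentially never pass
  expect_lt(mean(res$table$is_pcc[7:20]), 0.15)
  expect_equal(res$table$is_pcc, res$table$n_fields > 0)
  expect_equal(ncol(res$si_shuffle), 100)
})

test_that("order_by_peak uses a held-out split and is reproducible", {
  n_laps <- 12; n_bins <- 50
  centers <- seq(5, 45, by = 5)
  r <- planted_rate_tensor(n_laps, n_bins, centers, width_bins = 2, amp = 1,
                           base = 0)
  b <- binned_from_rate(r, 100)
  o1 <- order_by_peak(b, seed = 10)
  o2 <- order_by_peak(b, seed = 10)
  expect_identical(o1, o2)
  # noiseless periodic cells: ordering identical whichever split is drawn
  o3 <- order_by_peak(b, seed = 999)
  expect_identical(o1$order, o3$order)
  expect_identical(o1$order, order(centers))
  # held-out matrix row maxima lie on the planted diagonal
  peaks_held <- apply(o1$matrix[o1$order, ], 1, which.max)
  expect_true(all(abs(peaks_held - sort(centers)) <= 2))
  # < 10 laps falls back to odd/even with a message
  b2 <- binned_from_rate(r[1:8, , , drop = FALSE], 100)
  expect_message(o4 <- order_by_peak(b2, seed = 1), "odd/even")
  expect_identical(o4$order, order(centers))
})
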