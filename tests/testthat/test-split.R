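mk_readings <- function(t, d) data.frame(time = t, depth = d)

test_that("monotone profiles contain no peaks", {
  r <- mk_readings(seq(0, 1200, 300), c(5, 20, 40, 25, 6))
  expect_equal(nrow(find_dive_peaks(r)), 0)
})

test_that("a prominent interior minimum is one peak", {
  r <- mk_readings(c(0, 300, 600), c(40, 10, 42))
  pk <- find_dive_peaks(r)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$prominence, 30)
  expect_equal(pk$peak_depth, 10)
  expect_false(pk$plateau)
})

test_that("sub-threshold prominence is ignored (over 1 m, strict)", {
  r <- mk_readings(c(0, 300, 600), c(40, 39.5, 40))
  expect_equal(nrow(find_dive_peaks(r)), 0)
  r2 <- mk_readings(c(0, 300, 600), c(40, 39, 40))  # exactly 1 m
  expect_equal(nrow(find_dive_peaks(r2)), 0)
})

test_that("plateaus are reported once, at the run's first reading", {
  r <- mk_readings(seq(0, 1200, 300), c(40, 5, 5, 5, 38))
  pk <- find_dive_peaks(r)
  expect_equal(nrow(pk), 1)
  expect_true(pk$plateau)
  expect_equal(pk$peak_time, 300)
  expect_equal(pk$run_end_idx, 4)
})

test_that("the speed rule follows the stated arithmetic", {
  pk <- data.frame(peak_idx = 2L, run_end_idx = 2L, peak_time = 300,
                   peak_depth = 4, prev_time = 0, prev_depth = 64,
                   next_time = 600, next_depth = 64, prominence = 60,
                   plateau = FALSE)
  dec <- decide_split(pk, threshold = 3, nominal_dt = 300)
  expect_equal(dec$v_up, 0.2)
  expect_equal(dec$t_surface_up, 5)  # (4 - 3) / 0.2
  expect_true(dec$split)
  expect_equal(dec$rule, "speed_up")

  pk$peak_depth <- 150
  pk$prev_depth <- pk$next_depth <- 165  # v = 0.05 m/s
  dec2 <- decide_split(pk, 3, 300)
  expect_equal(dec2$t_surface_up, (150 - 3) / 0.05)  # 2940 s
  expect_false(dec2$split)
  expect_equal(dec2$rule, "none")
})

test_that("plateau peaks split unconditionally", {
  pk <- data.frame(peak_idx = 2L, run_end_idx = 3L, peak_time = 300,
                   peak_depth = 5, prev_time = 0, prev_depth = 80,
                   next_time = 1200, next_depth = 80, prominence = 75,
                   plateau = TRUE)
  dec <- decide_split(pk, 3, 300)
  expect_true(dec$split)
  expect_equal(dec$rule, "plateau")
})

test_that("zero time spacing around a peak is an input error", {
  pk <- data.frame(peak_idx = 2L, run_end_idx = 2L, peak_time = 300,
                   peak_depth = 5, prev_time = 300, prev_depth = 40,
                   next_time = 600, next_depth = 40, prominence = 35,
                   plateau = FALSE)
  expect_error(decide_split(pk, 3, 300), "zero time spacing")
})

# build a merged low-resolution dive from two fast successive dives
merged_fixture <- function(surface_interval = 60, seed = 1) {
  dd <- data.frame(state = 1,
                   start_time = c(200, 200 + 1200 + surface_interval),
                   max_depth = c(45, 50), dive_time = 1200,
                   bottom_time = 700,
                   surface_interval = c(surface_interval, 900))
  ser <- render_depth_series(dd, dt = 1)
  low <- resample_series(ser, 300)
  list(truth = dd, low = low)
}

test_that("splitting conserves recorded samples and maxima", {
  fx <- merged_fixture(60)
  d <- label_phases(detect_dives(fx$low))
  sp <- split_merged_dives(d, nominal_dt = 300)
  expect_gte(nrow(sp), nrow(d))
  all_before <- do.call(rbind, d$readings)
  all_after <- unique(do.call(rbind, sp$readings))
  expect_equal(all_after[order(all_after$time), "time"],
               all_before$time)
  for (i in seq_len(nrow(sp)))
    expect_equal(sp$max_depth[i], max(sp$readings[[i]]$depth))
  # total in-dive time never grows
  expect_lte(sum(sp$end_time - sp$start_time),
             sum(d$end_time - d$start_time) + 1e-9)
})

test_that("splitting is idempotent", {
  fx <- merged_fixture(45)
  d <- label_phases(detect_dives(fx$low))
  sp1 <- split_merged_dives(d, nominal_dt = 300)
  sp2 <- split_merged_dives(sp1, nominal_dt = 300)
  expect_equal(nrow(sp2), nrow(sp1))
  expect_equal(sp2$start_time, sp1$start_time)
})

test_that("fast successive dives are recovered by splitting", {
  set.seed(4)
  hits <- 0
  trials <- 12
  for (i in seq_len(trials)) {
    fx <- merged_fixture(runif(1, 30, 250))
    d <- label_phases(detect_dives(fx$low))
    sp <- split_merged_dives(d, nominal_dt = 300)
    m <- match_dives(fx$truth, sp)
    if (!anyNA(m)) hits <- hits + 1
  }
  expect_gte(hits / trials, 0.9)
})
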