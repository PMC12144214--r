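test_that("a constant surface offset is removed exactly", {
  t <- seq(0, 5 * 86400, 300)
  ser <- depth_series(t, rep(1.5, length(t)))
  z <- zero_offset_correct(ser)
  expect_lt(max(abs(z$depth)), 0.05)
})

test_that("zero drift leaves a trace unchanged up to clamping", {
  dv <- simulate_dive_sequence(sim_config(), 100, seed = 2)
  ser <- render_depth_series(dv, dt = 300)
  z <- zero_offset_correct(ser)
  expect_lt(max(abs(z$depth - pmax(ser$depth, 0))), 0.05)
})

test_that("linear drift is recovered by the correction round trip", {
  dv <- simulate_dive_sequence(sim_config(), 400, seed = 5)
  dv <- dv[dv$start_time + dv$dive_time < 10 * 86400, ]
  span_days <- max(dv$start_time + dv$dive_time) / 86400
  ser <- render_depth_series(dv, dt = 300)
  surface_frac <- mean(ser$depth == 0)
  expect_gt(surface_frac, 0.3)
  drifted <- add_sensor_drift(ser, rate = 2 / span_days)  # 0 -> 2 m overall
  z <- zero_offset_correct(drifted)
  expect_lt(max(abs(z$depth[ser$depth == 0])), 0.25)
})

test_that("a short deployment falls back to a global offset", {
  t <- seq(0, 3600, 300)
  ser <- depth_series(t, rep(2, length(t)))
  expect_warning(z <- zero_offset_correct(ser), "global offset")
  expect_equal(max(abs(z$depth)), 0)
})

test_that("no readings beyond the threshold means no dives", {
  t <- seq(0, 3000, 300)
  ser <- depth_series(t, runif(length(t), 0, 2.9))
  expect_equal(nrow(detect_dives(ser)), 0)
})

test_that("boundary times interpolate the 3 m crossing on the 10 s grid", {
  ser <- depth_series(c(0, 300, 600), c(0, 6, 0), nominal_dt = 300)
  d <- detect_dives(ser)
  expect_equal(nrow(d), 1)
  expect_equal(d$start_time, 150)  # 0 -> 6 m crosses 3 m halfway
  expect_equal(d$end_time, 450)
  expect_equal(d$max_depth, 6)
})

test_that("boundary depths sit in [threshold, threshold + slope * step]", {
  dv <- simulate_dive_sequence(sim_config(), 150, seed = 13)
  ser <- render_depth_series(dv, dt = 300)
  d <- detect_dives(ser)
  for (i in seq_len(nrow(d))) {
    r <- d$readings[[i]]
    j <- which(ser$time == r$time[1])
    if (j > 1) {
      slope <- (ser$depth[j] - ser$depth[j - 1]) / 300
      dep <- approx(ser$time[(j - 1):j], ser$depth[(j - 1):j],
                    d$start_time[i])$y
      expect_gte(dep, 3 - 1e-9)
      expect_lte(dep, 3 + slope * 10 + 1e-9)
    }
  }
})

test_that("dives spanning transmission holes are flagged internal_gap", {
  t <- c(0, 300, 600, 1500, 1800, 2100)  # 900 s hole mid-dive
  dep <- c(0, 20, 25, 22, 18, 0)
  ser <- depth_series(t, dep, nominal_dt = 300)
  d <- detect_dives(ser)
  expect_equal(nrow(d), 1)
  expect_equal(d$excluded_reason, "internal_gap")
})

test_that("bottom phase covers exactly the depths over 80% of maximum", {
  dd <- data.frame(state = 1, start_time = 0, max_depth = 100,
                   dive_time = 1000, bottom_time = 400,
                   surface_interval = 300)
  ser <- render_depth_series(dd, dt = 1)
  d <- label_phases(detect_dives(ser), keep_profile = TRUE)
  expect_equal(nrow(d), 1)
  pr <- d$phases[[1]]
  expect_true(all(pr$depth[pr$phase == "bottom"] >
                    0.8 * d$max_depth - 0.8))  # one grid step of slack
  expect_true(all(pr$depth[pr$phase != "bottom"] <=
                    0.8 * d$max_depth + 0.8))
  expect_lt(abs(d$bottom_time - 400), 25)
  # phase sequence is descent* bottom+ ascent*
  expect_true(all(diff(match(pr$phase,
                             c("descent", "bottom", "ascent"))) >= 0))
})

test_that("a symmetric vee dive has equal descent and ascent durations", {
  dd <- data.frame(state = 1, start_time = 0, max_depth = 60,
                   dive_time = 600, bottom_time = 6,
                   surface_interval = 100)
  ser <- render_depth_series(dd, dt = 1)
  d <- label_phases(detect_dives(ser))
  desc <- d$bottom_enter - d$start_time
  asc <- d$end_time - d$bottom_exit
  expect_lt(abs(desc - asc), 10 + 1e-9)
})

test_that("a square dive is nearly all bottom phase", {
  dd <- data.frame(state = 1, start_time = 0, max_depth = 40,
                   dive_time = 600, bottom_time = 570,
                   surface_interval = 100)
  ser <- render_depth_series(dd, dt = 1)
  d <- label_phases(detect_dives(ser))
  expect_lt(abs(d$bottom_time - (d$end_time - d$start_time)),
            2 * 10 + 30)
  # phase durations sum to the dive duration within one grid step
  total <- (d$bottom_enter - d$start_time) + d$bottom_time +
    (d$end_time - d$bottom_exit)
  expect_equal(total, d$end_time - d$start_time)
})

test_that("detected maxima match generated maxima on 1 s renderings", {
  dv <- simulate_dive_sequence(sim_config(), 120, seed = 21)
  ser <- render_depth_series(dv, dt = 1)
  det <- detect_dives(ser)
  truth <- dv[dv$max_depth > 10, ]
  expect_equal(sum(det$max_depth > 10), nrow(truth))
  m <- match_dives(truth, det)
  expect_false(anyNA(m))
  expect_lt(max(abs(det$max_depth[m] - truth$max_depth)), 0.5)
})
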