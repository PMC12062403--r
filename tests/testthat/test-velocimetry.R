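test_that("track construction and the CSV round trip preserve the series", {
  tr <- track_series(0:9, x = (0:9) * 2, y = rep(1, 10), conf = 0.95)
  expect_s3_class(tr, "track_series")
  expect_error(track_series(c(0, 0, 1), 1:3, 1:3), "strictly increasing")
  expect_error(track_series(0:2, 1:3, 1:3, conf = 2), "\\[0, 1\\]")
  path <- tempfile(fileext = ".csv")
  write_tracks(tr, path)
  tr2 <- load_tracks(path, "plain")
  expect_equal(as.data.frame(tr2), as.data.frame(tr))
})

test_that("plain reader reports missing columns and low confidence rows", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("frame,x", "0,1", "1,2"), path)
  expect_error(load_tracks(path, "plain"), "missing columns: y")
  # a 3-row handcrafted file loads into 3 samples
  writeLines(c("frame,x,y,conf", "0,0,0,1", "1,1,0,1", "2,2,0,1"), path)
  tr <- load_tracks(path, "plain")
  expect_equal(nrow(tr), 3)
  # confidence 0.2 everywhere: all rows rejected at the 0.9 threshold
  writeLines(c("frame,x,y,conf",
               paste(0:9, 0:9, 0, 0.2, sep = ",")), path)
  tr <- load_tracks(path, "plain")
  expect_true(all(tr$conf < 0.9))
  expect_error(estimate_speed(tr), "insufficient data")
})

test_that("pose-estimation dialect with header triplets parses", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "scorer,model,model,model,model,model,model",
    "bodyparts,mouth,mouth,mouth,fin_tip,fin_tip,fin_tip",
    "coords,x,y,likelihood,x,y,likelihood",
    paste(0:5, 10 * (0:5), 0, 0.99, 5, sin(0:5), 0.95, sep = ",")), path)
  tr <- load_tracks(path, "dlc", bodypart = "mouth")
  expect_equal(nrow(tr), 6)
  expect_equal(tr$x, 10 * (0:5))
  tr2 <- load_tracks(path, "dlc", bodypart = "fin_tip")
  expect_equal(tr2$x, rep(5, 6))
  expect_error(load_tracks(path, "dlc", bodypart = "tail"), "not found")
})

test_that("speed estimation is exact on noiseless uniform motion", {
  tr <- gen_track("constant_velocity", v = 1, duration = 2, noise_px = 0)
  est <- estimate_speed(tr)
  expect_equal(est$series$u, rep(1, nrow(est$series)), tolerance = 1e-10)
  expect_equal(est$u_e, 1, tolerance = 1e-10)
})

test_that("speed estimation recovers a constant acceleration within 1%", {
  a <- 0.64
  tr <- gen_track("constant_acceleration", a = a, duration = 1.14,
                  noise_px = 0)
  est <- estimate_speed(tr)
  fit <- stats::lm(u ~ t, data = est$series)
  expect_equal(unname(coef(fit)["t"]), a, tolerance = 0.01)
})

test_that("speed is recovered within 5% under 1 px noise", {
  tr <- gen_track("constant_velocity", v = 1, duration = 2, noise_px = 1,
                  seed = 11)
  est <- estimate_speed(tr)
  mid <- est$series$u[20:100]
  expect_equal(mean(mid), 1, tolerance = 0.05)
})

test_that("speed estimate is translation invariant and scales with calibration", {
  tr <- gen_track("constant_velocity", v = 0.8, duration = 1.5,
                  noise_px = 0.5, seed = 3)
  est <- estimate_speed(tr)
  tr_shift <- tr
  tr_shift$x <- tr$x + 123; tr_shift$y <- tr$y - 45
  expect_equal(estimate_speed(tr_shift)$series$u, est$series$u)
  tr_scaled <- tr
  attr(tr_scaled, "scale") <- attr(tr, "scale") * 2
  expect_equal(estimate_speed(tr_scaled)$series$u, est$series$u * 2)
})

test_that("integrating the estimated speed recovers the displacement", {
  tr <- gen_track("constant_acceleration", a = 0.5, duration = 2,
                  noise_px = 0)
  est <- estimate_speed(tr)
  dt <- diff(est$series$t)
  disp <- sum(dt * (est$series$u[-1] + est$series$u[-nrow(est$series)]) / 2)
  truth <- attr(tr, "truth")
  i0 <- 2; i1 <- nrow(tr) - 1
  exact <- 0.5 * 0.5 * (tr$t[i1]^2 - tr$t[i0]^2)
  expect_equal(disp, exact, tolerance = 0.01)
})

test_that("fin frequency is recovered at 14 and 29 Hz from 60 fps signals", {
  for (f in c(14, 29)) {
    fr <- 0:59
    tr <- track_series(fr, x = rep(0, 60),
                       y = sin(2 * pi * f * fr / 60), fps = 60)
    est <- fin_frequency(tr)
    expect_equal(as.numeric(est), f, tolerance = attr(est, "quantum") / f,
                 info = sprintf("f = %g", f))
  }
  flat <- track_series(0:59, x = rep(0, 60), y = rep(1, 60), fps = 60)
  expect_error(fin_frequency(flat), "insufficient data")
})

test_that("frequency-speed correlation recovers known relations", {
  f <- c(10, 14, 18, 22, 29)
  fit <- correlate_f_u(f, 0.1 * f)
  expect_equal(fit$slope, 0.1, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  anti <- correlate_f_u(f, -0.05 * f + 3)
  expect_lt(anti$r, 0)
  expect_error(correlate_f_u(c(1, 1, 1), 1:3), "zero variance")
  # noisy synthetic pairs: slope recovered within its standard error
  set.seed(5)
  fs <- runif(30, 8, 30)
  us <- 0.08 * fs + rnorm(30, sd = 0.15)
  nf <- correlate_f_u(fs, us)
  expect_lt(abs(nf$slope - 0.08), 2 * nf$slope_se)
})
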