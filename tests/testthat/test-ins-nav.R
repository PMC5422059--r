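test_that("constant acceleration integrates to a * t at segment end", {
  n <- 300
  tr <- make_trace(n, acc_y = c(rep(0, 100), rep(1, 100), rep(0, 100)))
  mask <- manual_mask(n, 101, 201)
  v <- integrate_velocity(tr, mask)
  expect_equal(v$v_y[200], 1.0)          # 100 samples * 1 m/s^2 * 0.01 s
  expect_true(all(v$v_y[1:100] == 0))    # ZUPT before
  expect_true(all(v$v_y[201:300] == 0))  # ZUPT after
})

test_that("an all-static trace has identically zero velocity", {
  tr <- make_trace(200, acc_y = rnorm(200, 0, 0.03))
  mask <- build_mask(tr, mode = "NM")
  v <- integrate_velocity(tr, mask)
  expect_equal(v$v_x, rep(0, 200))
  expect_equal(v$v_y, rep(0, 200))
})

test_that("a full sinusoid period integrates back to zero end velocity", {
  dt <- 0.01
  n <- 400
  f <- 1  # one full period over the first 100 samples of the segment
  idx <- 0:(n - 1)
  acc <- sinpi(2 * f * idx * dt)
  acc[idx * dt >= 1] <- 0
  tr <- make_trace(n, acc_y = acc)
  mask <- manual_mask(n, 1, 102)
  v <- integrate_velocity(tr, mask)
  expect_lt(abs(v$v_y[101]), 1e-6 + pi * dt)  # analytic integral is 0
})

test_that("length mismatch between trace and mask errors", {
  tr <- make_trace(50, acc_y = rep(0, 50))
  expect_error(integrate_velocity(tr, manual_mask(40, 2, 10)), "length")
})

test_that("drift compensation forces the end-of-segment velocity to zero", {
  dt <- 0.01
  n <- 200
  seg <- manual_mask(n, 1, 201, dt)$segments
  # ramp to 0.2 m/s over 2 s: slope must be 0.1 m/s^2
  v <- seq_len(n) * 0.001
  out <- compensate_drift(v, seg, dt)
  expect_equal(out$slope, 0.1)
  expect_equal(out$v_comp[n], 0)
  expect_equal(out$v_comp, rep(0, n))  # a pure line is pure drift
  # symmetric triangle ending at zero: nothing to compensate
  tri <- c(seq(0.005, 0.5, length.out = 100), seq(0.495, 0, length.out = 100))
  out2 <- compensate_drift(tri, seg, dt)
  expect_equal(out2$slope, 0)
  expect_equal(out2$v_comp, tri)
  expect_error(compensate_drift(v, transform(seg, duration = 0), dt), "duration")
})

test_that("displacement is the rectangular integral times the factor", {
  dt <- 0.01
  n <- 200
  seg <- manual_mask(n, 1, 201, dt)$segments
  tri <- c(seq(0, 0.5, length.out = 101)[-1], seq(0.5, 0, length.out = 101)[-1])
  out <- integrate_displacement(tri, seg, dt, factor = 1.4735)
  expect_equal(out$disp, 0.5, tolerance = 1e-2)
  expect_equal(out$disp_cal, 1.4735 * out$disp)
  expect_equal(integrate_displacement(tri, seg, dt, factor = 1)$disp_cal,
               integrate_displacement(tri, seg, dt, factor = 1)$disp)
  expect_equal(integrate_displacement(rep(0, n), seg, dt)$disp_cal, 0)
})

test_that("time-reversing a segment velocity negates its displacement", {
  dt <- 0.01
  set.seed(9)
  n <- 150
  seg <- manual_mask(n, 1, 151, dt)$segments
  v <- cumsum(rnorm(n, 0, 0.05)) * dt
  d1 <- integrate_displacement(v, seg, dt, factor = 1)$disp
  d2 <- integrate_displacement(rev(-v), seg, dt, factor = 1)$disp
  expect_equal(d2, -d1)
})

test_that("ZUPT and end-velocity-zero contracts hold on generator traces", {
  for (seed in c(31, 32)) {
    w <- gen_walk_trace(walk_spec(step_lengths = c(1, 2.25), seed = seed))
    k <- nav_kinematics(w$trace)
    static <- !k$mask$moving
    expect_true(all(k$velocity$v_zupt_x[static] == 0))
    expect_true(all(k$velocity$v_zupt_y[static] == 0))
    for (j in seq_len(nrow(k$segments))) {
      i_last <- k$segments$i_end[j] - 1L
      expect_lt(abs(k$velocity$v_comp_x[i_last]), 1e-9)
      expect_lt(abs(k$velocity$v_comp_y[i_last]), 1e-9)
    }
  }
})

test_that("the calibration regression recovers exact linear relations", {
  est <- c(0.4, 0.7, 1.1, 2.0)
  fit <- fit_calibration(data.frame(real = 1.4735 * est, estimated = est))
  expect_equal(fit$factor, 1.4735)
  expect_equal(fit$r2, 1)
  fit1 <- fit_calibration(data.frame(real = est, estimated = est))
  expect_equal(fit1$factor, 1)
  expect_error(fit_calibration(data.frame(real = 1, estimated = 1)), "at least 2")
  expect_error(fit_calibration(data.frame(real = c(1, 2), estimated = c(0, 0))),
               "zero")
  expect_error(fit_calibration(data.frame(a = 1:3)), "columns")
  td <- tidy(fit)
  expect_equal(td$estimate, 1.4735)
  expect_equal(glance(fit)$nobs, 4)
})

test_that("the calibration factor is recovered from seeded walks", {
  grid <- c(0.5, 0.75, 1, 1.5, 2.25, 3, 3.75)
  pairs <- purrr::map_dfr(1:24, function(i) {
    w <- gen_walk_trace(walk_spec(step_lengths = grid[(i - 1) %% 7 + 1],
                                  seed = 7000 + i))
    k <- nav_kinematics(w$trace, factor = 1)
    tibble::tibble(real = w$truth$segments$length,
                   estimated = k$segments$disp_norm)
  })
  fit <- fit_calibration(pairs)
  expect_lt(abs(fit$factor - 1.4735), 0.07)
  expect_gte(fit$r2, 0.98)
  val <- validate_calibration(pairs, fit$factor)
  expect_lt(abs(val$slope - 1), 0.05)
})

test_that("calibrated displacement error stays within the survey tolerance", {
  grid <- c(0.5, 0.75, 1, 1.5, 2.25, 3, 3.75)
  errs <- vapply(1:40, function(i) {
    w <- gen_walk_trace(walk_spec(step_lengths = grid[(i - 1) %% 7 + 1],
                                  seed = 7100 + i))
    k <- nav_kinematics(w$trace)
    abs(k$segments$disp_cal_norm[1] - w$truth$segments$length[1])
  }, numeric(1))
  expect_lte(mean(errs), 0.15)
})
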