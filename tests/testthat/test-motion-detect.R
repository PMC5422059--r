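test_that("signal magnitude is the absolute value of the channel", {
  expect_equal(signal_magnitude(-0.3), 0.3)
  expect_equal(signal_magnitude(rep(0, 5)), rep(0, 5))
  expect_equal(signal_magnitude(c(0.1, -0.2, 0.05)), c(0.1, 0.2, 0.05))
  expect_error(signal_magnitude(numeric(0)), "non-empty")
})

test_that("local-maxima envelope is blockwise constant with a partial tail", {
  expect_equal(local_max_envelope(c(1, 5, 2, 4, 1, 0), M = 3),
               c(5, 5, 5, 4, 4, 4))
  mag7 <- c(3, 1, 2, 9, 1, 1, 0.5)
  env7 <- local_max_envelope(mag7, M = 3)
  expect_equal(env7, c(3, 3, 3, 9, 9, 9, 0.5))
  expect_equal(tail(env7, 1), mag7[7])  # singleton final block
  expect_equal(local_max_envelope(rep(2, 10), M = 4), rep(2, 10))
  expect_length(local_max_envelope(numeric(0), M = 3), 0)
  expect_error(local_max_envelope(1:3, M = 0), ">= 1")
})

test_that("envelope dominates the magnitude and is constant on blocks", {
  set.seed(7)
  for (M in c(1, 5, 85)) {
    mag <- abs(rnorm(300))
    env <- local_max_envelope(mag, M)
    expect_true(all(env >= mag))
    blocks <- split(env, (seq_along(env) - 1) %/% M)
    expect_true(all(vapply(blocks, function(b) length(unique(b)) == 1, logical(1))))
  }
})

test_that("dynamic threshold is mean + K * sd(n) with a floor", {
  expect_equal(dynamic_threshold(rep(0, 100), K = 1.8, min_thd = 0.15), 0.15)
  # constructed series with known population mean/sd
  x <- c(0, 0.2)  # mu = 0.1, sigma_n = 0.1
  expect_equal(dynamic_threshold(x, K = 1.8, min_thd = 0.15),
               0.1 + 1.8 * 0.1)
  # mu = 0.02, sigma small: the floor binds
  expect_equal(dynamic_threshold(c(0.01, 0.03), K = 1.8, min_thd = 0.15), 0.15)
  # population (denominator n), not sample, standard deviation
  set.seed(1)
  y <- abs(rnorm(50))
  mu <- mean(y); sig <- sqrt(mean((y - mu)^2))
  expect_equal(dynamic_threshold(y, 0.44, 0), mu + 0.44 * sig)
})

test_that("a single acceleration burst yields a single movement segment", {
  set.seed(11)
  dt <- 0.01
  n_idle <- 200
  n_burst <- 500
  acc <- c(rnorm(n_idle, 0, 0.0327),
           0.8 * sinpi(2 * 2 * (0:(n_burst - 1)) * dt) + rnorm(n_burst, 0, 0.0327),
           rnorm(n_idle, 0, 0.0327))
  tr <- make_trace(length(acc), acc_y = acc)
  m <- build_mask(tr, mode = "NM")
  expect_equal(nrow(m$segments), 1)
  # boundary resolution is limited by the M-sample envelope blocks
  tol <- detection_config()$M * dt + 0.1
  expect_lt(abs(m$segments$t_start - 2.0), tol)
  expect_lt(abs(m$segments$t_end - 7.0), tol)
})

test_that("idle traces produce no segments and tiny offsets do not either", {
  set.seed(2)
  idle <- rnorm(900, 0, 0.0327)
  tr <- make_trace(length(idle), acc_y = idle)
  m <- build_mask(tr, mode = "NM")
  expect_equal(nrow(m$segments), 0)
  expect_false(any(m$moving))
  # adding a constant below the floor leaves an all-idle mask unchanged
  tr2 <- make_trace(length(idle), acc_y = idle + 0.05)
  m2 <- build_mask(tr2, mode = "NM")
  expect_equal(m2$moving, m$moving)
})

test_that("two bursts separated by idle yield two ordered segments", {
  set.seed(3)
  dt <- 0.01
  burst <- function(n) 0.9 * sinpi(2 * 2 * (0:(n - 1)) * dt)
  acc <- c(rnorm(200, 0, 0.03), burst(300), rnorm(300, 0, 0.03),
           burst(300), rnorm(200, 0, 0.03))
  tr <- make_trace(length(acc), acc_y = acc)
  m <- build_mask(tr, mode = "NM")
  expect_equal(nrow(m$segments), 2)
  expect_true(all(diff(m$segments$i_start) > 0))
  expect_true(all(m$segments$i_end[-nrow(m$segments)] <= m$segments$i_start[-1]))
})

test_that("segments are exactly the maximal runs of the moving mask", {
  set.seed(4)
  w <- gen_walk_trace(walk_spec(step_lengths = c(1, 2), seed = 21))
  m <- build_mask(w$trace)
  runs <- rle(m$moving)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  expect_equal(m$segments$i_start, starts[runs$values])
  expect_equal(m$segments$i_end, ends[runs$values] + 1L)
  expect_equal(m$segments$duration,
               (m$segments$i_end - m$segments$i_start) * 0.01)
})

test_that("movement runs shorter than min_segment are debounced away", {
  set.seed(5)
  acc <- c(rnorm(300, 0, 0.02), rep(1, 10), rnorm(300, 0, 0.02))
  tr <- make_trace(length(acc), acc_y = acc)
  m <- build_mask(tr, detection_config(min_segment = 2), mode = "NM")
  expect_equal(nrow(m$segments), 0)
})

test_that("a trace shorter than the window is still segmented validly", {
  # 40 samples: a single partial envelope block; the burst half lifts the
  # whole block above the threshold, so the entire block is one segment
  tr <- make_trace(40, acc_y = c(rep(0.01, 20), rep(1, 20)))
  m <- build_mask(tr, mode = "NM")
  expect_equal(nrow(m$segments), 1)
  expect_equal(m$segments$i_start, 1L)
  expect_equal(m$segments$i_end, 41L)
})

test_that("movement detection succeeds on seeded generator traces", {
  dt <- 0.01
  tol <- detection_config()$M * dt + 0.1
  grid <- c(0.5, 0.75, 1, 1.5, 2.25, 3, 3.75)
  ok <- vapply(1:60, function(i) {
    w <- gen_walk_trace(walk_spec(step_lengths = grid[(i - 1) %% 7 + 1],
                                  seed = 6000 + i))
    m <- build_mask(w$trace)
    nrow(m$segments) == 1 &&
      abs(m$segments$t_start - w$truth$segments$t_start) <= tol &&
      abs(m$segments$t_end - w$truth$segments$t_end) <= tol
  }, logical(1))
  expect_gte(mean(ok), 0.98)
})
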