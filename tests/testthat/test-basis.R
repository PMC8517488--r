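test_that("basis waveform vanishes at onset, peaks at 1 and stays in [0, 1]", {
  b <- basis_waveform(1.05, 3.80, 16.0, w = 0.963)
  expect_equal(evaluate_basis(b, 0), 0)
  expect_equal(evaluate_basis(b, b$t_peak), 1, tolerance = 1e-12)
  expect_error(evaluate_basis(b, -1), ">= 0")

  # value at twice the argmax: the bracket evaluated exactly at 2 * t_peak,
  # normalized by a fine-grid (dt = 1e-3 ms) estimate of the bracket peak
  tt <- seq(0, 120, by = 1e-3)
  br <- function(t) {
    0.963 * exp(-t / 3.80) + (1 - 0.963) * exp(-t / 16.0) - exp(-t / 1.05)
  }
  oracle <- br(2 * b$t_peak) / max(br(tt))
  expect_equal(evaluate_basis(b, 2 * b$t_peak), oracle, tolerance = 1e-5)

  vals <- evaluate_basis(b, seq(0, 200, 0.05))
  expect_true(all(vals >= -1e-12 & vals <= 1 + 1e-12))
})

test_that("normalization factor matches the two-exponential closed form", {
  # w = 1 and tc2 = 2 * tc1: peak of exp(-t/2a) - exp(-t/a) at t* = 2a ln 2
  a <- 1.7
  fn <- compute_fnorm(a, 2 * a, 50, w = 1)
  tstar <- 2 * a * log(2)
  peak <- exp(-tstar / (2 * a)) - exp(-tstar / a)
  expect_equal(fn$t_peak, tstar, tolerance = 1e-6)
  expect_equal(fn$fnorm, 1 / peak, tolerance = 1e-9)

  expect_error(compute_fnorm(3, 3, 16), "tc1 must be <")
  expect_error(compute_fnorm(2.9999999, 3, 16, w = 1), "degenerate")
})

test_that("normalized peak is 1 for many random valid triplets", {
  vals <- with_seed_local(7, {
    replicate(1000, {
      tc1 <- runif(1, 0.2, 5)
      tc2 <- tc1 + runif(1, 0.5, 20)
      tc3 <- tc1 + runif(1, 0.5, 100)
      w <- runif(1, 0.05, 0.99)
      b <- basis_waveform(tc1, tc2, tc3, w)
      tt <- seq(0, 6 * max(tc2, tc3), length.out = 4000)
      c(evaluate_basis(b, b$t_peak), max(evaluate_basis(b, tt)))
    })
  })
  # the value at the located argmax is exactly 1, and no sample exceeds it
  expect_true(all(abs(vals[1, ] - 1) < 1e-9))
  expect_true(all(vals[2, ] <= 1 + 1e-9))
})

test_that("FDHM matches closed forms and a dense brute-force scan", {
  # instant-rise exponential decay: FDHM = tau * ln 2
  tau <- 7
  dt <- 0.01
  y <- exp(-seq(0, 80, by = dt) / tau)
  expect_equal(fdhm(y, dt), tau * log(2), tolerance = dt / 2)

  # symmetric triangle of base B: FDHM = B / 2
  B <- 10
  tt <- seq(0, 30, by = dt)
  tri <- pmax(0, 1 - abs(tt - B / 2) / (B / 2))
  expect_equal(fdhm(tri, dt), B / 2, tolerance = dt / 2)

  expect_error(fdhm(rep(2, 100), dt), "never crosses")
  expect_error(fdhm(rep(0, 100), dt), "positive maximum")

  # brute-force oracle on random smooth unimodal waveforms
  with_seed_local(11, {
    for (i in 1:25) {
      tc1 <- runif(1, 0.3, 3)
      b <- basis_waveform(tc1, tc1 + runif(1, 1, 10),
                          tc1 + runif(1, 5, 60), runif(1, 0.3, 0.95))
      y <- evaluate_basis(b, seq(0, 400, by = dt))
      half <- max(y) / 2
      above <- which(y >= half)
      brute <- (max(above) - min(above)) * dt
      expect_equal(fdhm(y, dt), brute, tolerance = dt)
    }
  })
})

test_that("NRMSE follows its defining arithmetic", {
  y <- c(1, 2, 2)
  expect_equal(nrmse(y, y), 0)
  expect_equal(nrmse(c(1, 1), c(0, 0)), 1)
  expect_equal(nrmse(y, c(1, 1, 1)), sqrt(2 / 9))
  # scale invariance under joint rescaling
  expect_equal(nrmse(3.7 * y, 3.7 * c(1, 1, 1)), sqrt(2 / 9))
  expect_error(nrmse(c(0, 0), c(1, 1)), "zero energy")
  expect_error(nrmse(1:3, 1:4), "lengths")
})

test_that("grid search recovers on-grid triplets exactly", {
  grid <- tc_grid(tc1 = seq(0.5, 2, 0.25), tc2 = seq(3, 6, 0.5),
                  tc3 = seq(10, 25, 2.5), w = 0.963)
  target_b <- basis_waveform(1.0, 4.5, 17.5, 0.963)
  tt <- seq(0, 100, 0.1)
  target <- evaluate_basis(target_b, tt)
  fit <- optimize_time_constants(target, grid = grid, dt = 0.1)
  expect_equal(unname(fit$tc), c(1.0, 4.5, 17.5))
  expect_lt(fit$objective, 1e-10)
  expect_error(
    optimize_time_constants(target, grid = tc_grid(tc1 = numeric(0)),
                            dt = 0.1),
    "empty grid"
  )
})

test_that("waveform isolation assigns orders and averages within order", {
  sch <- fx_saturating()
  tr <- fx_transient()

  # single pulse: one order-1 waveform equal to the single-pulse response
  one <- isolate_and_average(sch, tr, 0, 0.1, order_cap = 3,
                             memory_window = 100)
  expect_equal(one$order, 1L)
  expect_equal(one$n, 1L)
  g <- glutamate_trace(0, tr, 0.1, 100)
  ref <- simulate_scheme(sch, g)$output
  expect_equal(one$waveform[[1]]$value, ref, tolerance = 1e-9)

  # linear scheme: all orders share the same mean waveform
  lin <- fx_linear()
  ev <- c(0, 20, 45, 300, 320, 350)
  avg <- isolate_and_average(lin, tr, ev, 0.1, order_cap = 3,
                             memory_window = 100)
  w1 <- avg$waveform[[1]]$value
  for (i in seq_len(nrow(avg))[-1]) {
    expect_lt(nrmse(w1, avg$waveform[[i]]$value), 1e-3)
  }
})

test_that("time-constant banks round-trip through YAML", {
  bank <- tc_bank(list(basis_waveform(1.05, 3.8, 16),
                       basis_waveform(1.1, 3.85, 18)), receptor = "demo")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_tc_bank(bank, path)
  back <- read_tc_bank(path)
  expect_equal(tidy(back), tidy(bank))
})
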