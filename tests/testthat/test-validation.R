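test_that("Poisson trains are Bernoulli-per-bin, seeded and rate-correct", {
  expect_equal(sum(poisson_train(0, 1000, 0.1, 1)$pulse), 0)
  a <- poisson_train(10, 2000, 0.1, 99)
  b <- poisson_train(10, 2000, 0.1, 99)
  expect_identical(a, b)
  expect_error(poisson_train(20000, 1000, 0.1, 1), "< 1")

  # mean event count over many seeds matches the binomial expectation
  counts <- vapply(1:200, function(s) {
    sum(poisson_train(10, 20000, 0.5, s)$pulse)
  }, numeric(1))
  # n = 40000 bins, p = 0.005: mean 200, se of the mean ~ 1
  expect_equal(mean(counts), 200, tolerance = 0.025)

  # seeding does not disturb the global RNG stream
  set.seed(123)
  x1 <- runif(1)
  set.seed(123)
  invisible(poisson_train(10, 100, 0.1, 7))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("spike detection interpolates rising threshold crossings", {
  dt <- 0.1
  expect_length(detect_spikes(rep(-65, 1000), dt)$times, 0)

  # triangular excursion crossing 0 upward once
  tt <- seq(0, 20, by = dt)
  v <- -60 + 80 * pmax(0, 1 - abs(tt - 10) / 5)
  st <- detect_spikes(v, dt)
  expect_length(st$times, 1)
  # rising edge: v = -60 + 80(1 - (10 - t)/5) crosses 0 at t = 8.75
  expect_equal(st$times, 8.75, tolerance = dt / 10)

  # sinusoid with rising zero crossings at 5, 25, 45, 65, 85 ms; each
  # crossing is preceded by below-threshold samples, so all five count
  tt <- seq(0, 100, by = dt)
  v <- 30 * sin(2 * pi * (tt - 5) / 20)
  expect_length(detect_spikes(v, dt)$times, 5)
})

test_that("van Rossum distance matches closed forms and metric axioms", {
  tau <- 10
  expect_equal(van_rossum(c(3, 9), c(3, 9), tau), 0)
  expect_equal(van_rossum(5, numeric(0), tau), 1 / sqrt(2))
  for (d in c(1, 5, 20)) {
    expect_equal(van_rossum(10, 10 + d, tau), sqrt(1 - exp(-d / tau)),
                 tolerance = 1e-12)
  }
  expect_error(van_rossum(1, 2, tau_vr = 0), "> 0")

  with_seed_local(21, {
    for (i in 1:40) {
      a <- sort(runif(sample(0:8, 1), 0, 200))
      b <- sort(runif(sample(0:8, 1), 0, 200))
      c_ <- sort(runif(sample(0:8, 1), 0, 200))
      dab <- van_rossum(a, b, tau)
      expect_gte(dab, 0)
      expect_equal(dab, van_rossum(b, a, tau))
      if (length(a) == length(b) && isTRUE(all.equal(a, b))) {
        expect_equal(dab, 0)
      }
      expect_lte(dab,
                 van_rossum(a, c_, tau) + van_rossum(c_, b, tau) + 1e-12)
    }
  })
})

test_that("closed-form distance equals brute-force kernel convolution", {
  # oracle: sample both filtered trains densely and integrate the squared
  # difference, D^2 = (1/tau) * sum (f - g)^2 * dt
  brute_vrd <- function(a, b, tau, horizon = 400, dt = 0.005) {
    tt <- seq(0, horizon, by = dt)
    f <- numeric(length(tt))
    for (s in a) f <- f + ifelse(tt >= s, exp(-(tt - s) / tau), 0)
    g <- numeric(length(tt))
    for (s in b) g <- g + ifelse(tt >= s, exp(-(tt - s) / tau), 0)
    sqrt(sum((f - g)^2) * dt / tau)
  }
  tau <- 8
  with_seed_local(31, {
    for (i in 1:100) {
      a <- sort(runif(sample(1:6, 1), 0, 150))
      b <- sort(runif(sample(1:6, 1), 0, 150))
      expect_equal(van_rossum(a, b, tau), brute_vrd(a, b, tau),
                   tolerance = 1e-3)
    }
  })
})

test_that("the point neuron rests, fires under drive, and is deterministic", {
  dt <- 0.1
  n <- 5000
  quiet <- point_neuron(rep(0, n), dt = dt)
  expect_true(all(abs(quiet$value - cell_params()$E_leak) < 1e-9))

  # sustained conductance drives at least one spike
  drive <- rep(20000, n)  # 20 nS of AMPA-like drive in pS
  v <- point_neuron(drive, dt = dt, ampa_params = receptor_params(nb_r = 1))
  st <- detect_spikes(v)
  expect_gt(length(st$times), 0)
  expect_true(all(diff(st$times) >= cell_params()$refractory_ms))

  v2 <- point_neuron(drive, dt = dt, ampa_params = receptor_params(nb_r = 1))
  expect_identical(v$value, v2$value)
  expect_equal(van_rossum(detect_spikes(v), detect_spikes(v2)), 0)
})

test_that("the validation report is deterministic and self-comparison is exact", {
  tb <- fx_table_n3()
  bank <- fx_bank()
  rep1 <- run_validation(fx_saturating(), fx_transient(), tb, bank,
                         rates = 10, seeds = 1, duration_ms = 1000,
                         models = "kinetic")
  expect_equal(rep1$nrmse, 0)
  rep2 <- run_validation(fx_saturating(), fx_transient(), tb, bank,
                         rates = 10, seeds = 1, duration_ms = 1000,
                         models = "kinetic")
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
  expect_error(run_validation(NULL, fx_transient(), tb, bank), "required")
})

test_that("traces and event lists round-trip through plain text", {
  tr <- tibble::tibble(time_ms = seq(0, 1, 0.1), value = sin(seq(0, 1, 0.1)))
  p <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, p)
  expect_equal(read_trace(p), tr, tolerance = 1e-12)
  ev <- c(0.5, 12.25, 100)
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_events(ev, p2)
  expect_equal(read_events(p2), ev)
})
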