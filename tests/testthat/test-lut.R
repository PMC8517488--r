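test_that("table sizes follow the combination formula and its expansions", {
  expect_equal(table_size(100, 2), 100)
  expect_equal(table_size(300, 4), 4455100)
  expect_equal(table_size(200, 5), 64684950)
  expect_equal(table_size(17, 1), 1)
  expect_error(table_size(2, 4), "R must be >=")

  # polynomial expansions for 4th and 5th order as functions of R
  R <- 4:1000
  expect_equal(sapply(R, table_size, N = 4), (R^3 - 3 * R^2 + 2 * R) / 6)
  expect_equal(sapply(R, table_size, N = 5),
               (R^4 - 6 * R^3 + 11 * R^2 - 6 * R) / 24)
})

test_that("memory accounting uses 8 bytes per double", {
  expect_equal(table_bytes(4455100), 35640800)
  expect_equal(table_bytes(64684950), 517479600)
  expect_equal(table_bytes(0), 0)
})

test_that("interpulse intervals quantize to 0-based strictly increasing bins", {
  # 92 ms at 5 ms granularity: nearest multiple is 90 ms, bin 17
  expect_equal(as.integer(quantize_ipis(92, 5, 500)), 17L)
  # exact multiples map to consecutive bins from 0
  expect_equal(as.integer(quantize_ipis(c(5, 10, 15), 5, 500)), 0:2)
  # rounding is half-up
  expect_equal(as.integer(quantize_ipis(12.5, 5, 500)), 2L)
  # collision: 6 and 7 ms both round to bin 0; the later is bumped
  expect_equal(as.integer(quantize_ipis(c(6, 7), 5, 500)), c(0L, 1L))
  # bumping past the last bin drops the oldest interval
  expect_message(
    out <- quantize_ipis(c(48, 50), 5, 50),
    "dropping the oldest"
  )
  expect_equal(as.integer(out), 9L)

  expect_error(quantize_ipis(600, 5, 500), "memory window")
  expect_error(quantize_ipis(c(10, 5), 5, 500), "strictly increasing")
  expect_error(quantize_ipis(10, 3, 100), "integer")
})

test_that("combinadic flattening matches the polynomial expansions", {
  expect_equal(flatten_index(c(0, 1, 2)), 0)
  expect_equal(flatten_index(c(1, 2, 3)), 3)
  expect_error(flatten_index(c(2, 2)), "strictly increasing")
  expect_error(flatten_index(c(-1, 2)), "non-negative")

  poly4 <- function(t1, t2, t3) {
    (t3^3 - 3 * t3^2 + 2 * t3) / 6 + (t2^2 - t2) / 2 + t1
  }
  poly5 <- function(t1, t2, t3, t4) {
    (t4^4 - 6 * t4^3 + 11 * t4^2 - 6 * t4) / 24 + poly4(t1, t2, t3)
  }
  with_seed_local(3, {
    for (i in 1:10000) {
      t4 <- sort(sample(0:299, 4))
      expect_identical(flatten_index(t4[1:3]), poly4(t4[1], t4[2], t4[3]))
      expect_identical(flatten_index(t4), poly5(t4[1], t4[2], t4[3], t4[4]))
    }
  })
})

test_that("flattening is a bijection onto the dense index range", {
  for (N in 2:5) {
    k <- N - 1
    for (R in c(k, k + 1, 7, 13, 30)) {
      if (R < k) next
      m <- synlut:::enumerate_tuples(R, k)
      idx <- apply(m, 1, flatten_index)
      expect_identical(sort(idx), as.numeric(seq_len(choose(R, k)) - 1))
    }
  }
})

test_that("generated tables match direct kinetic simulation entry by entry", {
  tb <- fx_table_n2_r5()
  sch <- fx_saturating()
  tr <- fx_transient()
  expect_length(tb$tables[[2]], 5)
  for (bin in 0:4) {
    ipi <- (bin + 1) * tb$delta
    oracle <- isolated_response_amplitude(sch, tr, c(0, ipi), tb$dt,
                                          tb$response_window)
    expect_equal(tb$tables[[2]][bin + 1], oracle, tolerance = 1e-12)
  }
  # first-order sub-table is the unconditioned single-pulse amplitude
  expect_equal(tb$tables[[1]],
               isolated_response_amplitude(sch, tr, 0, tb$dt,
                                           tb$response_window))
})

test_that("a linear scheme yields a flat table", {
  tb <- generate_table(fx_linear(), fx_transient(), N = 2, M = 50,
                       delta = 10, dt = 0.1)
  a1 <- tb$tables[[1]][1]
  expect_true(all(abs(tb$tables[[2]] - a1) / a1 < 1e-3))
})

test_that("degenerate order-1 tables hold a single scalar", {
  tb <- generate_table(fx_saturating(), fx_transient(), N = 1, M = 50,
                       delta = 10, dt = 0.1)
  expect_length(tb$tables, 1)
  expect_length(tb$tables[[1]], 1)
})

test_that("memory-window calibration finds the two-pulse recovery interval", {
  tr <- fx_transient()
  # linear scheme recovers immediately: the first grid point satisfies it
  expect_equal(
    calibrate_memory_window(fx_linear(), tr, grid = seq(10, 200, 10)),
    10
  )
  # slower unbinding lengthens the required window monotonically
  Ms <- sapply(c(0.2, 0.05, 0.02), function(koff) {
    calibrate_memory_window(synthetic_scheme("saturating", koff), tr,
                            grid = seq(10, 1000, 20), refine_ms = 2)
  })
  expect_true(all(diff(Ms) > 0))
  expect_error(
    calibrate_memory_window(synthetic_scheme("saturating", 0.001), tr,
                            grid = seq(10, 50, 10)),
    "criterion not met"
  )
})

test_that("tables persist bit-exactly with a validated header", {
  tb <- fx_table_n2_r5()
  path <- withr::local_tempfile(fileext = ".bin")
  save_table(tb, path)
  back <- load_table(path)
  expect_identical(back$tables, tb$tables)
  expect_equal(back$N, tb$N)
  expect_equal(back$M, tb$M)

  # truncated payload is refused
  raw <- readBin(path, "raw", n = file.size(path))
  writeBin(raw[1:(length(raw) - 8)], path)
  expect_error(load_table(path), "checksum")

  # header inconsistent with R integrality is refused
  save_table(tb, path)
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  hdr$delta_ms <- 7
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(load_table(path), "integer|inconsistent")
})

test_that("tidy and glance expose table structure", {
  tb <- fx_table_n2_r5()
  td <- tidy(tb)
  expect_equal(nrow(td), 6)
  expect_equal(td$amplitude[td$order == 2], tb$tables[[2]])
  gl <- glance(tb)
  expect_equal(gl$n_values, 6)
  expect_equal(gl$bytes, 48)
})
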