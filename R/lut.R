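#' Number of values in an Nth-order look-up table
#'
#' An Nth-order table is indexed by N-1 strictly increasing quantized
#' interpulse intervals, each taking one of R = M / delta values, so it
#' holds `choose(R, N - 1)` amplitudes ("R time slots, any N-1 of them
#' occupied"). Computed in exact integer arithmetic.
#'
#' @param R Number of interpulse-interval bins (memory window / granularity),
#'   a positive integer.
#' @param N Model order, `N - 1 <= R`.
#' @return The count `choose(R, N - 1)` as a double holding an exact integer
#'   (exact for all table sizes of practical interest).
#' @export
#' @examples
#' table_size(300, 4)  # 4,455,100
#' table_size(200, 5)  # 64,684,950
table_size <- function(R, N) {
  if (R != round(R) || N != round(N) || N < 1) {
    abort("R and N must be integers with N >= 1")
  }
  if (R < N - 1) abort("R must be >= N - 1")
  round(choose(R, N - 1))
}

#' Memory footprint of a look-up table
#'
#' Each stored amplitude is an 8-byte double.
#'
#' @param count Number of values (from [table_size()]).
#' @param value_width Bytes per value; default 8.
#' @return Size in bytes.
#' @export
table_bytes <- function(count, value_width = 8) {
  count * value_width
}

round_half_up <- function(x) floor(x + 0.5)

#' Quantize interpulse intervals into table bins
#'
#' Each interval tau (ms) maps to the 0-based bin
#' `round(tau / delta) - 1`, i.e. the nearest multiple of the granularity
#' delta, re-indexed so bins run 0..R-1. Rounding is half-up. Collisions
#' (two intervals rounding to the same bin, possible at runtime but never
#' during generation) are resolved by minimally bumping later bins upward;
#' if bumping would exceed R-1 the oldest interval is dropped and the
#' effective order reduced, with a message.
#'
#' @param taus Strictly increasing interpulse intervals (ms), each
#'   `0 < tau <= M`.
#' @param delta Granularity (ms).
#' @param M Memory window (ms); `R = M / delta` must be an integer.
#' @return Integer vector of strictly increasing 0-based bins (class
#'   `ipi_tuple`), possibly shorter than `taus` if intervals were dropped.
#' @export
#' @examples
#' quantize_ipis(92, delta = 5, M = 500)          # bin 17 (the 90 ms slot)
#' quantize_ipis(c(5, 10, 15), delta = 5, M = 500) # bins 0, 1, 2
quantize_ipis <- function(taus, delta, M) {
  R <- lut_ratio(M, delta)
  taus <- as.numeric(taus)
  if (length(taus)) {
    if (any(taus <= 0)) abort("interpulse intervals must be > 0")
    if (any(taus > M)) abort("interpulse intervals beyond the memory window must be filtered by the caller")
    if (length(taus) > 1 && any(diff(taus) <= 0)) {
      abort("interpulse intervals must be strictly increasing")
    }
  }
  bins <- pmax(0L, as.integer(round_half_up(taus / delta)) - 1L)
  # resolve quantization collisions by minimal upward bumping
  if (length(bins) > 1) {
    for (k in 2:length(bins)) {
      if (bins[k] <= bins[k - 1]) bins[k] <- bins[k - 1] + 1L
    }
  }
  while (length(bins) && bins[length(bins)] > R - 1L) {
    inform("quantized interval exceeds the bin range; dropping the oldest interval")
    bins <- bins[-length(bins)]
  }
  structure(bins, class = "ipi_tuple", R = R)
}

lut_ratio <- function(M, delta) {
  R <- M / delta
  if (abs(R - round(R)) > 1e-9) {
    abort("granularity must divide the memory window exactly (R = M / delta integer)")
  }
  as.integer(round(R))
}

#' Flatten an interpulse-interval tuple to a one-dimensional index
#'
#' Combinatorial number system (combinadic) ranking in colexicographic
#' order: a strictly increasing tuple of 0-based bins `(t1 < t2 < ...)`
#' maps to `sum(choose(t_n, n))`. The map is a bijection from the set of
#' admissible tuples onto `0 .. choose(R, N-1) - 1`, so the flat array is
#' dense.
#'
#' @param bins Strictly increasing non-negative integer bins (an
#'   `ipi_tuple` from [quantize_ipis()] or a plain integer vector).
#' @return 0-based integer index (a double holding an exact integer).
#' @export
#' @examples
#' flatten_index(c(0, 1, 2))  # 0, the smallest 4th-order tuple
#' flatten_index(c(1, 2, 3))  # 3
flatten_index <- function(bins) {
  bins <- as.numeric(unclass(bins))
  if (!length(bins)) return(0)
  if (any(bins < 0) || any(bins != round(bins))) {
    abort("bins must be non-negative integers")
  }
  if (length(bins) > 1 && any(diff(bins) <= 0)) {
    abort("bins must be strictly increasing")
  }
  sum(choose(bins, seq_along(bins)))
}

# all admissible 0-based tuples of length k from bins 0..R-1, one row per
# tuple, ordered by their flattened (colex) index
enumerate_tuples <- function(R, k) {
  if (k == 0) return(matrix(numeric(0), nrow = 1, ncol = 0))
  m <- t(utils::combn(0:(R - 1), k))
  idx <- apply(m, 1, flatten_index)
  m[order(idx), , drop = FALSE]
}

#' Generate a look-up table from a kinetic scheme
#'
#' For every admissible quantized interpulse-interval pattern at every
#' order k = 1..N, constructs the k-pulse train with those intervals,
#' simulates the kinetic scheme, and stores the isolated amplitude of the
#' k-th response (see [isolated_response_amplitude()]) at the pattern's
#' flattened index. Orders below N are stored as sub-tables alongside the
#' main order-N table, because runtime responses to the first pulses of a
#' burst have fewer predecessors in the window.
#'
#' @param scheme A [kinetic_scheme()].
#' @param transient A [glutamate_transient()].
#' @param N Model order (>= 1).
#' @param M Memory window (ms).
#' @param delta Granularity (ms); must divide M.
#' @param dt Simulation time step (ms). Default 0.1.
#' @param response_window Post-pulse window (ms) searched for the isolated
#'   peak. Default 100.
#' @param mode `"isolated"` (default) stores the subtracted contribution of
#'   the final pulse so that superposed basis waveforms reconstruct the
#'   kinetic trace; `"absolute"` stores the raw peak of the full response
#'   after the final pulse.
#' @param progress Print progress every so many entries (0 = silent).
#' @return An object of class `lookup_table`: fields `N`, `M`, `delta`,
#'   `R`, `receptor`, `mode`, and `tables`, a list whose k-th element is
#'   the order-k amplitude vector of length `choose(R, k - 1)` (a single
#'   scalar for order 1).
#' @export
generate_table <- function(scheme, transient, N, M, delta, dt = 0.1,
                           response_window = 100,
                           mode = c("isolated", "absolute"),
                           progress = 0) {
  mode <- match.arg(mode)
  R <- lut_ratio(M, delta)
  if (N < 1) abort("N must be >= 1")
  if (R < N - 1) abort("R must be >= N - 1")

  tables <- vector("list", N)
  for (k in seq_len(N)) {
    tuples <- enumerate_tuples(R, k - 1)
    vals <- numeric(nrow(tuples))
    for (r in seq_len(nrow(tuples))) {
      bins <- tuples[r, ]
      # bins are 0-based; interval tau_n = (bin + 1) * delta to the n-th
      # most recent pulse. Present pulse at t = max tau; earlier pulses
      # before it by their tau.
      taus <- (bins + 1) * delta
      t_last <- if (length(taus)) max(taus) else 0
      pulses <- sort(c(t_last - taus, t_last))
      amp <- if (mode == "isolated") {
        isolated_response_amplitude(scheme, transient, pulses, dt,
                                    response_window)
      } else {
        g <- glutamate_trace(pulses, transient, dt, t_last + response_window)
        sim <- simulate_scheme(scheme, g, dt)
        max(sim$output[sim$time_ms >= t_last])
      }
      idx <- flatten_index(bins)
      vals[idx + 1] <- amp
      if (progress > 0 && r %% progress == 0) {
        inform(sprintf("order %d: %d / %d", k, r, nrow(tuples)))
      }
    }
    tables[[k]] <- vals
  }

  structure(
    list(
      N = as.integer(N), M = M, delta = delta, R = R,
      receptor = scheme$name, mode = mode, dt = dt,
      response_window = response_window, tables = tables
    ),
    class = "lookup_table"
  )
}

#' @export
print.lookup_table <- function(x, ...) {
  cat(sprintf(
    "<lookup_table> %s: order %d, M = %g ms, delta = %g ms (R = %d)\n",
    x$receptor, x$N, x$M, x$delta, x$R
  ))
  sizes <- vapply(x$tables, length, integer(1))
  cat("  values per order:", paste(sizes, collapse = ", "),
      sprintf("(total %d, %s bytes)\n", sum(sizes),
              format(table_bytes(sum(sizes)), big.mark = ",")))
  invisible(x)
}

#' Calibrate the memory window of a kinetic scheme
#'
#' Finds the smallest two-pulse interval at which the isolated amplitude of
#' the second response is within a relative tolerance (default 2%) of the
#' first response's amplitude, indicating the receptor has returned to
#' baseline. A coarse grid is scanned from short to long intervals with
#' early exit, then the boundary is refined by bisection.
#'
#' @inheritParams generate_table
#' @param tolerance Relative amplitude tolerance; default 0.02.
#' @param grid Candidate intervals (ms), scanned in increasing order.
#' @param refine_ms Bisection resolution (ms). Default 1.
#' @param response_window Post-pulse peak window (ms).
#' @return The calibrated memory window (ms).
#' @export
calibrate_memory_window <- function(scheme, transient, dt = 0.1,
                                    tolerance = 0.02,
                                    grid = seq(10, 2000, by = 10),
                                    refine_ms = 1,
                                    response_window = 100) {
  if (!(tolerance > 0 && tolerance < 1)) abort("tolerance must be in (0, 1)")
  a1 <- isolated_response_amplitude(scheme, transient, 0, dt, response_window)
  rel_err <- function(ipi) {
    a2 <- isolated_response_amplitude(scheme, transient, c(0, ipi), dt,
                                      response_window)
    abs(a2 - a1) / a1
  }
  prev <- NULL
  hit <- NA_real_
  for (ipi in grid) {
    if (rel_err(ipi) <= tolerance) {
      hit <- ipi
      break
    }
    prev <- ipi
  }
  if (is.na(hit)) {
    abort(sprintf(
      "criterion not met within %g ms (residual %.4g at the cap)",
      max(grid), rel_err(max(grid))
    ))
  }
  if (is.null(prev)) return(hit)  # met at the first grid point
  lo <- prev
  hi <- hit
  while (hi - lo > refine_ms) {
    mid <- (lo + hi) / 2
    if (rel_err(mid) <= tolerance) hi <- mid else lo <- mid
  }
  hi
}

#' Persist a look-up table
#'
#' Writes the amplitude payload as raw little-endian 8-byte doubles (all
#' orders concatenated, order 1 first) with a JSON sidecar header
#' (`<path>.json`) recording receptor, N, M, delta, R, per-order counts,
#' generation mode and an md5 checksum of the payload. `load_table()`
#' validates the header against the payload before accepting it.
#'
#' @param table A `lookup_table` from [generate_table()].
#' @param path Payload file path; the header is written to `<path>.json`.
#' @export
save_table <- function(table, path) {
  payload <- unlist(table$tables)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(payload, con, size = 8, endian = "little")
  close(con)
  on.exit()
  header <- list(
    receptor = table$receptor, N = table$N, M_ms = table$M,
    delta_ms = table$delta, R = table$R, mode = table$mode,
    dt_ms = table$dt, response_window_ms = table$response_window,
    counts = vapply(table$tables, length, integer(1)),
    checksum = unname(tools::md5sum(path))
  )
  jsonlite::write_json(header, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_table
#' @export
load_table <- function(path) {
  hpath <- paste0(path, ".json")
  if (!file.exists(hpath)) abort("missing sidecar header")
  header <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  R <- lut_ratio(header$M_ms, header$delta_ms)
  if (R != header$R) abort("header R inconsistent with M and delta")
  expected <- vapply(seq_len(header$N), function(k) table_size(R, k),
                     numeric(1))
  if (!identical(as.numeric(header$counts), expected)) {
    abort("header counts inconsistent with N and R")
  }
  if (!identical(unname(tools::md5sum(path)), header$checksum)) {
    abort("payload checksum mismatch")
  }
  total <- sum(header$counts)
  con <- file(path, "rb")
  on.exit(close(con))
  payload <- readBin(con, "double", n = total + 1, size = 8,
                     endian = "little")
  if (length(payload) != total) {
    abort("payload length does not match header counts")
  }
  tables <- vector("list", header$N)
  off <- 0
  for (k in seq_len(header$N)) {
    tables[[k]] <- payload[(off + 1):(off + header$counts[k])]
    off <- off + header$counts[k]
  }
  structure(
    list(
      N = as.integer(header$N), M = header$M_ms, delta = header$delta_ms,
      R = R, receptor = header$receptor, mode = header$mode,
      dt = header$dt_ms, response_window = header$response_window_ms,
      tables = tables
    ),
    class = "lookup_table"
  )
}
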