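#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a look-up table into one row per stored amplitude
#'
#' @param x A `lookup_table`.
#' @param ... Ignored.
#' @return A tibble with `order`, `index` (0-based flat index), one `bin_n`
#'   column per interval slot (0-based, NA for lower orders) and
#'   `amplitude`.
#' @exportS3Method generics::tidy
#' @export
tidy.lookup_table <- function(x, ...) {
  rows <- lapply(seq_len(x$N), function(k) {
    tuples <- enumerate_tuples(x$R, k - 1)
    df <- tibble::tibble(
      order = k,
      index = seq_len(nrow(tuples)) - 1,
      amplitude = x$tables[[k]]
    )
    if (k > 1) {
      for (n in seq_len(k - 1)) {
        df[[paste0("bin_", n)]] <- tuples[, n]
      }
    }
    df
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a look-up table
#'
#' @param x A `lookup_table`.
#' @param ... Ignored.
#' @return A tibble with the structural parameters, total value count and
#'   memory footprint in bytes.
#' @exportS3Method generics::glance
#' @export
glance.lookup_table <- function(x, ...) {
  total <- sum(vapply(x$tables, length, integer(1)))
  tibble::tibble(
    receptor = x$receptor, N = x$N, M_ms = x$M, delta_ms = x$delta,
    R = x$R, mode = x$mode, n_values = total, bytes = table_bytes(total)
  )
}

#' Tidy a time-constant bank into one row per order
#'
#' @param x A [tc_bank()].
#' @param ... Ignored.
#' @return A tibble with `order`, `tc1`, `tc2`, `tc3`, `w`, `fnorm`,
#'   `t_peak_ms`.
#' @exportS3Method generics::tidy
#' @export
tidy.tc_bank <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$waveforms), function(i) {
    b <- x$waveforms[[i]]
    tibble::tibble(order = i, tc1 = b$tc1, tc2 = b$tc2, tc3 = b$tc3,
                   w = b$w, fnorm = b$fnorm, t_peak_ms = b$t_peak)
  }))
}
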