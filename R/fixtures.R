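#' Synthetic kinetic schemes for testing and examples
#'
#' Small receptor-like Markov schemes with known behavior:
#' \describe{
#'   \item{`linear`}{2-state C-O with weak ligand binding and fast
#'     unbinding, so state occupancy stays far from saturation and the
#'     response is effectively linear in the input.}
#'   \item{`saturating`}{2-state C-O with strong binding and slow unbinding
#'     (`recovery_rate`, ms^-1): closely spaced pulses find fewer closed
#'     receptors, so later response amplitudes are depressed.}
#'   \item{`desensitizing`}{3-state C-O-D: the open state desensitizes into
#'     D, which recovers slowly back to C, giving longer-lived pulse
#'     interactions.}
#' }
#' All output the open-state probability (weight 1 on O).
#'
#' @param type Scheme flavor.
#' @param recovery_rate Unbinding / recovery rate constant (ms^-1) for the
#'   `saturating` flavor; smaller values give longer memory.
#' @return A [kinetic_scheme()].
#' @export
synthetic_scheme <- function(type = c("saturating", "linear",
                                      "desensitizing"),
                             recovery_rate = 0.05) {
  type <- match.arg(type)
  switch(type,
    linear = kinetic_scheme(
      states = c("C", "O"),
      transitions = data.frame(
        from = c("C", "O"), to = c("O", "C"),
        rate = c(0.02, 1.0), ligand_dependent = c(TRUE, FALSE)
      ),
      output_weights = c(C = 0, O = 1),
      initial_state = "C", name = "linear-2state"
    ),
    saturating = kinetic_scheme(
      states = c("C", "O"),
      transitions = data.frame(
        from = c("C", "O"), to = c("O", "C"),
        rate = c(5, recovery_rate), ligand_dependent = c(TRUE, FALSE)
      ),
      output_weights = c(C = 0, O = 1),
      initial_state = "C", name = "saturating-2state"
    ),
    desensitizing = kinetic_scheme(
      states = c("C", "O", "D"),
      transitions = data.frame(
        from = c("C", "O", "O", "D"), to = c("O", "C", "D", "C"),
        rate = c(5, 0.2, 0.1, 0.02),
        ligand_dependent = c(TRUE, FALSE, FALSE, FALSE)
      ),
      output_weights = c(C = 0, O = 1, D = 0),
      initial_state = "C", name = "desensitizing-3state"
    )
  )
}

#' Write the bundled synthetic fixtures to a directory
#'
#' Deterministically generates everything the examples need with no
#' download: the three synthetic schemes as YAML, the default glutamate
#' transient parameters, Poisson event trains at 2 / 10 / 14 Hz, and small
#' look-up tables (R = 10) of orders 2..`max_order` built from the
#' saturating scheme.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for the Poisson trains.
#' @param max_order Highest table order to build. Default 3.
#' @param M,delta Table memory window and granularity (ms). Defaults 100
#'   and 10 (R = 10).
#' @param train_duration_ms Poisson train duration (ms). Default 2000.
#' @param dt Time step (ms). Default 0.1.
#' @return Invisibly, a named list of the file paths written.
#' @export
make_fixtures <- function(dir, seed = 1, max_order = 3, M = 100,
                          delta = 10, train_duration_ms = 2000, dt = 0.1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (type in c("linear", "saturating", "desensitizing")) {
    p <- file.path(dir, paste0("scheme-", type, ".yaml"))
    write_kinetic_scheme(synthetic_scheme(type), p)
    paths[[paste0("scheme_", type)]] <- p
  }
  tr <- glutamate_transient()
  p <- file.path(dir, "transient.yaml")
  yaml::write_yaml(
    list(peak_mM = tr$peak_mM, rise_ms = tr$rise_ms, decay_ms = tr$decay_ms,
         cleft_radius_nm = tr$cleft_radius_nm,
         cleft_height_nm = tr$cleft_height_nm,
         diffusivity_um2_ms = tr$diffusivity_um2_ms),
    p
  )
  paths$transient <- p
  for (rate in c(2, 10, 14)) {
    ev <- event_times(poisson_train(rate, train_duration_ms, dt,
                                    seed + rate))
    p <- file.path(dir, sprintf("train-%dhz.txt", rate))
    write_events(ev, p)
    paths[[sprintf("train_%dhz", rate)]] <- p
  }
  sch <- synthetic_scheme("saturating")
  for (N in 2:max_order) {
    tb <- generate_table(sch, tr, N = N, M = M, delta = delta, dt = dt)
    p <- file.path(dir, sprintf("table-saturating-n%d.bin", N))
    save_table(tb, p)
    paths[[sprintf("table_n%d", N)]] <- p
  }
  invisible(paths)
}
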