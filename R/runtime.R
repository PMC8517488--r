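#' Receptor constants for current calculations
#'
#' Defaults follow the standard glutamatergic parameterization: reversal
#' potential 0 mV for both receptors; NMDAr open-state conductances of 40
#' and 247 pS for the single- and double-glutamate-bound channel; 1 mM
#' external magnesium with an equilibrium constant of 3.57 and the classic
#' 0.062 per-mV voltage sensitivity of the block.
#'
#' @param nb_r Number of receptors (dimensionless scaling of the current).
#' @param V_rev Reversal potential (mV).
#' @param g1,g2 Single- and double-bound open conductances (pS).
#' @param Mg_o External magnesium concentration (mM).
#' @param K0 Magnesium equilibrium constant.
#' @param alpha Steepness (per mV) of the voltage-dependent transition
#'   between `g1` and `g2`; the default 0.1 makes the transition effectively
#'   complete across the physiological range.
#' @param voltage_slope Voltage sensitivity of the magnesium block (per mV).
#' @param mg_block `"standard"` uses the divisive block
#'   `g0 / (1 + (Mg_o / K0) * exp(-0.062 V))`; `"literal"` replaces the
#'   ratio with the sum `(Mg_o + K0)` for sensitivity checks.
#' @return An object of class `receptor_params`.
#' @export
receptor_params <- function(nb_r = 1, V_rev = 0, g1 = 40, g2 = 247,
                            Mg_o = 1, K0 = 3.57, alpha = 0.1,
                            voltage_slope = 0.062,
                            mg_block = c("standard", "literal")) {
  mg_block <- match.arg(mg_block)
  if (g1 <= 0 || g2 <= 0) abort("conductances must be > 0")
  if (Mg_o < 0) abort("Mg_o must be >= 0")
  if (K0 <= 0) abort("K0 must be > 0")
  structure(
    list(nb_r = nb_r, V_rev = V_rev, g1 = g1, g2 = g2, Mg_o = Mg_o,
         K0 = K0, alpha = alpha, voltage_slope = voltage_slope,
         mg_block = mg_block),
    class = "receptor_params"
  )
}

#' NMDAr conductance under magnesium block
#'
#' The magnesium-free conductance interpolates between the double- and
#' single-bound open conductances with membrane voltage:
#' `g0 = g1 + (g2 - g1) / (1 + exp(alpha * V))`. The voltage-dependent
#' magnesium block then scales it divisively,
#' `g_max = g0 / (1 + (Mg_o / K0) * exp(-0.062 * V))`, and the conducted
#' value is `g_max * O_NMDA`. With zero external magnesium, or at strongly
#' depolarized voltages, the block vanishes and `g_max -> g0`.
#'
#' @param O_NMDA Open-state probability in `[0, 1]` (vectorized).
#' @param V Membrane voltage (mV, vectorized).
#' @param params A [receptor_params()].
#' @return Conductance (pS).
#' @export
nmda_conductance <- function(O_NMDA, V, params = receptor_params()) {
  if (any(O_NMDA < -1e-12) || any(O_NMDA > 1 + 1e-12)) {
    abort("O_NMDA must lie in [0, 1]")
  }
  g0 <- params$g1 + (params$g2 - params$g1) / (1 + exp(params$alpha * V))
  block <- if (params$mg_block == "standard") {
    1 + (params$Mg_o / params$K0) * exp(-params$voltage_slope * V)
  } else {
    1 + (params$Mg_o + params$K0) * exp(-params$voltage_slope * V)
  }
  (g0 / block) * O_NMDA
}

#' Receptor-mediated synaptic current
#'
#' `I = nb_r * (V - V_rev) * g`, reported in pA (the pS x mV product scaled
#' by 1e-3). With the usual sign convention the current is negative
#' (inward) for `V < V_rev` and positive conductance.
#'
#' @param g Single-receptor conductance (pS, vectorized).
#' @param V Membrane voltage (mV, vectorized).
#' @param params A [receptor_params()].
#' @return Current (pA).
#' @export
epsc <- function(g, V, params = receptor_params()) {
  params$nb_r * (V - params$V_rev) * g * 1e-3
}

#' Assign a response order and interpulse intervals to an event
#'
#' An event with no predecessors within the memory window is first order;
#' otherwise its order is 1 + the number of in-window predecessors, capped
#' at the model order N, and its interpulse intervals are the times back to
#' the most recent predecessors. An interval of exactly M counts as inside
#' the window ("greater than M" resets the order).
#'
#' @param event_times Past event times (ms), sorted ascending, all
#'   `< t_now`.
#' @param t_now Present event time (ms).
#' @param M Memory window (ms).
#' @param N Model order.
#' @return A list with `order` (integer) and `taus` (increasing intervals
#'   to the `order - 1` most recent predecessors, ms).
#' @export
assign_order <- function(event_times, t_now, M, N) {
  event_times <- sort(as.numeric(event_times))
  if (length(event_times) && max(event_times) >= t_now) {
    abort("all past events must precede t_now")
  }
  gaps <- t_now - event_times
  within <- gaps[gaps <= M]
  k <- 1L + min(N - 1L, length(within))
  taus <- if (k > 1) sort(within)[seq_len(k - 1)] else numeric(0)
  list(order = as.integer(k), taus = taus)
}

#' Event-driven look-up-table synapse
#'
#' Couples a generated [generate_table()] amplitude table with a
#' [tc_bank()] of per-order basis waveforms. Events are processed in
#' timestamp order; each event is assigned an order and quantized
#' interpulse intervals, its amplitude is fetched from the corresponding
#' order sub-table, and the output trace is the additive superposition of
#' amplitude-scaled basis waveforms.
#'
#' @param table A `lookup_table`.
#' @param bank A [tc_bank()] with at least `table$N` waveforms (a shorter
#'   bank reuses its last waveform for higher orders).
#' @return An object of class `lut_synapse` with empty event state.
#' @export
lut_synapse <- function(table, bank) {
  if (!inherits(table, "lookup_table")) abort("table must be a lookup_table")
  if (!inherits(bank, "tc_bank")) abort("bank must be a tc_bank")
  structure(
    list(
      table = table, bank = bank, events = numeric(0),
      contributions = tibble::tibble(
        time_ms = numeric(0), order = integer(0), amplitude = numeric(0)
      )
    ),
    class = "lut_synapse"
  )
}

bank_waveform <- function(bank, order) {
  bank$waveforms[[min(order, length(bank$waveforms))]]
}

#' Process one presynaptic event
#'
#' Assigns order and interpulse intervals from the synapse's event buffer,
#' quantizes and flattens them, fetches the amplitude from the order's
#' sub-table, and records the contribution. Returns the updated synapse
#' (functional update); the fetched amplitude is available as
#' `attr(., "amplitude")`.
#'
#' @param synapse A [lut_synapse()].
#' @param t_now Event time (ms), not before the last processed event.
#' @return The updated `lut_synapse`.
#' @export
process_event <- function(synapse, t_now) {
  tb <- synapse$table
  if (length(synapse$events) && t_now < max(synapse$events)) {
    abort("events must be processed in timestamp order")
  }
  asg <- assign_order(synapse$events[synapse$events < t_now], t_now,
                      tb$M, tb$N)
  bins <- quantize_ipis(asg$taus, tb$delta, tb$M)
  k <- length(bins) + 1L  # quantization may drop intervals
  idx <- flatten_index(bins)
  sub <- tb$tables[[k]]
  if (idx + 1 > length(sub)) {
    abort(sprintf("lookup index %d out of range for order %d", idx, k))
  }
  amp <- sub[idx + 1]
  synapse$events <- c(synapse$events, t_now)
  synapse$contributions <- dplyr::bind_rows(
    synapse$contributions,
    tibble::tibble(time_ms = t_now, order = k, amplitude = amp)
  )
  attr(synapse, "amplitude") <- amp
  synapse
}

#' Process a whole event train
#'
#' @param synapse A [lut_synapse()].
#' @param times Event times (ms); sorted internally.
#' @return The updated `lut_synapse`.
#' @export
process_events <- function(synapse, times) {
  for (t in sort(as.numeric(times))) synapse <- process_event(synapse, t)
  synapse
}

# shared additive superposition of amplitude-scaled basis waveforms;
# contributions must be chronological so floating-point summation order is
# reproducible across models
superpose_waveforms <- function(times, amplitudes, waveforms, dt, duration) {
  tt <- seq(0, duration, by = dt)
  val <- numeric(length(tt))
  for (i in seq_along(times)) {
    i0 <- which(tt >= times[i])[1]
    if (is.na(i0)) next
    rel <- tt[i0:length(tt)] - times[i]
    val[i0:length(tt)] <- val[i0:length(tt)] +
      amplitudes[i] * evaluate_basis(waveforms[[i]], rel)
  }
  tibble::tibble(time_ms = tt, value = val)
}

#' Sampled output trace of a processed synapse
#'
#' `trace(t) = sum_i A_i * y_hat_{order_i}(t - t_i)` over all recorded
#' contributions: conductance for AMPAr-style tables, open probability for
#' NMDAr-style tables.
#'
#' @param synapse A [lut_synapse()] with events processed.
#' @param dt Sample step (ms).
#' @param duration Trace duration (ms).
#' @return A tibble with `time_ms`, `value`.
#' @export
output_trace <- function(synapse, dt, duration) {
  cb <- synapse$contributions
  wfs <- lapply(cb$order, function(o) bank_waveform(synapse$bank, o))
  superpose_waveforms(cb$time_ms, cb$amplitude, wfs, dt, duration)
}

#' Run a look-up-table synapse over an event train
#'
#' Convenience wrapper: process all events and sample the output trace.
#'
#' @inheritParams output_trace
#' @param table A `lookup_table`.
#' @param bank A [tc_bank()].
#' @param events Event times (ms).
#' @return A tibble with `time_ms`, `value`.
#' @export
lut_trace <- function(table, bank, events, dt, duration) {
  output_trace(process_events(lut_synapse(table, bank), events),
               dt, duration)
}

#' Linear exponential baseline synapse
#'
#' The classic linear synapse: every event elicits the same fixed-amplitude
#' copy of a single basis waveform, superposed additively. Equivalent to a
#' look-up-table synapse whose table entries are all equal to the
#' first-order amplitude; with such a constant table the two models agree
#' bitwise on any event train.
#'
#' @param events Event times (ms).
#' @param waveform A [basis_waveform()] (the order-1 template).
#' @param amplitude Fixed response amplitude (output units).
#' @param dt Sample step (ms).
#' @param duration Trace duration (ms).
#' @return A tibble with `time_ms`, `value`.
#' @export
exponential_synapse <- function(events, waveform, amplitude, dt, duration) {
  events <- sort(as.numeric(events))
  superpose_waveforms(
    events, rep(amplitude, length(events)),
    rep(list(waveform), length(events)), dt, duration
  )
}
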