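#' Binary Poisson pulse train
#'
#' Independent Bernoulli draw per time bin with success probability
#' `rate_hz * dt * 1e-3`, reproducible for a given seed. The global RNG
#' state is left untouched.
#'
#' @param rate_hz Mean firing rate (Hz).
#' @param duration_ms Train duration (ms).
#' @param dt Bin width (ms); `rate_hz * dt * 1e-3` must be `< 1`.
#' @param seed Integer seed.
#' @return A tibble with `time_ms` (bin starts) and `pulse` (0/1 integer).
#' @export
poisson_train <- function(rate_hz, duration_ms, dt, seed) {
  p <- rate_hz * dt * 1e-3
  if (p >= 1) abort("rate_hz * dt * 1e-3 must be < 1")
  n <- floor(duration_ms / dt)
  pulse <- with_local_seed(seed, rbinom(n, 1L, p))
  tibble::tibble(time_ms = (seq_len(n) - 1) * dt, pulse = as.integer(pulse))
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Event times of a binary train
#'
#' @param train A tibble from [poisson_train()] (columns `time_ms`,
#'   `pulse`).
#' @return Numeric event times (ms).
#' @export
event_times <- function(train) {
  train$time_ms[train$pulse > 0]
}

#' Spike train container
#'
#' @param times Spike times (ms), sorted into `[0, duration]`.
#' @param duration Recording duration (ms).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, duration) {
  times <- sort(as.numeric(times))
  if (length(times) && (min(times) < 0 || max(times) > duration)) {
    abort("spike times must lie within [0, duration]")
  }
  structure(list(times = times, duration = duration),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %g ms\n",
              length(x$times), x$duration))
  invisible(x)
}

#' Detect spikes as rising threshold crossings
#'
#' A spike time is the linearly interpolated instant at which the voltage
#' crosses the threshold (default 0 mV) during a rising phase. Crossings
#' within the refractory interval of the previous spike are discarded.
#'
#' @param voltage Voltage trace: tibble with `time_ms`, `value` (mV), or a
#'   numeric vector with `dt`.
#' @param dt Sample step (ms) for a bare vector.
#' @param threshold Crossing level (mV). Default 0.
#' @param refractory Minimum spike separation (ms). Default 1.
#' @return A [spike_train()].
#' @export
detect_spikes <- function(voltage, dt = NULL, threshold = 0,
                          refractory = 1) {
  if (is.data.frame(voltage)) {
    tt <- voltage$time_ms
    v <- voltage$value
  } else {
    if (is.null(dt)) abort("dt is required for a bare numeric trace")
    v <- as.numeric(voltage)
    tt <- seq(0, by = dt, length.out = length(v))
  }
  if (any(!is.finite(v))) abort("voltage trace must be finite")
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  times <- tt[up] + (threshold - v[up]) / (v[up + 1] - v[up]) *
    (tt[up + 1] - tt[up])
  if (length(times) > 1) {
    # sequential refractory pruning
    keep <- logical(length(times))
    keep[1] <- TRUE
    last <- times[1]
    for (i in seq_along(times)[-1]) {
      keep[i] <- (times[i] - last) >= refractory
      if (keep[i]) last <- times[i]
    }
    times <- times[keep]
  }
  spike_train(times, max(tt))
}

#' Van Rossum distance between spike trains
#'
#' Each train is convolved with a causal exponential kernel of time
#' constant `tau_vr`; the distance is the L2 norm of the difference,
#' normalized as `D^2 = (1/tau) * integral (f - g)^2 dt`. Computed by the
#' closed-form pairwise-exponential expression
#' `D^2 = (1/2) * (sum_ii' e^(-|t_i - t_i'|/tau) + sum_jj' e^(-|t_j -
#' t_j'|/tau) - 2 sum_ij e^(-|t_i - t_j|/tau))` rather than by sampled
#' convolution. Identical trains give 0; a single spike against an empty
#' train gives `1/sqrt(2)`.
#'
#' @param a,b Spike trains ([spike_train()] objects or numeric time
#'   vectors, ms).
#' @param tau_vr Kernel time constant (ms). Default 10.
#' @return Non-negative distance.
#' @export
van_rossum <- function(a, b, tau_vr = 10) {
  if (tau_vr <= 0) abort("tau_vr must be > 0")
  ta <- if (inherits(a, "spike_train")) a$times else as.numeric(a)
  tb <- if (inherits(b, "spike_train")) b$times else as.numeric(b)
  cross <- function(x, y) {
    if (!length(x) || !length(y)) return(0)
    sum(exp(-abs(outer(x, y, `-`)) / tau_vr))
  }
  d2 <- 0.5 * (cross(ta, ta) + cross(tb, tb) - 2 * cross(ta, tb))
  sqrt(max(d2, 0))
}

#' Leaky integrate-and-fire cell parameters
#'
#' A phenomenological point neuron used to translate synaptic conductance
#' into somatic spike times: a leaky membrane with a hard threshold, a
#' stereotyped spike sample at `V_peak` (so that rising zero-crossing spike
#' detection applies), reset and refractory period.
#'
#' @param C_pF Membrane capacitance (pF).
#' @param g_leak_nS Leak conductance (nS).
#' @param E_leak Leak reversal / resting potential (mV).
#' @param V_thresh Firing threshold (mV).
#' @param V_peak Spike peak sample (mV).
#' @param V_reset Post-spike reset (mV).
#' @param refractory_ms Absolute refractory period (ms).
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(C_pF = 100, g_leak_nS = 10, E_leak = -65,
                        V_thresh = -50, V_peak = 30, V_reset = -65,
                        refractory_ms = 2) {
  structure(
    list(C_pF = C_pF, g_leak_nS = g_leak_nS, E_leak = E_leak,
         V_thresh = V_thresh, V_peak = V_peak, V_reset = V_reset,
         refractory_ms = refractory_ms),
    class = "cell_params"
  )
}

#' Single-compartment conductance-driven point neuron
#'
#' Integrates `C dV/dt = -g_leak (V - E_leak) - I_AMPA - I_NMDA` with
#' forward Euler at the trace time step. AMPA input is a summed
#' conductance trace (pS); NMDA input is a summed open-probability trace
#' whose conductance is evaluated against the instantaneous membrane
#' voltage through the magnesium block. Threshold crossings emit a
#' stereotyped spike sample followed by reset and refractoriness. Fully
#' deterministic.
#'
#' @param g_ampa Summed AMPA conductance (pS): tibble (`time_ms`, `value`)
#'   or numeric vector.
#' @param o_nmda Optional summed NMDA open probability, same length/grid.
#' @param dt Sample step (ms) for bare vectors.
#' @param cell A [cell_params()].
#' @param ampa_params,nmda_params [receptor_params()] for each receptor
#'   (their `nb_r` acts as a synaptic weight).
#' @return A tibble with `time_ms`, `value` (membrane voltage, mV).
#' @export
point_neuron <- function(g_ampa, o_nmda = NULL, dt = NULL,
                         cell = cell_params(),
                         ampa_params = receptor_params(),
                         nmda_params = receptor_params()) {
  if (is.data.frame(g_ampa)) {
    tt <- g_ampa$time_ms
    ga <- g_ampa$value
    dt <- tt[2] - tt[1]
  } else {
    if (is.null(dt)) abort("dt is required for bare numeric traces")
    ga <- as.numeric(g_ampa)
    tt <- seq(0, by = dt, length.out = length(ga))
  }
  on <- if (is.null(o_nmda)) {
    NULL
  } else if (is.data.frame(o_nmda)) {
    o_nmda$value
  } else {
    as.numeric(o_nmda)
  }
  if (!is.null(on) && length(on) != length(ga)) {
    abort("AMPA and NMDA traces must share the time grid")
  }
  n <- length(ga)
  v <- numeric(n)
  v[1] <- cell$E_leak
  refr_until <- -Inf
  for (i in seq_len(n - 1)) {
    if (tt[i] < refr_until) {
      v[i + 1] <- cell$V_reset
      next
    }
    i_syn <- epsc(ga[i], v[i], ampa_params)
    if (!is.null(on)) {
      # summed open probability scales linearly; evaluate the block at O = 1
      gmax <- nmda_conductance(1, v[i], nmda_params)
      i_syn <- i_syn + epsc(gmax * on[i], v[i],
                            receptor_params(nb_r = nmda_params$nb_r,
                                            V_rev = nmda_params$V_rev))
    }
    # leak term nS*mV = pA; i_syn already in pA; C in pF, so dv is in mV
    dv <- dt * (-cell$g_leak_nS * (v[i] - cell$E_leak) - i_syn) / cell$C_pF
    v_next <- v[i] + dv
    if (!is.finite(v_next)) {
      abort(sprintf("membrane integration diverged at t = %g ms", tt[i]))
    }
    if (v_next >= cell$V_thresh) {
      v[i + 1] <- cell$V_peak
      refr_until <- tt[i + 1] + cell$refractory_ms
    } else {
      v[i + 1] <- v_next
    }
  }
  tibble::tibble(time_ms = tt, value = v)
}

#' Accuracy and spike-synchrony validation protocol
#'
#' Replays the comparison protocol used to characterize look-up-table
#' synapses against their kinetic ground truth and a linear exponential
#' baseline. For each (rate, seed): a Poisson train drives a single synapse
#' of each model and the trace-level NRMSE against the kinetic output is
#' recorded; optionally, `n_synapses` independently driven synapses per
#' model are summed into a point neuron and the van Rossum distance between
#' each model's spike train and the kinetic reference is recorded.
#'
#' @param scheme A [kinetic_scheme()] (the ground truth).
#' @param transient A [glutamate_transient()].
#' @param table A `lookup_table` generated from `scheme`.
#' @param bank A [tc_bank()].
#' @param rates Input rates (Hz). Default `c(2, 4, 6, 8, 10, 12, 14)`.
#' @param seeds Integer seeds, one trial per seed. Default `1:5`.
#' @param duration_ms Train duration (ms). Default 20000.
#' @param dt Time step (ms). Default 0.1.
#' @param models Subset of `c("kinetic", "lutsyn", "exponential")`.
#' @param n_synapses Synapses per cell for the spike-synchrony stage; 0
#'   skips it. Default 0 (trace-level only).
#' @param syn_weight Per-synapse weight (receptor count) applied to the
#'   summed conductance driving the point neuron.
#' @param tau_vr Van Rossum kernel time constant (ms). Default 10.
#' @param cell A [cell_params()].
#' @return A tibble with one row per (model, rate, seed): `model`,
#'   `rate_hz`, `seed`, `n_events`, `nrmse` and (when `n_synapses > 0`)
#'   `vrd`, `n_spikes`, `n_spikes_ref`.
#' @export
run_validation <- function(scheme, transient, table, bank,
                           rates = c(2, 4, 6, 8, 10, 12, 14),
                           seeds = 1:5, duration_ms = 20000, dt = 0.1,
                           models = c("kinetic", "lutsyn", "exponential"),
                           n_synapses = 0, syn_weight = 1, tau_vr = 10,
                           cell = cell_params()) {
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(table) || is.null(scheme)) {
    abort("a generated table and matching kinetic scheme are required")
  }
  a1 <- table$tables[[1]][1]
  b1 <- bank_waveform(bank, 1)

  model_trace <- function(model, events) {
    switch(model,
      kinetic = {
        g <- glutamate_trace(events, transient, dt, duration_ms)
        sim <- simulate_scheme(scheme, g, dt)
        tibble::tibble(time_ms = sim$time_ms, value = sim$output)
      },
      lutsyn = lut_trace(table, bank, events, dt, duration_ms),
      exponential = exponential_synapse(events, b1, a1, dt, duration_ms)
    )
  }

  rows <- list()
  for (rate in rates) {
    for (seed in seeds) {
      events <- event_times(poisson_train(rate, duration_ms, dt, seed))
      ref <- model_trace("kinetic", events)

      cell_data <- NULL
      if (n_synapses > 0) {
        syn_events <- lapply(seq_len(n_synapses), function(s) {
          event_times(poisson_train(rate, duration_ms, dt,
                                    seed * 10000 + s))
        })
        sum_trace <- function(model) {
          tot <- numeric(nrow(ref))
          for (ev in syn_events) tot <- tot + model_trace(model, ev)$value
          tot * syn_weight
        }
        ref_g <- sum_trace("kinetic")
        ref_spikes <- detect_spikes(point_neuron(ref_g, dt = dt,
                                                 cell = cell))
        cell_data <- list(sum_trace = sum_trace, ref_spikes = ref_spikes)
      }

      for (model in models) {
        est <- model_trace(model, events)
        row <- tibble::tibble(
          model = model, rate_hz = rate, seed = seed,
          n_events = length(events),
          nrmse = nrmse(ref$value, est$value)
        )
        if (!is.null(cell_data)) {
          g_mod <- cell_data$sum_trace(model)
          spikes <- detect_spikes(point_neuron(g_mod, dt = dt, cell = cell))
          row$vrd <- van_rossum(spikes, cell_data$ref_spikes, tau_vr)
          row$n_spikes <- length(spikes$times)
          row$n_spikes_ref <- length(cell_data$ref_spikes$times)
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- list(
    rates = rates, seeds = seeds, duration_ms = duration_ms, dt = dt,
    models = models, n_synapses = n_synapses, syn_weight = syn_weight,
    tau_vr = tau_vr
  )
  class(out) <- c("validation_report", class(out))
  out
}

#' Write a trace or event list to plain text
#'
#' Traces go to two-column CSV (`time_ms`, `value`); event trains to one
#' event time (ms) per line.
#'
#' @param trace A tibble with `time_ms`, `value`.
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace[, c("time_ms", "value")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' @rdname write_trace
#' @param events Event times (ms).
#' @export
write_events <- function(events, path) {
  writeLines(format(as.numeric(events), trim = TRUE, digits = 15), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_events <- function(path) {
  as.numeric(readLines(path))
}
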