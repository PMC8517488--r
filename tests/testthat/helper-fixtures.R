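# Shared fixtures, memoized per test run. Everything is generated in code;
# the expensive kinetic simulations (table generation, waveform isolation)
# are built once and reused across test files.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx, inherits = FALSE)) {
    assign(key, force(expr), envir = .fx)
  }
  get(key, envir = .fx)
}

fx_transient <- function() glutamate_transient()

fx_saturating <- function() synthetic_scheme("saturating")
fx_linear <- function() synthetic_scheme("linear")
fx_desens <- function() synthetic_scheme("desensitizing")

# R = 10 (M = 100 ms, delta = 10 ms), order 3, saturating scheme
fx_table_n3 <- function() {
  memo("table_n3", generate_table(
    fx_saturating(), fx_transient(), N = 3, M = 100, delta = 10, dt = 0.1
  ))
}

fx_table_n2_r5 <- function() {
  memo("table_n2_r5", generate_table(
    fx_saturating(), fx_transient(), N = 2, M = 50, delta = 10, dt = 0.1
  ))
}

# per-order isolated average waveforms on a 10 Hz train (saturating scheme)
fx_avg_waveforms <- function() {
  memo("avg_waveforms", {
    ev <- event_times(poisson_train(10, 2000, 0.1, 42))
    isolate_and_average(fx_saturating(), fx_transient(), ev, 0.1,
                        order_cap = 3, memory_window = 100)
  })
}

# basis waveform bank fitted to the average waveforms, orders 1..3
fx_bank <- function() {
  memo("bank", {
    avg <- fx_avg_waveforms()
    grid <- tc_grid(tc1 = seq(0.5, 3, 0.25), tc2 = seq(4, 14, 0.5),
                    tc3 = seq(15, 60, 2.5), w = 0.963)
    waveforms <- lapply(seq_len(nrow(avg)), function(i) {
      fit <- optimize_time_constants(avg$waveform[[i]]$value,
                                     target_fdhm = avg$fdhm_ms[i],
                                     grid = grid, dt = 0.1)
      basis_waveform(fit$tc[["tc1"]], fit$tc[["tc2"]], fit$tc[["tc3"]],
                     fit$w)
    })
    tc_bank(waveforms[order(avg$order)], receptor = fx_saturating()$name)
  })
}

# a bank replaying the same template at every order: required for the
# constant-table reduction to the linear exponential synapse, where the
# output must be a single waveform scaled by a single amplitude
fx_flat_bank <- function() {
  memo("flat_bank", {
    b1 <- fx_bank()$waveforms[[1]]
    tc_bank(list(b1, b1, b1), receptor = fx_bank()$receptor)
  })
}

# a constant-valued table (every amplitude equals the order-1 amplitude)
fx_constant_table <- function() {
  memo("constant_table", {
    tb <- fx_table_n3()
    a1 <- tb$tables[[1]][1]
    tb$tables <- lapply(tb$tables, function(v) rep(a1, length(v)))
    tb
  })
}

random_spike_train <- function(n, duration, seed) {
  with_seed_local(seed, sort(runif(n, 0, duration)))
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}
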