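#' Construct a Markov kinetic receptor scheme
#'
#' A kinetic scheme is a continuous-time Markov state model of a ligand-gated
#' receptor. States are connected by directed transitions with first-order
#' rate constants; transitions flagged as ligand-dependent have their
#' effective rate multiplied by the instantaneous glutamate concentration
#' (so their base rate carries units of mM^-1 ms^-1, all others ms^-1).
#' The scheme's scalar output is the dot product of the state-occupancy
#' probabilities with per-state output weights: channel conductance in pS
#' for AMPAr-style schemes, or a 0/1 open-state indicator whose weighted sum
#' is an open probability for NMDAr-style schemes.
#'
#' @param states Character vector of state labels.
#' @param transitions Data frame with columns `from`, `to` (state labels),
#'   `rate` (non-negative, ms^-1 or mM^-1 ms^-1) and `ligand_dependent`
#'   (logical).
#' @param output_weights Named (or positional) numeric vector, one weight per
#'   state.
#' @param initial_distribution Probability vector over states (sums to 1).
#'   Alternatively supply `initial_state`, a single label given probability 1.
#' @param initial_state Convenience alternative to `initial_distribution`.
#' @param name Optional scheme name (used in printing and provenance).
#'
#' @return An object of class `kinetic_scheme`.
#' @export
#' @examples
#' sch <- kinetic_scheme(
#'   states = c("C", "O"),
#'   transitions = data.frame(
#'     from = c("C", "O"), to = c("O", "C"),
#'     rate = c(5, 0.5), ligand_dependent = c(TRUE, FALSE)
#'   ),
#'   output_weights = c(C = 0, O = 1),
#'   initial_state = "C"
#' )
#' sch
kinetic_scheme <- function(states, transitions, output_weights,
                           initial_distribution = NULL, initial_state = NULL,
                           name = "scheme") {
  states <- as.character(states)
  if (anyDuplicated(states)) abort("duplicate state labels")
  transitions <- as.data.frame(transitions)
  req <- c("from", "to", "rate", "ligand_dependent")
  if (!all(req %in% names(transitions))) {
    abort(paste("transitions must have columns:", paste(req, collapse = ", ")))
  }
  if (!all(transitions$from %in% states) || !all(transitions$to %in% states)) {
    abort("transition endpoints must be declared states")
  }
  if (any(transitions$from == transitions$to)) abort("self-transitions are not allowed")
  if (any(transitions$rate < 0)) abort("all rate constants must be >= 0")

  if (!is.null(initial_state)) {
    if (!is.null(initial_distribution)) {
      abort("give either initial_distribution or initial_state, not both")
    }
    if (!initial_state %in% states) abort("unknown initial_state")
    initial_distribution <- as.numeric(states == initial_state)
  }
  if (is.null(initial_distribution)) abort("an initial distribution is required")
  initial_distribution <- as.numeric(initial_distribution)
  if (length(initial_distribution) != length(states)) {
    abort("initial_distribution length must match number of states")
  }
  if (any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-12) {
    abort("initial_distribution must be non-negative and sum to 1")
  }

  output_weights <- as.numeric(output_weights)
  if (length(output_weights) != length(states)) {
    abort("output_weights length must match number of states")
  }

  # connectivity of the undirected transition graph
  n <- length(states)
  adj <- matrix(FALSE, n, n)
  i <- match(transitions$from, states)
  j <- match(transitions$to, states)
  adj[cbind(i, j)] <- TRUE
  adj <- adj | t(adj)
  seen <- logical(n)
  seen[1] <- TRUE
  repeat {
    reach <- seen | apply(adj[, seen, drop = FALSE], 1, any)
    if (identical(reach, seen)) break
    seen <- reach
  }
  if (!all(seen)) abort("scheme graph must be connected")

  structure(
    list(
      name = name,
      states = states,
      transitions = tibble::as_tibble(transitions),
      output_weights = setNames(output_weights, states),
      initial_distribution = setNames(initial_distribution, states)
    ),
    class = "kinetic_scheme"
  )
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> ", x$name, "\n", sep = "")
  cat("  states: ", paste(x$states, collapse = ", "), "\n", sep = "")
  cat("  transitions: ", nrow(x$transitions),
      " (", sum(x$transitions$ligand_dependent), " ligand-dependent)\n",
      sep = "")
  invisible(x)
}

# Generator matrices: G(L) = G_base + L * G_ligand, with dP/dt = G(L) %*% P.
scheme_generators <- function(scheme) {
  n <- length(scheme$states)
  Kb <- matrix(0, n, n)
  Kl <- matrix(0, n, n)
  i <- match(scheme$transitions$from, scheme$states)
  j <- match(scheme$transitions$to, scheme$states)
  lig <- scheme$transitions$ligand_dependent
  r <- scheme$transitions$rate
  for (k in seq_along(r)) {
    if (lig[k]) Kl[i[k], j[k]] <- Kl[i[k], j[k]] + r[k]
    else Kb[i[k], j[k]] <- Kb[i[k], j[k]] + r[k]
  }
  list(
    Gb = t(Kb) - diag(rowSums(Kb), n),
    Gl = t(Kl) - diag(rowSums(Kl), n)
  )
}

#' Read or write a kinetic scheme as YAML
#'
#' Plain-text config with keys `name`, `states`, `transitions` (list of
#' `from`/`to`/`rate`/`ligand_dependent` entries), `output_weights`
#' (named by state) and `initial_state` or `initial_distribution`, so that
#' literature rate constants can be transcribed without code changes.
#'
#' @param path File path.
#' @return `read_kinetic_scheme()` returns a [kinetic_scheme()].
#' @export
read_kinetic_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  tr <- dplyr::bind_rows(lapply(cfg$transitions, tibble::as_tibble))
  tr$ligand_dependent <- as.logical(tr$ligand_dependent)
  ow <- unlist(cfg$output_weights)[cfg$states]
  kinetic_scheme(
    states = cfg$states, transitions = tr, output_weights = ow,
    initial_distribution = if (!is.null(cfg$initial_distribution)) {
      unlist(cfg$initial_distribution)[cfg$states]
    },
    initial_state = cfg$initial_state,
    name = cfg$name %||% "scheme"
  )
}

#' @rdname read_kinetic_scheme
#' @param scheme A [kinetic_scheme()].
#' @export
write_kinetic_scheme <- function(scheme, path) {
  cfg <- list(
    name = scheme$name,
    states = scheme$states,
    transitions = lapply(seq_len(nrow(scheme$transitions)), function(k) {
      as.list(scheme$transitions[k, ])
    }),
    output_weights = as.list(scheme$output_weights),
    initial_distribution = as.list(scheme$initial_distribution)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Stereotyped glutamate cleft transient
#'
#' The concentration time course of cleft glutamate following a single
#' vesicle release, modelled as a normalized biexponential pulse
#' `c(t) = peak * (exp(-t/decay) - exp(-t/rise)) / k` with `k` chosen so the
#' pulse peaks exactly at `peak_mM`. The cleft geometry (radius, height,
#' diffusivity) is carried for provenance; an analytic disc-diffusion
#' solution can be slotted in through the `value_fn` hook.
#'
#' @param peak_mM Peak cleft concentration (mM). Default 1.
#' @param rise_ms,decay_ms Rise and decay time constants (ms); `rise_ms`
#'   must be strictly smaller than `decay_ms`.
#' @param cleft_radius_nm,cleft_height_nm,diffusivity_um2_ms Cleft geometry
#'   (defaults 60 nm, 20 nm, 0.33 um^2/ms); provenance only for the
#'   biexponential form.
#' @param value_fn Optional replacement `function(t)` returning mM for
#'   `t >= 0` (vectorized); overrides the biexponential.
#' @return An object of class `glutamate_transient`.
#' @export
glutamate_transient <- function(peak_mM = 1, rise_ms = 0.1, decay_ms = 1.2,
                                cleft_radius_nm = 60, cleft_height_nm = 20,
                                diffusivity_um2_ms = 0.33, value_fn = NULL) {
  if (is.null(value_fn)) {
    if (!(rise_ms > 0 && decay_ms > rise_ms)) {
      abort("need 0 < rise_ms < decay_ms")
    }
    if (peak_mM < 0) abort("peak_mM must be >= 0")
  }
  structure(
    list(
      peak_mM = peak_mM, rise_ms = rise_ms, decay_ms = decay_ms,
      cleft_radius_nm = cleft_radius_nm, cleft_height_nm = cleft_height_nm,
      diffusivity_um2_ms = diffusivity_um2_ms, value_fn = value_fn
    ),
    class = "glutamate_transient"
  )
}

#' Evaluate a glutamate transient at elapsed times
#'
#' @param transient A [glutamate_transient()].
#' @param t Elapsed time since release (ms); values `< 0` give 0.
#' @return Concentration (mM), same length as `t`.
#' @export
transient_value <- function(transient, t) {
  if (!is.null(transient$value_fn)) {
    out <- ifelse(t < 0, 0, transient$value_fn(pmax(t, 0)))
    return(out)
  }
  tr <- transient$rise_ms
  td <- transient$decay_ms
  # argmax of the unnormalized difference of exponentials
  tstar <- log(td / tr) * tr * td / (td - tr)
  norm <- exp(-tstar / td) - exp(-tstar / tr)
  out <- ifelse(t < 0, 0,
                transient$peak_mM * (exp(-t / td) - exp(-t / tr)) / norm)
  pmax(out, 0)
}

#' Glutamate concentration trace for a pulse train
#'
#' Superposes one identical transient per presynaptic pulse on a fixed-step
#' time grid.
#'
#' @param pulse_times Pulse onset times (ms), within `[0, duration)`.
#' @param transient A [glutamate_transient()].
#' @param dt Time step (ms).
#' @param duration Trace duration (ms); grid is `seq(0, duration, by = dt)`.
#' @return A tibble with columns `time_ms`, `glutamate_mM`.
#' @export
glutamate_trace <- function(pulse_times, transient, dt, duration) {
  if (dt <= 0) abort("dt must be > 0")
  pulse_times <- sort(as.numeric(pulse_times))
  if (length(pulse_times) &&
      (min(pulse_times) < 0 || max(pulse_times) >= duration)) {
    abort("all pulse_times must lie within [0, duration)")
  }
  time_ms <- seq(0, duration, by = dt)
  conc <- numeric(length(time_ms))
  for (tp in pulse_times) {
    conc <- conc + transient_value(transient, time_ms - tp)
  }
  tibble::tibble(time_ms = time_ms, glutamate_mM = conc)
}

#' Integrate a kinetic scheme under a glutamate drive
#'
#' Solves the master equation `dP/dt = G(L(t)) P` with an adaptive implicit
#' solver (stiff-capable `lsoda`, analytic Jacobian), where ligand-dependent
#' transition rates scale with the glutamate concentration `L(t)` obtained
#' by linear interpolation of the supplied trace. The solution is sampled
#' onto the trace's fixed grid.
#'
#' @param scheme A [kinetic_scheme()].
#' @param glutamate Either a tibble from [glutamate_trace()] (columns
#'   `time_ms`, `glutamate_mM`) or a numeric concentration vector sampled
#'   at `dt` starting from 0.
#' @param dt Time step (ms); required when `glutamate` is a bare vector.
#' @param rtol,atol Solver tolerances.
#' @return A tibble with `time_ms`, one probability column per state, and
#'   `output` (probabilities dotted with the scheme's output weights).
#' @export
simulate_scheme <- function(scheme, glutamate, dt = NULL,
                            rtol = 1e-9, atol = 1e-11) {
  if (is.data.frame(glutamate)) {
    time_ms <- glutamate$time_ms
    conc <- glutamate$glutamate_mM
  } else {
    if (is.null(dt)) abort("dt is required when glutamate is a bare vector")
    conc <- as.numeric(glutamate)
    time_ms <- seq(0, by = dt, length.out = length(conc))
  }
  if (any(conc < 0)) abort("glutamate concentrations must be >= 0")
  G <- scheme_generators(scheme)
  lfun <- approxfun(time_ms, conc, rule = 2)
  deriv <- function(t, p, parms) {
    list((G$Gb + lfun(t) * G$Gl) %*% p)
  }
  jac <- function(t, p, parms) {
    G$Gb + lfun(t) * G$Gl
  }
  sol <- deSolve::ode(
    y = scheme$initial_distribution, times = time_ms, func = deriv,
    parms = NULL, jacfunc = jac, jactype = "fullusr",
    method = "lsoda", rtol = rtol, atol = atol
  )
  istate <- attr(sol, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    abort(sprintf(
      "stiff solver failed (istate = %d) near t = %.6g ms",
      istate, max(sol[, 1])
    ))
  }
  probs <- sol[, -1, drop = FALSE]
  out <- tibble::as_tibble(as.data.frame(probs))
  names(out) <- scheme$states
  out <- tibble::add_column(out, time_ms = time_ms, .before = 1)
  out$output <- as.numeric(probs %*% scheme$output_weights)
  out
}

#' Isolated response amplitude of the last pulse in a train
#'
#' Simulates the full N-pulse train and the train with the last pulse
#' removed, subtracts the two output traces, and returns the peak of the
#' difference in a window after the last pulse. This subtraction isolates
#' the contribution of the final pulse even when responses overlap.
#'
#' @param scheme A [kinetic_scheme()].
#' @param transient A [glutamate_transient()].
#' @param pulse_times Strictly increasing pulse times (ms), length >= 1.
#' @param dt Time step (ms).
#' @param response_window Length (ms) of the post-pulse window searched for
#'   the peak. Default 100.
#' @return The isolated peak amplitude (output units). A non-positive peak
#'   indicates a pathological scheme and raises a warning; the signed value
#'   is returned unchanged.
#' @export
isolated_response_amplitude <- function(scheme, transient, pulse_times, dt,
                                        response_window = 100) {
  pulse_times <- as.numeric(pulse_times)
  n <- length(pulse_times)
  if (n < 1) abort("at least one pulse is required")
  if (n > 1 && any(diff(pulse_times) <= 0)) {
    abort("pulse times must be strictly increasing")
  }
  t_last <- pulse_times[n]
  duration <- t_last + response_window
  g_full <- glutamate_trace(pulse_times, transient, dt, duration)
  full <- simulate_scheme(scheme, g_full, dt)
  if (n == 1) {
    diff_out <- full$output
  } else {
    g_sub <- glutamate_trace(pulse_times[-n], transient, dt, duration)
    sub <- simulate_scheme(scheme, g_sub, dt)
    diff_out <- full$output - sub$output
  }
  sel <- full$time_ms >= t_last
  peak <- max(diff_out[sel])
  if (peak <= 0) {
    warn(sprintf(
      "isolated peak is non-positive (%.6g); pathological scheme?", peak
    ))
  }
  peak
}

`%||%` <- function(x, y) if (is.null(x)) y else x
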