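#' Ventricular myocyte parameters (ten Tusscher-Panfilov 2006)
#'
#' Maximal conductances and pump/exchanger scales of the 2006 human
#' ventricular myocyte model, with the published transmural subtype
#' differences: endocardial and epicardial cells share gKs = 0.392 nS/pF
#' while M cells use 0.098; the transient-outward conductance is 0.294 nS/pF
#' for epi/M and 0.073 for endo, and the endo s-gate has its own kinetics.
#'
#' @param subtype cell subtype, one of `"epi"`, `"endo"`, `"M"`.
#' @return A list of class `"cell_parameters"` with elements `g` (named
#'   vector of maximal conductances and scales) and `subtype`.
#' @examples
#' cell_parameters("epi")$g[["gKr"]]
#' @export
cell_parameters <- function(subtype = c("epi", "endo", "M")) {
  subtype <- match.arg(subtype)
  g <- c(
    gNa    = 14.838,       # nS/pF
    gCaL   = 0.0000398,    # cm^3 uF^-1 s^-1 (model units)
    gKr    = 0.153,
    gKs    = if (subtype == "M") 0.098 else 0.392,
    gK1    = 5.405,
    gto    = if (subtype == "endo") 0.073 else 0.294,
    gpCa   = 0.1238,
    gpK    = 0.0146,
    gbNa   = 0.00029,
    gbCa   = 0.000592,
    PNaK   = 2.724,        # pA/pF
    kNaCa  = 1000,
    Vmaxup = 0.006375,     # mM/ms
    Vrel   = 0.102         # mM/ms
  )
  stopifnot(all(g >= 0))
  structure(list(g = g, subtype = subtype), class = "cell_parameters")
}

subtype_code <- function(subtype) {
  match(subtype, c("endo", "epi", "M")) - 1L
}

#' Scale channel conductances by a drug block
#'
#' Tonic pore-block scaling: each affected maximal conductance is multiplied
#' by one minus the fractional inhibition, `g' = g * (1 - E)`, for gKr, gKs,
#' gNa and gCaL. All other model parameters are untouched, and a zero block
#' returns the input bitwise.
#'
#' @param params [cell_parameters()] object.
#' @param block [channel_block()] of inhibition fractions.
#' @return A `cell_parameters` object with scaled conductances.
#' @examples
#' p <- scale_conductances(cell_parameters("epi"), channel_block(IKr = 0.5))
#' p$g[["gKr"]]
#' @export
scale_conductances <- function(params, block) {
  stop_if(!inherits(params, "cell_parameters"), "params must be cell_parameters")
  block <- as_block(block)
  map <- c(IKr = "gKr", IKs = "gKs", INa = "gNa", ICaL = "gCaL")
  for (ch in names(map)) {
    if (block[[ch]] > 0)
      params$g[[map[[ch]]]] <- params$g[[map[[ch]]]] * (1 - block[[ch]])
  }
  params
}

#' Pacing protocol
#'
#' @param cl cycle length in ms (> 0); also taken as the RR interval for
#'   rate correction downstream.
#' @param beats number of paced beats (>= 1).
#' @param dt integration step in ms, at most 0.05.
#' @param stim_amplitude stimulus amplitude in pA/pF (applied depolarizing).
#' @param stim_duration stimulus duration in ms.
#' @return A list of class `"pacing_protocol"`.
#' @export
pacing_protocol <- function(cl = 1000, beats = 50, dt = 0.02,
                            stim_amplitude = 52, stim_duration = 1) {
  stop_if(!is.finite(cl) || cl <= 0, "cycle length must be positive")
  stop_if(!is.numeric(beats) || beats < 1, "at least one beat is required")
  stop_if(!is.finite(dt) || dt <= 0 || dt > 0.05,
          "dt must be in (0, 0.05] ms")
  stop_if(stim_amplitude <= 0 || stim_duration <= 0,
          "stimulus amplitude and duration must be positive")
  structure(list(cl = cl, beats = as.integer(beats), dt = dt,
                 stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration),
            class = "pacing_protocol")
}

#' Initial state of the myocyte model
#'
#' The published resting initial conditions: membrane potential, the twelve
#' gating variables, intracellular Na+/K+/Ca2+ and the SR release flag.
#'
#' @return Named numeric vector of the 19 state variables.
#' @export
cell_state <- function() {
  c(V = -86.2, Nai = 7.67, Ki = 138.3,
    Cai = 0.00007, CaSS = 0.00007, CaSR = 1.3, Rbar = 1,
    m = 0, h = 0.75, j = 0.75, xr1 = 0, xr2 = 1, xs = 0,
    r = 0, s = 1, d = 0, f = 1, f2 = 1, fcass = 1)
}

#' Advance the myocyte model by one step
#'
#' Rush-Larsen update for the gating variables, forward Euler for voltage
#' and ionic concentrations (with rapid-buffering calcium updates).
#'
#' @param state named state vector as from [cell_state()].
#' @param params [cell_parameters()].
#' @param dt step in ms.
#' @param stim stimulus amplitude in pA/pF (>= 0; applied as a depolarizing
#'   current for the duration of this step).
#' @return The updated state vector.
#' @export
step_cell <- function(state, params, dt, stim = 0) {
  stop_if(!inherits(params, "cell_parameters"), "params must be cell_parameters")
  stop_if(any(!is.finite(state)), "state must be finite")
  stop_if(!is.finite(dt) || dt <= 0, "dt must be positive")
  # internal sign convention: a depolarizing stimulus is a negative
  # membrane current
  tt_step_cpp(state, params$g, subtype_code(params$subtype), dt, -stim)
}

#' Simulate a paced action potential and measure APD90
#'
#' Paces a single cell for `protocol$beats` beats and returns the final
#' beat's voltage trace together with APD90, measured from the maximal
#' upstroke velocity to 90 % repolarization toward the pre-stimulus
#' diastolic potential. If the cell fails to repolarize within the cycle the
#' APD90 is reported as the available diastolic-interval bound with a
#' warning and `repolarized = FALSE`.
#'
#' @param params [cell_parameters()], possibly drug-scaled via
#'   [scale_conductances()].
#' @param protocol [pacing_protocol()].
#' @param state optional starting state (defaults to [cell_state()]).
#' @param sample_ms sampling interval of the returned trace in ms.
#' @return A list of class `"ap_trace"`: `time`, `V` (final beat), `apd90`,
#'   `vmax`, `vrest`, `repolarized`, and `state` (end state, reusable for
#'   further pacing).
#' @export
simulate_ap <- function(params, protocol, state = cell_state(),
                        sample_ms = 1) {
  stop_if(!inherits(protocol, "pacing_protocol"),
          "protocol must be a pacing_protocol")
  sample_every <- max(1L, as.integer(round(sample_ms / protocol$dt)))
  res <- tt_pace_cpp(state, params$g, subtype_code(params$subtype),
                     protocol$cl, protocol$beats, protocol$dt,
                     protocol$stim_amplitude, protocol$stim_duration,
                     sample_every)
  ap <- apd90_from_trace(res$time, res$V)
  structure(c(res[c("time", "V", "Cai")], ap, list(state = res$state)),
            class = "ap_trace")
}

# APD90 from a single-beat voltage trace sampled on a uniform grid.
apd90_from_trace <- function(time, V) {
  dv <- diff(V) / diff(time)
  iup <- which.max(dv)               # maximal upstroke velocity
  t_up <- time[iup]
  vrest <- V[1]                      # pre-stimulus diastolic potential
  vmax <- max(V[iup:length(V)])
  v90 <- vmax - 0.9 * (vmax - vrest)
  ipk <- which.max(V)
  below <- which(V[-seq_len(ipk)] <= v90)
  if (length(below) == 0) {
    warning("cell failed to repolarize to 90 % within the cycle; ",
            "APD90 reported as the diastolic-interval bound")
    return(list(apd90 = time[length(time)] - t_up, vmax = vmax,
                vrest = vrest, repolarized = FALSE))
  }
  i2 <- ipk + below[1]
  i1 <- i2 - 1L
  # linear interpolation of the crossing time
  tc <- time[i1] + (v90 - V[i1]) * (time[i2] - time[i1]) / (V[i2] - V[i1])
  list(apd90 = tc - t_up, vmax = vmax, vrest = vrest, repolarized = TRUE)
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf(
    "Action potential: APD90 = %.1f ms (Vrest %.1f mV, Vmax %.1f mV)%s\n",
    x$apd90, x$vrest, x$vmax,
    if (x$repolarized) "" else " [did not repolarize]"))
  invisible(x)
}
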