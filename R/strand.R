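#' Transmural strand configuration
#'
#' A 1D monodomain cable of endocardial, mid-myocardial and epicardial cells
#' stimulated at the endo end, with a virtual unipolar electrode on the
#' cable axis beyond the epi end. The transmural APD gradient (long-APD M
#' cells mid-strand) is what gives the pseudo-ECG its upright T wave.
#'
#' @param n_endo,n_m,n_epi cell counts per subtype (total >= 20).
#' @param dx inter-cell spacing in mm.
#' @param diff_coef voltage diffusion coefficient in mm^2/ms.
#' @param electrode_mm electrode distance beyond the epi end in mm (> 0).
#' @param protocol [pacing_protocol()] used for strand pacing (its `beats`
#'   counts strand beats; see `prepace_beats`).
#' @param prepace_beats single-cell pre-pacing beats used to bring each
#'   subtype to its drugged steady state before assembling the strand.
#' @return A list of class `"strand_config"`.
#' @export
strand_config <- function(n_endo = 25, n_m = 35, n_epi = 40,
                          dx = 0.15, diff_coef = 0.154,
                          electrode_mm = 20,
                          protocol = pacing_protocol(beats = 2),
                          prepace_beats = 50) {
  stop_if(n_endo < 0 || n_m < 0 || n_epi < 0, "cell counts must be >= 0")
  stop_if(n_endo + n_m + n_epi < 20, "strand must have at least 20 cells")
  stop_if(!is.finite(dx) || dx <= 0, "dx must be positive")
  stop_if(!is.finite(diff_coef) || diff_coef < 0,
          "diffusion coefficient must be >= 0")
  stop_if(!is.finite(electrode_mm) || electrode_mm <= 0,
          "electrode must sit off the strand (distance > 0)")
  stop_if(!inherits(protocol, "pacing_protocol"),
          "protocol must be a pacing_protocol")
  structure(list(n_endo = n_endo, n_m = n_m, n_epi = n_epi, dx = dx,
                 diff_coef = diff_coef, electrode_mm = electrode_mm,
                 protocol = protocol,
                 prepace_beats = as.integer(prepace_beats)),
            class = "strand_config")
}

strand_subtypes <- function(config) {
  rep(c("endo", "M", "epi"), c(config$n_endo, config$n_m, config$n_epi))
}

#' Simulate the strand under a uniform drug block
#'
#' Each subtype is first pre-paced as a single cell (with the drug-scaled
#' conductances) to its periodic steady state; those states seed the strand,
#' which is then paced from the endo end for `protocol$beats` beats. The
#' monodomain cable is solved by operator splitting: a reaction step per
#' cell followed by an explicit diffusion step with no-flux boundaries.
#'
#' @param config [strand_config()].
#' @param block [channel_block()] applied uniformly to every cell.
#' @return A list of class `"strand_field"`: `time` (ms), `x` (cell
#'   positions, mm), `V` (time x cell voltage matrix for the final beat) and
#'   `config`.
#' @export
simulate_strand <- function(config, block = channel_block()) {
  stop_if(!inherits(config, "strand_config"), "config must be a strand_config")
  block <- as_block(block)
  subs <- strand_subtypes(config)
  groups <- unique(subs)
  prot <- config$protocol

  params_list <- vector("list", length(groups))
  states <- matrix(NA_real_, nrow = 19, ncol = length(subs))
  subtype_codes <- integer(length(groups))
  for (gi in seq_along(groups)) {
    p <- scale_conductances(cell_parameters(groups[gi]), block)
    params_list[[gi]] <- p$g
    subtype_codes[gi] <- subtype_code(groups[gi])
    st <- cell_state()
    if (config$prepace_beats > 0) {
      pre <- tt_pace_cpp(st, p$g, subtype_codes[gi], prot$cl,
                         config$prepace_beats, prot$dt,
                         prot$stim_amplitude, prot$stim_duration, 100000L)
      st <- pre$state
    }
    states[, subs == groups[gi]] <- st
  }
  group_idx <- match(subs, groups) - 1L

  sample_every <- max(1L, as.integer(round(1 / prot$dt)))  # 1 ms sampling
  nstim <- max(3L, as.integer(round(length(subs) * 0.03)))
  res <- tt_strand_cpp(states, params_list, group_idx, subtype_codes,
                       config$diff_coef, config$dx, prot$cl, prot$beats,
                       prot$dt, prot$stim_amplitude, prot$stim_duration,
                       nstim, sample_every)
  x <- (seq_along(subs) - 1) * config$dx
  if (config$diff_coef > 0) {
    act <- activation_times(res$time, res$V)
    if (any(!is.finite(act)))
      stop("conduction failure: excitation did not reach ",
           sum(!is.finite(act)), " cell(s)", call. = FALSE)
  }
  structure(list(time = res$time, x = x, V = res$V, config = config),
            class = "strand_field")
}

#' Activation time per cell
#'
#' Time at which each cell's membrane potential first crosses a threshold
#' (default 0 mV) on the recorded beat, interpolated linearly between
#' samples; `NA` where no crossing occurs.
#'
#' @param time time grid (ms).
#' @param V time x cell voltage matrix.
#' @param threshold crossing threshold in mV.
#' @return Numeric vector of activation times (ms).
#' @export
activation_times <- function(time, V, threshold = 0) {
  apply(V, 2, function(v) {
    i <- which(v > threshold)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(time[1])
    time[i - 1] + (threshold - v[i - 1]) * (time[i] - time[i - 1]) /
      (v[i] - v[i - 1])
  })
}

#' Pseudo-ECG from a strand voltage field
#'
#' Unipolar lead approximation for a 1D source: the extracellular potential
#' at an axial electrode is proportional to the integral of the spatial
#' voltage gradient weighted by the gradient of 1/r,
#' \eqn{\Phi_e(t) \propto -\int (\partial V/\partial x)\,
#' \partial(1/r)/\partial x \, dx}. A spatially uniform field therefore
#' yields an identically zero trace, and moving the electrode away only
#' scales the amplitude.
#'
#' @param field `strand_field` from [simulate_strand()].
#' @param config optional [strand_config()] overriding `field$config`
#'   (e.g. to move the electrode).
#' @return A data frame of class `"pseudoecg"` with columns `time_ms` and
#'   `phi` (arbitrary units); attribute `rr_ms` carries the pacing cycle
#'   length.
#' @export
compute_pseudoecg <- function(field, config = NULL) {
  stop_if(!inherits(field, "strand_field"), "field must be a strand_field")
  if (is.null(config)) config <- field$config
  V <- field$V
  x <- field$x
  stop_if(ncol(V) < 3, "field must span at least 3 cells")
  xe <- max(x) + config$electrode_mm
  # gradients at interior midpoints
  xm <- (x[-1] + x[-length(x)]) / 2
  dx <- diff(x)
  dVdx <- t(apply(V, 1, diff)) / rep(dx, each = nrow(V))
  r <- xe - xm
  dinv <- 1 / r^2   # d(1/r)/dx for r = xe - x
  phi <- -as.vector(dVdx %*% (dinv * dx))
  structure(data.frame(time_ms = field$time, phi = phi),
            class = c("pseudoecg", "data.frame"),
            rr_ms = config$protocol$cl)
}

#' Measure the QT interval on a pseudo-ECG beat
#'
#' QRS onset is the first time the absolute slope of the trace exceeds 5 %
#' of its maximum; the end of the T wave is located by the tangent method —
#' the steepest tangent on the terminal limb of the T wave is extrapolated
#' to its intersection with the isoelectric baseline. Both landmarks are
#' invariant to time translation and amplitude scaling of the trace.
#'
#' @param trace a `pseudoecg` data frame (or any data frame with `time_ms`
#'   and `phi` sampled uniformly, one beat).
#' @param twave_after_ms start of the T-wave search window, in ms after QRS
#'   onset.
#' @return A list of class `"qt_measure"`: `qt_ms`, `qrs_onset_ms`,
#'   `tend_ms`, `tpeak_ms`, `baseline`.
#' @export
measure_qt <- function(trace, twave_after_ms = 120) {
  stop_if(!all(c("time_ms", "phi") %in% names(trace)),
          "trace needs columns time_ms and phi")
  t <- trace$time_ms; phi <- trace$phi
  stop_if(length(t) < 10, "trace too short")
  dphi <- diff(phi) / diff(t)
  tm <- (t[-1] + t[-length(t)]) / 2

  thr <- 0.05 * max(abs(dphi))
  onset <- tm[which(abs(dphi) > thr)[1]]

  # isoelectric baseline: median of the terminal diastolic samples
  tail_idx <- t >= (max(t) - 0.1 * (max(t) - min(t)))
  baseline <- median(phi[tail_idx])

  win <- t >= (onset + twave_after_ms)
  stop_if(!any(win), "no samples in the T-wave window")
  dev <- abs(phi - baseline) * win
  ipk <- which.max(dev)
  stop_if(dev[ipk] < 10 * .Machine$double.eps + 1e-12 * max(abs(phi)),
          "no detectable T wave")
  tpeak <- t[ipk]

  # steepest return-to-baseline slope after the T peak
  post <- which(tm > tpeak)
  stop_if(length(post) < 2, "T wave truncated by the end of the trace")
  slopes <- dphi[post]
  sign_ret <- -sign(phi[ipk] - baseline)     # direction back to baseline
  cand <- slopes * sign_ret
  is_ <- post[which.max(cand)]
  stop_if(max(cand) <= 0, "no descending limb after the T peak")
  ts <- tm[is_]
  ys <- (phi[is_] + phi[is_ + 1]) / 2
  tend <- ts + (baseline - ys) / dphi[is_]

  structure(list(qt_ms = tend - onset, qrs_onset_ms = onset, tend_ms = tend,
                 tpeak_ms = tpeak, baseline = baseline),
            class = "qt_measure")
}

#' @export
print.qt_measure <- function(x, ...) {
  cat(sprintf("QT = %.1f ms (QRS onset %.1f ms, T end %.1f ms)\n",
              x$qt_ms, x$qrs_onset_ms, x$tend_ms))
  invisible(x)
}

#' Bazett heart-rate correction
#'
#' \eqn{QTc_B = QT / \sqrt{RR/1000}} with QT and RR in ms; at RR = 1000 ms
#' the correction is the identity.
#'
#' @param qt QT interval in ms (> 0).
#' @param rr RR interval in ms (> 0).
#' @return Corrected QTcB in ms.
#' @examples
#' bazett(400, 640)  # 500
#' @export
bazett <- function(qt, rr) {
  stop_if(any(!is.finite(qt)) || any(qt <= 0), "qt must be positive")
  stop_if(any(!is.finite(rr)) || any(rr <= 0), "rr must be positive")
  qt / sqrt(rr / 1000)
}

#' QTcB of a strand under a drug block
#'
#' Convenience wrapper: strand simulation, pseudo-ECG, QT detection and
#' Bazett correction with RR equal to the pacing cycle length.
#'
#' @inheritParams simulate_strand
#' @return A list: `qt_ms`, `rr_ms`, `qtcb_ms`, plus the `qt_measure`.
#' @export
strand_qtcb <- function(config, block = channel_block()) {
  field <- simulate_strand(config, block)
  ecg <- compute_pseudoecg(field)
  m <- measure_qt(ecg)
  rr <- attr(ecg, "rr_ms")
  list(qt_ms = m$qt_ms, rr_ms = rr, qtcb_ms = bazett(m$qt_ms, rr),
       measure = m)
}
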