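# Shared fixtures for the suite. Strand work uses the scaled-down 50-cell
# configuration (the package's desk-scale default); single-cell tests use
# short pacing runs, which is enough for the monotonicity and convergence
# properties exercised here.

test_strand <- function(...) strand_config_scaled(...)

# Synthetic one-beat pseudo-ECG with known landmarks: a square QRS complex
# and a triangular T wave whose terminal limb reaches baseline at `t_end`.
synthetic_ecg <- function(qrs_on = 10, qrs_off = 50, t_rise = 250,
                          t_peak = 350, t_end = 400, t_total = 450,
                          amp_qrs = 1, amp_t = 0.5, dt = 1) {
  t <- seq(0, t_total, by = dt)
  phi <- numeric(length(t))
  phi[t >= qrs_on & t < qrs_off] <- amp_qrs
  up <- t >= t_rise & t <= t_peak
  phi[up] <- amp_t * (t[up] - t_rise) / (t_peak - t_rise)
  dn <- t > t_peak & t <= t_end
  phi[dn] <- amp_t * (t_end - t[dn]) / (t_end - t_peak)
  data.frame(time_ms = t, phi = phi)
}

# Two pure-IKr blockers whose driving concentrations sit mid-curve, so the
# three interaction models are well separated.
ikr_blocker_table <- function() {
  data.frame(drug = c("drugA", "drugB"), channel = "IKr",
             ic50_uM = c(1, 1), hill_n = c(1, 1))
}

mid_exposure_pk <- function() pk_params(dose_mg = 60, f_bio = 1, ka = 1,
                                        ke = 0.1, v_L = 100, mw = 400)
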