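#' One-compartment oral PK parameter set
#'
#' First-order absorption and elimination; heart-tissue concentration is the
#' plasma concentration times a constant partition ratio. This synthetic
#' generator reproduces exposure magnitudes (Cmax, AUC), not mechanism.
#'
#' @param dose_mg dose in mg.
#' @param f_bio bioavailability fraction in (0, 1].
#' @param ka absorption rate constant (1/h).
#' @param ke elimination rate constant (1/h).
#' @param v_L volume of distribution (L).
#' @param mw molecular weight (g/mol), used for the ng/ml to uM conversion.
#' @param partition heart:plasma partition ratio (dimensionless).
#' @return A list of class `"pk_params"`.
#' @export
pk_params <- function(dose_mg, f_bio = 1, ka = 1, ke = 0.1, v_L = 100,
                      mw = 400, partition = 1) {
  vals <- c(dose_mg, f_bio, ka, ke, v_L, mw, partition)
  stop_if(any(!is.finite(vals)) || any(vals <= 0),
          "all PK parameters must be positive and finite")
  stop_if(f_bio > 1, "bioavailability fraction cannot exceed 1")
  structure(list(dose_mg = dose_mg, f_bio = f_bio, ka = ka, ke = ke,
                 v_L = v_L, mw = mw, partition = partition),
            class = "pk_params")
}

# plasma concentration in ng/ml at times t (h); analytic ka == ke limit
pk_conc <- function(p, t) {
  stopifnot(all(t >= 0))
  if (abs(p$ka - p$ke) < 1e-9 * p$ka) {
    c_mgL <- p$f_bio * p$dose_mg * p$ka * t * exp(-p$ka * t) / p$v_L
  } else {
    c_mgL <- p$f_bio * p$dose_mg * p$ka / (p$v_L * (p$ka - p$ke)) *
      (exp(-p$ke * t) - exp(-p$ka * t))
  }
  1000 * c_mgL  # mg/L (= ug/ml) -> ng/ml
}

#' Closed-form exposure summaries
#'
#' `pk_auc()` is the total area under the curve F*D/(ke*V) in ng.h/ml;
#' `pk_tmax()` is `log(ka/ke)/(ka - ke)` h (1/ka in the ka = ke limit);
#' `pk_cmax()` evaluates the profile at tmax (ng/ml).
#'
#' @param p [pk_params()].
#' @return A scalar.
#' @export
pk_auc <- function(p) 1000 * p$f_bio * p$dose_mg / (p$ke * p$v_L)

#' @rdname pk_auc
#' @export
pk_tmax <- function(p) {
  if (abs(p$ka - p$ke) < 1e-9 * p$ka) 1 / p$ka
  else log(p$ka / p$ke) / (p$ka - p$ke)
}

#' @rdname pk_auc
#' @export
pk_cmax <- function(p) pk_conc(p, pk_tmax(p))

#' Convert plasma/tissue concentration between ng/ml and uM
#'
#' 1 uM of a compound of molecular weight MW g/mol is MW ng/ml, so
#' `uM = (ng/ml) / MW`.
#'
#' @param x concentration value(s).
#' @param mw molecular weight in g/mol.
#' @return Converted value(s).
#' @export
ngml_to_uM <- function(x, mw) x / mw

#' @rdname ngml_to_uM
#' @export
uM_to_ngml <- function(x, mw) x * mw

#' Heart-tissue concentration-time profile
#'
#' Evaluates the closed-form one-compartment profile on a time grid and
#' applies the heart:plasma partition ratio. Concentrations are reported in
#' both ng/ml and uM.
#'
#' @param p [pk_params()].
#' @param times_h sorted non-negative time grid in hours.
#' @param subject subject identifier stored with the profile.
#' @param arm arm label (`"BL"`, `"T"`, `"I"` or `"T+I"`).
#' @return A data frame of class `"concentration_profile"` with columns
#'   `subject`, `arm`, `time_h`, `conc_ngml`, `conc_uM`; the generating
#'   parameters are kept in attribute `pk_params`.
#' @export
pk_profile <- function(p, times_h = seq(0, 24, by = 0.1), subject = 1L,
                       arm = "T") {
  stop_if(!inherits(p, "pk_params"), "p must be pk_params")
  stop_if(any(!is.finite(times_h)) || any(times_h < 0) ||
            is.unsorted(times_h), "times must be sorted and non-negative")
  conc <- pk_conc(p, times_h) * p$partition
  structure(data.frame(subject = subject, arm = arm, time_h = times_h,
                       conc_ngml = conc, conc_uM = ngml_to_uM(conc, p$mw)),
            class = c("concentration_profile", "data.frame"),
            pk_params = p)
}

#' Calibrate PK parameters to target Cmax and AUC
#'
#' Deterministic two-stage solve with dose and bioavailability fixed: the
#' ratio Cmax/AUC depends only on (ka, ke), so ke is found by bracketed
#' root-finding in (0, ka) and V then follows from AUC = F*D/(ke*V). The
#' absorption rate is fixed at `ka`, raised automatically if the requested
#' Cmax/AUC ratio exceeds the one-compartment bound ka/e.
#'
#' @param target_cmax target maximal concentration (ng/ml, > 0).
#' @param target_auc target AUC (ng.h/ml, > 0).
#' @param dose_mg,f_bio fixed dose and bioavailability.
#' @param ka absorption rate (1/h); treated as a lower bound.
#' @param ka_max largest absorption rate the solver may use (1/h). Target
#'   pairs whose Cmax/AUC ratio exceeds the one-compartment bound
#'   `ka_max / e` are rejected as infeasible.
#' @param mw,partition carried through to the returned parameter set.
#' @return A [pk_params()] whose simulated Cmax and AUC match the targets
#'   within 1 %.
#' @export
calibrate_pk <- function(target_cmax, target_auc, dose_mg = 60, f_bio = 1,
                         ka = 1, ka_max = 50, mw = 400, partition = 1) {
  stop_if(!is.finite(target_cmax) || target_cmax <= 0,
          "target Cmax must be positive")
  stop_if(!is.finite(target_auc) || target_auc <= 0,
          "target AUC must be positive")
  ratio <- target_cmax / target_auc       # 1/h
  stop_if(!is.finite(ratio) || ratio <= 0,
          "infeasible target pair: Cmax/AUC ratio is not positive")
  # one-compartment bound: Cmax/AUC < ka/e; keep comfortably inside it
  ka_use <- max(ka, exp(1) * ratio * 1.5)
  stop_if(ka_use > ka_max,
          "infeasible target pair: Cmax/AUC = %.3g /h exceeds the bound %.3g /h",
          ratio, ka_max / exp(1))

  # shape function: Cmax/AUC for unit dose/volume given (ka, ke)
  shape <- function(ke) {
    tmax <- log(ka_use / ke) / (ka_use - ke)
    ke * ka_use / (ka_use - ke) * (exp(-ke * tmax) - exp(-ka_use * tmax))
  }
  lo <- ratio * 1e-6
  hi <- ka_use * (1 - 1e-9)
  stop_if(shape(hi * 0.999999) < ratio,
          "infeasible target pair (Cmax too large for the AUC)")
  ke <- uniroot(function(k) shape(k) - ratio, c(lo, hi * 0.999999),
                tol = 1e-12)$root
  v_L <- 1000 * f_bio * dose_mg / (ke * target_auc)
  out <- pk_params(dose_mg, f_bio, ka_use, ke, v_L, mw, partition)
  err <- abs(pk_cmax(out) / target_cmax - 1)
  stop_if(err > 0.01, "calibration failed to reach the Cmax target")
  out
}

#' Sample a virtual population of PK parameter sets
#'
#' Independent log-normal perturbation of ka, ke and V per subject with a
#' common coefficient of variation; the log-scale mean is shifted so the
#' arithmetic mean of each parameter equals the base value. Reproducible
#' under a fixed seed.
#'
#' @param base [pk_params()] typical-subject parameters.
#' @param n number of subjects (>= 1).
#' @param cv log-normal coefficient of variation (>= 0).
#' @param seed integer seed.
#' @return A list of `n` `pk_params` objects.
#' @export
sample_population <- function(base, n, cv = 0.3, seed = 1L) {
  stop_if(!inherits(base, "pk_params"), "base must be pk_params")
  stop_if(!is.numeric(n) || n < 1, "n must be >= 1")
  stop_if(!is.finite(cv) || cv < 0, "cv must be >= 0")
  if (cv == 0) return(rep(list(base), n))
  sdlog <- sqrt(log(1 + cv^2))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    fac <- rlnorm(3, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    pk_params(base$dose_mg, base$f_bio, base$ka * fac[1], base$ke * fac[2],
              base$v_L * fac[3], base$mw, base$partition)
  })
}

#' Exposure modifier describing the PK side of the interaction
#'
#' Multiplicative increase of the victim drug's AUC and Cmax when the
#' perpetrator is co-dosed (metabolic inhibition raises exposure, so both
#' multipliers must be >= 1).
#'
#' @param auc_mult,cmax_mult multipliers (>= 1).
#' @return A list of class `"exposure_modifier"`.
#' @export
exposure_modifier <- function(auc_mult = 1, cmax_mult = 1) {
  stop_if(!is.finite(auc_mult) || !is.finite(cmax_mult),
          "multipliers must be finite")
  stop_if(auc_mult < 1 || cmax_mult < 1,
          "exposure multipliers must be >= 1 for metabolic inhibitors")
  structure(list(auc_mult = auc_mult, cmax_mult = cmax_mult),
            class = "exposure_modifier")
}

#' Apply an exposure modifier to a victim profile
#'
#' Deterministic amplitude-and-time rescaling: concentrations are multiplied
#' by the Cmax multiplier and time is stretched by `auc_mult / cmax_mult`,
#' i.e. `C'(t) = cmax_mult * C(t * cmax_mult / auc_mult)`, which hits both
#' the Cmax and the AUC targets exactly. With equal multipliers this reduces
#' to pure amplitude scaling.
#'
#' @param profile a `concentration_profile` from [pk_profile()].
#' @param mod an [exposure_modifier()].
#' @return The rescaled profile (same time grid, same class); the stored
#'   generating parameters are updated to the rescaled equivalents.
#' @export
apply_interaction <- function(profile, mod) {
  stop_if(!inherits(profile, "concentration_profile"),
          "profile must be a concentration_profile")
  stop_if(!inherits(mod, "exposure_modifier"), "mod must be exposure_modifier")
  p <- attr(profile, "pk_params")
  tscale <- mod$cmax_mult / mod$auc_mult
  if (!is.null(p)) {
    # equivalent closed-form parameters: rate constants scale with time,
    # amplitude via an effective volume change
    p2 <- pk_params(p$dose_mg, p$f_bio, p$ka * tscale, p$ke * tscale,
                    p$v_L / mod$cmax_mult, p$mw, p$partition)
    out <- pk_profile(p2, profile$time_h, subject = profile$subject[1],
                      arm = profile$arm[1])
  } else {
    conc <- approx(profile$time_h, profile$conc_ngml,
                   xout = profile$time_h * tscale, rule = 2)$y *
      mod$cmax_mult
    out <- profile
    out$conc_ngml <- conc
    out$conc_uM <- ngml_to_uM(conc, 400)
  }
  out
}

#' Trapezoid AUC of a profile
#'
#' @param profile a `concentration_profile`.
#' @return AUC over the profile's time span in ng.h/ml.
#' @export
profile_auc <- function(profile) {
  t <- profile$time_h; c_ <- profile$conc_ngml
  sum(diff(t) * (c_[-1] + c_[-length(c_)]) / 2)
}
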