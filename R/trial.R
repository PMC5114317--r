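#' Specification of one drug for a virtual trial
#'
#' Bundles the drug's name, its typical-subject PK parameter set and its
#' channel-block parameter table.
#'
#' @param name drug name; must match the `drug` column of `blocks`.
#' @param pk [pk_params()].
#' @param blocks data frame as from [read_drug_blocks()] (rows for other
#'   drugs are ignored).
#' @return A list of class `"drug_spec"`.
#' @export
drug_spec <- function(name, pk, blocks) {
  stop_if(!inherits(pk, "pk_params"), "pk must be pk_params")
  stop_if(!all(c("drug", "channel", "ic50_uM", "hill_n") %in% names(blocks)),
          "blocks must have columns drug, channel, ic50_uM, hill_n")
  structure(list(name = name, pk = pk, blocks = blocks),
            class = "drug_spec")
}

#' Virtual QT trial design
#'
#' Describes one replicate virtual study: population size, number of
#' replicate studies (the published design repeats each study 10 times to
#' capture inter-study variability), arms, interaction models, pacing and
#' seeding. The baseline and combination arms are always present.
#'
#' @param study study label.
#' @param n_subjects subjects per replicate (>= 1).
#' @param n_replicates replicate studies (>= 1; default 10).
#' @param arms subset of `c("BL", "T", "I", "T+I")`; BL and T+I are forced in.
#' @param models interaction models to run for the combination arm.
#' @param cv log-normal inter-individual PK coefficient of variation.
#' @param seed master seed (mandatory); per-replicate seeds are derived as
#'   `seed + 1000 * replicate`, a fixed splitting rule.
#' @param strand [strand_config()] used for every simulation.
#' @param conc_scale multiplier applied to every block-driving
#'   concentration (diagnostic dial; 0 turns all drugs off).
#' @return A list of class `"trial_design"`.
#' @export
trial_design <- function(study, n_subjects = 10, n_replicates = 10,
                         arms = c("BL", "T", "I", "T+I"),
                         models = c("sum", "bliss", "loewe"),
                         cv = 0.3, seed,
                         strand = strand_config_scaled(),
                         conc_scale = 1) {
  stop_if(missing(seed) || !is.finite(seed), "a master seed is mandatory")
  stop_if(n_subjects < 1 || n_replicates < 1,
          "need at least one subject and one replicate")
  arms <- union(c("BL", "T+I"), match.arg(arms, several.ok = TRUE))
  models <- match.arg(models, several.ok = TRUE)
  stop_if(!inherits(strand, "strand_config"), "strand must be a strand_config")
  stop_if(!is.finite(conc_scale) || conc_scale < 0,
          "conc_scale must be >= 0")
  structure(list(study = study, n_subjects = as.integer(n_subjects),
                 n_replicates = as.integer(n_replicates), arms = arms,
                 models = models, cv = cv, seed = as.integer(seed),
                 strand = strand, conc_scale = conc_scale),
            class = "trial_design")
}

#' Scaled-down strand configuration for desk-speed trials
#'
#' 50 cells (12 endo / 18 M / 20 epi), 20 pre-pacing beats and 2 strand
#' beats: small enough that a replicate trial runs in seconds per arm,
#' while preserving propagation, the transmural gradient and an upright
#' T wave. The full-scale default is [strand_config()].
#'
#' @param ... overrides passed to [strand_config()].
#' @return A `strand_config`.
#' @export
strand_config_scaled <- function(...) {
  args <- list(...)
  defaults <- list(n_endo = 12, n_m = 18, n_epi = 20, prepace_beats = 20,
                   protocol = pacing_protocol(beats = 2))
  do.call(strand_config, utils::modifyList(defaults, args))
}

# heart-tissue driving concentration (uM) at the drug's own Tmax
driving_conc_uM <- function(pk) {
  ngml_to_uM(pk_cmax(pk) * pk$partition, pk$mw)
}

#' Run a replicate virtual QT trial
#'
#' For each replicate: a virtual population is sampled (log-normal PK
#' variability, seeded by the fixed splitting rule); each subject's
#' heart-tissue concentration at the drug's Tmax drives Hill-equation block
#' of IKr/IKs/INa/ICaL per drug; the combination arm combines the two
#' drugs' block vectors under each interaction model; every block vector is
#' run through the transmural strand to a pseudo-ECG QTcB. The same subject
#' (same PK draw, same strand) is carried across arms and models, so
#' per-subject ΔQTcB contrasts are paired. The victim's exposure increase
#' in the combination arm enters via the study's [exposure_modifier()].
#'
#' Identical strand inputs are memoized within the run, so e.g. the
#' baseline arm is simulated once, not once per subject.
#'
#' @param design [trial_design()].
#' @param victim,perpetrator [drug_spec()]s.
#' @param modifier [exposure_modifier()] for the victim's exposure in the
#'   combination arm.
#' @return A list of class `"qt_trial"` with elements `results` (data frame:
#'   replicate, subject, arm, model, conc_uM, qtcb_ms, dqtcb_ms) and
#'   `design`.
#' @export
run_trial <- function(design, victim, perpetrator,
                      modifier = exposure_modifier()) {
  stop_if(!inherits(design, "trial_design"), "design must be a trial_design")
  stop_if(!inherits(victim, "drug_spec"), "victim must be a drug_spec")
  stop_if(!inherits(perpetrator, "drug_spec"),
          "perpetrator must be a drug_spec")
  stop_if(!inherits(modifier, "exposure_modifier"),
          "modifier must be an exposure_modifier")

  cache <- new.env(parent = emptyenv())
  qtcb_of <- function(block) {
    key <- paste(signif(unclass(block), 8), collapse = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch(
      strand_qtcb(design$strand, block)$qtcb_ms,
      error = function(e) stop("strand simulation failed: ",
                               conditionMessage(e), call. = FALSE))
    cache[[key]] <- val
    val
  }

  rows <- list()
  for (rep_i in seq_len(design$n_replicates)) {
    seed_r <- design$seed + 1000L * rep_i
    pop_v <- sample_population(victim$pk, design$n_subjects, design$cv,
                               seed = seed_r)
    pop_p <- sample_population(perpetrator$pk, design$n_subjects, design$cv,
                               seed = seed_r + 500L)
    for (subj in seq_len(design$n_subjects)) {
      add_row <- function(arm, model, conc, qtcb, qtcb_bl) {
        rows[[length(rows) + 1L]] <<- data.frame(
          replicate = rep_i, subject = subj, arm = arm, model = model,
          conc_uM = conc, qtcb_ms = qtcb, dqtcb_ms = qtcb - qtcb_bl)
      }
      conc_v <- driving_conc_uM(pop_v[[subj]]) * design$conc_scale
      conc_p <- driving_conc_uM(pop_p[[subj]]) * design$conc_scale
      conc_v_ti <- conc_v * modifier$cmax_mult

      block_v <- drug_block_at(conc_v, victim$name, victim$blocks)
      block_p <- drug_block_at(conc_p, perpetrator$name, perpetrator$blocks)
      block_v_ti <- drug_block_at(conc_v_ti, victim$name, victim$blocks)

      qtcb_bl <- qtcb_of(channel_block())
      add_row("BL", NA_character_, 0, qtcb_bl, qtcb_bl)
      if ("T" %in% design$arms)
        add_row("T", NA_character_, conc_v, qtcb_of(block_v), qtcb_bl)
      if ("I" %in% design$arms)
        add_row("I", NA_character_, conc_p, qtcb_of(block_p), qtcb_bl)
      for (m in design$models) {
        comb <- combine_channels(block_v_ti, block_p, m)
        add_row("T+I", m, conc_v_ti, qtcb_of(comb), qtcb_bl)
      }
    }
  }
  structure(list(results = do.call(rbind, rows), design = design),
            class = "qt_trial")
}

#' Summarize a virtual trial
#'
#' Means are taken over subjects within each replicate, then over
#' replicates; the 95 % confidence interval uses the t distribution over
#' replicate means (NA with a single replicate).
#'
#' @param trial a `qt_trial` from [run_trial()].
#' @return A data frame: arm, model, mean QTcB, mean ΔQTcB, CI bounds.
#' @export
summarize_trial <- function(trial) {
  stop_if(!inherits(trial, "qt_trial"), "trial must be a qt_trial")
  res <- trial$results
  res$grp <- paste(res$arm, ifelse(is.na(res$model), "-", res$model))
  out <- list()
  for (g in unique(res$grp)) {
    sub <- res[res$grp == g, ]
    rep_means <- tapply(sub$dqtcb_ms, sub$replicate, mean)
    rep_qtcb <- tapply(sub$qtcb_ms, sub$replicate, mean)
    nrep <- length(rep_means)
    se <- if (nrep > 1) stats::sd(rep_means) / sqrt(nrep) else NA_real_
    tq <- if (nrep > 1) qt(0.975, nrep - 1) else NA_real_
    out[[g]] <- data.frame(
      arm = sub$arm[1], model = ifelse(is.na(sub$model[1]), "-", sub$model[1]),
      mean_qtcb_ms = mean(rep_qtcb), mean_dqtcb_ms = mean(rep_means),
      ci_lo = mean(rep_means) - tq * se, ci_hi = mean(rep_means) + tq * se)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.qt_trial <- function(x, ...) {
  d <- x$design
  cat(sprintf("Virtual QT trial '%s': %d subjects x %d replicates, arms %s\n",
              d$study, d$n_subjects, d$n_replicates,
              paste(d$arms, collapse = "/")))
  print(summarize_trial(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.qt_trial <- function(object, ...) summarize_trial(object)

#' Per-subject combination-arm ΔQTcB by interaction model
#'
#' Reshapes a trial result into the matrix [count_flips()] consumes: one row
#' per (replicate, subject), one column per model, values ΔQTcB in ms for
#' the combination arm.
#'
#' @param trial a `qt_trial`.
#' @return Numeric matrix with model columns.
#' @export
per_subject_deltas <- function(trial) {
  res <- trial$results
  res <- res[res$arm == "T+I", ]
  models <- unique(res$model)
  ids <- unique(res[, c("replicate", "subject")])
  m <- sapply(models, function(mod) {
    sub <- res[res$model == mod, ]
    sub$dqtcb_ms[match(paste(ids$replicate, ids$subject),
                       paste(sub$replicate, sub$subject))]
  })
  m <- matrix(m, nrow = nrow(ids), dimnames = list(NULL, models))
  stop_if(anyNA(m), "missing model values for some subjects")
  m
}
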