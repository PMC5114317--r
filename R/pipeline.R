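# Study-level glue: builds drug specifications from the bundled exposure
# table and runs the end-to-end pipeline.

# Molecular weights (g/mol) used for the ng/ml -> uM conversion.
DRUG_MW <- c(terfenadine = 471.7, fluoxetine = 309.3, erythromycin = 733.9,
             fluconazole = 306.3, itraconazole = 705.6,
             ketoconazole = 531.4, clarithromycin = 748.0,
             paroxetine = 329.4)

study_inhibitor <- function(study) sub("_cr[0-9]+$", "", study)

# Assumed victim elimination rate used when a study's exposure table prints
# Cmax but no AUC (illustrative terminal half-life of about 8.5 h).
DEFAULT_KE <- log(2) / 8.5

#' Build victim/perpetrator drug specs for a bundled study
#'
#' PK parameter sets are calibrated so the simulated Cmax (and, where the
#' exposure table prints one, AUC) of the terfenadine-alone and
#' inhibitor-alone arms match the table's predicted values; where no AUC is
#' printed an illustrative elimination half-life fixes the profile shape.
#' The combination arm's exposure increase is encoded as an
#' [exposure_modifier()] from the ratio of predicted combination to
#' single-drug values.
#'
#' @param study study label as used in the bundled tables (e.g.
#'   `"ketoconazole"`, `"erythromycin_cr19"`).
#' @param blocks channel-block table (default: the bundled synthetic one).
#' @param tab1 exposure table (default: the bundled fixture).
#' @return A list: `victim`, `perpetrator` ([drug_spec()]s), `modifier`.
#' @export
study_setup <- function(study, blocks = qtddi_table("drug_blocks_synthetic"),
                        tab1 = qtddi_table("table1")) {
  rows <- tab1[tab1$study == study, ]
  stop_if(nrow(rows) == 0, "unknown study '%s'", study)
  inhib <- study_inhibitor(study)

  pick <- function(col, arm) rows[[col]][match(arm, rows$arm)]
  cmax_t <- pick("cmax_pred", "T")
  cmax_ti <- pick("cmax_pred", "T+I")
  auc_t <- suppressWarnings(as.numeric(pick("auc_pred", "T")))
  auc_ti <- suppressWarnings(as.numeric(pick("auc_pred", "T+I")))
  if (!is.finite(auc_t)) auc_t <- cmax_t / DEFAULT_KE
  if (!is.finite(auc_ti)) auc_ti <- cmax_ti / DEFAULT_KE

  victim_pk <- calibrate_pk(cmax_t, auc_t, dose_mg = 60,
                            mw = DRUG_MW[["terfenadine"]])
  # inhibitor exposure: no predicted table for its own profile; reuse the
  # victim arm's shape at an illustrative Cmax of 1x its hERG IC50 scale
  inhib_rows <- blocks[blocks$drug == inhib, , drop = FALSE]
  inhib_cmax_ngml <- if (nrow(inhib_rows) > 0)
    uM_to_ngml(min(inhib_rows$ic50_uM) * 0.5, DRUG_MW[[inhib]])
  else 100
  perp_pk <- calibrate_pk(inhib_cmax_ngml, inhib_cmax_ngml / DEFAULT_KE,
                          dose_mg = 200, mw = DRUG_MW[[inhib]])

  list(
    victim = drug_spec("terfenadine", victim_pk, blocks),
    perpetrator = drug_spec(inhib, perp_pk, blocks),
    modifier = exposure_modifier(
      auc_mult = max(1, auc_ti / auc_t),
      cmax_mult = max(1, cmax_ti / cmax_t)))
}

#' Read a pipeline configuration from YAML
#'
#' Required field: `seed`. Optional: `studies`, `n_subjects`,
#' `n_replicates`, `models`, `cv`, `scaled_down`, `threshold_ms`,
#' `out_dir`, `drug_blocks` (path to a CSV overriding the bundled synthetic
#' block table).
#'
#' @param path YAML file.
#' @return A named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  stop_if(!file.exists(path), "config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  stop_if(is.null(cfg$seed), "config must set a seed")
  cfg
}

pipeline_defaults <- function() {
  list(studies = "paroxetine", n_subjects = 4, n_replicates = 2,
       models = c("sum", "bliss", "loewe"), cv = 0.3, scaled_down = TRUE,
       threshold_ms = 5, out_dir = "qtddi_out", drug_blocks = NULL)
}

#' Run the end-to-end study pipeline
#'
#' For each selected study: synthetic PK calibration, per-channel Hill
#' block, interaction-model combination, strand pseudo-ECG QTcB in a
#' replicate virtual trial, then the evaluation layer (trial summary,
#' per-subject 5-ms flip counting, and the observed-vs-predicted distance
#' table recomputed from the bundled comparison table). All intermediate
#' CSVs and a text report are written under `out_dir`.
#'
#' @param config list (or path to a YAML file) with at least `seed`; see
#'   [read_pipeline_config()] for the optional fields.
#' @return Invisibly, a list with the per-study trials, summaries, flip
#'   reports and the distance table.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stop_if(!is.list(config) || is.null(config$seed),
          "config must be a list with a seed")
  cfg <- utils::modifyList(pipeline_defaults(), config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  fix_dir <- file.path(cfg$out_dir, "fixtures")
  stage("fixtures", make_fixtures(fix_dir))

  blocks <- stage("drug-parameters", {
    if (is.null(cfg$drug_blocks)) qtddi_table("drug_blocks_synthetic")
    else read_drug_blocks(cfg$drug_blocks)
  })

  strand <- if (isTRUE(cfg$scaled_down)) strand_config_scaled()
            else strand_config()

  trials <- list(); summaries <- list(); flips <- list()
  for (st in cfg$studies) {
    setup <- stage(paste0("study-setup:", st),
                   study_setup(st, blocks = blocks))
    design <- trial_design(st, n_subjects = cfg$n_subjects,
                           n_replicates = cfg$n_replicates,
                           models = cfg$models, cv = cfg$cv,
                           seed = cfg$seed, strand = strand)
    trial <- stage(paste0("trial:", st),
                   run_trial(design, setup$victim, setup$perpetrator,
                             setup$modifier))
    summ <- summarize_trial(trial)
    flip <- count_flips(per_subject_deltas(trial),
                        threshold_ms = cfg$threshold_ms)
    write.csv(trial$results,
              file.path(cfg$out_dir, paste0("trial_", st, ".csv")),
              row.names = FALSE)
    write.csv(summ, file.path(cfg$out_dir, paste0("summary_", st, ".csv")),
              row.names = FALSE)
    trials[[st]] <- trial; summaries[[st]] <- summ; flips[[st]] <- flip
  }

  dist <- stage("evaluation", table2_distances())
  write.csv(as.data.frame(dist), file.path(cfg$out_dir, "distances.csv"),
            row.names = FALSE)

  report <- file.path(cfg$out_dir, "report.txt")
  con <- file(report, "w"); on.exit(close(con))
  writeLines(sprintf("qtddi pipeline report (seed %d)", cfg$seed), con)
  for (st in names(trials)) {
    writeLines(sprintf("\n== %s ==", st), con)
    writeLines(utils::capture.output(print(summaries[[st]], digits = 4,
                                           row.names = FALSE)), con)
    writeLines(sprintf("flip cases at %.0f ms: %d of %d subjects (%.1f%%)",
                       cfg$threshold_ms, flips[[st]]$n_cases,
                       flips[[st]]$n_subjects, flips[[st]]$pct_cases), con)
  }
  writeLines("\n== observed-vs-predicted distances (ms) ==", con)
  writeLines(utils::capture.output(print(dist)), con)

  invisible(list(trials = trials, summaries = summaries, flips = flips,
                 distances = dist, out_dir = cfg$out_dir))
}
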