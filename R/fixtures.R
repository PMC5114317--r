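# Published clinical-comparison tables bundled as in-code data so fixture
# CSVs can be regenerated byte-identically. Censored or qualified cells keep
# their printed flags rather than imputed numbers.

table1_data <- function() {
  # study, arm, observed/predicted Cmax (ng/ml) and AUC (ng.h/ml);
  # flag records the printed footnote on the observed value
  df <- read.csv(text = 'study,arm,cmax_obs,cmax_obs_flag,cmax_pred,auc_obs,auc_pred
fluoxetine,T,2,,2.3,24.6,15.3
fluoxetine,T+I,1.4,,2.3,14.2,15.3
erythromycin_cr15,T,<5,,2.71,NA,NA
erythromycin_cr15,T+I,20.3,for 3 of 9 subjects,9.74,NA,NA
fluconazole,T,<5,,2.48,NA,NA
fluconazole,T+I,<5,,4.11,NA,NA
itraconazole,T,7.63,for 3 of 6 subjects,4.9,NA,NA
itraconazole,T+I,14.97,for 3 of 6 subjects,14.6,NA,NA
ketoconazole,T,7,for 1 of 6 subjects,2.23,NA,NA
ketoconazole,T+I,49.3,graph estimate for 5 of 6 subjects,19.67,NA,NA
clarithromycin,T,<5,,9,NA,NA
clarithromycin,T+I,2.39,,7.03,NA,NA
erythromycin_cr19,T,<5,,2.47,NA,NA
erythromycin_cr19,T+I,7.6,for 3 of 6 subjects,8.98,NA,NA
paroxetine,T,3.68,,2.31,30.8,20.5
paroxetine,T+I,3.64,,2.48,30,27.5
', stringsAsFactors = FALSE, colClasses = c(
    "character", "character", "character", "character",
    "numeric", "character", "numeric"))
  df
}

table2_data <- function() {
  # observed and per-model predicted QTc (ms); NA where the study did not
  # report the value. For erythromycin_cr15 the observed entries are QT
  # *changes* (delta_only flag), not absolute intervals.
  read.csv(text = 'study,arm,observed,pred_sum,pred_bliss,pred_loewe,delta_only
fluoxetine,BL,372.4,396.0,396.0,396.0,0
fluoxetine,T,374.9,398.5,398.5,398.5,0
fluoxetine,I,NA,400.9,400.9,400.9,0
fluoxetine,T+I,379,401.6,400.8,400.2,0
erythromycin_cr15,BL,NA,392.8,392.8,392.8,1
erythromycin_cr15,T,8,398.5,398.5,398.5,1
erythromycin_cr15,I,21,403.7,403.7,403.7,1
erythromycin_cr15,T+I,39,418.2,413.6,411.4,1
fluconazole,BL,398.5,395.2,395.2,395.2,0
fluconazole,T,398.4,401.3,401.3,401.3,0
fluconazole,I,NA,414.3,414.3,414.3,0
fluconazole,T+I,411,422.6,418.6,416.8,0
itraconazole,BL,376,430.5,430.5,430.5,0
itraconazole,T,390,438,438,438,0
itraconazole,I,NA,486.9,486.9,486.9,0
itraconazole,T+I,417,452.2,448.9,447.3,0
ketoconazole,BL,408,394.5,394.5,394.5,0
ketoconazole,T,416,395,395,395,0
ketoconazole,I,NA,415.4,415.4,415.4,0
ketoconazole,T+I,490,439,427.9,423.6,0
clarithromycin,BL,409,395.5,395.5,395.5,0
clarithromycin,T,410,401.4,401.4,401.4,0
clarithromycin,I,407,393.9,393.9,393.9,0
clarithromycin,T+I,430,404.4,403.8,402.7,0
erythromycin_cr19,BL,394,397.5,397.5,397.5,0
erythromycin_cr19,T,408,403.7,403.7,403.7,0
erythromycin_cr19,I,409,405.8,405.8,405.8,0
erythromycin_cr19,T+I,428,420.1,415.6,413.5,0
paroxetine,BL,381,392.0,392.0,392.0,0
paroxetine,T,387,394.5,394.5,394.5,0
paroxetine,I,NA,393.5,393.5,393.5,0
paroxetine,T+I,386,396.6,393.6,396.8,0
', stringsAsFactors = FALSE)
}

table2_printed_distances <- function() {
  read.csv(text = 'study,model,distance
fluoxetine,sum,1.49
fluoxetine,bliss,2.59
fluoxetine,loewe,3.34
erythromycin_cr15,sum,18.38
erythromycin_cr15,bliss,22.75
erythromycin_cr15,loewe,25.13
fluconazole,sum,31.28
fluconazole,bliss,26.02
fluconazole,loewe,23.65
itraconazole,sum,24.05
itraconazole,bliss,28.50
itraconazole,loewe,30.68
ketoconazole,sum,48.61
ketoconazole,bliss,64.03
ketoconazole,loewe,70.14
clarithromycin,sum,21.43
clarithromycin,bliss,22.96
clarithromycin,loewe,23.79
erythromycin_cr19,sum,14.27
erythromycin_cr19,bliss,19.46
erythromycin_cr19,loewe,22.17
paroxetine,sum,4.69
paroxetine,bliss,4.86
paroxetine,loewe,4.78
', stringsAsFactors = FALSE)
}

table3_data <- function() {
  read.csv(text = 'study,pct_cases
fluoxetine,0.1
erythromycin_cr15,2.8
fluconazole,3.8
itraconazole,2.3
ketoconazole,5.6
clarithromycin,0.2
erythromycin_cr19,3.3
paroxetine,0
', stringsAsFactors = FALSE)
}

#' Write the bundled clinical-comparison fixture tables
#'
#' Writes `table1.csv` (observed vs simulated Cmax/AUC per study and arm,
#' with censoring flags such as "<5"), `table2.csv` (observed vs per-model
#' predicted QTc triplets), `table2_distances.csv` (the printed per-model
#' distance values) and `table3.csv` (percentage of subjects for whom model
#' choice flips the 5-ms safety conclusion). Regeneration is idempotent:
#' repeated calls produce byte-identical files.
#'
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stop_if(file.access(out_dir, 2) != 0, "directory not writable: %s", out_dir)
  tabs <- list(table1 = table1_data(), table2 = table2_data(),
               table2_distances = table2_printed_distances(),
               table3 = table3_data())
  paths <- character(0)
  for (nm in names(tabs)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tabs[[nm]], p, row.names = FALSE, quote = TRUE, na = "NA")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a bundled fixture table from the installed package
#'
#' @param name one of `"table1"`, `"table2"`, `"table2_distances"`,
#'   `"table3"`, `"drug_blocks_synthetic"`.
#' @return A data frame.
#' @export
qtddi_table <- function(name = c("table1", "table2", "table2_distances",
                                 "table3", "drug_blocks_synthetic")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "qtddi",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
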