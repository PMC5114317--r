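#' Distance between observed and predicted QTc triplets
#'
#' Both triplets are (BL, T, T+I): baseline, victim alone, victim plus
#' inhibitor. Within each source the baseline is subtracted, giving
#' \eqn{\Delta T} and \eqn{\Delta T\!+\!I}; the distance is
#' \deqn{D = \sqrt{(\Delta T_p - \Delta T_o)^2 +
#'   (\Delta TI_p - \Delta TI_o)^2 +
#'   ((\Delta TI_p - \Delta T_p) - (\Delta TI_o - \Delta T_o))^2}}
#' i.e. the prediction error of the victim effect, of the combination
#' effect, and of the inhibitor's incremental effect, in quadrature. Because
#' only within-source differences enter, D is invariant to adding a
#' constant to either triplet.
#'
#' For studies reporting only QT changes, pass the changes directly via
#' `obs_deltas`/`pred_deltas` (each `c(dT, dTI)`).
#'
#' @param obs,pred numeric triplets `c(BL, T, TI)` in ms.
#' @param obs_deltas,pred_deltas alternative interface: baseline-subtracted
#'   pairs `c(dT, dTI)` in ms.
#' @return Distance D in ms (>= 0).
#' @examples
#' qt_distance(obs = c(408, 416, 490), pred = c(394.5, 395, 439))  # 48.61
#' @export
qt_distance <- function(obs = NULL, pred = NULL,
                        obs_deltas = NULL, pred_deltas = NULL) {
  d <- function(trip) c(trip[2] - trip[1], trip[3] - trip[1])
  if (is.null(obs_deltas)) {
    stop_if(length(obs) != 3 || any(!is.finite(obs)),
            "obs must be a finite triplet (BL, T, T+I)")
    obs_deltas <- d(obs)
  }
  if (is.null(pred_deltas)) {
    stop_if(length(pred) != 3 || any(!is.finite(pred)),
            "pred must be a finite triplet (BL, T, T+I)")
    pred_deltas <- d(pred)
  }
  stop_if(length(obs_deltas) != 2 || length(pred_deltas) != 2 ||
            any(!is.finite(c(obs_deltas, pred_deltas))),
          "deltas must be finite pairs (dT, dTI)")
  e1 <- pred_deltas[1] - obs_deltas[1]
  e2 <- pred_deltas[2] - obs_deltas[2]
  e3 <- (pred_deltas[2] - pred_deltas[1]) - (obs_deltas[2] - obs_deltas[1])
  sqrt(e1^2 + e2^2 + e3^2)
}

#' Distances for every study and interaction model in a comparison table
#'
#' Takes a table in the bundled `table2` layout (columns `study`, `arm`,
#' `observed`, `pred_sum`, `pred_bliss`, `pred_loewe`, `delta_only`) and
#' recomputes D per study and model. For `delta_only` studies the observed
#' T and T+I entries are used directly as baseline-subtracted changes.
#'
#' @param tab2 data frame in the `table2` fixture layout (default: the
#'   bundled fixture).
#' @return A data frame of class `"study_comparison"`: one row per
#'   (study, model) with the distance and the underlying deltas.
#' @export
table2_distances <- function(tab2 = qtddi_table("table2")) {
  models <- c("sum", "bliss", "loewe")
  out <- list()
  for (st in unique(tab2$study)) {
    rows <- tab2[tab2$study == st, ]
    pick <- function(col, arm) rows[[col]][match(arm, rows$arm)]
    delta_only <- pick("delta_only", "T") == 1
    if (delta_only) {
      obs_deltas <- c(pick("observed", "T"), pick("observed", "T+I"))
      obs <- NULL
    } else {
      obs <- c(pick("observed", "BL"), pick("observed", "T"),
               pick("observed", "T+I"))
      obs_deltas <- NULL
    }
    for (m in models) {
      col <- paste0("pred_", m)
      pred <- c(pick(col, "BL"), pick(col, "T"), pick(col, "T+I"))
      D <- qt_distance(obs = obs, pred = pred, obs_deltas = obs_deltas)
      out[[length(out) + 1L]] <- data.frame(
        study = st, model = m, distance = D,
        d_t_pred = pred[2] - pred[1], d_ti_pred = pred[3] - pred[1],
        d_t_obs = if (delta_only) obs_deltas[1] else obs[2] - obs[1],
        d_ti_obs = if (delta_only) obs_deltas[2] else obs[3] - obs[1])
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("study_comparison", "data.frame")
  res
}

#' @export
print.study_comparison <- function(x, ...) {
  cat("Observed-vs-predicted QTc comparison (distance D, ms):\n")
  wide <- stats::reshape(
    as.data.frame(x)[, c("study", "model", "distance")],
    idvar = "study", timevar = "model", direction = "wide")
  names(wide) <- sub("^distance\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Welch two-sample t test of observed vs predicted QTc changes
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom,
#' two-sided; delegates to [stats::t.test()].
#'
#' @param obs_deltas,pred_deltas numeric vectors (each >= 2 values with
#'   nonzero variance).
#' @return A list with `t`, `df`, `p`.
#' @export
welch_t <- function(obs_deltas, pred_deltas) {
  stop_if(length(obs_deltas) < 2 || length(pred_deltas) < 2,
          "each sample needs at least 2 values")
  stop_if(var(obs_deltas) == 0 && var(pred_deltas) == 0,
          "degenerate input: both samples have zero variance")
  ht <- t.test(obs_deltas, pred_deltas, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Count subjects for whom model choice flips the safety conclusion
#'
#' A subject is a "case" when the per-model predicted QTc changes straddle
#' the prolongation threshold: the smallest model prediction is below it
#' and the largest reaches it, so choosing a different interaction model
#' would change the verdict. The regulatory threshold of concern, 5 ms, is
#' the default.
#'
#' @param per_subject numeric matrix (or data frame) of per-subject QTc
#'   changes in ms: one row per subject, one column per interaction model.
#'   No missing values are allowed.
#' @param threshold_ms prolongation threshold in ms (> 0).
#' @return A list of class `"flip_report"`: `n_subjects`, `n_cases`,
#'   `pct_cases`.
#' @examples
#' m <- rbind(c(4.9, 5.1, 5.0), c(3, 3, 3))
#' count_flips(m)$pct_cases  # 50
#' @export
count_flips <- function(per_subject, threshold_ms = 5) {
  m <- as.matrix(per_subject)
  stop_if(!is.numeric(m) || ncol(m) < 2,
          "per_subject must be numeric with one column per model (>= 2)")
  stop_if(anyNA(m), "missing model predictions for some subjects")
  stop_if(!is.finite(threshold_ms) || threshold_ms <= 0,
          "threshold must be positive")
  lo <- apply(m, 1, min)
  hi <- apply(m, 1, max)
  cases <- lo < threshold_ms & hi >= threshold_ms
  structure(list(n_subjects = nrow(m), n_cases = sum(cases),
                 pct_cases = 100 * mean(cases)),
            class = "flip_report")
}

#' @export
print.flip_report <- function(x, ...) {
  cat(sprintf("%d of %d subjects (%.1f%%) flip the safety verdict with model choice\n",
              x$n_cases, x$n_subjects, x$pct_cases))
  invisible(x)
}

#' Rank interaction models by distance
#'
#' Ascending sort by D; exact ties keep the fixed order sum, Bliss, Loewe.
#'
#' @param distances named numeric vector of distances, names among
#'   `"sum"`, `"bliss"`, `"loewe"` (any subset, >= 1).
#' @return Character vector of model names, best first.
#' @examples
#' best_model(c(sum = 1, bliss = 2, loewe = 3))
#' @export
best_model <- function(distances) {
  stop_if(length(distances) < 1 || is.null(names(distances)),
          "distances must be a named vector")
  order_fixed <- c("sum", "bliss", "loewe")
  tie <- match(names(distances), order_fixed)
  names(distances)[order(distances, tie)]
}
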