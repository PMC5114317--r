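#' @useDynLib qtddi, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx median qt quantile rlnorm runif setNames t.test
#'   uniroot var
#' @importFrom utils read.csv write.csv
NULL

# The four cardiac currents subject to drug block, in fixed order.
QTDDI_CHANNELS <- c("IKr", "IKs", "INa", "ICaL")

stop_if <- function(cond, ...) if (cond) stop(sprintf(...), call. = FALSE)

#' Per-channel inhibition vector
#'
#' Constructs a vector of fractional current block for the four currents the
#' pipeline perturbs: IKr, IKs, INa and ICaL. Each entry is the fraction of
#' the current that is blocked, so 0 means no drug effect and 1 means
#' complete block.
#'
#' @param IKr,IKs,INa,ICaL fractional block in `[0, 1]`.
#' @return A named numeric vector of class `"channel_block"`.
#' @examples
#' channel_block(IKr = 0.5)
#' @export
channel_block <- function(IKr = 0, IKs = 0, INa = 0, ICaL = 0) {
  e <- c(IKr = IKr, IKs = IKs, INa = INa, ICaL = ICaL)
  validate_block(e)
  structure(e, class = "channel_block")
}

validate_block <- function(e) {
  stop_if(!is.numeric(e) || length(e) != 4L,
          "a channel block must be 4 numeric values (IKr, IKs, INa, ICaL)")
  stop_if(is.null(names(e)) || !identical(sort(names(e)), sort(QTDDI_CHANNELS)),
          "channel set must be exactly {IKr, IKs, INa, ICaL}")
  stop_if(any(!is.finite(e)), "inhibition fractions must be finite")
  stop_if(any(e < 0 | e > 1), "inhibition fractions must lie in [0, 1]")
  invisible(e)
}

as_block <- function(e) {
  if (inherits(e, "channel_block")) return(e)
  validate_block(e)
  structure(e[QTDDI_CHANNELS], class = "channel_block")
}

#' @export
print.channel_block <- function(x, ...) {
  cat("Channel inhibition fractions:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Hill-equation fractional channel block
#'
#' Standard concentration-dependent block model
#' \eqn{E = C^n / (IC_{50}^n + C^n)}: zero at zero concentration, 0.5 at the
#' IC50, saturating at complete block.
#'
#' @param conc drug concentration (same units as `ic50`, conventionally uM);
#'   vectorized, all values must be finite and non-negative.
#' @param ic50 half-maximal inhibitory concentration (> 0).
#' @param hill_n Hill coefficient (> 0).
#' @return Inhibition fraction(s) in `[0, 1]`.
#' @examples
#' hill_inhibition(1, ic50 = 1, hill_n = 1)  # 0.5 at the IC50
#' @export
hill_inhibition <- function(conc, ic50, hill_n = 1) {
  stop_if(!is.numeric(conc) || any(!is.finite(conc)),
          "concentration must be finite numeric")
  stop_if(any(conc < 0), "concentration must be non-negative")
  stop_if(!is.finite(ic50) || ic50 <= 0, "ic50 must be a positive number")
  stop_if(!is.finite(hill_n) || hill_n <= 0,
          "hill coefficient must be positive")
  cn <- (conc / ic50)^hill_n
  cn / (1 + cn)
}

check_fraction <- function(e, arg) {
  stop_if(!is.numeric(e) || any(!is.finite(e)),
          "%s must be finite numeric", arg)
  stop_if(any(e < 0 | e > 1), "%s must lie in [0, 1]", arg)
}

#' Two-drug interaction models for fractional channel block
#'
#' Combine the inhibition fractions of two co-administered drugs acting on the
#' same current. Three models are provided:
#' \describe{
#'   \item{`combine_sum()`}{arithmetic sum capped at complete block,
#'     \eqn{\min(E_A + E_B, 1)} — additive effects up to the physiological
#'     maximum.}
#'   \item{`combine_bliss()`}{Bliss independence,
#'     \eqn{E_A + E_B - E_A E_B} — the drugs act independently (distinct
#'     sites/mechanisms).}
#'   \item{`combine_loewe()`}{Loewe additivity,
#'     \eqn{(E_A + E_B - 2 E_A E_B)/(1 - E_A E_B)} — dose addition for drugs
#'     sharing a site and mechanism. At \eqn{E_A = E_B = 1} the expression is
#'     0/0 and the combined block is defined as 1 by continuity.}
#' }
#' All three are symmetric, return `ea` exactly when `eb = 0`, are
#' non-decreasing in each argument, and for interior fractions satisfy
#' Loewe <= Bliss <= capped sum. None assumes synergy or antagonism.
#'
#' @param ea,eb inhibition fractions of the two drugs, each in `[0, 1]`
#'   (vectorized).
#' @return Combined inhibition fraction(s) in `[0, 1]`.
#' @examples
#' combine_sum(0.2, 0.3)    # 0.5
#' combine_bliss(0.5, 0.5)  # 0.75
#' combine_loewe(0.5, 0.5)  # 2/3
#' @export
combine_sum <- function(ea, eb) {
  check_fraction(ea, "ea"); check_fraction(eb, "eb")
  pmin(ea + eb, 1)
}

#' @rdname combine_sum
#' @export
combine_bliss <- function(ea, eb) {
  check_fraction(ea, "ea"); check_fraction(eb, "eb")
  ea + eb - ea * eb
}

#' @rdname combine_sum
#' @export
combine_loewe <- function(ea, eb) {
  check_fraction(ea, "ea"); check_fraction(eb, "eb")
  out <- ifelse(ea * eb == 1, 1, (ea + eb - 2 * ea * eb) / (1 - ea * eb))
  pmin(pmax(out, 0), 1)
}

#' Combine two drugs' channel-block vectors under an interaction model
#'
#' Applies the selected two-drug interaction model element-wise over the four
#' currents. Only pairwise combination is supported: the Loewe dose-addition
#' formula used here is inherently a two-drug expression.
#'
#' @param a,b [channel_block] vectors (or named numerics over the same four
#'   channels).
#' @param model one of `"sum"`, `"bliss"`, `"loewe"`.
#' @return A [channel_block] with the combined fractions.
#' @examples
#' a <- channel_block(IKr = 0.5)
#' combine_channels(a, a, "bliss")
#' @export
combine_channels <- function(a, b, model = c("sum", "bliss", "loewe")) {
  model <- match.arg(model)
  a <- as_block(a); b <- as_block(b)
  f <- switch(model, sum = combine_sum, bliss = combine_bliss,
              loewe = combine_loewe)
  out <- setNames(f(unclass(a), unclass(b)[names(a)]), names(a))
  structure(out, class = "channel_block")
}

#' Read a drug channel-block parameter table
#'
#' The table has one row per (drug, channel) with columns `drug`,
#' `channel` (one of IKr, IKs, INa, ICaL), `ic50_uM` and `hill_n`. A channel
#' absent for a drug means the drug does not block that current.
#'
#' @param path CSV file path.
#' @return A data frame with validated columns.
#' @export
read_drug_blocks <- function(path) {
  stop_if(!file.exists(path), "drug block table not found: %s", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "channel", "ic50_uM", "hill_n")
  miss <- setdiff(need, names(tab))
  stop_if(length(miss) > 0, "drug block table missing columns: %s",
          paste(miss, collapse = ", "))
  bad <- setdiff(unique(tab$channel), QTDDI_CHANNELS)
  stop_if(length(bad) > 0, "unknown channels in block table: %s",
          paste(bad, collapse = ", "))
  stop_if(any(!is.finite(tab$ic50_uM)) || any(tab$ic50_uM <= 0),
          "ic50_uM must be positive and finite")
  stop_if(any(!is.finite(tab$hill_n)) || any(tab$hill_n <= 0),
          "hill_n must be positive and finite")
  tab
}

#' Channel block of one drug at a given concentration
#'
#' Evaluates the Hill model for every channel the drug is parameterized for;
#' channels without a row get zero block.
#'
#' @param conc_uM drug concentration in uM (scalar).
#' @param drug drug name matching the `drug` column.
#' @param block_table data frame as returned by [read_drug_blocks()].
#' @return A [channel_block].
#' @export
drug_block_at <- function(conc_uM, drug, block_table) {
  stop_if(length(conc_uM) != 1L || !is.finite(conc_uM) || conc_uM < 0,
          "conc_uM must be a single non-negative number")
  rows <- block_table[block_table$drug == drug, , drop = FALSE]
  e <- setNames(numeric(4), QTDDI_CHANNELS)
  for (k in seq_len(nrow(rows))) {
    ch <- rows$channel[k]
    e[ch] <- hill_inhibition(conc_uM, rows$ic50_uM[k], rows$hill_n[k])
  }
  structure(e, class = "channel_block")
}
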