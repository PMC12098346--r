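#' Thermodynamic constants
#'
#' @param temperature Kelvin; 25 degrees Celsius maps to 298.15 K exactly.
#' @param gas_constant kcal mol^-1 K^-1.
#' @return list of class `thermo_constants`.
#' @export
thermo_constants <- function(temperature = 298.15,
                             gas_constant = 1.9872042586e-3) {
  stopifnot(temperature >= 0, gas_constant > 0)
  structure(list(gas_constant = gas_constant, temperature = temperature),
            class = "thermo_constants")
}

#' Thermal energy RT
#'
#' At 25 degrees Celsius RT is about 0.59 kcal/mol, conventionally rounded
#' to 0.6 kcal/mol — the scale of thermal noise against which small
#' delta-delta-G values are judged.
#'
#' @param constants a [thermo_constants()].
#' @return RT in kcal/mol.
#' @export
rt_energy <- function(constants = thermo_constants()) {
  constants$gas_constant * constants$temperature
}

#' Dissociation-constant fold change implied by a binding delta-delta-G
#'
#' `exp(|ddg| / RT)`: a 1 kcal/mol change at 25 degrees Celsius corresponds
#' to roughly a 5-fold change in Kd.
#'
#' @param ddg delta-delta-G in kcal/mol (vectorized).
#' @param constants a [thermo_constants()].
#' @return fold change, always >= 1.
#' @export
kd_fold_change <- function(ddg, constants = thermo_constants()) {
  stopifnot(all(is.finite(ddg)))
  exp(abs(ddg) / rt_energy(constants))
}

#' Significance thresholds for delta-delta-G classification
#'
#' A predicted change is `significant` when strictly larger (in magnitude)
#' than 1 kcal/mol; values at or below about 0.6 kcal/mol (roughly RT at
#' 25 degrees Celsius) are `within_noise`; the band in between is
#' `above_noise`.
#'
#' @param significant kcal/mol, default 1.0.
#' @param noise kcal/mol, default 0.6.
#' @return list of class `ddg_thresholds`.
#' @export
ddg_thresholds <- function(significant = 1.0, noise = 0.6) {
  stopifnot(noise > 0, significant >= noise)
  structure(list(significant = significant, noise = noise),
            class = "ddg_thresholds")
}

#' Classify a delta-delta-G value
#'
#' Uses the magnitude `|ddg|` (the sign — stabilizing vs destabilizing — is
#' reported separately by [ddg_report()]). Boundaries are strict on the
#' significance side: exactly 1.0 kcal/mol is not "larger than 1" and so is
#' `above_noise`; exactly 0.6 kcal/mol is `within_noise`.
#'
#' @param ddg kcal/mol (vectorized).
#' @param thresholds a [ddg_thresholds()].
#' @return character vector: `"significant"`, `"above_noise"` or
#'   `"within_noise"`.
#' @export
classify_ddg <- function(ddg, thresholds = ddg_thresholds()) {
  stopifnot(all(is.finite(ddg)))
  m <- abs(ddg)
  ifelse(m > thresholds$significant, "significant",
         ifelse(m > thresholds$noise, "above_noise", "within_noise"))
}

#' Classify a table of stability / affinity delta-delta-G predictions
#'
#' Input rows carry a complex label, a mutation label, and predicted
#' delta-delta-G for folding stability and for binding affinity (both
#' kcal/mol; values are consumed as input — prediction itself is out of
#' scope). Each row is classified on both axes and the affinity value is
#' converted to a Kd fold change. Rows with non-numeric values are flagged
#' and the run continues.
#'
#' @param records data.frame (or TSV path) with columns `complex_id`,
#'   `mutation`, `ddg_stability`, `ddg_affinity`.
#' @param thresholds a [ddg_thresholds()].
#' @param constants a [thermo_constants()].
#' @return list of class `ddg_report`: `table` (classified rows, ordered by
#'   `complex_id`) and `summary` (character vector).
#' @export
ddg_report <- function(records, thresholds = ddg_thresholds(),
                       constants = thermo_constants()) {
  if (is.character(records) && length(records) == 1L)
    records <- read.delim(records, stringsAsFactors = FALSE)
  need <- c("complex_id", "mutation", "ddg_stability", "ddg_affinity")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("delta-delta-G table is missing column(s): ",
         paste(miss, collapse = ", "))
  tb <- records
  tb$ddg_stability <- suppressWarnings(as.numeric(tb$ddg_stability))
  tb$ddg_affinity <- suppressWarnings(as.numeric(tb$ddg_affinity))
  tb$error <- ifelse(is.na(tb$ddg_stability) | is.na(tb$ddg_affinity),
                     "non-numeric delta-delta-G", "")
  ok <- !nzchar(tb$error)
  tb$class_stability <- rep(NA_character_, nrow(tb))
  tb$class_affinity <- rep(NA_character_, nrow(tb))
  tb$sign_stability <- rep(NA_character_, nrow(tb))
  tb$sign_affinity <- rep(NA_character_, nrow(tb))
  tb$kd_fold_change <- rep(NA_real_, nrow(tb))
  tb$class_stability[ok] <- classify_ddg(tb$ddg_stability[ok], thresholds)
  tb$class_affinity[ok] <- classify_ddg(tb$ddg_affinity[ok], thresholds)
  sgn <- function(x) ifelse(x > 0, "destabilizing",
                            ifelse(x < 0, "stabilizing", "neutral"))
  tb$sign_stability[ok] <- sgn(tb$ddg_stability[ok])
  tb$sign_affinity[ok] <- sgn(tb$ddg_affinity[ok])
  tb$kd_fold_change[ok] <- kd_fold_change(tb$ddg_affinity[ok], constants)
  tb <- tb[order(tb$complex_id), , drop = FALSE]
  rownames(tb) <- NULL
  n_ok <- sum(ok)
  summary <- c(
    sprintf("%d record(s), %d classified, %d error(s)", nrow(tb), n_ok,
            sum(!ok)),
    sprintf("stability: %d significant, %d above noise, %d within noise",
            sum(tb$class_stability == "significant", na.rm = TRUE),
            sum(tb$class_stability == "above_noise", na.rm = TRUE),
            sum(tb$class_stability == "within_noise", na.rm = TRUE)),
    sprintf("affinity: %d significant, %d above noise, %d within noise",
            sum(tb$class_affinity == "significant", na.rm = TRUE),
            sum(tb$class_affinity == "above_noise", na.rm = TRUE),
            sum(tb$class_affinity == "within_noise", na.rm = TRUE)),
    sprintf("thresholds: significant > %.3g kcal/mol, noise <= %.3g kcal/mol; RT = %.4f kcal/mol at %.2f K",
            thresholds$significant, thresholds$noise, rt_energy(constants),
            constants$temperature))
  structure(list(table = tb, summary = summary, thresholds = thresholds,
                 constants = constants), class = "ddg_report")
}

#' @export
print.ddg_report <- function(x, ...) {
  cat("<ddg_report>\n")
  cat(paste0("  ", x$summary, collapse = "\n"), "\n")
  invisible(x)
}
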