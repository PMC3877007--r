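#' Convert a mass concentration to molarity
#'
#' `uM = (ng/ml) / (g/mol)`; e.g. 1 ug/ml (1000 ng/ml) is 2 uM for a
#' molecular weight of 500 g/mol and 3 uM for 333 g/mol (the rule of
#' thumb used when comparing plasma exposures in weight/volume units with
#' IC50s in uM).
#'
#' @param conc_ng_ml concentration in ng/ml, >= 0 (vectorised)
#' @param mw molecular weight in g/mol, > 0
#' @return concentration in uM
#' @export
#' @examples
#' mass_to_molar(1000, 500)  # 2 uM
mass_to_molar <- function(conc_ng_ml, mw) {
  if (any(mw <= 0) || any(!is.finite(mw))) stop("mw must be > 0", call. = FALSE)
  if (any(conc_ng_ml < 0, na.rm = TRUE))
    stop("concentration must be >= 0", call. = FALSE)
  conc_ng_ml / mw
}

#' @rdname mass_to_molar
#' @param conc_uM concentration in uM, >= 0
#' @export
molar_to_mass <- function(conc_uM, mw) {
  if (any(mw <= 0) || any(!is.finite(mw))) stop("mw must be > 0", call. = FALSE)
  if (any(conc_uM < 0, na.rm = TRUE))
    stop("concentration must be >= 0", call. = FALSE)
  conc_uM * mw
}

#' Compare a plasma exposure with a panel IC50 row
#'
#' Converts Cmax to uM and forms the per-line ratio Cmax / IC50. A line
#' is "covered" when peak exposure reaches its IC50 (ratio >= 1);
#' censored IC50s (true value above the tested range) count as not
#' covered, missing entries are excluded from the fraction.
#'
#' @param cmax_ng_ml peak plasma concentration in ng/ml
#' @param mw molecular weight in g/mol (error if missing/invalid)
#' @param ic50s named IC50 vector over cell lines (uM)
#' @param censored logical vector flagging censored entries (default none)
#' @param compound compound id used in error messages
#' @return list with `cmax_uM`, `ratios` (NA where censored/missing) and
#'   `fraction_covered`
#' @export
exposure_coverage <- function(cmax_ng_ml, mw, ic50s, censored = NULL,
                              compound = "compound") {
  if (is.null(mw) || is.na(mw) || mw <= 0)
    stop(sprintf("missing or invalid molecular weight for %s", compound),
         call. = FALSE)
  if (is.null(cmax_ng_ml) || is.na(cmax_ng_ml))
    stop(sprintf("Cmax absent for %s", compound), call. = FALSE)
  if (is.null(censored)) censored <- rep(FALSE, length(ic50s))
  cmax_uM <- mass_to_molar(cmax_ng_ml, mw)
  ratios <- cmax_uM / ic50s
  ratios[censored] <- NA_real_
  covered <- !is.na(ratios) & ratios >= 1
  denom <- sum(!is.na(ic50s))            # censored lines stay in the denominator
  list(cmax_uM = cmax_uM, ratios = ratios,
       fraction_covered = if (denom == 0) 0 else sum(covered) / denom)
}

#' Read a pharmacokinetics record table
#'
#' Tab-separated with columns `compound`, `dose`, `Cmax_ng_ml`,
#' `AUC_ng_h_ml`, `half_life_h`, `source`; empty cells are NA. A
#' transcription of published human PK records for the antimalarials
#' ships as `system.file("extdata", "pk_human_records.tsv",
#' package = "pharmpanel")` (ranges were collapsed to midpoints).
#'
#' @param path TSV path
#' @return data.frame of PK records
#' @export
read_pk_table <- function(path) {
  pk <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c("", "NA"))
  need <- c("compound", "dose", "Cmax_ng_ml", "AUC_ng_h_ml")
  if (!all(need %in% names(pk)))
    stop("PK table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(pk$Cmax_ng_ml < 0, na.rm = TRUE) || any(pk$AUC_ng_h_ml < 0, na.rm = TRUE))
    stop("PK concentrations must be >= 0", call. = FALSE)
  pk
}
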