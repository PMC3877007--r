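#' Construct a dose-response plate experiment
#'
#' Container for one compound x cell-line experiment on a 96-well plate:
#' a dilution series of test-compound wells (replicated) plus untreated
#' control wells, all measured in fluorescence units (FU).
#'
#' @param compound compound identifier
#' @param cell_line cell-line identifier
#' @param concentrations strictly increasing positive concentrations (uM)
#' @param signals numeric matrix of raw signals, one row per concentration,
#'   one column per replicate (>= 2 replicates)
#' @param control_signals numeric vector of untreated-control signals (>= 1)
#' @param assay assay chemistry label: `"adherent-PI"` (propidium-iodide
#'   readout for adherent lines) or `"suspension-viability"`
#' @return an object of class `plate_experiment`
#' @export
#' @examples
#' p <- plate_experiment("drugA", "line1", c(0.1, 1, 10, 100),
#'   matrix(c(900, 880, 510, 490, 120, 110, 20, 25), 4, 2, byrow = TRUE),
#'   control_signals = rep(1000, 6))
#' normalize_plate(p)
plate_experiment <- function(compound, cell_line, concentrations, signals,
                             control_signals,
                             assay = c("adherent-PI", "suspension-viability")) {
  assay <- match.arg(assay)
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) < 4L)
    stop("need >= 4 concentrations", call. = FALSE)
  assert_positive(concentrations, "concentrations")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("`concentrations` must be strictly increasing", call. = FALSE)
  signals <- as.matrix(signals)
  if (nrow(signals) != length(concentrations))
    stop("`signals` needs one row per concentration", call. = FALSE)
  if (ncol(signals) < 2L)
    stop("need >= 2 replicates per concentration", call. = FALSE)
  if (any(signals < 0) || any(!is.finite(signals)))
    stop("signals must be finite and >= 0", call. = FALSE)
  control_signals <- as.numeric(control_signals)
  if (length(control_signals) < 1L || mean(control_signals) <= 0)
    stop("controls absent or with non-positive mean: plate not normalizable",
         call. = FALSE)
  structure(list(compound = compound, cell_line = cell_line,
                 concentrations = concentrations, signals = signals,
                 control_signals = control_signals, assay = assay),
            class = "plate_experiment")
}

#' @export
print.plate_experiment <- function(x, ...) {
  cat(sprintf("<plate_experiment> %s x %s (%s)\n", x$compound, x$cell_line,
              x$assay))
  cat(sprintf("  %d concentrations (%.4g - %.4g uM), %d replicates, %d controls\n",
              length(x$concentrations), min(x$concentrations),
              max(x$concentrations), ncol(x$signals),
              length(x$control_signals)))
  invisible(x)
}

#' Normalize plate signals against untreated controls
#'
#' Divides the mean replicate signal at each concentration by the mean of
#' the untreated-control wells, giving the treated-over-control fraction
#' T/C and the fraction affected fa = 1 - T/C. fa is returned unclipped:
#' negative values indicate apparent growth stimulation and are flagged,
#' not truncated.
#'
#' @param p a [plate_experiment()]
#' @return data.frame with columns `conc_uM`, `tc`, `fa`, `stimulation`
#' @export
normalize_plate <- function(p) {
  stopifnot(inherits(p, "plate_experiment"))
  ctrl <- mean(p$control_signals)
  if (!is.finite(ctrl) || ctrl <= 0)
    stop("control mean must be > 0: plate not normalizable", call. = FALSE)
  tc <- rowMeans(p$signals) / ctrl
  data.frame(conc_uM = p$concentrations, tc = tc, fa = 1 - tc,
             stimulation = tc > 1)
}

# 4PL on the log10-dose axis: TC(D) = bottom + (top-bottom)/(1+(D/ec50)^hill)
.tc_4pl <- function(D, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (D / ec50)^hill)
}

# absolute IC50: dose where the fitted curve crosses T/C = 0.5, with
# censoring against the tested concentration range
.absolute_ic50 <- function(bottom, top, ec50, hill, conc_range) {
  if (top <= 0.5) return(list(ic50 = NA_real_, censor = "below_min"))
  if (bottom >= 0.5) return(list(ic50 = NA_real_, censor = "above_max"))
  d <- ec50 * ((top - 0.5) / (0.5 - bottom))^(1 / hill)
  if (d > conc_range[2]) list(ic50 = NA_real_, censor = "above_max")
  else if (d < conc_range[1]) list(ic50 = NA_real_, censor = "below_min")
  else list(ic50 = d, censor = "in_range")
}

#' Four-parameter logistic dose-response fit
#'
#' Least-squares fit of `TC(D) = bottom + (top - bottom) / (1 + (D/ec50)^hill)`
#' to normalized T/C fractions, on a log10-dose axis with box constraints
#' (`bottom` in \[-0.2, 1\], `top` in \[0.5, 1.5\], `hill` in (0, 10\]) and a
#' multi-start over hill seeds to avoid local minima. The reported `ic50` is
#' the absolute IC50 -- the concentration where the fitted curve crosses
#' T/C = 0.5 -- censored (`above_max` / `below_min`) when that crossing lies
#' outside the tested range. The relative midpoint `ec50` is kept for
#' diagnostics.
#'
#' @param concentrations positive dose vector (uM), >= 4 distinct values
#' @param tc normalized treated-over-control fractions, same length
#' @return an object of class `dose_response_fit` with elements `bottom`,
#'   `top`, `hill`, `ec50`, `ic50`, `censor`, `rss`, `converged`,
#'   `n_experiments`, `conc_range`
#' @export
#' @examples
#' d <- 10^seq(-2, 2, length.out = 9)
#' fit_4pl(d, 1 / (1 + d))  # ic50 = 1 uM
fit_4pl <- function(concentrations, tc) {
  concentrations <- as.numeric(concentrations)
  tc <- as.numeric(tc)
  stopifnot(length(concentrations) == length(tc))
  assert_positive(concentrations, "concentrations")
  if (length(unique(concentrations)) < 4L)
    stop("need >= 4 distinct concentrations", call. = FALSE)
  ld <- log10(concentrations)
  rng <- range(concentrations)

  obj <- function(par) {
    pred <- .tc_4pl(concentrations, par[1], par[2], 10^par[3], exp(par[4]))
    sum((tc - pred)^2) + 1e6 * max(0, par[1] - par[2] + 1e-6)^2
  }
  lower <- c(-0.2, 0.5, min(ld) - 3, log(1e-2))
  upper <- c(1.0, 1.5, max(ld) + 3, log(10))
  b0 <- min(max(min(tc), -0.2), 0.99)
  t0 <- min(max(max(tc), 0.5), 1.5)
  # dose whose observed tc is closest to the midpoint
  l0 <- ld[which.min(abs(tc - (b0 + t0) / 2))]
  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    p0 <- pmin(pmax(c(b0, t0, l0, log(h0)), lower), upper)
    res <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    return(structure(list(bottom = NA_real_, top = NA_real_, hill = NA_real_,
                          ec50 = NA_real_, ic50 = NA_real_, censor = NA_character_,
                          rss = NA_real_, converged = FALSE, n_experiments = 1L,
                          conc_range = rng),
                     class = "dose_response_fit"))
  }
  par <- best$par
  bottom <- par[1]; top <- par[2]; ec50 <- 10^par[3]; hill <- exp(par[4])
  cens <- .absolute_ic50(bottom, top, ec50, hill, rng)
  structure(list(bottom = bottom, top = top, hill = hill, ec50 = ec50,
                 ic50 = cens$ic50, censor = cens$censor, rss = best$value,
                 converged = best$convergence == 0, n_experiments = 1L,
                 conc_range = rng),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  ic <- if (identical(x$censor, "in_range")) sprintf("%.4g uM", x$ic50)
        else sprintf("censored (%s, tested up to %.4g uM)", x$censor,
                     x$conc_range[2])
  cat(sprintf("<dose_response_fit> IC50 %s | bottom %.3f top %.3f hill %.3f ec50 %.4g | rss %.3g | n_exp %d\n",
              ic, x$bottom, x$top, x$hill, x$ec50, x$rss, x$n_experiments))
  invisible(x)
}

#' Aggregate IC50 fits from independent experiments
#'
#' Summarises 2-4 independent experiments of the same compound x cell line
#' by the arithmetic mean of the in-range IC50s. If every experiment is
#' censored above the top tested concentration the summary is itself
#' censored at the highest tested concentration; a mixture of censored and
#' in-range fits yields the mean of the in-range values with
#' `partial = TRUE`.
#'
#' @param fits non-empty list of [fit_4pl()] results for one compound x line
#' @return a `dose_response_summary` with `ic50`, `censor`, `bound`,
#'   `n_experiments`, `partial`
#' @export
aggregate_ic50 <- function(fits) {
  if (length(fits) == 0L) stop("empty fit list", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "dose_response_fit")))
  censors <- vapply(fits, function(f) f$censor %||% NA_character_, character(1))
  in_range <- which(censors == "in_range")
  max_tested <- max(vapply(fits, function(f) f$conc_range[2], numeric(1)))
  if (length(in_range) == 0L) {
    return(structure(list(ic50 = NA_real_, censor = "above_max",
                          bound = max_tested, n_experiments = length(fits),
                          partial = FALSE),
                     class = "dose_response_summary"))
  }
  structure(list(ic50 = mean(vapply(fits[in_range], `[[`, numeric(1), "ic50")),
                 censor = "in_range", bound = NA_real_,
                 n_experiments = length(fits),
                 partial = length(in_range) < length(fits)),
            class = "dose_response_summary")
}

#' @export
print.dose_response_summary <- function(x, ...) {
  if (identical(x$censor, "in_range"))
    cat(sprintf("<dose_response_summary> IC50 %.4g uM (mean of %d experiments%s)\n",
                x$ic50, x$n_experiments, if (x$partial) ", partial" else ""))
  else
    cat(sprintf("<dose_response_summary> IC50 >%.4g uM (all %d experiments censored)\n",
                x$bound, x$n_experiments))
  invisible(x)
}
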