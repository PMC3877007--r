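#' Fit the median-effect line of Chou and Talalay
#'
#' The median-effect model relates dose and effect by
#' `fa/fu = (D/Dm)^m` with `fu = 1 - fa`, which is linear after a log-log
#' transform: `log10(fa/fu) = m log10(D) - m log10(Dm)`. An ordinary
#' least-squares fit of `log10(fa/fu)` on `log10(D)` yields the slope `m`;
#' the x-intercept yields `log10(Dm)`, the median-effect dose (50%
#' inhibition). The Pearson correlation `r` of the plotted points measures
#' how well the data obey the model (cell-culture data typically give
#' r > 0.90). Points with fa outside (0, 1) cannot be plotted and are
#' excluded (and recorded), not truncated.
#'
#' @param concentrations positive doses (uM)
#' @param fa fractions affected, same length
#' @return an object of class `median_effect_fit` with `m`, `Dm`, `r`,
#'   `n_used`, `excluded` (indices of dropped points)
#' @export
#' @examples
#' D <- c(0.125, 0.25, 0.5, 1, 2)
#' fa <- 1 / (1 + (0.5 / D)^2)       # m = 2, Dm = 0.5
#' median_effect_fit(D, fa)
median_effect_fit <- function(concentrations, fa) {
  concentrations <- as.numeric(concentrations)
  fa <- as.numeric(fa)
  stopifnot(length(concentrations) == length(fa))
  assert_positive(concentrations, "concentrations")
  usable <- is.finite(fa) & fa > 0 & fa < 1
  excluded <- which(!usable)
  if (sum(usable) < 2L)
    stop("fewer than 2 points with fa strictly inside (0, 1)", call. = FALSE)
  x <- log10(concentrations[usable])
  y <- log10(fa[usable] / (1 - fa[usable]))
  if (length(unique(x)) < 2L)
    stop("need >= 2 distinct usable doses", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  b <- fit$coefficients
  m <- unname(b[2])
  Dm <- 10^(-unname(b[1]) / m)
  r <- if (stats::sd(y) == 0) 1 else unname(stats::cor(x, y))
  structure(list(m = m, Dm = Dm, r = r, n_used = sum(usable),
                 excluded = excluded),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("<median_effect_fit> m = %.4g, Dm = %.4g uM, r = %.4f (n = %d, %d excluded)\n",
              x$m, x$Dm, x$r, x$n_used, length(x$excluded)))
  invisible(x)
}

# accept either a median_effect_fit or a bare list(m =, Dm =)
.me_params <- function(fit) {
  if (!is.list(fit) || is.null(fit$m) || is.null(fit$Dm))
    stop("expected a median_effect_fit or list(m =, Dm =)", call. = FALSE)
  if (fit$Dm <= 0 || fit$m <= 0)
    stop("median-effect parameters must satisfy m > 0, Dm > 0", call. = FALSE)
  fit
}

#' Effect at a dose under a median-effect fit
#'
#' Rearranges `fa/fu = (D/Dm)^m` to `fa = 1 / (1 + (Dm/D)^m)`; `fa(0) = 0`.
#'
#' @param fit a [median_effect_fit()] (or `list(m =, Dm =)`)
#' @param D dose (uM), >= 0, vectorised
#' @return fraction affected in \[0, 1)
#' @export
fa_at_dose <- function(fit, D) {
  fit <- .me_params(fit)
  stopifnot(all(D >= 0))
  ifelse(D == 0, 0, 1 / (1 + (fit$Dm / D)^fit$m))
}

#' Dose producing a given effect under a median-effect fit
#'
#' The inverse of [fa_at_dose()]: `Dx = Dm * (fa/(1-fa))^(1/m)`, the dose
#' of the drug alone that gives `fa` fractional inhibition.
#'
#' @param fit a [median_effect_fit()] (or `list(m =, Dm =)`)
#' @param fa effect level strictly inside (0, 1), vectorised
#' @return dose in uM
#' @export
dose_at_fa <- function(fit, fa) {
  fit <- .me_params(fit)
  if (any(fa <= 0 | fa >= 1))
    stop("`fa` must lie strictly inside (0, 1)", call. = FALSE)
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Combination index for a constant-ratio drug pair
#'
#' For a mixture co-diluted at a fixed dose ratio, the total mixture dose
#' producing effect `fa` is read from the mixture's own median-effect fit
#' and split into the component doses `(D)1`, `(D)2` by the ratio. With
#' `(Dx)i` the isoeffective monotherapy doses, the exclusive (classic
#' isobologram) combination index is
#' `CI = (D)1/(Dx)1 + (D)2/(Dx)2`; the nonexclusive (mutually
#' nonexclusive drugs) variant adds the product term
#' `[(D)1 (D)2] / [(Dx)1 (Dx)2]`, so it always exceeds the exclusive
#' value. CI < 1 indicates synergism, CI = 1 additivity, CI > 1 antagonism.
#'
#' @param fitA,fitB monotherapy [median_effect_fit()]s
#' @param fitMix [median_effect_fit()] of the constant-ratio mixture,
#'   expressed in total (summed) dose
#' @param ratio length-2 dose fractions of drugs A and B, summing to 1
#' @param fa effect level in (0, 1)
#' @param mode `"exclusive"` (default) or `"nonexclusive"`
#' @return a single CI value
#' @export
#' @examples
#' f <- list(m = 1, Dm = 1)
#' combination_index(f, f, f, c(0.5, 0.5), fa = 0.5)  # 1: self-combination
combination_index <- function(fitA, fitB, fitMix, ratio, fa,
                              mode = c("exclusive", "nonexclusive")) {
  mode <- match.arg(mode)
  if (length(ratio) != 2L || abs(sum(ratio) - 1) > 1e-9 || any(ratio <= 0))
    stop("`ratio` must be two positive fractions summing to 1", call. = FALSE)
  if (length(fa) != 1L || fa <= 0 || fa >= 1)
    stop("`fa` must be a single value inside (0, 1)", call. = FALSE)
  D_total <- dose_at_fa(fitMix, fa)
  D1 <- ratio[1] * D_total
  D2 <- ratio[2] * D_total
  Dx1 <- dose_at_fa(fitA, fa)
  Dx2 <- dose_at_fa(fitB, fa)
  ci <- D1 / Dx1 + D2 / Dx2
  if (mode == "nonexclusive") ci <- ci + (D1 * D2) / (Dx1 * Dx2)
  ci
}

#' Classify a combination index as synergism, additivity or antagonism
#'
#' Strict rule: CI < 1 synergism, CI = 1 additive, CI > 1 antagonism. An
#' optional band `epsilon` widens the additive call for noisy estimates.
#'
#' @param ci combination index, > 0 (vectorised)
#' @param band_epsilon half-width of the additive band (default 0, strict)
#' @return character vector in `{"synergism", "additive", "antagonism"}`
#' @export
classify_interaction <- function(ci, band_epsilon = 0) {
  stopifnot(all(ci > 0), band_epsilon >= 0)
  out <- ifelse(abs(ci - 1) <= band_epsilon, "additive",
                ifelse(ci < 1, "synergism", "antagonism"))
  out
}

#' Tabulate combination indices over a grid of effect levels
#'
#' @inheritParams combination_index
#' @param fa_grid effect levels (default `c(0.50, 0.75, 0.90)`)
#' @param band_epsilon additive band for [classify_interaction()]
#' @return a `combination_index_result` data.frame with columns `fa`,
#'   `D1`, `D2`, `Dx1`, `Dx2`, `ci_exclusive`, `ci_nonexclusive`,
#'   `classification` (from the exclusive CI)
#' @export
ci_profile <- function(fitA, fitB, fitMix, ratio,
                       fa_grid = c(0.50, 0.75, 0.90), band_epsilon = 0) {
  rows <- lapply(fa_grid, function(f) {
    D_total <- dose_at_fa(fitMix, f)
    data.frame(fa = f,
               D1 = ratio[1] * D_total, D2 = ratio[2] * D_total,
               Dx1 = dose_at_fa(fitA, f), Dx2 = dose_at_fa(fitB, f),
               ci_exclusive = combination_index(fitA, fitB, fitMix, ratio, f,
                                                "exclusive"),
               ci_nonexclusive = combination_index(fitA, fitB, fitMix, ratio,
                                                   f, "nonexclusive"))
  })
  out <- do.call(rbind, rows)
  out$classification <- classify_interaction(out$ci_exclusive, band_epsilon)
  attr(out, "ratio") <- ratio
  class(out) <- c("combination_index_result", "data.frame")
  out
}
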