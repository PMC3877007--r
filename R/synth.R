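#' Default plate design for the synthetic generators
#'
#' Mirrors the screening design used throughout: ten concentrations in
#' duplicate per compound, six untreated control wells per plate. The
#' dilution factor (half-log) and the multiplicative noise level
#' (10\% CV, typical of fluorescence plate readers) are package choices,
#' exposed here.
#'
#' @param n_conc number of concentrations (>= 4)
#' @param dilution_factor geometric spacing between consecutive doses
#' @param n_replicates treated replicates per concentration (>= 2)
#' @param n_controls untreated control wells (>= 1)
#' @param control_mean_signal expected control fluorescence (FU)
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal signal noise (0 = noise-free)
#' @return a list of design parameters
#' @export
plate_design <- function(n_conc = 10L, dilution_factor = sqrt(10),
                         n_replicates = 2L, n_controls = 6L,
                         control_mean_signal = 10000, noise_cv = 0.1) {
  if (n_conc < 4L || n_replicates < 2L || n_controls < 1L)
    stop("design counts too small: need n_conc >= 4, n_replicates >= 2, n_controls >= 1",
         call. = FALSE)
  if (dilution_factor <= 1) stop("dilution_factor must be > 1", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  list(n_conc = as.integer(n_conc), dilution_factor = dilution_factor,
       n_replicates = as.integer(n_replicates),
       n_controls = as.integer(n_controls),
       control_mean_signal = control_mean_signal, noise_cv = noise_cv)
}

# geometric dilution series centered on `center`
.dilution_series <- function(center, n_conc, dilution_factor) {
  k <- seq_len(n_conc) - 1 - (n_conc - 1) / 2
  center * dilution_factor^k
}

#' Simulate one dose-response plate experiment
#'
#' Treated signals are drawn as
#' `control_mean_signal * TC(D) * lognormal(cv = noise_cv)` with the true
#' inhibition curve `TC(D) = 1 / (1 + (D / true_ic50)^hill)` (a 4PL with
#' bottom 0 and top 1, identical to a median-effect curve with
#' `m = hill`, `Dm = true_ic50`); control wells sit at TC = 1. The noise
#' factor has unit mean, so with `noise_cv = 0` every signal lies exactly
#' on the model curve. The dilution series is centered geometrically on
#' `true_ic50` unless `concentrations` is supplied.
#'
#' @param true_ic50 true median-effect dose (uM), > 0
#' @param hill true slope, > 0
#' @param design a [plate_design()]
#' @param seed integer seed; same seed, same plate, bit for bit
#' @param compound,cell_line identifiers carried into the plate
#' @param concentrations optional explicit dose series (uM) overriding the
#'   centered design series
#' @return a [plate_experiment()]
#' @export
#' @examples
#' p <- gen_plate_experiment(1, 1, plate_design(noise_cv = 0), seed = 1)
#' normalize_plate(p)
gen_plate_experiment <- function(true_ic50, hill, design = plate_design(),
                                 seed, compound = "compound",
                                 cell_line = "line",
                                 concentrations = NULL) {
  assert_positive(true_ic50, "true_ic50")
  assert_positive(hill, "hill")
  if (is.null(concentrations))
    concentrations <- .dilution_series(true_ic50, design$n_conc,
                                       design$dilution_factor)
  assert_positive(concentrations, "concentrations")
  with_seed(seed, {
    tc <- 1 / (1 + (concentrations / true_ic50)^hill)
    n <- length(concentrations) * design$n_replicates
    treated <- design$control_mean_signal * rep(tc, design$n_replicates) *
      lognorm_factor(n, design$noise_cv)
    signals <- matrix(treated, nrow = length(concentrations),
                      ncol = design$n_replicates)
    controls <- design$control_mean_signal *
      lognorm_factor(design$n_controls, design$noise_cv)
    plate_experiment(compound, cell_line, concentrations, signals, controls)
  })
}

#' Simulate a constant-ratio drug-combination experiment
#'
#' Generates three plates -- drug A alone, drug B alone, and their
#' mixture co-diluted at a constant dose ratio -- from median-effect
#' curves sharing the slope `m`. The mixture's median-effect dose is
#' `Dm_mix = psi / (r1/Dm_A + r2/Dm_B)`: `psi = 1` encodes exact Loewe
#' additivity (for equal slopes the Loewe-additive mixture is itself
#' median-effect, which is why the generator is restricted to a shared
#' `m`), `psi < 1` synergy and `psi > 1` antagonism. Under this
#' construction the exclusive combination index equals `psi` at every
#' effect level, giving a closed-form oracle for the scoring code.
#'
#' @param fitA_params,fitB_params `list(m =, Dm =)` for the two drugs;
#'   `m` must be equal
#' @param ratio length-2 positive dose fractions summing to 1
#' @param psi interaction factor, > 0
#' @param design a [plate_design()]
#' @param seed integer seed
#' @return list with elements `A`, `B`, `mix` ([plate_experiment()]s, the
#'   mixture dosed in total concentration), `ratio`, `psi`, `Dm_mix`, `m`
#' @export
gen_combination_dataset <- function(fitA_params, fitB_params,
                                    ratio = c(0.5, 0.5), psi = 1,
                                    design = plate_design(), seed) {
  a <- .me_params(fitA_params); b <- .me_params(fitB_params)
  if (!isTRUE(all.equal(a$m, b$m)))
    stop("generator requires equal slopes m for both drugs", call. = FALSE)
  if (length(ratio) != 2L || abs(sum(ratio) - 1) > 1e-9 || any(ratio <= 0))
    stop("`ratio` must be two positive fractions summing to 1", call. = FALSE)
  assert_positive(psi, "psi")
  Dm_mix <- psi / (ratio[1] / a$Dm + ratio[2] / b$Dm)
  with_seed(seed, {
    sub <- sample.int(2^31 - 1, 3)
    list(A = gen_plate_experiment(a$Dm, a$m, design, sub[1], "drugA"),
         B = gen_plate_experiment(b$Dm, b$m, design, sub[2], "drugB"),
         mix = gen_plate_experiment(Dm_mix, a$m, design, sub[3], "mixture"),
         ratio = ratio, psi = psi, Dm_mix = Dm_mix, m = a$m)
  })
}

#' Simulate a compound x cell-line potency panel with cluster structure
#'
#' Compounds belong to named groups (e.g. mechanistic classes); log10 IC50
#' profiles across cell lines are built from a shared group latent profile
#' so that the population Pearson correlation between two compounds is
#' `within_cor` inside a group and `between_cor` across groups. This is
#' the known-truth input for clustering recovery tests.
#'
#' @param groups named list: group label -> character vector of compound ids
#' @param cell_lines character vector of line ids (or a count)
#' @param within_cor,between_cor population correlations of log10-IC50
#'   profiles within and between groups; `0 <= between_cor < within_cor < 1`
#' @param log_ic50_mean,log_ic50_sd location/scale of log10 IC50 (uM)
#' @param hill true Hill slope assigned to every compound
#' @param seed integer seed
#' @return a `true_panel_model`: list with `compounds`, `cell_lines`,
#'   `true_ic50` (compounds x lines matrix, uM), `true_hill`, `group_of`
#' @export
gen_potency_panel <- function(groups, cell_lines, within_cor = 0.95,
                              between_cor = 0.2, log_ic50_mean = 0,
                              log_ic50_sd = 1, hill = 1, seed) {
  if (is.numeric(cell_lines) && length(cell_lines) == 1L)
    cell_lines <- sprintf("line%02d", seq_len(cell_lines))
  if (!(between_cor >= 0 && between_cor < within_cor && within_cor < 1))
    stop("need 0 <= between_cor < within_cor < 1", call. = FALSE)
  compounds <- unlist(groups, use.names = FALSE)
  group_of <- rep(names(groups), lengths(groups))
  names(group_of) <- compounds
  n_lines <- length(cell_lines)
  a <- sqrt(within_cor)
  bshare <- between_cor / within_cor   # latent profiles share a common factor
  with_seed(seed, {
    common <- stats::rnorm(n_lines)
    latent <- sapply(names(groups), function(g)
      sqrt(bshare) * common + sqrt(1 - bshare) * stats::rnorm(n_lines))
    z <- t(sapply(compounds, function(cp) {
      g <- group_of[[cp]]
      a * latent[, g] + sqrt(1 - a^2) * stats::rnorm(n_lines)
    }))
    ic50 <- 10^(log_ic50_mean + log_ic50_sd * z)
    dimnames(ic50) <- list(compounds, cell_lines)
    hills <- stats::setNames(rep(hill, length(compounds)), compounds)
    structure(list(compounds = compounds, cell_lines = cell_lines,
                   true_ic50 = ic50, true_hill = hills, group_of = group_of),
              class = "true_panel_model")
  })
}

#' Simulate a natural-scale expression matrix with planted associations
#'
#' Background genes are independent of potency: each gene gets a
#' lognormal baseline intensity (a configurable fraction of genes falls
#' below the 500-signal expression floor used by the screen's filter) and
#' per-line values scatter multiplicatively around it. A planted gene is
#' built on the natural scale as
#' `mean + sd * (s * rho * z + sqrt(1 - rho^2) * e)` where `z` is the
#' standardized potency row, `rho = target_abs_r`, and `s = -1` for a
#' sensitivity gene (higher expression, lower IC50) or `+1` for
#' resistance -- so the expected Pearson correlation with potency is
#' `-rho` / `+rho`. Values are truncated at 0 (the planted mean is far
#' from 0, so truncation is negligible).
#'
#' @param n_genes number of background genes
#' @param potency_row named IC50 vector over cell lines (uM), the vector
#'   the downstream screen will correlate against; >= 4 lines
#' @param planted list of `list(gene =, compound =, direction =,
#'   target_abs_r =)` entries, `direction` in `{"sensitivity","resistance"}`,
#'   `target_abs_r` strictly inside (0, 1)
#' @param background list: `log_mean`, `log_sd` of the gene baseline
#'   intensity; `frac_below_floor` (overrides `log_mean` so that this
#'   fraction of baselines falls below `floor`); `line_cv` per-line scatter;
#'   `floor` the screen's signal cutoff (default 500)
#' @param planted_mean,planted_sd intensity location/scale of planted genes;
#'   the default ratio keeps the zero-truncation far (>14 sd) from the mean
#'   so the realised correlation is not distorted even for heavy-tailed
#'   potency rows
#' @param seed integer seed
#' @return list with `expr` (genes x lines matrix, rownames gene ids) and
#'   `truth` (data.frame of planted genes)
#' @export
gen_expression_panel <- function(n_genes, potency_row, planted = list(),
                                 background = list(), planted_mean = 5000,
                                 planted_sd = 350, seed) {
  n_lines <- length(potency_row)
  if (n_lines < 4L) stop("need >= 4 cell lines", call. = FALSE)
  lines <- names(potency_row) %||% sprintf("line%02d", seq_len(n_lines))
  bg <- utils::modifyList(list(log_mean = log(2000), log_sd = 1.5,
                               frac_below_floor = NULL, line_cv = 0.2,
                               floor = 500), background)
  for (p in planted) {
    if (is.null(p$target_abs_r) || p$target_abs_r <= 0 || p$target_abs_r >= 1)
      stop("planted target_abs_r must lie strictly inside (0, 1)",
           call. = FALSE)
    if (!p$direction %in% c("sensitivity", "resistance"))
      stop("planted direction must be 'sensitivity' or 'resistance'",
           call. = FALSE)
  }
  if (!is.null(bg$frac_below_floor) &&
      (bg$frac_below_floor <= 0 || bg$frac_below_floor >= 1))
    stop("frac_below_floor must lie strictly inside (0, 1)", call. = FALSE)
  log_mean <- if (!is.null(bg$frac_below_floor))
    log(bg$floor) - bg$log_sd * stats::qnorm(bg$frac_below_floor)
  else bg$log_mean
  with_seed(seed, {
    base <- stats::rlnorm(n_genes, meanlog = log_mean, sdlog = bg$log_sd)
    expr <- base * matrix(lognorm_factor(n_genes * n_lines, bg$line_cv),
                          n_genes, n_lines)
    rownames(expr) <- sprintf("bg_gene%05d", seq_len(n_genes))
    colnames(expr) <- lines
    z <- as.numeric(scale(potency_row))
    truth <- NULL
    for (p in planted) {
      s <- if (p$direction == "sensitivity") -1 else 1
      rho <- p$target_abs_r
      g <- s * rho * z + sqrt(1 - rho^2) * stats::rnorm(n_lines)
      row <- pmax(planted_mean + planted_sd * g, 0)
      expr <- rbind(expr, matrix(row, 1, n_lines,
                                 dimnames = list(p$gene, lines)))
      truth <- rbind(truth, data.frame(gene = p$gene,
                                       compound = p$compound %||% NA_character_,
                                       direction = p$direction,
                                       target_abs_r = rho))
    }
    list(expr = expr, truth = truth)
  })
}

#' Simulate a gene -> GO-BP annotation table
#'
#' Each gene receives a Poisson(`mean_terms_per_gene`) number of distinct
#' terms (capped at the vocabulary size) sampled uniformly. Purely a
#' fixture generator for the term-frequency stage.
#'
#' @param genes character vector of gene ids
#' @param terms non-empty character vector of GO-BP term names
#' @param mean_terms_per_gene expected annotations per gene (>= 0)
#' @param seed integer seed
#' @return data.frame with columns `gene`, `term` (zero rows possible)
#' @export
gen_annotation_table <- function(genes, terms, mean_terms_per_gene, seed) {
  if (length(terms) == 0L) stop("`terms` must be non-empty", call. = FALSE)
  stopifnot(mean_terms_per_gene >= 0)
  with_seed(seed, {
    rows <- lapply(genes, function(g) {
      k <- min(stats::rpois(1, mean_terms_per_gene), length(terms))
      if (k == 0L) return(NULL)
      data.frame(gene = g, term = sample(terms, k))
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame(gene = character(), term = character())
    out
  })
}
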