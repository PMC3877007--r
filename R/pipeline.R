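#' Default (all-synthetic) pipeline configuration
#'
#' A small demonstration panel: seven compounds in three mechanistic
#' groups (artemisinins, synthetic peroxides, DHFR inhibitors) across 12
#' cell lines, one synthetic synergy pair, an expression screen with two
#' planted genes, a toy GO-BP vocabulary, and PK coverage against the
#' packaged human PK records. Every stage can be toggled and every
#' random block carries its own seed derived from `seed`.
#'
#' @param seed master integer seed; stage seeds are derived from it
#' @return a `pipeline_config` list
#' @export
default_config <- function(seed = 20131231) {
  structure(list(
    seed = seed,
    stages = list(potency = TRUE, cluster = TRUE, synergy = TRUE,
                  expression = TRUE, go = TRUE, pk = TRUE),
    panel = list(
      groups = list(artemisinin = c("ART", "DHA", "artemisone"),
                    peroxide = c("OZ277", "OZ439"),
                    dhfr = c("pyrimethamine", "P218")),
      n_lines = 12, within_cor = 0.95, between_cor = 0.2,
      log_ic50_mean = 0.5, log_ic50_sd = 0.8, hill = 1),
    design = list(n_conc = 10, dilution_factor = sqrt(10), n_replicates = 2,
                  n_controls = 6, control_mean_signal = 10000, noise_cv = 0.1),
    max_conc = 30,
    combination = list(drugA = list(m = 1, Dm = 1), drugB = list(m = 1, Dm = 2),
                       ratio = c(0.5, 0.5), psi = 0.5,
                       fa_grid = c(0.5, 0.75, 0.9), band_epsilon = 0),
    expression = list(n_genes = 400, frac_below_floor = 0.3, min_signal = 500,
                      p_cutoff = 5e-4, potency_scale = "natural",
                      planted = list(
                        list(gene = "SENS1", compound = "ART",
                             direction = "sensitivity", target_abs_r = 0.9),
                        list(gene = "RES1", compound = "ART",
                             direction = "resistance", target_abs_r = 0.9))),
    go = list(n_terms = 25, mean_terms_per_gene = 2, k = 30),
    cluster = list(log10 = TRUE, censor_policy = "impute_at_bound", k = 3),
    pk = list(records = NULL,   # NULL = packaged human records table
              # demonstration molecular weights (g/mol), user-supplied config
              mw = c(ART = 384.4, DHA = 284.4, artemisone = 401.5,
                     OZ277 = 392.5, OZ439 = 469.6, pyrimethamine = 248.7,
                     P218 = 452.5))
  ), class = "pipeline_config")
}

# stable hash of the configuration for output provenance headers
.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# derive per-stage sub-seeds (< 2^31) from the master seed
.stage_seeds <- function(seed) {
  with_seed(seed, stats::setNames(sample.int(2^31 - 1, 6),
                                  c("panel", "plates", "combination",
                                    "expression", "annotation", "spare")))
}

#' Run the full panel-analysis pipeline on a configuration
#'
#' Chains all stages on synthetic inputs with known ground truth:
#' (1) generate a true potency panel, simulate one plate per compound x
#' cell line, normalize and fit IC50s into a potency table; (2) Ward
#' clustering of the log10 potency fingerprints with Newick and
#' merge-table outputs; (3) a constant-ratio combination experiment
#' scored by the combination index; (4) an expression-potency screen per
#' compound; (5) GO-BP term frequencies of each hit list; (6) PK exposure
#' coverage. All outputs are plain TSV with a provenance header, plus a
#' `run_metadata.json` echoing the configuration, seeds and versions.
#'
#' @param cfg a [default_config()]-style `pipeline_config`
#' @param out_dir output directory (created if absent)
#' @return invisibly, a list with the in-memory stage results and the
#'   paths written
#' @export
run_pipeline <- function(cfg = default_config(), out_dir) {
  stopifnot(is.list(cfg), !missing(out_dir))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(cfg)
  seeds <- .stage_seeds(cfg$seed)
  res <- list()
  paths <- character()
  design <- do.call(plate_design, cfg$design)

  panel <- do.call(gen_potency_panel,
                   c(cfg$panel[setdiff(names(cfg$panel), "n_lines")],
                     list(cell_lines = cfg$panel$n_lines,
                          seed = seeds[["panel"]])))
  res$panel <- panel

  if (isTRUE(cfg$stages$potency)) {
    nc <- length(panel$compounds); nl <- length(panel$cell_lines)
    ic50 <- matrix(NA_real_, nc, nl,
                   dimnames = list(panel$compounds, panel$cell_lines))
    censored <- matrix(FALSE, nc, nl, dimnames = dimnames(ic50))
    plate_seeds <- with_seed(seeds[["plates"]], sample.int(2^31 - 1, nc * nl))
    k <- 0L
    for (cp in panel$compounds) for (ln in panel$cell_lines) {
      k <- k + 1L
      true <- panel$true_ic50[cp, ln]
      concs <- pmin(.dilution_series(true, design$n_conc,
                                     design$dilution_factor), cfg$max_conc)
      concs <- sort(unique(concs))
      if (length(concs) < 4L) concs <- cfg$max_conc / design$dilution_factor^
        ((design$n_conc:1) - 1)
      p <- gen_plate_experiment(true, panel$true_hill[cp], design,
                                seed = plate_seeds[k], compound = cp,
                                cell_line = ln, concentrations = concs)
      f <- fit_4pl(p$concentrations, normalize_plate(p)$tc)
      if (identical(f$censor, "in_range")) {
        ic50[cp, ln] <- f$ic50
      } else if (identical(f$censor, "above_max")) {
        ic50[cp, ln] <- f$conc_range[2]
        censored[cp, ln] <- TRUE
      } # below_min left missing
    }
    pm <- potency_matrix(ic50, censored)
    res$potency <- pm
    paths["potency"] <- file.path(out_dir, "potency.tsv")
    write_potency_table(pm, paths["potency"], hash)
    message(sprintf("[potency] fitted %d compound x line IC50s (%d censored, %d missing)",
                    sum(!is.na(ic50)), sum(censored), sum(is.na(ic50))))
  }

  if (isTRUE(cfg$stages$cluster) && !is.null(res$potency)) {
    m <- transform_potency(res$potency, log10 = cfg$cluster$log10,
                           censor_policy = cfg$cluster$censor_policy)
    tree <- ward_cluster(m)
    res$tree <- tree
    paths["newick"] <- file.path(out_dir, "potency_clusters.nwk")
    writeLines(to_newick(tree), paths["newick"])
    paths["merges"] <- file.path(out_dir, "potency_cluster_merges.tsv")
    write_report_tsv(data.frame(step = seq_along(tree$height),
                                left = tree$merge[, 1], right = tree$merge[, 2],
                                height = tree$height, size = tree$size),
                     paths["merges"], hash)
    message(sprintf("[cluster] %d compounds over %d complete lines",
                    nrow(m), ncol(m)))
  }

  if (isTRUE(cfg$stages$synergy)) {
    cb <- cfg$combination
    ds <- gen_combination_dataset(cb$drugA, cb$drugB, cb$ratio, cb$psi,
                                  design, seeds[["combination"]])
    fits <- lapply(ds[c("A", "B", "mix")], function(p) {
      nz <- normalize_plate(p)
      median_effect_fit(nz$conc_uM, nz$fa)
    })
    prof <- ci_profile(fits$A, fits$B, fits$mix, cb$ratio,
                       fa_grid = cb$fa_grid, band_epsilon = cb$band_epsilon)
    res$synergy <- list(dataset = ds, fits = fits, profile = prof)
    paths["ci"] <- file.path(out_dir, "combination_index.tsv")
    write_report_tsv(as.data.frame(prof), paths["ci"], hash)
    message(sprintf("[synergy] psi=%.3g -> CI(fa=0.5)=%.4g (%s)", cb$psi,
                    prof$ci_exclusive[1], prof$classification[1]))
  }

  if (isTRUE(cfg$stages$expression) && !is.null(res$potency)) {
    ex <- cfg$expression
    first <- panel$compounds[1]
    pot_row <- res$potency$ic50[ex$planted[[1]]$compound %||% first, ]
    gen <- gen_expression_panel(ex$n_genes, pot_row, planted = ex$planted,
                                background = list(frac_below_floor =
                                                    ex$frac_below_floor),
                                seed = seeds[["expression"]])
    res$expression <- gen
    filtered <- filter_expression(gen$expr, min_signal = ex$min_signal)
    message(sprintf("[expression] %d of %d genes pass the %g-signal filter",
                    nrow(filtered), nrow(gen$expr), ex$min_signal))
    res$associations <- list()
    for (cp in panel$compounds) {
      assoc <- screen_associations(filtered, res$potency$ic50[cp, ],
                                   p_cutoff = ex$p_cutoff,
                                   potency_scale = ex$potency_scale)
      res$associations[[cp]] <- assoc
      paths[paste0("assoc_", cp)] <-
        file.path(out_dir, sprintf("associations_%s.tsv", cp))
      write_report_tsv(assoc, paths[paste0("assoc_", cp)], hash)
    }
  }

  if (isTRUE(cfg$stages$go) && length(res$associations %||% list())) {
    ann <- gen_annotation_table(rownames(res$expression$expr),
                                sprintf("GO-BP term %02d", seq_len(cfg$go$n_terms)),
                                cfg$go$mean_terms_per_gene,
                                seeds[["annotation"]])
    res$annotation <- ann
    for (cp in names(res$associations)) {
      counts <- term_frequencies(res$associations[[cp]]$gene, ann)
      tab <- top_k(counts, cfg$go$k)
      paths[paste0("go_", cp)] <-
        file.path(out_dir, sprintf("go_frequencies_%s.tsv", cp))
      write_report_tsv(tab, paths[paste0("go_", cp)], hash)
    }
    message(sprintf("[go] annotated %d genes with %d terms",
                    length(unique(ann$gene)), cfg$go$n_terms))
  }

  if (isTRUE(cfg$stages$pk) && !is.null(res$potency)) {
    pk_path <- cfg$pk$records %||%
      system.file("extdata", "pk_human_records.tsv", package = "pharmpanel")
    pk <- read_pk_table(pk_path)
    rows <- NULL
    for (cp in intersect(rownames(res$potency$ic50), unique(pk$compound))) {
      if (!cp %in% names(cfg$pk$mw)) next
      cmax <- max(pk$Cmax_ng_ml[pk$compound == cp], na.rm = TRUE)
      cov <- exposure_coverage(cmax, cfg$pk$mw[[cp]], res$potency$ic50[cp, ],
                               res$potency$censored[cp, ], compound = cp)
      rows <- rbind(rows, data.frame(compound = cp, Cmax_ng_ml = cmax,
                                     Cmax_uM = cov$cmax_uM,
                                     fraction_covered = cov$fraction_covered))
    }
    res$pk_coverage <- rows
    paths["pk"] <- file.path(out_dir, "pk_coverage.tsv")
    write_report_tsv(rows, paths["pk"], hash)
    message(sprintf("[pk] exposure coverage for %d compounds",
                    nrow(rows %||% data.frame())))
  }

  meta <- list(package = "pharmpanel",
               version = as.character(utils::packageVersion("pharmpanel")),
               r_version = R.version.string,
               config_hash = hash, seed = cfg$seed,
               stage_seeds = as.list(seeds), config = cfg)
  paths["metadata"] <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, paths["metadata"], auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(list(results = res, paths = paths))
}
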