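# small config so pipeline tests stay fast
small_config <- function(seed = 7) {
  cfg <- default_config(seed)
  cfg$panel$groups <- list(g1 = c("ART", "DHA"), g2 = c("OZ277", "OZ439"))
  cfg$panel$n_lines <- 8
  cfg$expression$n_genes <- 120
  cfg$expression$planted <- list(list(gene = "SENS1", compound = "ART",
                                      direction = "sensitivity",
                                      target_abs_r = 0.95))
  cfg
}

test_that("potency TSV round-trips values, censoring and missingness", {
  ic50 <- matrix(c(0.5, 30, NA, 2.25, 0.001, 12), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("l1", "l2", "l3")))
  cens <- matrix(c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE), 2)
  pm <- potency_matrix(ic50, cens)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_potency_table(pm, path)
  back <- read_potency_table(path)
  expect_equal(back$ic50, pm$ic50)
  expect_equal(back$censored, pm$censored)
})

test_that("potency cells are parsed per the >X / blank / numeric dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound\tl1\tl2", "a\t0.5\t>30", "b\t\t2"), path)
  pm <- read_potency_table(path)
  expect_equal(pm$ic50["a", "l1"], 0.5)
  expect_equal(pm$ic50["a", "l2"], 30)
  expect_true(pm$censored["a", "l2"])
  expect_true(is.na(pm$ic50["b", "l1"]))

  writeLines(c("compound\tl1\tl2", "a\t0.5\toops"), path)
  expect_error(read_potency_table(path), "row 1 \\(a\\), column l2")
})

test_that("plate CSV and expression TSV round-trip", {
  p <- gen_plate_experiment(1, 1, plate_design(), seed = 3,
                            compound = "ART", cell_line = "HT29")
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(p, path)
  back <- read_plate_csv(path)[["ART|HT29"]]
  expect_equal(back$concentrations, p$concentrations)
  expect_equal(unname(back$signals), unname(p$signals))
  expect_equal(back$control_signals, p$control_signals)

  em <- with_seed_helper(5, matrix(rlnorm(12, 7), 3,
                                   dimnames = list(paste0("g", 1:3),
                                                   paste0("l", 1:4))))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(em, path2)
  expect_equal(read_expression_table(path2), em)
})

test_that("the pipeline is deterministic and emits one association table per compound", {
  cfg <- small_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_pipeline(cfg, d1)
  r2 <- run_pipeline(cfg, d2)
  tsvs <- sort(list.files(d1, pattern = "\\.(tsv|nwk)$"))
  expect_true(length(tsvs) >= 6)
  for (f in tsvs) {
    expect_identical(read_table_body(file.path(d1, f)),
                     read_table_body(file.path(d2, f)), label = f)
  }
  compounds <- unlist(cfg$panel$groups, use.names = FALSE)
  expect_setequal(names(r1$results$associations), compounds)
  expect_true(all(sprintf("associations_%s.tsv", compounds) %in% tsvs))
  # run metadata records the seeds
  meta <- jsonlite::read_json(file.path(d1, "run_metadata.json"))
  expect_equal(meta$seed, cfg$seed)
  expect_true(all(c("panel", "plates", "combination", "expression",
                    "annotation") %in% names(meta$stage_seeds)))
})

test_that("toggling off the expression stage leaves other outputs unchanged", {
  cfg <- small_config()
  cfg_off <- cfg
  cfg_off$stages$expression <- FALSE
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_pipeline(cfg, d1)
  run_pipeline(cfg_off, d2)
  expect_length(list.files(d2, pattern = "^associations_"), 0)
  expect_length(list.files(d2, pattern = "^go_"), 0)
  for (f in c("potency.tsv", "potency_clusters.nwk",
              "combination_index.tsv", "pk_coverage.tsv")) {
    expect_identical(read_table_body(file.path(d1, f)),
                     read_table_body(file.path(d2, f)), label = f)
  }
})

test_that("two pipelines in one process with different seeds do not interact", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  run_pipeline(small_config(seed = 7), d1)
  run_pipeline(small_config(seed = 8), d2)
  run_pipeline(small_config(seed = 7), d3)
  expect_identical(read_table_body(file.path(d1, "potency.tsv")),
                   read_table_body(file.path(d3, "potency.tsv")))
  expect_false(identical(read_table_body(file.path(d1, "potency.tsv")),
                         read_table_body(file.path(d2, "potency.tsv"))))
})

test_that("the CLI wires files through to the analysis functions", {
  d <- withr::local_tempdir()
  # simulate writes demo inputs
  pharmpanel_cli(c("simulate", "--out", d, "--seed", "4"))
  expect_true(file.exists(file.path(d, "plates.csv")))
  # fit: plate CSV -> potency rows
  outf <- file.path(d, "fits.tsv")
  pharmpanel_cli(c("fit", "--plates", file.path(d, "plates.csv"),
                   "--out", outf))
  fits <- utils::read.delim(outf, comment.char = "#")
  expect_equal(nrow(fits), 1L)
  expect_equal(as.numeric(fits$ic50_uM), 1, tolerance = 0.2)
  # cluster: potency TSV -> newick + merges
  pharmpanel_cli(c("cluster", "--potency", file.path(d, "potency.tsv"),
                   "--out", file.path(d, "tree")))
  expect_true(file.exists(file.path(d, "tree.nwk")))
  # pkconvert prints the molar conversion
  out <- capture.output(pharmpanel_cli(c("pkconvert", "--ng-ml", "1000",
                                         "--mw", "500")))
  expect_match(out, "^2 uM$")
  expect_error(pharmpanel_cli(c("nonsense")), "unknown subcommand")
  expect_error(pharmpanel_cli(character()), "usage")
})
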