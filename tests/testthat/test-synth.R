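test_that("noise-free plates lie exactly on the model curve", {
  des <- plate_design(n_conc = 9, noise_cv = 0)  # odd series: middle = IC50
  p <- gen_plate_experiment(1, 1.8, des, seed = 1)
  tc_true <- 1 / (1 + (p$concentrations / 1)^1.8)
  expect_equal(p$signals,
               matrix(des$control_mean_signal * tc_true, length(tc_true),
                      des$n_replicates))
  expect_equal(p$control_signals, rep(des$control_mean_signal, des$n_controls))
  # midpoint: a tested concentration equal to the true IC50 reads 50%
  mid <- which.min(abs(p$concentrations - 1))
  expect_equal(p$concentrations[mid], 1, tolerance = 1e-12)
  expect_equal(normalize_plate(p)$tc[mid], 0.5, tolerance = 1e-12)
})

test_that("generators are pure functions of (parameters, seed)", {
  des <- plate_design()
  expect_identical(gen_plate_experiment(2, 1, des, seed = 42),
                   gen_plate_experiment(2, 1, des, seed = 42))
  expect_false(identical(gen_plate_experiment(2, 1, des, seed = 42)$signals,
                         gen_plate_experiment(2, 1, des, seed = 43)$signals))
  pot <- stats::setNames(1:8, paste0("l", 1:8))
  expect_identical(gen_expression_panel(20, pot, seed = 5),
                   gen_expression_panel(20, pot, seed = 5))
  expect_identical(gen_annotation_table(letters, LETTERS, 2, seed = 9),
                   gen_annotation_table(letters, LETTERS, 2, seed = 9))
  # no RNG state leaks into the session
  set.seed(123); before <- .Random.seed
  invisible(gen_plate_experiment(1, 1, des, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("generator inputs are validated", {
  des <- plate_design()
  expect_error(gen_plate_experiment(-1, 1, des, seed = 1), "> 0")
  expect_error(gen_plate_experiment(1, 1, des, seed = 1,
                                    concentrations = c(0, 1, 2, 3)), "> 0")
  expect_error(plate_design(n_conc = 3), "too small")
  expect_error(plate_design(n_replicates = 1), "too small")
  expect_error(gen_combination_dataset(list(m = 1, Dm = 1),
                                       list(m = 2, Dm = 1),
                                       c(0.5, 0.5), 1, des, 1),
               "equal slopes")
  expect_error(gen_combination_dataset(list(m = 1, Dm = 1),
                                       list(m = 1, Dm = 1),
                                       c(0.6, 0.6), 1, des, 1),
               "summing to 1")
  pot <- stats::setNames(1:8, paste0("l", 1:8))
  expect_error(gen_expression_panel(5, pot,
                                    planted = list(list(gene = "g",
                                                        direction = "sensitivity",
                                                        target_abs_r = 1.2)),
                                    seed = 1),
               "strictly inside")
  expect_error(gen_expression_panel(5, pot[1:3], seed = 1), ">= 4")
  expect_error(gen_annotation_table("g", character(), 1, seed = 1),
               "non-empty")
})

test_that("fitted IC50s recover the generating parameter at 10% CV", {
  des <- plate_design(noise_cv = 0.1)
  fits <- sapply(1:100, function(s) {
    p <- gen_plate_experiment(1, 1, des, seed = 3000 + s)
    fit_4pl(p$concentrations, normalize_plate(p)$tc)$ic50
  })
  expect_equal(mean(fits), 1, tolerance = 0.1)
})

test_that("equipotent-ratio mixtures make each component isoeffective at 50%", {
  a <- list(m = 1.5, Dm = 0.5); b <- list(m = 1.5, Dm = 2)
  ratio <- c(a$Dm, b$Dm) / (a$Dm + b$Dm)
  ds <- gen_combination_dataset(a, b, ratio, psi = 1,
                                plate_design(noise_cv = 0), seed = 3)
  D_total <- dose_at_fa(list(m = ds$m, Dm = ds$Dm_mix), 0.5)
  expect_equal(ratio[1] * D_total / dose_at_fa(a, 0.5),
               ratio[2] * D_total / dose_at_fa(b, 0.5), tolerance = 1e-12)
  expect_equal(ratio[1] * D_total / dose_at_fa(a, 0.5), 0.5,
               tolerance = 1e-12)
})

test_that("potency panels carry the configured cluster structure", {
  panel <- gen_potency_panel(list(g1 = paste0("a", 1:4), g2 = paste0("b", 1:4)),
                             40, within_cor = 0.95, between_cor = 0.2,
                             seed = 21)
  expect_true(all(panel$true_ic50 > 0))
  expect_true(all(panel$true_hill > 0))
  lg <- log10(panel$true_ic50)
  cors <- cor(t(lg))
  same <- outer(panel$group_of, panel$group_of, "==")
  diag(same) <- NA
  within <- cors[which(same)]
  between <- cors[which(!same)]
  expect_gt(min(within), max(between))
  expect_gt(mean(within), 0.85)
  expect_lt(mean(between), 0.5)
})

test_that("planted expression correlation converges to target_abs_r", {
  pot <- with_seed_helper(5, stats::rlnorm(2000))
  names(pot) <- paste0("l", seq_along(pot))
  for (spec in list(c(dir = "sensitivity", r = 0.9),
                    c(dir = "resistance", r = 0.4))) {
    g <- gen_expression_panel(0, pot,
                              planted = list(list(gene = "g",
                                                  direction = spec[["dir"]],
                                                  target_abs_r = as.numeric(spec[["r"]]))),
                              seed = 8)
    r <- cor(pot, g$expr["g", ])
    expect_equal(abs(r), as.numeric(spec[["r"]]), tolerance = 0.02)
    expect_equal(sign(r), if (spec[["dir"]] == "sensitivity") -1 else 1)
  }
})

test_that("background expression floor fraction and non-negativity hold", {
  pot <- stats::setNames(exp(stats::qnorm((1:50) / 51)), paste0("l", 1:50))
  g <- gen_expression_panel(2000, pot,
                            background = list(frac_below_floor = 0.3),
                            seed = 12)
  expect_true(all(g$expr >= 0))
  expect_equal(mean(rowMeans(g$expr) < 500), 0.3, tolerance = 0.06)
})

test_that("annotation generator obeys its contract", {
  none <- gen_annotation_table(letters[1:5], c("t1", "t2"), 0, seed = 1)
  expect_equal(nrow(none), 0L)
  ann <- gen_annotation_table(letters[1:10], paste0("t", 1:4), 2, seed = 2)
  expect_true(all(ann$gene %in% letters[1:10]))
  expect_true(all(ann$term %in% paste0("t", 1:4)))
  # distinct terms per gene
  expect_false(any(duplicated(ann)))
  # total term-count mass downstream equals the number of (gene, term) pairs
  counts <- term_frequencies(letters[1:10], ann)
  expect_equal(sum(counts), nrow(ann))
})
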