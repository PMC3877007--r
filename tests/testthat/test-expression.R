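test_that("filter_expression keeps genes above the signal floor", {
  em <- rbind(low = rep(499, 6), high = rep(10000, 6),
              edge = rep(500, 6), mid = c(100, 100, 100, 2000, 2000, 2000))
  out <- filter_expression(em)
  expect_setequal(rownames(out), c("high", "mid"))   # edge: mean not > 500
  expect_equal(attr(out, "n_kept"), 2L)
  # counting oracle: brute-force recomputation over a random toy matrix
  em2 <- with_seed_helper(7, matrix(rlnorm(5 * 8, log(600), 1), 5,
                                    dimnames = list(paste0("g", 1:5), NULL)))
  keep <- sapply(seq_len(5), function(i) mean(em2[i, ]) > 500)
  expect_equal(rownames(filter_expression(em2)), paste0("g", 1:5)[keep])
  expect_error(filter_expression(-em), ">= 0")
})

test_that("correlate_potency matches the covariance/variance definition", {
  pot <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  expect_equal(correlate_potency(pot, 2 * pot + 5), 1)
  expect_error(correlate_potency(pot, rep(7, 5)), "zero variance")
  expect_error(correlate_potency(pot[1:3], pot[1:3] * 2), "fewer than 4")
  x <- with_seed_helper(11, rnorm(10)); y <- rnorm(10)
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate_potency(x, y), r_def, tolerance = 1e-12)
  # pairwise-complete behaviour
  y[3] <- NA
  expect_equal(correlate_potency(x, y), cor(x[-3], y[-3]))
})

test_that("correlation_pvalue implements the two-sided t recipe", {
  expect_equal(correlation_pvalue(0, 30), 1)
  expect_lt(correlation_pvalue(0.6, 30), correlation_pvalue(0.3, 30))
  expect_lt(correlation_pvalue(0.3, 80), correlation_pvalue(0.3, 20))
  expect_equal(correlation_pvalue(1, 10), 0)      # limiting flag value
  expect_equal(correlation_pvalue(-1, 10), 0)
  expect_error(correlation_pvalue(0.5, 2), "n >= 3")
  # quadrature oracle on a grid of (r, n)
  for (r in c(0.1, 0.3, 0.5, 0.8, -0.6)) {
    for (n in c(10, 30, 85)) {
      expect_equal(correlation_pvalue(r, n), quadrature_cor_pvalue(r, n),
                   tolerance = 1e-8)
    }
  }
})

test_that("r and p are invariant under affine rescaling of either vector", {
  x <- with_seed_helper(13, rnorm(20)); y <- rnorm(20)
  r0 <- correlate_potency(x, y)
  expect_equal(correlate_potency(3 * x + 7, y), r0)
  expect_equal(correlate_potency(x, -2 * y + 1), -r0)
  expect_equal(correlation_pvalue(correlate_potency(3 * x + 7, -2 * y), 20),
               correlation_pvalue(r0, 20))
})

test_that("screen_associations finds planted genes with the right direction", {
  pot <- with_seed_helper(17, stats::setNames(rlnorm(85), paste0("l", 1:85)))
  gen <- gen_expression_panel(300, pot,
                              planted = list(
                                list(gene = "SENS", direction = "sensitivity",
                                     target_abs_r = 0.9),
                                list(gene = "RES", direction = "resistance",
                                     target_abs_r = 0.9)),
                              seed = 19)
  assoc <- screen_associations(filter_expression(gen$expr), pot)
  expect_true(all(c("SENS", "RES") %in% assoc$gene))
  expect_equal(assoc$direction[assoc$gene == "SENS"], "sensitivity")
  expect_equal(assoc$direction[assoc$gene == "RES"], "resistance")
  expect_true(!is.unsorted(assoc$p))
  expect_true(all(assoc$p < 5e-4))
  expect_equal(unique(assoc$n), 85L)
})

test_that("screening an empty matrix returns an empty association list", {
  out <- screen_associations(matrix(numeric(), 0, 5), 1:5)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_tested"), 0L)
})

test_that("permuting potency labels destroys planted associations", {
  pot <- with_seed_helper(23, stats::setNames(rlnorm(40), paste0("l", 1:40)))
  gen <- gen_expression_panel(0, pot,
                              planted = list(list(gene = "g",
                                                  direction = "sensitivity",
                                                  target_abs_r = 0.9)),
                              seed = 29)
  expr <- gen$expr["g", ]
  set.seed(31)
  perm_p <- replicate(100, {
    r <- correlate_potency(sample(pot), expr)
    correlation_pvalue(r, 40)
  })
  expect_gt(median(perm_p), 0.05)
  expect_lt(correlation_pvalue(correlate_potency(pot, expr), 40), 1e-6)
})

test_that("bonferroni_threshold divides alpha by the test count", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})
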