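#' Filter an expression matrix by signal level
#'
#' Keeps genes whose typical natural-scale intensity exceeds the floor
#' (default 500 FU, below which summarized array signals are mostly
#' noise). "Typical" is the per-gene mean across lines by default; median
#' and max are offered as alternatives.
#'
#' @param em numeric genes x lines matrix, natural scale, values >= 0
#' @param min_signal signal floor (default 500)
#' @param stat per-gene summary: `"mean"` (default), `"median"`, `"max"`
#' @return the filtered matrix, with attribute `n_kept`
#' @export
filter_expression <- function(em, min_signal = 500,
                              stat = c("mean", "median", "max")) {
  stat <- match.arg(stat)
  em <- as.matrix(em)
  if (any(em < 0, na.rm = TRUE))
    stop("expression values must be >= 0 (natural scale)", call. = FALSE)
  s <- switch(stat,
              mean = rowMeans(em, na.rm = TRUE),
              median = apply(em, 1, stats::median, na.rm = TRUE),
              max = apply(em, 1, max, na.rm = TRUE))
  out <- em[s > min_signal, , drop = FALSE]
  attr(out, "n_kept") <- nrow(out)
  out
}

#' Pearson correlation between a potency row and an expression row
#'
#' Computed over pairwise-complete cell lines; at least 4 pairs required.
#'
#' @param ic50_row named IC50 vector over lines
#' @param expr_row named expression vector over the same lines
#' @return Pearson r
#' @export
correlate_potency <- function(ic50_row, expr_row) {
  stopifnot(length(ic50_row) == length(expr_row))
  ok <- is.finite(ic50_row) & is.finite(expr_row)
  if (sum(ok) < 4L) stop("fewer than 4 complete (potency, expression) pairs",
                         call. = FALSE)
  x <- ic50_row[ok]; y <- expr_row[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' The significance of r over n paired observations via
#' `t = |r| sqrt(n - 2) / sqrt(1 - r^2)` referred to the t distribution
#' with n - 2 degrees of freedom, two-sided (the TDIST(..., 2) recipe).
#'
#' @param r Pearson correlation, |r| <= 1 (vectorised)
#' @param n number of paired observations, >= 3
#' @return two-sided p in (0, 1\]; exactly 0 returned (as the limiting
#'   value) when |r| = 1
#' @export
correlation_pvalue <- function(r, n) {
  if (any(n < 3)) stop("need n >= 3", call. = FALSE)
  stopifnot(all(abs(r) <= 1 + 1e-12))
  r <- pmin(pmax(r, -1), 1)
  out <- numeric(length(r))
  lim <- abs(r) >= 1
  out[lim] <- 0
  t <- abs(r[!lim]) * sqrt(n - 2) / sqrt(1 - r[!lim]^2)
  out[!lim] <- 2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
  out
}

#' Screen genes for expression-potency association
#'
#' For every gene in a (filtered) expression matrix, correlates its
#' expression across cell lines with the compound's IC50 row and keeps
#' genes significant at the raw p cutoff (default p < 0.0005; positive
#' and negative correlations are grouped). A gene with r < 0 is a
#' "sensitivity" gene (higher expression, lower IC50 -- greater
#' sensitivity); r > 0 marks "resistance". Genes with zero variance are
#' skipped. The Bonferroni per-test threshold for the screened universe
#' is attached for context but not applied.
#'
#' @param em genes x lines expression matrix (run [filter_expression()]
#'   first to apply the signal floor)
#' @param potency_row named IC50 vector; names must match `colnames(em)`
#' @param p_cutoff raw two-sided p cutoff (default 5e-4)
#' @param potency_scale correlate against `"natural"` (default) or
#'   `"log10"` IC50s
#' @return data.frame (`gene_association`) with columns `gene`, `r`, `p`,
#'   `n`, `direction`, sorted by p ascending (ties by gene id);
#'   attributes `n_tested`, `bonferroni`
#' @export
screen_associations <- function(em, potency_row, p_cutoff = 5e-4,
                                potency_scale = c("natural", "log10")) {
  potency_scale <- match.arg(potency_scale)
  em <- as.matrix(em)
  empty <- data.frame(gene = character(), r = numeric(), p = numeric(),
                      n = integer(), direction = character())
  if (nrow(em) == 0L) {
    attr(empty, "n_tested") <- 0L
    return(empty)
  }
  if (!is.null(names(potency_row)) && !is.null(colnames(em))) {
    if (!all(colnames(em) %in% names(potency_row)))
      stop("expression lines missing from potency row", call. = FALSE)
    potency_row <- potency_row[colnames(em)]
  }
  x <- if (potency_scale == "log10") log10(potency_row) else potency_row
  res <- lapply(seq_len(nrow(em)), function(i) {
    r <- tryCatch(correlate_potency(x, em[i, ]), error = function(e) NA_real_)
    if (is.na(r)) return(NULL)
    n <- sum(is.finite(x) & is.finite(em[i, ]))
    data.frame(gene = rownames(em)[i] %||% as.character(i), r = r,
               p = correlation_pvalue(r, n), n = n,
               direction = if (r < 0) "sensitivity" else "resistance")
  })
  res <- do.call(rbind, res)
  n_tested <- if (is.null(res)) 0L else nrow(res)
  if (is.null(res)) res <- empty
  else {
    res <- res[res$p < p_cutoff, , drop = FALSE]
    res <- res[order(res$p, res$gene), , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "n_tested") <- n_tested
  attr(res, "bonferroni") <- if (n_tested > 0) bonferroni_threshold(0.05, n_tested) else NA_real_
  res
}

#' Bonferroni per-test significance threshold
#'
#' @param alpha family-wise error rate (default 0.05)
#' @param n_tests number of tests, >= 1
#' @return `alpha / n_tests`
#' @export
#' @examples
#' bonferroni_threshold(0.05, 16722)  # ~3e-6
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  alpha / n_tests
}
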