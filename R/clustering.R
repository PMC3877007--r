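#' Construct a compounds x cell-lines potency matrix
#'
#' Holds IC50s in uM together with per-entry censoring flags: a censored
#' entry records only that the IC50 exceeded the highest tested
#' concentration (a ">X" table cell), whose bound is stored in the value
#' slot. Missing entries (line not tested) are `NA`.
#'
#' @param ic50 numeric matrix (compounds x lines); censored entries hold
#'   their bounding concentration
#' @param censored logical matrix of the same shape (default: none)
#' @return an object of class `potency_matrix`
#' @export
potency_matrix <- function(ic50, censored = NULL) {
  ic50 <- as.matrix(ic50)
  if (is.null(censored)) censored <- matrix(FALSE, nrow(ic50), ncol(ic50))
  censored <- as.matrix(censored)
  stopifnot(identical(dim(ic50), dim(censored)))
  ok <- is.na(ic50) | ic50 > 0
  if (!all(ok)) stop("IC50 values (and censoring bounds) must be > 0",
                     call. = FALSE)
  censored[is.na(ic50)] <- FALSE
  dimnames(censored) <- dimnames(ic50)
  structure(list(ic50 = ic50, censored = censored), class = "potency_matrix")
}

#' @export
print.potency_matrix <- function(x, ...) {
  cat(sprintf("<potency_matrix> %d compounds x %d cell lines (%d censored, %d missing)\n",
              nrow(x$ic50), ncol(x$ic50), sum(x$censored), sum(is.na(x$ic50))))
  invisible(x)
}

#' Transform a potency matrix into a clustering input
#'
#' IC50s span orders of magnitude, so profiles are log10-transformed by
#' default. Censored entries are imputed at their bound (default) or the
#' whole cell line is dropped; after the censoring policy, only lines
#' complete across all compounds are retained (no imputation of missing
#' entries).
#'
#' @param pm a [potency_matrix()]
#' @param log10 log10-transform the uM values (default TRUE)
#' @param censor_policy `"impute_at_bound"` or `"drop_line"`
#' @param standardize z-score each compound profile after transform
#' @return numeric compounds x lines matrix with no missing values
#' @export
transform_potency <- function(pm, log10 = TRUE,
                              censor_policy = c("impute_at_bound", "drop_line"),
                              standardize = FALSE) {
  stopifnot(inherits(pm, "potency_matrix"))
  censor_policy <- match.arg(censor_policy)
  m <- pm$ic50
  if (censor_policy == "drop_line") {
    drop <- apply(pm$censored, 2, any)
    m <- m[, !drop, drop = FALSE]
  }
  keep <- colSums(is.na(m)) == 0
  m <- m[, keep, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("fewer than 2 compounds or 2 complete cell lines after censor policy",
         call. = FALSE)
  if (log10) m <- log10(m)
  if (standardize) m <- t(scale(t(m)))
  m
}

#' Agglomerative Ward clustering of compound potency profiles
#'
#' Ward's minimum-variance method on Euclidean distances between compound
#' profiles: at every step the pair of clusters whose merger least
#' increases the total within-cluster sum of squared deviations from the
#' cluster means is joined. Implemented by the Lance-Williams update on
#' squared Euclidean distances; the reported merge height is the Euclidean
#' scale `sqrt(D)` of the minimized Ward distance, which is non-decreasing
#' along the merge sequence. Ties are broken by the lowest pair of cluster
#' indices (row-major), making the tree deterministic for a given row
#' ordering.
#'
#' @param m numeric matrix (rows = items to cluster) with no missing values
#' @return a `linkage_tree`: list with `merge` (n-1 x 2, negative entries
#'   are leaves, positive entries reference earlier merges -- the
#'   [stats::hclust()] convention), `height`, `size` (cluster size after
#'   each merge), `labels`
#' @export
ward_cluster <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 rows to cluster", call. = FALSE)
  if (anyNA(m)) stop("missing values not allowed; see transform_potency()",
                     call. = FALSE)
  labels <- rownames(m) %||% as.character(seq_len(n))
  D <- as.matrix(stats::dist(m))^2      # squared Euclidean
  size <- rep(1L, n)
  id <- -seq_len(n)                      # hclust leaf convention
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  msize <- integer(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        if (D[i, j] < bestd - 1e-12) { bestd <- D[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- sqrt(max(bestd, 0))
    msize[step] <- size[i] + size[j]
    # Lance-Williams Ward update of squared distances to the new cluster i
    for (k in active) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        ((size[i] + size[k]) * D[i, k] + (size[j] + size[k]) * D[j, k] -
           size[k] * D[i, j]) / (size[i] + size[j] + size[k])
    }
    size[i] <- size[i] + size[j]
    id[i] <- step
    active <- setdiff(active, j)
  }
  structure(list(merge = merge, height = height, size = msize,
                 labels = labels),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> %d leaves, %d merges, heights %.4g - %.4g\n",
              length(x$labels), nrow(x$merge), min(x$height), max(x$height)))
  invisible(x)
}

# leaf ordering by recursive traversal (for as.hclust)
.tree_order <- function(merge) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(nrow(merge))
}

#' Convert a linkage tree to an hclust object
#'
#' Enables the standard toolbox ([stats::cutree()], [stats::plot.hclust()],
#' [stats::as.dendrogram()]) on trees built by [ward_cluster()].
#'
#' @param x a `linkage_tree`
#' @param ... unused
#' @return an object of class `hclust`
#' @export
as.hclust.linkage_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = .tree_order(x$merge), labels = x$labels,
                 method = "ward", dist.method = "euclidean",
                 call = match.call()),
            class = "hclust")
}

#' Cut a linkage tree into k groups
#'
#' @param tree a `linkage_tree`
#' @param k number of groups
#' @return named integer vector of group memberships
#' @export
cut_tree <- function(tree, k) {
  stats::cutree(stats::as.hclust(tree), k = k)
}

#' Serialize a linkage tree to Newick
#'
#' Branch lengths are differences of merge heights (leaves sit at height
#' 0), so the tree is ultrametric and a height-0 merge yields zero-length
#' branches.
#'
#' @param tree a `linkage_tree`
#' @return a single Newick string terminated by ";"
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "linkage_tree"))
  h <- tree$height
  rec <- function(node, parent_h) {
    if (node < 0) {
      lab <- gsub("[,;:()\\s]", "_", tree$labels[-node], perl = TRUE)
      return(sprintf("%s:%.10g", lab, parent_h))
    }
    sprintf("(%s,%s):%.10g",
            rec(tree$merge[node, 1], h[node]),
            rec(tree$merge[node, 2], h[node]),
            parent_h - h[node])
  }
  root <- nrow(tree$merge)
  sprintf("(%s,%s);", rec(tree$merge[root, 1], h[root]),
          rec(tree$merge[root, 2], h[root]))
}
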