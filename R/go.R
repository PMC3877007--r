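#' Tally GO-BP term frequencies over an association hit list
#'
#' Counts, for every GO Biological Process term, how many hit genes carry
#' that annotation. A gene contributes at most once per distinct term
#' (duplicate (gene, term) rows are collapsed) but once for each distinct
#' term it carries. Unannotated hit genes add nothing to the counts; the
#' number of annotated hits is reported as a coverage attribute.
#'
#' @param hits character vector of hit gene ids
#' @param ann annotation table: data.frame with columns `gene`, `term`
#' @return named integer vector term -> count, with attributes
#'   `n_hits`, `n_annotated`
#' @export
term_frequencies <- function(hits, ann) {
  stopifnot(is.data.frame(ann), all(c("gene", "term") %in% names(ann)))
  ann <- unique(ann[, c("gene", "term")])
  sub <- ann[ann$gene %in% hits, , drop = FALSE]
  counts <- if (nrow(sub) == 0L) {
    stats::setNames(integer(0), character(0))
  } else {
    tab <- table(sub$term)
    stats::setNames(as.integer(tab), names(tab))
  }
  attr(counts, "n_hits") <- length(unique(hits))
  attr(counts, "n_annotated") <- length(unique(sub$gene))
  counts
}

#' Rank term frequencies and keep the top k
#'
#' Descending by count; equal counts are ordered alphabetically by term
#' for determinism.
#'
#' @param counts named count vector from [term_frequencies()]
#' @param k maximum number of terms to keep (default 30)
#' @return data.frame with columns `term`, `count`, `fraction_of_hits`
#'   (count over the number of hit genes, when known)
#' @export
top_k <- function(counts, k = 30) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  n_hits <- attr(counts, "n_hits")
  if (length(counts) == 0L)
    return(data.frame(term = character(), count = integer(),
                      fraction_of_hits = numeric()))
  ord <- order(-as.integer(counts), names(counts))
  sel <- ord[seq_len(min(k, length(counts)))]
  data.frame(term = names(counts)[sel], count = as.integer(counts[sel]),
             fraction_of_hits = if (is.null(n_hits) || n_hits == 0) NA_real_
                                else as.integer(counts[sel]) / n_hits)
}
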