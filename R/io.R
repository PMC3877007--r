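# Canonical interchange dialects: TSV for matrices, CSV for long-format
# plate data; UTF-8, "." decimal separator, uM for all concentrations.
# Lines starting with "#" are metadata comments and skipped on read.

.meta_header <- function(config_hash = NULL) {
  v <- tryCatch(as.character(utils::packageVersion("pharmpanel")),
                error = function(e) "dev")
  sprintf("# pharmpanel %s%s", v,
          if (is.null(config_hash)) "" else paste0(" config=", config_hash))
}

#' Read a potency matrix from TSV
#'
#' Expects compound rows and cell-line columns (first column = compound
#' id). Cells are IC50s in uM; `">X"` marks an IC50 censored above the
#' highest tested concentration X; empty cells are missing. Any other
#' content is rejected with its row/column coordinates.
#'
#' @param path TSV path
#' @return a [potency_matrix()]
#' @export
read_potency_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#", colClasses = "character")
  compounds <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  ic50 <- matrix(NA_real_, nrow(cells), ncol(cells),
                 dimnames = list(compounds, colnames(cells)))
  censored <- matrix(FALSE, nrow(cells), ncol(cells),
                     dimnames = dimnames(ic50))
  for (i in seq_len(nrow(cells))) {
    for (j in seq_len(ncol(cells))) {
      cell <- trimws(cells[i, j])
      if (is.na(cell) || cell == "" || cell == "NA") next
      if (startsWith(cell, ">")) {
        val <- suppressWarnings(as.numeric(substring(cell, 2)))
        if (is.na(val)) stop(sprintf("malformed cell at row %d (%s), column %s: '%s'",
                                     i, compounds[i], colnames(cells)[j], cell),
                             call. = FALSE)
        ic50[i, j] <- val
        censored[i, j] <- TRUE
      } else {
        val <- suppressWarnings(as.numeric(cell))
        if (is.na(val)) stop(sprintf("malformed cell at row %d (%s), column %s: '%s'",
                                     i, compounds[i], colnames(cells)[j], cell),
                             call. = FALSE)
        ic50[i, j] <- val
      }
    }
  }
  potency_matrix(ic50, censored)
}

#' Write a potency matrix to TSV
#'
#' Censored entries are written in `">X"` notation, missing entries as
#' empty cells; round-trips through [read_potency_table()].
#'
#' @param pm a [potency_matrix()]
#' @param path output path
#' @param config_hash optional run identifier echoed into the header comment
#' @return `path`, invisibly
#' @export
write_potency_table <- function(pm, path, config_hash = NULL) {
  stopifnot(inherits(pm, "potency_matrix"))
  cells <- matrix("", nrow(pm$ic50), ncol(pm$ic50))
  num <- !is.na(pm$ic50)
  cells[num] <- sprintf("%.10g", pm$ic50[num])
  cells[pm$censored] <- sprintf(">%.10g", pm$ic50[pm$censored])
  df <- data.frame(compound = rownames(pm$ic50), cells, check.names = FALSE)
  colnames(df) <- c("compound", colnames(pm$ic50))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a natural-scale expression matrix from TSV
#'
#' Gene rows, cell-line columns; first column = gene id.
#'
#' @param path TSV path
#' @return numeric genes x lines matrix
#' @export
read_expression_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values", call. = FALSE)
  rownames(m) <- raw[[1]]
  m
}

#' Write an expression matrix to TSV
#'
#' @param em genes x lines matrix
#' @param path output path
#' @param config_hash optional run identifier echoed into the header comment
#' @return `path`, invisibly
#' @export
write_expression_table <- function(em, path, config_hash = NULL) {
  df <- data.frame(gene = rownames(em), em, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene -> GO-BP annotation table
#'
#' Two tab-separated columns (`gene`, `term`), one row per (gene, term)
#' pair; multiple rows per gene allowed.
#'
#' @param path TSV path
#' @return data.frame with columns `gene`, `term`
#' @export
read_annotation_table <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("gene", "term") %in% names(ann)))
    stop("annotation table needs columns `gene` and `term`", call. = FALSE)
  ann[, c("gene", "term")]
}

#' Read long-format plate data from CSV
#'
#' Columns: `compound`, `cell_line`, `conc_uM`, `replicate`, `signal`,
#' `is_control` (TRUE/FALSE). Control rows carry no concentration. Rows
#' are grouped into one [plate_experiment()] per compound x cell line.
#'
#' @param path CSV path
#' @return named list of [plate_experiment()]s (`compound|cell_line`)
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("compound", "cell_line", "conc_uM", "replicate", "signal",
            "is_control")
  if (!all(need %in% names(df)))
    stop("plate CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$is_control <- as.logical(df$is_control)
  keys <- unique(df[, c("compound", "cell_line")])
  plates <- lapply(seq_len(nrow(keys)), function(k) {
    sub <- df[df$compound == keys$compound[k] &
                df$cell_line == keys$cell_line[k], ]
    ctrl <- sub$signal[sub$is_control]
    trt <- sub[!sub$is_control, ]
    concs <- sort(unique(trt$conc_uM))
    sig <- t(vapply(concs, function(d) {
      s <- trt[trt$conc_uM == d, ]
      s$signal[order(s$replicate)]
    }, numeric(max(trt$replicate))))
    plate_experiment(keys$compound[k], keys$cell_line[k], concs, sig, ctrl)
  })
  names(plates) <- paste(keys$compound, keys$cell_line, sep = "|")
  plates
}

#' Write plate experiments to long-format CSV
#'
#' @param plates a [plate_experiment()] or list of them
#' @param path output path
#' @param config_hash optional run identifier echoed into the header comment
#' @return `path`, invisibly
#' @export
write_plate_csv <- function(plates, path, config_hash = NULL) {
  if (inherits(plates, "plate_experiment")) plates <- list(plates)
  rows <- lapply(plates, function(p) {
    trt <- data.frame(compound = p$compound, cell_line = p$cell_line,
                      conc_uM = rep(p$concentrations, ncol(p$signals)),
                      replicate = rep(seq_len(ncol(p$signals)),
                                      each = length(p$concentrations)),
                      signal = as.vector(p$signals), is_control = FALSE)
    ctl <- data.frame(compound = p$compound, cell_line = p$cell_line,
                      conc_uM = NA_real_,
                      replicate = seq_along(p$control_signals),
                      signal = p$control_signals, is_control = TRUE)
    rbind(trt, ctl)
  })
  out <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(config_hash), con)
  utils::write.table(out, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a generic TSV report table with the package header comment
#'
#' @param df data.frame
#' @param path output path
#' @param config_hash optional run identifier
#' @return `path`, invisibly
#' @export
write_report_tsv <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
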