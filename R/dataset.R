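#' Expression time-course dataset
#'
#' Bundles a probes x samples log2 expression matrix with its sample design
#' and (optionally) a matched matrix of detection p-values. The design must
#' have one row per matrix column, with sex in \{XX, XY\}, a strain label, a
#' contiguous stage index 1..T, and a replicate id. Every sex x strain x stage
#' cell must contain at least one sample.
#'
#' @param exprs numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids), log2 scale.
#' @param design data.frame with columns `sample`, `sex`, `strain`, `stage`,
#'   `replicate`; rows map 1:1 onto the columns of `exprs`.
#' @param detection optional numeric matrix of detection p-values with the
#'   same dimnames as `exprs`.
#' @return an object of class `expr_dataset`.
#' @export
expression_dataset <- function(exprs, design, detection = NULL) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stop("`exprs` must be a numeric matrix")
  if (is.null(rownames(exprs)))
    rownames(exprs) <- sprintf("probe%05d", seq_len(nrow(exprs)))
  need <- c("sample", "sex", "strain", "stage", "replicate")
  if (!all(need %in% names(design)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (nrow(design) != ncol(exprs))
    stop("design rows (", nrow(design), ") must match expression columns (",
         ncol(exprs), ")")
  if (!is.null(colnames(exprs)) &&
      !identical(as.character(design$sample), colnames(exprs)))
    stop("design$sample must match colnames(exprs) in order")
  if (is.null(colnames(exprs))) colnames(exprs) <- as.character(design$sample)
  design$sex <- as.character(design$sex)
  if (!all(design$sex %in% c("XX", "XY")))
    stop("sex must be 'XX' or 'XY'")
  design$strain <- as.character(design$strain)
  design$stage <- as.integer(design$stage)
  stages <- sort(unique(design$stage))
  if (!identical(stages, seq_len(max(stages))))
    stop("stage indices must be contiguous 1..T")
  cells <- table(design$sex, design$strain, design$stage)
  if (any(cells == 0))
    stop("every sex x strain x stage cell needs at least one sample")
  if (!is.null(detection)) {
    if (!identical(dim(detection), dim(exprs)))
      stop("detection matrix must have the same dimensions as exprs")
    dimnames(detection) <- dimnames(exprs)
  }
  structure(
    list(exprs = exprs, design = design, detection = detection),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  d <- x$design
  cat("Expression time-course dataset\n")
  cat(sprintf("  %d probes x %d samples\n", nrow(x$exprs), ncol(x$exprs)))
  cat(sprintf("  strains: %s; stages: 1..%d; sexes: XX/XY\n",
              paste(unique(d$strain), collapse = ", "), max(d$stage)))
  cat(sprintf("  detection p-values: %s\n",
              if (is.null(x$detection)) "absent" else "present"))
  invisible(x)
}

#' Number of stages in a dataset
#' @param dataset an `expr_dataset`.
#' @return integer T.
#' @export
n_stages <- function(dataset) max(dataset$design$stage)

#' Strain labels present in a dataset
#' @param dataset an `expr_dataset`.
#' @return character vector of strain labels.
#' @export
strains <- function(dataset) sort(unique(dataset$design$strain))

#' Write / read a dataset as TSV files
#'
#' The expression (and detection) matrices are written probes-in-rows with a
#' leading `probe` column; the design as a plain TSV. `read_dataset()` is the
#' inverse.
#'
#' @param dataset an `expr_dataset`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written (write) or an `expr_dataset` (read).
#' @export
write_dataset <- function(dataset, dir, prefix = "dataset") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    exprs = file.path(dir, paste0(prefix, "_expression.tsv")),
    design = file.path(dir, paste0(prefix, "_design.tsv"))
  )
  write_matrix_tsv(dataset$exprs, paths[["exprs"]])
  utils::write.table(dataset$design, paths[["design"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$detection)) {
    paths[["detection"]] <- file.path(dir, paste0(prefix, "_detection.tsv"))
    write_matrix_tsv(dataset$detection, paths[["detection"]])
  }
  invisible(paths)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir, prefix = "dataset") {
  exprs <- read_matrix_tsv(file.path(dir, paste0(prefix, "_expression.tsv")))
  design <- utils::read.delim(file.path(dir, paste0(prefix, "_design.tsv")),
                              stringsAsFactors = FALSE)
  dpath <- file.path(dir, paste0(prefix, "_detection.tsv"))
  detection <- if (file.exists(dpath)) read_matrix_tsv(dpath) else NULL
  expression_dataset(exprs, design, detection)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(probe = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

# indices of samples in one sex x strain x stage cell
cell_index <- function(design, sex, strain, stage) {
  which(design$sex == sex & design$strain == strain & design$stage == stage)
}
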