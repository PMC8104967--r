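#' Construct an expression matrix container
#'
#' A thin container for a genes-by-cells (or genes-by-samples) matrix of
#' non-negative values with unique gene ids as rownames, cell/sample ids as
#' colnames, and a `layer` tag recording the scale of the values.
#'
#' @param values Numeric matrix, genes in rows, cells in columns, with
#'   rownames and colnames set.
#' @param layer One of `"counts"`, `"cp10k_log"`, `"imputed"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, layer = c("counts", "cp10k_log", "imputed")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and cell colnames")
  if (anyDuplicated(rownames(values)))
    stop("gene ids must be unique (collapse duplicates before construction)")
  if (any(values < 0)) stop("expression values must be non-negative")
  structure(list(values = values, layer = layer), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @method print expr_matrix
#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells, layer=%s\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' Gene and cell identifiers of an expression matrix
#' @param m An `expr_matrix`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname gene_ids
#' @export
cell_ids <- function(m) colnames(m$values)

#' Read an expression matrix
#'
#' Supports the 10x-style triplet layout (a MatrixMarket `matrix.mtx` with
#' `features.tsv` and `barcodes.tsv` companions, genes in rows) and a dense
#' TSV with a header row of cell ids and gene ids in the first column.
#' Duplicate gene ids are resolved by summing their rows.
#'
#' @param path For `triplet_mtx`, the directory holding the three files (or
#'   a character vector of the three paths: matrix, features, barcodes);
#'   for `dense_tsv`, the file path (`.gz` supported).
#' @param format `"auto"` (directory implies triplet), `"triplet_mtx"`, or
#'   `"dense_tsv"`.
#' @return An [expr_matrix()] with `layer = "counts"`.
#' @export
read_matrix <- function(path, format = c("auto", "triplet_mtx", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path[1L]) || length(path) == 3L) "triplet_mtx" else "dense_tsv"
  vals <- if (format == "triplet_mtx") .read_triplet(path) else .read_dense_tsv(path)
  vals <- .collapse_duplicate_genes(vals)
  expr_matrix(vals, layer = "counts")
}

.read_triplet <- function(path) {
  if (length(path) == 3L) {
    mtx <- path[1L]; feat <- path[2L]; barc <- path[3L]
  } else {
    pick <- function(names) {
      for (nm in names) {
        hit <- file.path(path, nm)
        if (file.exists(hit)) return(hit)
      }
      stop("missing ", names[1L], " in ", path)
    }
    mtx  <- pick(c("matrix.mtx", "matrix.mtx.gz"))
    feat <- pick(c("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz"))
    barc <- pick(c("barcodes.tsv", "barcodes.tsv.gz"))
  }
  m <- as.matrix(Matrix::readMM(mtx))
  features <- fread(feat, header = FALSE, sep = "\t")
  barcodes <- fread(barc, header = FALSE, sep = "\t")
  if (nrow(features) != nrow(m))
    stop(sprintf("feature file has %d rows but matrix has %d", nrow(features), nrow(m)))
  if (nrow(barcodes) != ncol(m))
    stop(sprintf("barcode file has %d rows but matrix has %d columns",
                 nrow(barcodes), ncol(m)))
  dimnames(m) <- list(as.character(features[[1L]]), as.character(barcodes[[1L]]))
  m
}

.read_dense_tsv <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t", colClasses = list(character = 1L))
  ids <- dt[[1L]]
  body <- as.data.frame(dt[, -1L, drop = FALSE])
  for (j in seq_along(body)) {
    col <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(col) & !is.na(body[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric value at gene row %d, cell column %d in %s",
                   bad[1L], j, path))
    body[[j]] <- col
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  m
}

.collapse_duplicate_genes <- function(vals) {
  if (anyDuplicated(rownames(vals))) {
    n_dup <- sum(duplicated(rownames(vals)))
    message(sprintf("summing rows of %d duplicate gene id(s)", n_dup))
    vals <- rowsum(vals, group = rownames(vals), reorder = FALSE)
  }
  vals
}

#' Write an expression matrix
#'
#' Writes either a dense TSV (values at 12 significant digits, lossless for
#' round-trips at working precision) or the 10x-style triplet layout into a
#' directory.
#'
#' @param m An [expr_matrix()].
#' @param path Output file (dense) or directory (triplet).
#' @param format `"dense_tsv"` or `"triplet_mtx"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("dense_tsv", "triplet_mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "expr_matrix"))
  if (format == "dense_tsv") {
    dt <- data.table(gene_id = gene_ids(m))
    vals <- signif(m$values, 12)
    for (j in seq_len(ncol(vals))) dt[[colnames(vals)[j]]] <- vals[, j]
    fwrite(dt, path, sep = "\t")
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    sp <- methods::as(Matrix::Matrix(m$values, sparse = TRUE), "generalMatrix")
    Matrix::writeMM(sp, file.path(path, "matrix.mtx"))
    writeLines(gene_ids(m), file.path(path, "features.tsv"))
    writeLines(cell_ids(m), file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}

#' Filter genes and cells by detection counts
#'
#' Applies the gene filter first (genes detected, i.e. value > 0, in at
#' least `min_cells_per_gene` cells), then the cell filter (cells with at
#' least `min_genes_per_cell` detected genes among the surviving genes).
#'
#' @param m An [expr_matrix()].
#' @param min_cells_per_gene,min_genes_per_cell Non-negative thresholds.
#' @return A filtered [expr_matrix()] on the same layer.
#' @export
filter_matrix <- function(m, min_cells_per_gene = 0L, min_genes_per_cell = 0L) {
  stopifnot(inherits(m, "expr_matrix"),
            min_cells_per_gene >= 0, min_genes_per_cell >= 0)
  v <- m$values
  keep_g <- rowSums(v > 0) >= min_cells_per_gene
  if (!any(keep_g))
    stop("gene filter removed every gene; lower min_cells_per_gene")
  v <- v[keep_g, , drop = FALSE]
  keep_c <- colSums(v > 0) >= min_genes_per_cell
  if (!any(keep_c))
    stop("cell filter removed every cell; lower min_genes_per_cell")
  v <- v[, keep_c, drop = FALSE]
  message(sprintf("filter: kept %d/%d genes, %d/%d cells",
                  sum(keep_g), length(keep_g), sum(keep_c), length(keep_c)))
  out <- expr_matrix(v, layer = "counts")
  out$layer <- m$layer
  out
}

#' Library-size normalization: counts per 10k, log1p
#'
#' Scales each cell to a total of 10,000 counts and applies `log(1 + x)`.
#' This is the working scale for the dropout mixture model.
#'
#' @param m An [expr_matrix()] with `layer = "counts"`.
#' @return An [expr_matrix()] with `layer = "cp10k_log"`. The per-cell
#'   library sizes are kept in attribute `lib_size` so the transform is
#'   invertible via [denormalize_cp10k_log()].
#' @export
normalize_cp10k_log <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$layer != "counts")
    stop("normalize_cp10k_log expects a counts layer, got ", m$layer)
  totals <- colSums(m$values)
  if (any(totals == 0))
    stop("cell(s) with zero total counts: ",
         paste(head(cell_ids(m)[totals == 0], 5L), collapse = ","))
  v <- log1p(sweep(m$values, 2L, totals / 1e4, "/"))
  out <- expr_matrix(v, layer = "cp10k_log")
  attr(out, "lib_size") <- totals
  out
}

#' Invert the CP10K/log1p transform
#'
#' Maps a `cp10k_log` (or imputed-on-that-scale) matrix back to the count
#' scale using the stored per-cell library sizes. Used when downstream
#' correlations are requested on the count scale.
#'
#' @param m An [expr_matrix()] carrying a `lib_size` attribute.
#' @return An [expr_matrix()] with `layer = "counts"` (non-integer values
#'   are possible after imputation).
#' @export
denormalize_cp10k_log <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  lib <- attr(m, "lib_size")
  if (is.null(lib)) stop("matrix has no lib_size attribute; cannot invert")
  v <- sweep(expm1(m$values), 2L, lib / 1e4, "*")
  v[v < 0] <- 0
  expr_matrix(v, layer = "counts")
}
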