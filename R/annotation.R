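#' @importFrom data.table data.table as.data.table setkey setorder := fread fwrite rbindlist
#' @importFrom stats setNames
NULL

# data.table NSE column names used across the package
utils::globalVariables(c(
  "gene_id", "symbol", "chrom", "strand", "tss", "span_start", "span_end",
  "biotype", "minus_gene", "plus_gene", "minus_tss", "plus_tss",
  "tss_distance", ".", ".N", "type", "start", "end"
))

#' Read gene models from a GTF file or a plain gene table
#'
#' Collapses an annotation to one record per gene with a representative
#' transcription start site (TSS). The representative TSS is the 5'-most
#' start across the gene's transcripts: the minimum start coordinate on the
#' plus strand and the maximum end coordinate on the minus strand. All
#' coordinates are 1-based inclusive (GTF convention).
#'
#' @param path Path to a GTF file (optionally gzipped) or a tab-delimited
#'   gene table with columns `gene_id chrom strand txStart txEnd` or
#'   `gene_id symbol chrom strand txStart txEnd biotype` (header required).
#' @param format One of `"auto"`, `"gtf"`, `"table"`. `"auto"` decides by
#'   file extension (`.gtf`, `.gtf.gz` are GTF; anything else is a table).
#' @param biotype_filter Character vector of gene biotypes to keep. Genes
#'   whose biotype is not in this set are dropped. If the annotation carries
#'   no biotype information at all, every gene is assumed `protein_coding`
#'   (with a warning).
#'
#' @return A `data.frame` (class `gene_models`) with one row per gene:
#'   `gene_id`, `symbol`, `chrom`, `strand`, `tss`, `span_start`,
#'   `span_end`, `biotype`.
#'
#' @details Records with a strand other than `+`/`-` are skipped with a
#'   warning. Duplicate gene ids are collapsed to a single record spanning
#'   all of that gene's transcripts.
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "table"),
                             biotype_filter = "protein_coding") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "table"
  }
  dt <- if (format == "gtf") .read_gtf_features(path) else .read_gene_table(path)

  bad <- !(dt$strand %in% c("+", "-"))
  if (any(bad)) {
    warning(sprintf("skipping %d record(s) with strand not in {+,-}", sum(bad)))
    dt <- dt[!bad]
  }
  if (nrow(dt) == 0L) stop("no usable gene records in ", path)

  no_biotype <- all(is.na(dt$biotype))
  if (no_biotype) {
    warning("annotation carries no biotype attribute; assuming protein_coding")
    dt[, biotype := "protein_coding"]
  }

  # collapse transcripts / duplicate ids: union span, 5'-most TSS
  genes <- dt[, {
    if (length(unique(strand)) > 1L || length(unique(chrom)) > 1L)
      warning(sprintf("gene %s has inconsistent chrom/strand; using first record", gene_id[1L]))
    s <- strand[1L]
    list(symbol   = symbol[1L],
         chrom    = chrom[1L],
         strand   = s,
         tss      = if (s == "+") min(start) else max(end),
         span_start = min(start),
         span_end   = max(end),
         biotype  = biotype[1L])
  }, by = gene_id]

  genes <- genes[biotype %in% biotype_filter]
  if (nrow(genes) == 0L)
    stop("no genes left after biotype filter (", paste(biotype_filter, collapse = ","), ")")
  setorder(genes, chrom, tss, gene_id)
  out <- as.data.frame(genes)
  class(out) <- c("gene_models", "data.frame")
  out
}

.read_gtf_features <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("failed to parse GTF ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  mc <- as.data.frame(gr)
  # prefer transcript rows (they define TSSs); fall back to gene/exon rows
  if ("type" %in% names(mc)) {
    keep <- mc$type %in% c("transcript", "mRNA")
    if (!any(keep)) keep <- mc$type %in% "gene"
    if (!any(keep)) keep <- rep(TRUE, nrow(mc))
    mc <- mc[keep, , drop = FALSE]
  }
  if (!"gene_id" %in% names(mc)) stop("GTF ", path, " has no gene_id attribute")
  bt <- if ("gene_biotype" %in% names(mc)) mc$gene_biotype
        else if ("gene_type" %in% names(mc)) mc$gene_type
        else NA_character_
  data.table(
    gene_id = as.character(mc$gene_id),
    symbol  = if ("gene_name" %in% names(mc)) as.character(mc$gene_name) else as.character(mc$gene_id),
    chrom   = as.character(mc$seqnames),
    strand  = as.character(mc$strand),
    start   = as.integer(mc$start),
    end     = as.integer(mc$end),
    biotype = as.character(bt)
  )
}

.read_gene_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("gene table ", path, " has no data rows")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  n_col <- length(header)
  if (!n_col %in% c(5L, 7L))
    stop("gene table must have 5 or 7 tab-separated columns, found ", n_col)
  rows <- vector("list", length(lines) - 1L)
  for (i in seq_along(rows)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(f) != n_col)
      stop(sprintf("malformed line %d in %s: expected %d fields, found %d",
                   i + 1L, path, n_col, length(f)))
    st <- suppressWarnings(as.integer(if (n_col == 5L) f[4L] else f[5L]))
    en <- suppressWarnings(as.integer(if (n_col == 5L) f[5L] else f[6L]))
    if (is.na(st) || is.na(en))
      stop(sprintf("malformed line %d in %s: non-numeric coordinate", i + 1L, path))
    rows[[i]] <- if (n_col == 5L)
      data.table(gene_id = f[1L], symbol = f[1L], chrom = f[2L], strand = f[3L],
                 start = st, end = en, biotype = NA_character_)
    else
      data.table(gene_id = f[1L], symbol = f[2L], chrom = f[3L], strand = f[4L],
                 start = st, end = en, biotype = f[7L])
  }
  rbindlist(rows)
}

#' Detect head-to-head (divergent) bidirectional gene pairs
#'
#' Scans a set of gene models for pairs whose TSSs diverge on opposite DNA
#' strands within a maximum distance: a minus-strand gene whose TSS lies at
#' or to the left of a plus-strand gene's TSS, on the same chromosome, with
#' `tss(plus) - tss(minus) <= max_distance`. Transcription then proceeds
#' away from the shared intergenic region on both strands.
#'
#' Each gene joins at most one pair. When several candidates qualify, the
#' pair with the smallest TSS distance wins; ties break by lexicographic
#' partner gene id, making the catalog unique and reproducible regardless
#' of input order.
#'
#' @param genes A `gene_models` data.frame from [read_gene_models()].
#' @param max_distance Maximum TSS-to-TSS distance in bp (default 1000).
#' @return A `data.frame` (class `bdg_pairs`) sorted by chromosome then
#'   minus-gene TSS, with columns `minus_gene`, `plus_gene`, `chrom`,
#'   `minus_tss`, `plus_tss`, `tss_distance`, `orientation`.
#' @export
detect_bdg_pairs <- function(genes, max_distance = 1000) {
  stopifnot(max_distance > 0)
  if (is.null(genes) || nrow(genes) == 0L) return(.empty_bdg_pairs())
  g <- as.data.table(genes)
  minus <- g[strand == "-", .(minus_gene = gene_id, chrom, minus_tss = tss)]
  plus  <- g[strand == "+", .(plus_gene = gene_id, chrom, plus_tss = tss)]
  if (nrow(minus) == 0L || nrow(plus) == 0L) return(.empty_bdg_pairs())

  cand <- minus[plus, on = .(chrom), allow.cartesian = TRUE, nomatch = NULL]
  cand <- cand[plus_tss - minus_tss >= 0 & plus_tss - minus_tss <= max_distance]
  if (nrow(cand) == 0L) return(.empty_bdg_pairs())
  cand[, tss_distance := plus_tss - minus_tss]

  # greedy matching: smallest distance first, lexicographic ids on ties
  setorder(cand, tss_distance, minus_gene, plus_gene)
  used <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$minus_gene[i] %in% used) && !(cand$plus_gene[i] %in% used)) {
      keep[i] <- TRUE
      used <- c(used, cand$minus_gene[i], cand$plus_gene[i])
    }
  }
  pairs <- cand[keep]
  pairs[, orientation := "divergent"]
  setorder(pairs, chrom, minus_tss, minus_gene)
  out <- as.data.frame(pairs[, .(minus_gene, plus_gene, chrom, minus_tss,
                                 plus_tss, tss_distance, orientation)])
  class(out) <- c("bdg_pairs", "data.frame")
  out
}

.empty_bdg_pairs <- function() {
  out <- data.frame(minus_gene = character(0), plus_gene = character(0),
                    chrom = character(0), minus_tss = integer(0),
                    plus_tss = integer(0), tss_distance = integer(0),
                    orientation = character(0))
  class(out) <- c("bdg_pairs", "data.frame")
  out
}

#' Intergenic span of a bidirectional pair
#'
#' The distance in bp between the two 5' ends (TSSs) of a divergent pair;
#' the shared promoter region lies within this span.
#'
#' @param pair One or more rows of a `bdg_pairs` data.frame.
#' @return Integer vector of TSS distances.
#' @export
intergenic_span <- function(pair) {
  stopifnot(is.data.frame(pair), "tss_distance" %in% names(pair))
  pair$tss_distance
}

#' Write a bidirectional-pair catalog to TSV
#'
#' @param pairs A `bdg_pairs` data.frame.
#' @param path Output path (`.gz` supported).
#' @return `path`, invisibly.
#' @export
write_bdg_catalog <- function(pairs, path) {
  fwrite(as.data.table(pairs)[, .(minus_gene, plus_gene, chrom, minus_tss,
                                  plus_tss, tss_distance)],
         path, sep = "\t")
  invisible(path)
}
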