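# Independent oracles and small fixture builders, written against the
# definitions rather than the package internals.

# random toy gene table (data.frame in gene_models layout)
random_gene_models <- function(n_genes, n_chrom = 2, max_pos = 50000L) {
  chrom <- paste0("chr", sample.int(n_chrom, n_genes, replace = TRUE))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  tss <- sample.int(max_pos, n_genes, replace = TRUE)
  span_start <- ifelse(strand == "+", tss, pmax(tss - 999L, 1L))
  span_end <- ifelse(strand == "+", tss + 999L, tss)
  g <- data.frame(gene_id = sprintf("G%03d", seq_len(n_genes)),
                  symbol = sprintf("G%03d", seq_len(n_genes)),
                  chrom = chrom, strand = strand, tss = tss,
                  span_start = span_start, span_end = span_end,
                  biotype = "protein_coding", stringsAsFactors = FALSE)
  class(g) <- c("gene_models", "data.frame")
  g
}

# O(n^2) brute-force head-to-head pair enumeration + greedy matching,
# written independently of detect_bdg_pairs (all n^2 ordered index pairs)
brute_force_pairs <- function(genes, max_distance = 1000) {
  n <- nrow(genes)
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  d <- genes$tss[ij$j] - genes$tss[ij$i]
  hit <- genes$strand[ij$i] == "-" & genes$strand[ij$j] == "+" &
    genes$chrom[ij$i] == genes$chrom[ij$j] & d >= 0 & d <= max_distance
  if (!any(hit)) return(data.frame(minus_gene = character(0),
                                   plus_gene = character(0),
                                   dist = integer(0)))
  cand <- data.frame(minus_gene = genes$gene_id[ij$i[hit]],
                     plus_gene = genes$gene_id[ij$j[hit]],
                     dist = d[hit], stringsAsFactors = FALSE)
  cand <- cand[order(cand$dist, cand$minus_gene, cand$plus_gene), ]
  used <- character(0)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!(cand$minus_gene[r] %in% used) && !(cand$plus_gene[r] %in% used)) {
      keep[r] <- TRUE
      used <- c(used, cand$minus_gene[r], cand$plus_gene[r])
    }
  }
  out <- cand[keep, ]
  out[order(out$minus_gene), ]
}

# plain UPGMA (average linkage) recomputation over a distance matrix
brute_force_upgma_heights <- function(D) {
  n <- nrow(D)
  active <- as.list(seq_len(n))
  d <- D
  heights <- numeric(0)
  sizes <- rep(1L, n)
  while (length(active) > 1L) {
    k <- length(active)
    best <- c(NA, NA); bestd <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (d[i, j] < bestd) { bestd <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bestd)
    new_d <- sapply(seq_len(k), function(l) {
      (sizes[i] * d[i, l] + sizes[j] * d[j, l]) / (sizes[i] + sizes[j])
    })
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], new_d[keep]),
               c(new_d[keep], 0))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
  }
  heights
}

# small expression matrix with named dimensions
toy_expr <- function(vals, layer = "counts") {
  m <- as.matrix(vals)
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%d", seq_len(ncol(m)))
  expr_matrix(m, layer = layer)
}

# write a gene table TSV in the 7-column layout
write_gene_table <- function(genes, path) {
  hdr <- c("gene_id", "symbol", "chrom", "strand", "txStart", "txEnd", "biotype")
  rows <- apply(genes, 1L, function(r) {
    paste(r[["gene_id"]], r[["symbol"]], r[["chrom"]], r[["strand"]],
          r[["span_start"]], r[["span_end"]], r[["biotype"]], sep = "\t")
  })
  writeLines(c(paste(hdr, collapse = "\t"), rows), path)
  path
}
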