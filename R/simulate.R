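#' Configuration for the synthetic single-cell study
#'
#' Defines the scale and statistical structure of the simulated study: a
#' toy annotation with head-to-head bidirectional pairs plus isolated
#' genes, and a matched negative-binomial count matrix with mean-dependent
#' dropout. Defaults mirror a single-cell experiment of ~1,500 captured
#' cells screened against ~2,000 annotated bidirectional pairs.
#'
#' Counts are generated from a Gaussian copula on per-cell latents: the
#' two genes of a planted pair share bivariate-normal latents with the
#' requested correlation `rho`, all other genes are independent. Latents
#' are mapped through each gene's lognormal mean, counts drawn
#' negative-binomially, and technical zeros introduced with probability
#' `1 / (1 + exp(a * (log(mean) - b)))`, i.e. decreasing in gene mean.
#'
#' @param n_genes Total genes (pair members plus isolated genes).
#' @param n_cells Cells to simulate.
#' @param n_bdg_pairs Number of head-to-head pairs in the toy annotation.
#' @param planted_pairs data.frame with columns `pair` (1-based pair index)
#'   and `rho` (latent correlation in (-1, 1)); all other pairs have
#'   latent correlation 0.
#' @param meanlog,sdlog Lognormal distribution of gene means (count scale).
#' @param dispersion Negative-binomial dispersion (1 / size); scalar or
#'   per-gene vector.
#' @param dropout_a,dropout_b Slope (> 0) and midpoint (log-mean scale) of
#'   the logistic dropout curve.
#' @param latent_sd Standard deviation of the per-cell latent on the log
#'   scale (biological cell-to-cell variability).
#' @param planted_mean_quantile Planted-pair genes take their mean at this
#'   quantile of the gene-mean distribution, so the planted signal sits in
#'   the detectably expressed regime rather than in a gene the simulation
#'   happened to silence.
#' @param tss_distance_meanlog,tss_distance_sdlog Lognormal TSS-distance
#'   distribution for pairs, truncated at 1000 bp (median ~200 bp).
#' @param gene_length Gene-body length in bp for the toy annotation.
#' @param chrom_length Toy chromosome length; `NULL` sizes it to fit.
#' @param seed Integer seed; every generator output is a deterministic
#'   function of (config, seed).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 4200L, n_cells = 1500L,
                              n_bdg_pairs = 2000L,
                              planted_pairs = data.frame(pair = integer(0),
                                                         rho = numeric(0)),
                              meanlog = 0.5, sdlog = 1.2,
                              dispersion = 0.3,
                              dropout_a = 1.5, dropout_b = 0.5,
                              latent_sd = 0.8,
                              planted_mean_quantile = 0.7,
                              tss_distance_meanlog = log(200),
                              tss_distance_sdlog = 0.6,
                              gene_length = 1000L,
                              chrom_length = NULL,
                              seed = 1L) {
  stopifnot(n_bdg_pairs * 2L <= n_genes,
            all(abs(planted_pairs$rho) < 1),
            all(planted_pairs$pair >= 1L & planted_pairs$pair <= n_bdg_pairs),
            dropout_a > 0, latent_sd >= 0, n_cells >= 1)
  cfg <- list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
              n_bdg_pairs = as.integer(n_bdg_pairs),
              planted_pairs = planted_pairs,
              meanlog = meanlog, sdlog = sdlog, dispersion = dispersion,
              dropout_a = dropout_a, dropout_b = dropout_b,
              latent_sd = latent_sd,
              planted_mean_quantile = planted_mean_quantile,
              tss_distance_meanlog = tss_distance_meanlog,
              tss_distance_sdlog = tss_distance_sdlog,
              gene_length = as.integer(gene_length),
              chrom_length = chrom_length,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

.sim_gene_ids <- function(cfg) {
  np <- cfg$n_bdg_pairs
  n_iso <- cfg$n_genes - 2L * np
  pair_ids <- if (np > 0)
    as.vector(rbind(sprintf("GPAIR%04d_M", seq_len(np)),
                    sprintf("GPAIR%04d_P", seq_len(np))))
  else character(0)
  iso_ids <- if (n_iso > 0) sprintf("GISO%04d", seq_len(n_iso)) else character(0)
  list(pair = pair_ids, iso = iso_ids, all = c(pair_ids, iso_ids))
}

# run expr with a deterministic RNG state, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' Write a toy GTF annotation matching a simulation config
#'
#' Places `n_bdg_pairs` head-to-head pairs (minus-strand TSS at or left of
#' the plus-strand TSS, distance drawn from the configured truncated
#' lognormal) along one toy chromosome, with all remaining genes isolated
#' (more than 10 kb from anything else). Gene ids match the rows of
#' [simulate_counts()] for the same config.
#'
#' @param cfg A [simulation_config()].
#' @param path Output GTF path; `NULL` returns the GTF text invisibly
#'   without writing.
#' @return Character vector of GTF lines, invisibly; the planted pair
#'   table is attached as attribute `pairs` (`minus_gene`, `plus_gene`,
#'   `tss_distance`).
#' @export
make_toy_annotation <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    ids <- .sim_gene_ids(cfg)
    np <- cfg$n_bdg_pairs
    n_iso <- cfg$n_genes - 2L * np
    gl <- cfg$gene_length
    gap <- 15000L

    dists <- integer(0)
    if (np > 0) {
      dists <- as.integer(round(stats::rlnorm(np, cfg$tss_distance_meanlog,
                                              cfg$tss_distance_sdlog)))
      while (any(dists > 1000L | dists < 0L)) {
        redo <- which(dists > 1000L | dists < 0L)
        dists[redo] <- as.integer(round(stats::rlnorm(length(redo),
                                                      cfg$tss_distance_meanlog,
                                                      cfg$tss_distance_sdlog)))
      }
    }

    rows <- vector("list", np + n_iso)
    pos <- 1L
    for (i in seq_len(np)) {
      minus_tss <- pos + gl            # minus gene spans [pos, minus_tss]
      plus_tss <- minus_tss + dists[i]
      rows[[i]] <- data.frame(
        gene_id = c(ids$pair[2L * i - 1L], ids$pair[2L * i]),
        strand = c("-", "+"),
        start = c(pos, plus_tss),
        end = c(minus_tss, plus_tss + gl - 1L))
      pos <- plus_tss + gl - 1L + gap
    }
    iso_strands <- if (n_iso > 0) sample(c("+", "-"), n_iso, replace = TRUE) else character(0)
    for (j in seq_len(n_iso)) {
      rows[[np + j]] <- data.frame(gene_id = ids$iso[j], strand = iso_strands[j],
                                   start = pos, end = pos + gl - 1L)
      pos <- pos + gl - 1L + gap
    }
    tab <- do.call(rbind, rows)
    if (!is.null(cfg$chrom_length) && pos > cfg$chrom_length)
      stop(sprintf("genes need %d bp but chrom_length is %d", pos, cfg$chrom_length))

    gtf <- character(0)
    for (i in seq_len(nrow(tab))) {
      attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "protein_coding";',
                       tab$gene_id[i], tab$gene_id[i])
      gtf <- c(gtf,
               sprintf("chrT\ttoy\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       tab$start[i], tab$end[i], tab$strand[i], attrs),
               sprintf("chrT\ttoy\ttranscript\t%d\t%d\t.\t%s\t.\t%s transcript_id \"%s.t1\";",
                       tab$start[i], tab$end[i], tab$strand[i], attrs, tab$gene_id[i]))
    }
    if (!is.null(path)) writeLines(gtf, path)
    pair_tab <- if (np > 0)
      data.frame(minus_gene = ids$pair[seq(1L, 2L * np, by = 2L)],
                 plus_gene = ids$pair[seq(2L, 2L * np, by = 2L)],
                 tss_distance = dists)
    else data.frame(minus_gene = character(0), plus_gene = character(0),
                    tss_distance = integer(0))
    attr(gtf, "pairs") <- pair_tab
    invisible(gtf)
  })
}

#' Simulate a single-cell count matrix with planted pair correlations
#'
#' @param cfg A [simulation_config()].
#' @return A list with `matrix` (an [expr_matrix()] of observed counts,
#'   `layer = "counts"`) and `truth`: `pre_dropout` (counts before the
#'   dropout step), `mask` (logical matrix, `TRUE` where a nonzero count
#'   was zeroed by dropout), `pairs` (pair table with latent `rho`),
#'   `gene_means`, `dispersion`, `dropout_rate` (per gene).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed + 1L, {
    ids <- .sim_gene_ids(cfg)
    G <- cfg$n_genes; C <- cfg$n_cells; np <- cfg$n_bdg_pairs

    disp <- rep_len(cfg$dispersion, G)
    if (any(disp <= 0)) stop("dispersion must be positive")
    if (cfg$sdlog < 0) stop("sdlog must be non-negative")

    log_means <- stats::rnorm(G, cfg$meanlog, cfg$sdlog)
    names(log_means) <- ids$all

    rho <- rep(0, np)
    if (nrow(cfg$planted_pairs)) {
      rho[cfg$planted_pairs$pair] <- cfg$planted_pairs$rho
      planted_genes <- c(2L * cfg$planted_pairs$pair - 1L,
                         2L * cfg$planted_pairs$pair)
      log_means[planted_genes] <-
        stats::qnorm(cfg$planted_mean_quantile, cfg$meanlog, cfg$sdlog)
    }

    # Gaussian copula latents: pair members share correlated normals
    Z <- matrix(stats::rnorm(G * C), G, C)
    if (np > 0) {
      mi <- seq(1L, 2L * np, by = 2L)
      pi_ <- mi + 1L
      Z[pi_, ] <- rho * Z[mi, ] + sqrt(1 - rho^2) * Z[pi_, ]
    }

    s <- cfg$latent_sd
    mu <- exp(log_means + s * Z - s^2 / 2)
    counts <- matrix(stats::rnbinom(G * C, mu = mu, size = rep(1 / disp, C)),
                     G, C)
    dimnames(counts) <- list(ids$all, sprintf("cell%04d", seq_len(C)))

    p_drop <- 1 / (1 + exp(cfg$dropout_a * (log_means - cfg$dropout_b)))
    drop_event <- matrix(stats::runif(G * C) < p_drop, G, C)
    mask <- drop_event & counts > 0
    observed <- counts
    observed[drop_event] <- 0L
    dimnames(mask) <- dimnames(counts)

    pair_tab <- if (np > 0)
      data.frame(minus_gene = ids$pair[seq(1L, 2L * np, by = 2L)],
                 plus_gene = ids$pair[seq(2L, 2L * np, by = 2L)],
                 rho = rho)
    else data.frame(minus_gene = character(0), plus_gene = character(0),
                    rho = numeric(0))

    list(matrix = expr_matrix(observed, layer = "counts"),
         truth = list(pre_dropout = counts, mask = mask, pairs = pair_tab,
                      gene_means = exp(log_means), dispersion = disp,
                      dropout_rate = p_drop))
  })
}
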