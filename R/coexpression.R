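#' Pearson correlation for each bidirectional gene pair
#'
#' Computes, for every pair in the catalog whose two genes are present in
#' the matrix and have nonzero variance, the Pearson correlation of the two
#' genes' values across all cells. Pairs with a missing gene or a
#' zero-variance gene are flagged (`missing_gene`, `zero_variance`) and
#' carry no coefficient.
#'
#' @param m An [expr_matrix()] with at least 3 cells (any layer).
#' @param pairs A `bdg_pairs` data.frame from [detect_bdg_pairs()], or any
#'   data.frame with `minus_gene` and `plus_gene` columns.
#' @return A data.frame (class `pair_correlations`) with `minus_gene`,
#'   `plus_gene`, `r`, `n`, `status`.
#' @export
pair_correlations <- function(m, pairs) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(pairs) || nrow(pairs) == 0L) stop("empty pair list")
  if (ncol(m$values) < 3L) stop("need at least 3 cells to correlate")
  X <- m$values
  n_cells <- ncol(X)
  ids <- rownames(X)

  a <- match(pairs$minus_gene, ids)
  b <- match(pairs$plus_gene, ids)
  status <- rep("ok", nrow(pairs))
  status[is.na(a) | is.na(b)] <- "missing_gene"

  r <- rep(NA_real_, nrow(pairs))
  ok <- which(status == "ok")
  if (length(ok)) {
    Xa <- X[a[ok], , drop = FALSE]
    Xb <- X[b[ok], , drop = FALSE]
    ma <- rowMeans(Xa); mb <- rowMeans(Xb)
    Xa <- Xa - ma; Xb <- Xb - mb
    va <- rowSums(Xa * Xa); vb <- rowSums(Xb * Xb)
    zero_var <- va <= 0 | vb <= 0
    status[ok[zero_var]] <- "zero_variance"
    good <- ok[!zero_var]
    if (length(good))
      r[good] <- rowSums(Xa[!zero_var, , drop = FALSE] * Xb[!zero_var, , drop = FALSE]) /
        sqrt(va[!zero_var] * vb[!zero_var])
  }
  n_flag <- sum(status != "ok")
  if (n_flag > 0)
    message(sprintf("%d pair(s) excluded (%d missing_gene, %d zero_variance)",
                    n_flag, sum(status == "missing_gene"),
                    sum(status == "zero_variance")))
  out <- data.frame(minus_gene = pairs$minus_gene, plus_gene = pairs$plus_gene,
                    r = r, n = ifelse(status == "ok", n_cells, NA_integer_),
                    status = status, row.names = NULL)
  class(out) <- c("pair_correlations", "data.frame")
  out
}

#' Build the genome-wide correlation distribution, optionally with a query
#'
#' Collects the coefficients of all scored pairs and, when a query pair is
#' named, its rank percentile from the top: the percentage of pairs (the
#' query included) whose correlation is at least as large as the query's.
#'
#' @param cors A [pair_correlations()] result.
#' @param query Optional `c(minus_gene, plus_gene)` naming the query pair.
#' @param absolute If `TRUE`, rank on `|r|` rather than signed `r`.
#' @return An object of class `correlation_distribution`: list with
#'   `values`, `n_pairs`, `query`, `query_r`, `query_percentile`.
#' @export
correlation_distribution <- function(cors, query = NULL, absolute = FALSE) {
  stopifnot(inherits(cors, "data.frame"), all(c("r", "status") %in% names(cors)))
  okv <- cors$r[cors$status == "ok"]
  if (absolute) okv <- abs(okv)
  if (!length(okv)) stop("no scored pairs in the distribution")
  res <- list(values = okv, n_pairs = length(okv), query = NULL,
              query_r = NULL, query_percentile = NULL, absolute = absolute)
  if (!is.null(query)) {
    hit <- which(cors$minus_gene == query[1L] & cors$plus_gene == query[2L])
    if (!length(hit))
      hit <- which(cors$minus_gene == query[2L] & cors$plus_gene == query[1L])
    if (!length(hit))
      stop("query pair ", paste(query, collapse = "/"), " not in the pair list")
    if (cors$status[hit[1L]] != "ok")
      stop("query pair ", paste(query, collapse = "/"),
           " was not scored (status=", cors$status[hit[1L]], ")")
    qr <- cors$r[hit[1L]]
    if (absolute) qr <- abs(qr)
    res$query <- paste(query, collapse = "/")
    res$query_r <- qr
    res$query_percentile <- rank_percentile(okv, qr)
  }
  structure(res, class = "correlation_distribution")
}

#' @method print correlation_distribution
#' @export
print.correlation_distribution <- function(x, ...) {
  cat(sprintf("<correlation_distribution> %d pairs, median r = %.3f\n",
              x$n_pairs, stats::median(x$values)))
  if (!is.null(x$query))
    cat(sprintf("  query %s: r = %.3f, rank percentile %.2f%% from top\n",
                x$query, x$query_r, x$query_percentile))
  invisible(x)
}

#' Rank percentile from the top
#'
#' `100 * (number of values >= query) / n`. Ties count toward the
#' numerator, which is conservative for "top X percent" statements.
#'
#' @param dist A numeric vector of coefficients or a
#'   [correlation_distribution()] object.
#' @param query_r The query coefficient.
#' @return A percentage in `(0, 100]`.
#' @export
rank_percentile <- function(dist, query_r) {
  values <- if (inherits(dist, "correlation_distribution")) dist$values else dist
  stopifnot(is.numeric(values), length(values) > 0, is.finite(query_r))
  100 * sum(values >= query_r) / length(values)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Pearson correlation of midranks, with a two-sided p-value from the
#' t-distribution with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, at least 4 observations.
#' @return A list with `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Co-expression dendrogram of a gene set
#'
#' Pairwise Pearson correlation of the listed genes across samples,
#' agglomerative hierarchical clustering with distance `1 - r` and average
#' linkage, and each gene's top co-expression partner. Genes are processed
#' in lexicographic order so the result does not depend on input order.
#'
#' @param m An [expr_matrix()] over samples.
#' @param gene_list Genes to cluster (at least 3; all must be present).
#' @return A list (class `coexpr_dendrogram`) with `correlations` (gene x
#'   gene matrix), `tree` (an `hclust`), `leaf_order` (gene ids in dendrogram
#'   order), and `top_partner` (data.frame `gene`, `partner`, `r`).
#' @export
coexpression_dendrogram <- function(m, gene_list) {
  stopifnot(inherits(m, "expr_matrix"))
  gene_list <- sort(unique(as.character(gene_list)))
  if (length(gene_list) < 3L) stop("need at least 3 genes to cluster")
  missing <- setdiff(gene_list, gene_ids(m))
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ","))
  X <- t(m$values[gene_list, , drop = FALSE])
  R <- stats::cor(X)
  d <- stats::as.dist(1 - R)
  tree <- stats::hclust(d, method = "average")
  diag_na <- R; diag(diag_na) <- -Inf
  top_idx <- apply(diag_na, 1L, which.max)
  top <- data.frame(gene = gene_list,
                    partner = gene_list[top_idx],
                    r = diag_na[cbind(seq_along(gene_list), top_idx)],
                    row.names = NULL)
  structure(list(correlations = R, tree = tree,
                 leaf_order = gene_list[tree$order], top_partner = top),
            class = "coexpr_dendrogram")
}

#' ANOVA post-test for linear trend across ordered groups
#'
#' Tests for a linear trend in group means across `k` ordered groups using
#' equally spaced centered contrast scores \eqn{c_i = i - (k+1)/2}: the
#' contrast estimate is \eqn{L = \sum_i c_i \bar y_i}, its standard error
#' \eqn{\sqrt{\mathrm{MSE} \sum_i c_i^2 / n_i}} with the within-group mean
#' square from the one-way ANOVA, and \eqn{t = L / SE} on \eqn{N - k}
#' degrees of freedom (two-sided p). At `k = 2` this reduces exactly to
#' the pooled-variance two-sample t-test.
#'
#' @param values Numeric measurements.
#' @param group Ordinal group label per value. A factor's level order (or,
#'   for non-factors, the sorted unique values) defines the trend order —
#'   e.g. copy-number classes -1, 0, 1, 2.
#' @return A list (class `trend_test`) with `groups`, `n`, `means`,
#'   `contrast`, `estimate`, `se`, `statistic`, `df`, `p_value`.
#' @export
linear_trend_test <- function(values, group) {
  stopifnot(length(values) == length(group))
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]; group <- group[keep]
  f <- if (is.factor(group)) droplevels(group) else factor(group, levels = sort(unique(group)))
  k <- nlevels(f)
  if (k < 2L) stop("linear trend needs at least 2 groups")
  n_i <- as.integer(table(f))
  N <- length(values)
  if (N <= k) stop("need more observations than groups")
  means <- tapply(values, f, mean)
  ci <- seq_len(k) - (k + 1) / 2
  L <- sum(ci * means)
  sse <- sum(tapply(values, f, function(v) sum((v - mean(v))^2)))
  df <- N - k
  mse <- sse / df
  se <- sqrt(mse * sum(ci^2 / n_i))
  if (se == 0) {
    statistic <- if (L == 0) 0 else sign(L) * Inf
    p <- if (L == 0) 1 else 0
  } else {
    statistic <- L / se
    p <- 2 * stats::pt(-abs(statistic), df = df)
  }
  structure(list(groups = levels(f), n = n_i, means = as.numeric(means),
                 contrast = ci, estimate = L, se = se, statistic = statistic,
                 df = df, p_value = p),
            class = "trend_test")
}

#' @method print trend_test
#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("Linear trend across %d groups (%s): L = %.4g, t = %.3f, df = %d, p = %.3g\n",
              length(x$groups), paste(x$groups, collapse = " < "),
              x$estimate, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Per-sample expression ratio of two genes, optionally marker-normalized
#'
#' Computes `a / b` per sample (samples with `b = 0` are excluded and
#' counted) and, when a normalizer gene such as the proliferation marker
#' MKI67 is given, `(a / b) / normalizer` for samples where the normalizer
#' is also positive. Summaries (median, IQR) are reported per group.
#'
#' @param m An [expr_matrix()] over samples.
#' @param gene_a,gene_b Numerator and denominator gene ids.
#' @param normalizer Optional gene id to divide the ratio by.
#' @param group Optional group label per sample.
#' @return A list (class `ratio_result`) with `ratios` (data.frame
#'   `sample`, `ratio`, `group`), `n_excluded`, `normalized`,
#'   `normalizer`, and `summary` (per-group median and IQR).
#' @export
expression_ratio <- function(m, gene_a, gene_b, normalizer = NULL, group = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  need <- c(gene_a, gene_b, normalizer)
  missing <- setdiff(need, gene_ids(m))
  if (length(missing)) stop("gene(s) absent from matrix: ", paste(missing, collapse = ","))
  a <- m$values[gene_a, ]
  b <- m$values[gene_b, ]
  ok <- b > 0
  ratio <- rep(NA_real_, length(a))
  ratio[ok] <- a[ok] / b[ok]
  if (!is.null(normalizer)) {
    nv <- m$values[normalizer, ]
    ok <- ok & nv > 0
    ratio[!ok] <- NA_real_
    ratio[ok] <- (a[ok] / b[ok]) / nv[ok]
  }
  grp <- if (is.null(group)) rep("all", length(a)) else as.character(group)
  df <- data.frame(sample = cell_ids(m), ratio = ratio, group = grp,
                   row.names = NULL)
  kept <- df[!is.na(df$ratio), , drop = FALSE]
  summ <- do.call(rbind, lapply(split(kept$ratio, kept$group), function(v) {
    data.frame(n = length(v), median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)))
  }))
  summ <- cbind(group = rownames(summ), summ)
  rownames(summ) <- NULL
  structure(list(ratios = df, n_excluded = sum(!ok),
                 normalized = !is.null(normalizer),
                 normalizer = if (is.null(normalizer)) NA_character_ else normalizer,
                 summary = summ),
            class = "ratio_result")
}

#' Histogram table of a correlation distribution
#'
#' Bins the pairwise coefficients for plotting or export, mirroring the
#' genome-wide histogram with the query pair marked by its percentile.
#'
#' @param dist A [correlation_distribution()].
#' @param breaks Number of bins (default 40) over `[-1, 1]`.
#' @return data.frame with `bin_low`, `bin_high`, `count`.
#' @export
distribution_histogram <- function(dist, breaks = 40L) {
  stopifnot(inherits(dist, "correlation_distribution"))
  lo <- if (dist$absolute) 0 else -1
  br <- seq(lo, 1, length.out = breaks + 1L)
  h <- hist(pmin(pmax(dist$values, lo), 1), breaks = br, plot = FALSE)
  data.frame(bin_low = h$breaks[-length(h$breaks)],
             bin_high = h$breaks[-1L], count = h$counts)
}
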