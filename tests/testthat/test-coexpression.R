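test_that("pair correlations match the covariance formula and flag bad pairs", {
  set.seed(20)
  v <- matrix(rpois(200 * 100, 5), 200, 100,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("c%d", 1:100)))
  v["g003", ] <- v["g004", ]          # identical vectors
  v["g005", ] <- 7                    # constant gene
  m <- expr_matrix(v)
  pairs <- data.frame(minus_gene = sprintf("g%03d", seq(1, 99, 2)),
                      plus_gene = sprintf("g%03d", seq(2, 100, 2)))
  pairs <- rbind(pairs, data.frame(minus_gene = "g001", plus_gene = "absent"))
  cors <- suppressMessages(pair_correlations(m, pairs))

  expect_equal(cors$r[cors$minus_gene == "g003"], 1)
  expect_equal(cors$status[cors$minus_gene == "g005"], "zero_variance")
  expect_equal(cors$status[cors$plus_gene == "absent"], "missing_gene")

  # direct covariance/sd oracle
  for (i in which(cors$status == "ok")) {
    x <- v[cors$minus_gene[i], ]; y <- v[cors$plus_gene[i], ]
    r_oracle <- mean((x - mean(x)) * (y - mean(y))) / (sd(x) * sd(y)) *
      length(x) / (length(x) - 1)
    expect_equal(cors$r[i], r_oracle, tolerance = 1e-12)
  }
  expect_error(pair_correlations(m, pairs[0, ]), "empty")
})

test_that("Pearson r is invariant under positive affine transforms", {
  set.seed(21)
  v <- matrix(rpois(20 * 50, 4) + 0.0, 20, 50,
              dimnames = list(sprintf("g%d", 1:20), sprintf("c%d", 1:50)))
  pairs <- data.frame(minus_gene = sprintf("g%d", 1:10),
                      plus_gene = sprintf("g%d", 11:20))
  r0 <- pair_correlations(expr_matrix(v), pairs)$r
  v2 <- v; v2[1:10, ] <- 3.7 * v2[1:10, ] + 2.2
  r1 <- pair_correlations(expr_matrix(v2), pairs)$r
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("rank percentile counts ties upward and matches sort-and-count", {
  vals <- c(0.9, 0.5, 0.1, -0.2)
  expect_equal(rank_percentile(vals, 0.9), 25)
  expect_equal(rank_percentile(vals, -0.2), 100)

  set.seed(22)
  big <- runif(1000, -1, 1)
  qs <- sample(big, 100)
  for (q in qs[1:20]) {
    brute <- 100 * sum(sort(big, decreasing = TRUE) >= q) / length(big)
    expect_equal(rank_percentile(big, q), brute)
  }
  # monotone non-increasing in the query, bounded in (0, 100]
  grid <- sort(sample(big, 50))
  pct <- sapply(grid, rank_percentile, dist = big)
  expect_true(all(diff(pct) <= 0))
  expect_true(all(pct > 0 & pct <= 100))
})

test_that("query percentile flows from the distribution object", {
  cors <- data.frame(minus_gene = c("a", "c", "e"), plus_gene = c("b", "d", "f"),
                     r = c(0.8, 0.2, NA), n = c(10, 10, NA),
                     status = c("ok", "ok", "zero_variance"))
  d <- correlation_distribution(cors, query = c("a", "b"))
  expect_equal(d$n_pairs, 2L)
  expect_equal(d$query_percentile, 50)
  expect_error(correlation_distribution(cors, query = c("e", "f")), "zero_variance")
  expect_error(correlation_distribution(cors, query = c("x", "y")), "not in")
  h <- distribution_histogram(d)
  expect_equal(sum(h$count), 2L)
})

test_that("spearman matches rank-then-Pearson and cor.test", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman_correlation(x, x^3 + 2)$rho, 1)     # monotone map
  expect_equal(spearman_correlation(x, -x)$rho, -1)

  set.seed(23)
  for (i in 1:5) {
    a <- rnorm(20); b <- 0.5 * a + rnorm(20)
    got <- spearman_correlation(a, b)
    expect_equal(got$rho, cor(rank(a), rank(b)), tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(a, b, method = "spearman"))
    expect_equal(got$rho, unname(ct$estimate), tolerance = 1e-12)
  }
  expect_error(spearman_correlation(rep(1, 5), rnorm(5)), "constant")
  expect_error(spearman_correlation(1:3, 2:4), "at least 4")
})

test_that("dendrogram merges identical genes first and finds top partners", {
  set.seed(24)
  n <- 60
  a <- rnorm(n); c_ <- rnorm(n)
  v <- rbind(gA = a, gB = a, gC = c_) + 5
  v <- pmax(v, 0); colnames(v) <- sprintf("s%d", 1:n)
  m <- expr_matrix(v)
  res <- coexpression_dendrogram(m, c("gC", "gA", "gB"))
  expect_equal(res$tree$height[1], 0, tolerance = 1e-12)    # A,B merge at d=0
  tp <- res$top_partner
  expect_equal(tp$partner[tp$gene == "gA"], "gB")
  expect_error(coexpression_dendrogram(m, c("gA", "gB", "gZ")), "gZ")
})

test_that("linkage heights match a brute-force average-linkage recomputation", {
  set.seed(25)
  v <- matrix(rnorm(10 * 40, 5), 10, 40,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:40)))
  m <- expr_matrix(abs(v))
  res <- coexpression_dendrogram(m, rownames(v))
  D <- 1 - res$correlations
  expect_equal(res$tree$height, brute_force_upgma_heights(D), tolerance = 1e-10)
  # input order does not change the result
  res2 <- coexpression_dendrogram(m, rev(rownames(v)))
  expect_equal(res2$tree$height, res$tree$height)
  expect_equal(res2$leaf_order, res$leaf_order)
})

test_that("trend test reduces to the pooled t-test at k = 2", {
  set.seed(26)
  y <- c(rnorm(8, 1), rnorm(11, 2))
  g <- rep(c("low", "high"), c(8, 11))
  got <- linear_trend_test(y, factor(g, levels = c("low", "high")))
  tt <- t.test(y[g == "high"], y[g == "low"], var.equal = TRUE)
  expect_equal(abs(got$statistic), abs(unname(tt$statistic)), tolerance = 1e-10)
  expect_equal(got$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("symmetric group means give zero trend", {
  y <- c(3, 3, 5, 5, 3, 3) + 0
  g <- factor(rep(c("a", "b", "c"), each = 2), levels = c("a", "b", "c"))
  got <- linear_trend_test(y, g)
  expect_equal(got$estimate, 0)
  expect_equal(got$p_value, 1)
  expect_error(linear_trend_test(y, rep("a", 6)), "at least 2")
})

test_that("trend test matches a cell-means contrast oracle at k = 4", {
  set.seed(27)
  n_i <- c(5, 9, 7, 12)
  g <- factor(rep(1:4, n_i))
  y <- rnorm(sum(n_i), mean = as.integer(g) * 0.4)
  got <- linear_trend_test(y, g)

  # independent route: cell-means least squares + contrast with pooled MSE
  fit <- lm(y ~ 0 + g)
  ci <- 1:4 - (4 + 1) / 2
  L <- sum(ci * coef(fit))
  mse <- sum(residuals(fit)^2) / fit$df.residual
  se <- sqrt(mse * sum(ci^2 / n_i))
  tstat <- L / se
  p <- 2 * pt(-abs(tstat), df = fit$df.residual)
  expect_equal(got$estimate, L, tolerance = 1e-10)
  expect_equal(got$statistic, tstat, tolerance = 1e-10)
  expect_equal(got$p_value, p, tolerance = 1e-10)
  expect_equal(got$df, fit$df.residual)
  expect_equal(sum(got$contrast), 0)
})

test_that("expression ratios divide elementwise with exclusions counted", {
  v <- rbind(a = c(2, 4, 6, 0), b = c(1, 2, 0, 5), k = c(1, 1, 1, 1),
             n2 = c(2, 2, 2, 2))
  colnames(v) <- sprintf("s%d", 1:4)
  m <- expr_matrix(v)
  res <- expression_ratio(m, "a", "a")
  expect_equal(res$ratios$ratio[1:3], rep(1, 3))       # a/a = 1 where a > 0

  r2 <- expression_ratio(m, "a", "b")
  expect_equal(r2$ratios$ratio, c(2, 2, NA, 0))
  expect_equal(r2$n_excluded, 1L)

  # constant normalizer of 1 changes nothing
  r3 <- expression_ratio(m, "a", "b", normalizer = "k")
  expect_equal(r3$ratios$ratio, r2$ratios$ratio)
  r4 <- expression_ratio(m, "a", "b", normalizer = "n2")
  expect_equal(r4$ratios$ratio, r2$ratios$ratio / 2)

  set.seed(28)
  vv <- matrix(runif(3 * 30, 1, 5), 3, 30,
               dimnames = list(c("x", "y", "z"), sprintf("s%d", 1:30)))
  mm <- expr_matrix(vv)
  rr <- expression_ratio(mm, "x", "y", group = rep(c("g1", "g2"), 15))
  expect_equal(rr$ratios$ratio, unname(vv["x", ] / vv["y", ]))
  expect_equal(nrow(rr$summary), 2L)
  expect_error(expression_ratio(mm, "x", "nope"), "nope")
})
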