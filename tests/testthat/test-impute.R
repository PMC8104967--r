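as_log_layer <- function(m) { m$layer <- "cp10k_log"; m }

test_that("genes with no mass near zero get lambda ~ 0 and no dropouts", {
  set.seed(10)
  v <- matrix(abs(rnorm(3 * 60, 5, 0.1)), 3, 60,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:60)))
  m <- as_log_layer(toy_expr(v))
  fit <- suppressWarnings(fit_dropout_model(m))
  expect_true(all(fit$params$lambda < 0.01))
  expect_true(all(fit$dropout_prob < 0.01))
})

test_that("constant genes are flagged and never imputed", {
  v <- rbind(g1 = rep(2, 30), g2 = c(rep(0, 12), abs(rnorm(18, 4, 0.5))))
  colnames(v) <- paste0("c", 1:30)
  m <- as_log_layer(expr_matrix(v))
  fit <- suppressWarnings(fit_dropout_model(m))
  expect_true(fit$params$constant[1])
  expect_equal(unname(fit$dropout_prob["g1", ]), rep(0, 30))
  imp <- suppressMessages(impute_matrix(m, fit, k_neighbors = 5))
  expect_identical(imp$values["g1", ], m$values["g1", ])
})

test_that("zeros of an expressed gene are recognized as dropouts", {
  set.seed(11)
  v <- matrix(abs(rnorm(20 * 100, 4, 0.7)), 20, 100)
  drop <- matrix(runif(2000) < 0.3, 20, 100)
  v[drop] <- 0
  m <- as_log_layer(toy_expr(v))
  fit <- suppressWarnings(fit_dropout_model(m))
  expect_true(all(fit$dropout_prob[drop] > 0.9))
  expect_true(all(fit$dropout_prob[!drop] < 0.1))
})

test_that("EM recovers known gamma-normal mixture parameters", {
  truth <- c(lambda = 0.4, mu = 4, sigma = 0.8)
  ests <- t(sapply(1:8, function(s) {
    set.seed(s)
    n <- 2000L
    z <- runif(n) < truth["lambda"]
    x <- ifelse(z, rgamma(n, shape = 1.5, rate = 3), rnorm(n, 4, 0.8))
    x <- pmax(x, 0)
    m <- as_log_layer(toy_expr(matrix(x, 1, n)))
    fit <- suppressWarnings(fit_dropout_model(m))
    c(fit$params$lambda, fit$params$mu, fit$params$sigma)
  }))
  est_mean <- colMeans(ests)
  mc_se <- apply(ests, 2L, sd) / sqrt(nrow(ests))
  expect_true(all(abs(est_mean - truth) <= 3 * mc_se + 0.02))
})

test_that("compiled EM matches the R reference implementation exactly", {
  set.seed(12)
  v <- matrix(abs(c(rgamma(300, 1.5, 3), rnorm(300, 4, 0.8))), 20, 30)
  m <- as_log_layer(toy_expr(v))
  fit <- suppressWarnings(fit_dropout_model(m))
  init <- bdgcoex:::.mix_init(m$values)
  ref <- bdgcoex:::.mix_em(m$values, init, max_iter = 100, tol = 1e-6,
                           eps = fit$eps)
  gm <- ref$shape / ref$rate
  keep <- ref$lambda >= 1e-4 & gm < ref$mu - 2 * ref$sigma & gm < 0.5 * ref$mu
  expect_equal(fit$params$lambda[keep], unname(ref$lambda[keep]), tolerance = 1e-12)
  expect_equal(fit$params$mu, unname(ref$mu), tolerance = 1e-12)
  expect_equal(fit$params$sigma, unname(ref$sigma), tolerance = 1e-12)
})

test_that("imputation is monotone-safe and respects threshold boundaries", {
  set.seed(13)
  cfg <- simulation_config(n_genes = 60, n_cells = 80, n_bdg_pairs = 20, seed = 13)
  sim <- simulate_counts(cfg)
  norm <- normalize_cp10k_log(sim$matrix)
  fit <- suppressWarnings(fit_dropout_model(norm))

  imp <- suppressMessages(impute_matrix(norm, fit, k_neighbors = 10))
  conf <- fit$dropout_prob <= 0.5
  expect_identical(imp$values[conf], norm$values[conf])  # confident untouched
  expect_true(all(imp$values >= 0))

  # clamp: nothing exceeds 1.5x the gene's max confident value
  max_conf <- apply(ifelse(conf, norm$values, -Inf), 1L, max)
  changed <- imp$values != norm$values
  idx <- which(changed, arr.ind = TRUE)
  if (nrow(idx))
    expect_true(all(imp$values[idx] <= 1.5 * max_conf[idx[, 1]] + 1e-12))

  # t = 1: nothing exceeds the threshold, output identical
  imp1 <- impute_matrix(norm, fit, threshold = 1, k_neighbors = 10)
  expect_identical(imp1$values, norm$values)

  # no zeros and lambda ~ 0 everywhere: identity
  v <- matrix(abs(rnorm(10 * 40, 5, 0.2)), 10, 40)
  m5 <- as_log_layer(toy_expr(v))
  f5 <- suppressWarnings(fit_dropout_model(m5))
  expect_identical(impute_matrix(m5, f5, k_neighbors = 8)$values, m5$values)

  expect_error(impute_matrix(norm, fit, k_neighbors = 1000), "smaller")
  expect_error(impute_matrix(norm, fit, threshold = 1.2), "\\[0,1\\]")
  expect_error(fit_dropout_model(as_log_layer(toy_expr(matrix(1:8, 2, 4)))),
               "at least 10 cells")
})

test_that("imputation lowers masked-entry error and correlation attenuation", {
  rmse_obs <- rmse_imp <- att_obs <- att_imp <- numeric(0)
  for (s in 1:6) {
    cfg <- simulation_config(n_genes = 160, n_cells = 250, n_bdg_pairs = 60,
                             planted_pairs = data.frame(pair = 1:3, rho = 0.8),
                             seed = 100 + s)
    sim <- simulate_counts(cfg)
    norm <- normalize_cp10k_log(sim$matrix)
    fit <- suppressWarnings(fit_dropout_model(norm))
    imp <- suppressMessages(impute_matrix(norm, fit))

    mask <- sim$truth$mask
    truth_log <- log1p(sim$truth$pre_dropout)
    imp_counts <- denormalize_cp10k_log(imp)
    rmse_obs <- c(rmse_obs, sqrt(mean((log1p(sim$matrix$values[mask]) - truth_log[mask])^2)))
    rmse_imp <- c(rmse_imp, sqrt(mean((log1p(imp_counts$values[mask]) - truth_log[mask])^2)))

    pl <- sim$truth$pairs[1:3, ]
    for (i in 1:3) {
      r0 <- cor(norm$values[pl$minus_gene[i], ], norm$values[pl$plus_gene[i], ])
      r1 <- cor(imp$values[pl$minus_gene[i], ], imp$values[pl$plus_gene[i], ])
      att_obs <- c(att_obs, abs(r0 - pl$rho[i]))
      att_imp <- c(att_imp, abs(r1 - pl$rho[i]))
    }
  }
  expect_lt(mean(rmse_imp), mean(rmse_obs))
  expect_lt(mean(att_imp), mean(att_obs))
})
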