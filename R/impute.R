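#' Fit a per-gene gamma-normal dropout mixture
#'
#' Models each gene's normalized expression across cells as a two-component
#' mixture: a gamma component capturing dropout (technical zeros and
#' near-zero values) and a normal component capturing genuine expression,
#' \deqn{f(x) = \lambda \, \mathrm{Gamma}(x;\alpha,\beta) +
#'   (1-\lambda) \, \mathcal{N}(x;\mu,\sigma).}
#' The posterior probability that an entry belongs to the gamma component
#' is its dropout probability.
#'
#' Fitting is by EM, vectorized across genes. Initialization: \eqn{\lambda}
#' is the fraction of entries below the gene median, gamma moments come
#' from the lower half and normal moments from the upper half. A gene whose
#' fitted dropout component does not sit clearly below its expressed
#' component (gamma mean under both \eqn{\mu - 2\sigma} and \eqn{\mu/2})
#' carries no evidence of dropout and is
#' assigned \eqn{\lambda = 0}; constant genes are flagged and get dropout
#' probability 0 everywhere.
#'
#' @param m An [expr_matrix()] with `layer = "cp10k_log"` and at least 10
#'   cells.
#' @param max_iter Maximum EM iterations per gene (default 100).
#' @param tol Stop a gene when its log-likelihood gain drops below this
#'   (default 1e-6).
#' @param seed Reserved for neighbor subsampling on very large matrices;
#'   the fit itself is deterministic and ignores it.
#' @return An object of class `dropout_model`: a list with `params` (a
#'   data.frame of per-gene `lambda`, `shape`, `rate`, `mu`, `sigma`,
#'   `converged`, `constant`) and `dropout_prob` (a genes-by-cells matrix
#'   in `[0, 1]`).
#' @export
fit_dropout_model <- function(m, max_iter = 100L, tol = 1e-6, seed = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$layer != "cp10k_log")
    stop("fit_dropout_model expects layer cp10k_log, got ", m$layer)
  X <- m$values
  G <- nrow(X); C <- ncol(X)
  if (C < 10L) stop("need at least 10 cells to fit the dropout model, got ", C)

  # zeros are a point mass on this scale; evaluate them half-way below the
  # smallest positive value so the dropout component can sit on them
  pos <- X[X > 0]
  eps <- if (length(pos)) max(min(pos) / 2, 1e-4) else 1e-4
  row_var <- rowVars_(X)
  constant <- row_var <= 0
  modeled <- which(!constant)

  lambda <- numeric(G); shape <- rep(1, G); rate <- rep(1, G)
  mu <- rowMeans(X); sigma <- rep(1, G); converged <- rep(NA, G)
  P <- matrix(0, G, C, dimnames = dimnames(X))

  if (length(modeled)) {
    Xm <- X[modeled, , drop = FALSE]
    init <- .mix_init(Xm)
    fit <- .mix_em_cpp(Xm, init$lambda, init$shape, init$rate, init$mu,
                       init$sigma, as.integer(max_iter), tol, eps)

    # identifiability guard: the dropout component must lie below the
    # expressed component's lower tail, otherwise the fit has merely split
    # a unimodal gene in two and there is no dropout support
    gam_mean <- fit$shape / fit$rate
    no_drop <- !(gam_mean < fit$mu - 2 * fit$sigma &
                 gam_mean < 0.5 * fit$mu) | fit$lambda < 1e-4
    fit$lambda[no_drop] <- 0

    lambda[modeled] <- fit$lambda
    shape[modeled] <- fit$shape; rate[modeled] <- fit$rate
    mu[modeled] <- fit$mu; sigma[modeled] <- fit$sigma
    converged[modeled] <- fit$converged
    if (any(!fit$converged))
      warning(sprintf("%d gene(s) hit max_iter before convergence; last iterate kept",
                      sum(!fit$converged)))
    P[modeled, ] <- .mix_posterior(Xm, fit$lambda, fit$shape, fit$rate,
                                   fit$mu, fit$sigma, eps)
  }

  structure(list(
    params = data.frame(gene_id = rownames(X), lambda = lambda, shape = shape,
                        rate = rate, mu = mu, sigma = sigma,
                        converged = converged, constant = constant,
                        row.names = NULL),
    dropout_prob = P,
    layer = m$layer,
    eps = eps
  ), class = "dropout_model")
}

#' @method print dropout_model
#' @export
print.dropout_model <- function(x, ...) {
  cat(sprintf("<dropout_model> %d genes x %d cells; %d constant; mean lambda %.3f\n",
              nrow(x$dropout_prob), ncol(x$dropout_prob),
              sum(x$params$constant), mean(x$params$lambda)))
  invisible(x)
}

rowVars_ <- function(X) {
  mu <- rowMeans(X)
  rowMeans(X * X) - mu * mu
}

.mix_init <- function(X) {
  n <- ncol(X)
  med <- apply(X, 1L, stats::median)
  below <- X < med
  n_below <- rowSums(below)
  lam <- pmin(pmax(n_below / n, 0.05), 0.95)

  sum_lo <- rowSums(X * below); m_lo <- ifelse(n_below > 0, sum_lo / pmax(n_below, 1L), 0)
  v_lo <- rowSums((X - m_lo)^2 * below) / pmax(n_below - 1L, 1L)
  m_lo <- pmax(m_lo, 1e-3); v_lo <- pmax(v_lo, 1e-6)
  shape <- pmin(pmax(m_lo^2 / v_lo, 1e-2), 1e3)
  rate <- pmin(pmax(m_lo / v_lo, 1e-4), 1e4)

  above <- !below
  n_ab <- rowSums(above)
  m_hi <- rowSums(X * above) / pmax(n_ab, 1L)
  s_hi <- sqrt(rowSums((X - m_hi)^2 * above) / pmax(n_ab - 1L, 1L))
  s_hi <- pmax(s_hi, 1e-3)
  list(lambda = lam, shape = shape, rate = rate, mu = m_hi, sigma = s_hi)
}

# component densities, hand-rolled on the log scale for speed: gene-wise
# parameter vectors (length nrow) recycle down the column-major matrices
.mix_densities <- function(X, Xc, logXc, shape, rate, mu, sigma) {
  cg <- shape * log(rate) - lgamma(shape)
  fg <- exp((shape - 1) * logXc - rate * Xc + cg)
  fn <- exp(-0.5 * ((X - mu) / sigma)^2) / (sigma * sqrt(2 * pi))
  list(fg = fg, fn = fn)
}

.mix_posterior <- function(X, lambda, shape, rate, mu, sigma, eps) {
  Xc <- pmax(X, eps)
  d <- .mix_densities(X, Xc, log(Xc), shape, rate, mu, sigma)
  num <- lambda * d$fg
  den <- num + (1 - lambda) * d$fn
  P <- num / pmax(den, 1e-300)
  P[lambda == 0, ] <- 0
  dimnames(P) <- dimnames(X)
  P
}

# EM for the gamma-normal mixture, vectorized across gene rows with an
# active set so converged genes stop being updated.
.mix_em <- function(X, par, max_iter, tol, eps = 1e-4) {
  G <- nrow(X); C <- ncol(X)
  lambda <- par$lambda; shape <- par$shape; rate <- par$rate
  mu <- par$mu; sigma <- par$sigma
  converged <- rep(FALSE, G)
  ll_old <- rep(-Inf, G)
  active <- seq_len(G)
  XcF <- pmax(X, eps)
  logXcF <- log(XcF)

  for (it in seq_len(max_iter)) {
    Xa <- X[active, , drop = FALSE]
    Xca <- XcF[active, , drop = FALSE]
    logXca <- logXcF[active, , drop = FALSE]
    d <- .mix_densities(Xa, Xca, logXca, shape[active], rate[active],
                        mu[active], sigma[active])
    num <- lambda[active] * d$fg
    den <- num + (1 - lambda[active]) * d$fn
    den <- pmax(den, 1e-300)
    gam <- num / den
    ll <- rowSums(log(den))

    # M-step
    lam_new <- pmin(pmax(rowMeans(gam), 1e-6), 1 - 1e-6)
    w <- 1 - gam
    sw <- pmax(rowSums(w), 1e-8)
    mu_new <- rowSums(w * Xa) / sw
    sig_new <- pmax(sqrt(rowSums(w * (Xa - mu_new)^2) / sw), 1e-3)

    T1 <- pmax(rowSums(gam), 1e-8)
    T2 <- pmax(rowSums(gam * Xca), 1e-12)
    T3 <- rowSums(gam * logXca)
    s <- pmax(log(T2 / T1) - T3 / T1, 1e-8)
    a <- shape[active]
    for (nw in 1:3) { # Newton on the gamma shape score equation
      a <- a - (log(a) - digamma(a) - s) / (1 / a - trigamma(a))
      a <- pmin(pmax(a, 1e-3), 1e4)
    }
    shape_new <- a
    rate_new <- pmin(pmax(shape_new * T1 / T2, 1e-6), 1e8)

    lambda[active] <- lam_new; mu[active] <- mu_new; sigma[active] <- sig_new
    shape[active] <- shape_new; rate[active] <- rate_new

    done <- (ll - ll_old[active]) < tol & is.finite(ll_old[active])
    ll_old[active] <- ll
    converged[active[done]] <- TRUE
    active <- active[!done]
    if (!length(active)) break
  }
  list(lambda = lambda, shape = shape, rate = rate, mu = mu, sigma = sigma,
       converged = converged)
}

#' Impute dropout entries by similarity-weighted neighbor averaging
#'
#' Entries whose dropout probability exceeds `threshold` are replaced by a
#' weighted mean of the same gene in the cell's `k_neighbors` most similar
#' cells. Cell-cell similarity is the Pearson correlation computed only
#' over genes confidently expressed (dropout probability at or below the
#' threshold) in both cells; weights are `max(similarity, 0)`,
#' renormalized, and only neighbors in which the gene itself is confident
#' contribute. Entries with no usable neighbor are left unchanged, as are
#' all confident entries (bit-identical pre/post). Imputed values are
#' clamped at 1.5 times the gene's largest confident value to prevent
#' outlier blowup.
#'
#' @param m The [expr_matrix()] the model was fitted on (same layer).
#' @param model A [fit_dropout_model()] result matching `m`'s dimensions.
#' @param threshold Dropout-probability cutoff in `[0, 1]` (default 0.5).
#' @param k_neighbors Number of neighbor cells (default 20; must be smaller
#'   than the number of cells).
#' @return An [expr_matrix()] with `layer = "imputed"`; any `lib_size`
#'   attribute on `m` is carried over so count-scale back-transformation
#'   remains possible.
#' @export
impute_matrix <- function(m, model, threshold = 0.5, k_neighbors = 20L) {
  stopifnot(inherits(m, "expr_matrix"), inherits(model, "dropout_model"))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0,1]")
  X <- m$values
  if (!identical(dim(model$dropout_prob), dim(X)))
    stop("model dimensions do not match the matrix")
  C <- ncol(X)
  if (k_neighbors >= C) stop("k_neighbors must be smaller than the number of cells")

  P <- model$dropout_prob
  out <- X
  drop_mask <- P > threshold
  if (any(drop_mask)) {
    conf <- !drop_mask
    sim <- .masked_cell_cor(X, conf)
    diag(sim) <- NA_real_

    max_conf <- suppressWarnings(apply(ifelse(conf, X, -Inf), 1L, max))
    cap <- 1.5 * max_conf

    n_unfilled <- 0L
    storage.mode(conf) <- "double"
    for (cc in seq_len(C)) {
      rows <- which(drop_mask[, cc])
      if (!length(rows)) next
      s <- sim[, cc]
      ord <- order(-s, seq_along(s), na.last = TRUE)
      nb <- ord[seq_len(k_neighbors)]
      w <- pmax(s[nb], 0)
      w[is.na(w)] <- 0
      if (sum(w) == 0) { n_unfilled <- n_unfilled + length(rows); next }
      Xn <- X[rows, nb, drop = FALSE]
      Cn <- conf[rows, nb, drop = FALSE]
      den <- drop(Cn %*% w)
      num <- drop((Xn * Cn) %*% w)
      ok <- den > 0
      vals <- num[ok] / den[ok]
      vals <- pmin(vals, cap[rows[ok]])
      out[rows[ok], cc] <- vals
      n_unfilled <- n_unfilled + sum(!ok)
    }
    if (n_unfilled > 0)
      message(sprintf("%d dropout entr(ies) had no usable neighbor and were left unchanged",
                      n_unfilled))
  }
  res <- expr_matrix(out, layer = "imputed")
  attr(res, "lib_size") <- attr(m, "lib_size")
  res
}

# Pearson correlation between cells over genes confident in both, computed
# with masked cross-products (exact, no per-pair loops).
.masked_cell_cor <- function(X, conf) {
  W <- conf; storage.mode(W) <- "double"
  Xw <- X * W
  n <- crossprod(W)
  Sx <- crossprod(Xw, W)       # Sx[a,b] = sum_g x_ga over joint mask
  Sxy <- crossprod(Xw)
  Sxx <- crossprod(Xw * Xw, W)
  Sy <- t(Sx); Syy <- t(Sxx)
  cov <- Sxy - Sx * Sy / pmax(n, 1)
  vx <- Sxx - Sx * Sx / pmax(n, 1)
  vy <- Syy - Sy * Sy / pmax(n, 1)
  r <- cov / sqrt(pmax(vx, 0) * pmax(vy, 0))
  r[n < 3 | vx <= 0 | vy <= 0] <- NA_real_
  r
}

#' Write fitted mixture parameters to TSV
#'
#' @param model A [fit_dropout_model()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dropout_model <- function(model, path) {
  fwrite(as.data.table(model$params), path, sep = "\t")
  invisible(path)
}
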