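# Independent oracles and small fixture builders used across the suite.

# classic weighted averaging with inverse linear deshrinking: fitted values
wa_inverse_oracle <- function(Y, x) {
  opt <- colSums(Y * x) / colSums(Y)
  init <- drop(Y %*% opt) / rowSums(Y)
  unname(fitted(stats::lm(x ~ init)))
}

# same, as a leave-one-out predictor (fully independent of the package LOO)
wa_inverse_loo_oracle <- function(Y, x) {
  n <- nrow(Y)
  vapply(seq_len(n), function(i) {
    Yt <- Y[-i, , drop = FALSE]
    keep <- colSums(Yt) > 0
    Yt <- Yt[, keep, drop = FALSE]
    opt <- colSums(Yt * x[-i]) / colSums(Yt)
    init <- drop(Yt %*% opt) / rowSums(Yt)
    co <- stats::coef(stats::lm(x[-i] ~ init))
    init_new <- sum(Y[i, keep] * opt) / sum(Y[i, keep])
    unname(co[1] + co[2] * init_new)
  }, numeric(1))
}

# brute-force squared-chord k-nearest analogue prediction (self excluded)
analogue_loo_oracle <- function(Y, x, k) {
  P <- sqrt(Y / rowSums(Y))
  n <- nrow(Y)
  vapply(seq_len(n), function(i) {
    d <- rowSums(sweep(P, 2, P[i, ])^2)
    d[i] <- Inf
    mean(x[order(d)[seq_len(k)]])
  }, numeric(1))
}

# hand-written Gaussian LDA with pooled covariance and given priors:
# returns posterior matrix for new points
lda_posterior_oracle <- function(scores, groups, prior, new_scores) {
  lev <- sort(unique(groups))
  mu <- t(vapply(lev, function(g)
    colMeans(scores[groups == g, , drop = FALSE]),
    numeric(ncol(scores))))
  S <- matrix(0, ncol(scores), ncol(scores))
  for (g in lev) {
    Xg <- scale(scores[groups == g, , drop = FALSE], center = TRUE,
                scale = FALSE)
    S <- S + crossprod(Xg)
  }
  S <- S / (nrow(scores) - length(lev))
  Sinv <- solve(S)
  logd <- vapply(seq_along(lev), function(j) {
    dif <- sweep(new_scores, 2, mu[j, ])
    -0.5 * rowSums((dif %*% Sinv) * dif) + log(prior[j])
  }, numeric(nrow(new_scores)))
  logd <- matrix(logd, nrow = nrow(new_scores))
  post <- exp(logd - apply(logd, 1, max))
  post / rowSums(post)
}

# dense-grid + fine local search oracle for a single breakpoint
breakpoint_oracle <- function(x, y, res = 0.01) {
  cand <- seq(min(x) + res, max(x) - res, by = res)
  rss <- vapply(cand, function(b) {
    X <- cbind(1, x, pmax(x - b, 0))
    sum(stats::.lm.fit(X, y)$residuals^2)
  }, numeric(1))
  cand[which.min(rss)]
}

# small Gaussian-response training set (noiseless taxa tracking x)
toy_training <- function(n = 50, m = 10, seed = 42, xlim = c(0, 20)) {
  set.seed(seed)
  x <- stats::runif(n, xlim[1], xlim[2])
  opt <- stats::runif(m, xlim[1], xlim[2])
  Y <- exp(-0.5 * outer(x, opt, "-")^2 / (0.2 * diff(xlim))^2) *
    matrix(stats::runif(n * m, 0.5, 1.5), n, m)
  Y <- 100 * Y / rowSums(Y)
  dimnames(Y) <- list(paste0("s", seq_len(n)), paste0("t", seq_len(m)))
  list(Y = Y, x = x)
}

# reduced synthetic modern dataset (percentages) for fast tests
small_modern <- function(n = 300, seed = 7, ...) {
  cfg <- synthetic_config(n_modern = n, seed = seed, ...)
  gm <- generate_modern(cfg)
  ds <- gm$dataset
  ds$pollen <- to_percentages(ds$pollen)
  list(ds = modern_dataset(ds$pollen, ds$meta), truth = gm$truth,
       cfg = cfg)
}

# write a pollen matrix to a temp file and return the path
tmp_table <- function(df, sep = "\t") {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = sep, quote = FALSE, row.names = FALSE)
  f
}
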