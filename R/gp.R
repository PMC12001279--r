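# Gaussian-process surrogate (Matern 5/2, isotropic lengthscale chosen by
# marginal likelihood on a small grid) used by bayes_optimize(). Inputs are
# assumed scaled to the unit cube.

matern52 <- function(D, l) {
  r <- sqrt(5) * D / l
  (1 + r + r^2 / 3) * exp(-r)
}

gp_fit <- function(X, y, nugget = 1e-6) {
  X <- as.matrix(X)
  mu <- mean(y); sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy <= 0) sdy <- 1
  ys <- (y - mu) / sdy
  D <- as.matrix(stats::dist(X))
  best <- NULL
  for (l in c(0.05, 0.1, 0.2, 0.35, 0.6, 1, 2)) {
    K <- matern52(D, l)
    diag(K) <- diag(K) + nugget
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, backsolve(ch, ys, transpose = TRUE))
    # log marginal likelihood up to constants
    lml <- -0.5 * sum(ys * alpha) - sum(log(diag(ch)))
    if (is.null(best) || lml > best$lml)
      best <- list(l = l, ch = ch, alpha = alpha, lml = lml)
  }
  if (is.null(best)) stop("GP fit failed (singular kernel)")
  list(X = X, mu = mu, sdy = sdy, l = best$l, ch = best$ch,
       alpha = best$alpha, nugget = nugget)
}

gp_predict <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  # cross-covariances
  n <- nrow(fit$X); m <- nrow(Xnew)
  D <- sqrt(pmax(outer(rowSums(Xnew^2), rowSums(fit$X^2), "+") -
                 2 * Xnew %*% t(fit$X), 0))
  Ks <- matern52(D, fit$l)
  mean_s <- as.vector(Ks %*% fit$alpha)
  v <- backsolve(fit$ch, t(Ks), transpose = TRUE)
  var_s <- pmax(1 + fit$nugget - colSums(v^2), 1e-12)
  list(mean = fit$mu + fit$sdy * mean_s, sd = fit$sdy * sqrt(var_s))
}

expected_improvement <- function(mu, sd, best) {
  z <- (best - mu) / sd
  (best - mu) * stats::pnorm(z) + sd * stats::dnorm(z)
}
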