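# Multinomial log-linear model (softmax regression) fitted by BFGS on the
# penalized negative log-likelihood. Symmetric (one coefficient vector per
# class) parametrization; the small quadratic decay both identifies the
# parameters and matches the weight-decay habit of neural-network style
# multinomial fitters.

multinom_fit <- function(X, y, decay = 1e-4, maxit = 3000L) {
  y <- factor(y)
  K <- nlevels(y)
  n <- nrow(X)
  X1 <- cbind(`(Intercept)` = 1, X)
  p1 <- ncol(X1)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1

  nll <- function(b) {
    B <- matrix(b, p1, K)
    eta <- X1 %*% B
    eta <- eta - apply(eta, 1L, max)
    lse <- log(rowSums(exp(eta)))
    -sum(eta[Y == 1] - lse) + decay * sum(B[-1, ]^2)
  }
  grad <- function(b) {
    B <- matrix(b, p1, K)
    eta <- X1 %*% B
    eta <- eta - apply(eta, 1L, max)
    P <- exp(eta) / rowSums(exp(eta))
    G <- t(X1) %*% (P - Y)
    G[-1, ] <- G[-1, ] + 2 * decay * B[-1, ]
    as.vector(G)
  }
  opt <- stats::optim(rep(0, p1 * K), nll, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  if (opt$convergence != 0L) {
    stop("pd_no_convergence: multinomial fit did not converge (code ",
         opt$convergence, ", value ", signif(opt$value, 6), ")")
  }
  B <- matrix(opt$par, p1, K,
              dimnames = list(colnames(X1), levels(y)))
  structure(list(coefficients = B, levels = levels(y), decay = decay,
                 value = opt$value),
            class = "pd_multinom")
}

predict_multinom <- function(fit, X) {
  eta <- cbind(1, X) %*% fit$coefficients
  fit$levels[max.col(eta, ties.method = "first")]
}
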