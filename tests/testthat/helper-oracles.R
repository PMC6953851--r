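# Independent oracles, kept free of the implementation paths they check.

# MPN: direct maximization of the log-likelihood on a log-density scale
# (vs the score-equation root finding in the package).
mpnLogLik <- function(lambda, m, n, g) {
  sum(g * log1p(-exp(-lambda * m))) - sum((n - g) * lambda * m)
}
mpnByGridSearch <- function(m, n, g) {
  ll <- function(x) mpnLogLik(exp(x), m, n, g)
  exp(optimize(ll, c(log(1e-2), log(1e9)), maximum = TRUE, tol = 1e-12)$maximum)
}

# Scott-Knott: exhaustive evaluation of every ordered split point with
# the lambda statistic, recursing on accepted halves.
skOracle <- function(means, mse, r, nu, alpha = 0.05) {
  means <- sort(means, decreasing = TRUE)
  s2 <- mse / r
  groups <- integer(length(means))
  counter <- 0L
  rec <- function(idx) {
    k <- length(idx)
    m <- as.numeric(means[idx])
    if (k >= 2) {
      b0 <- vapply(seq_len(k - 1), function(i) {
        sum(m[1:i])^2 / i + sum(m[-(1:i)])^2 / (k - i) - sum(m)^2 / k
      }, numeric(1))
      i_star <- which.max(b0)
      sig0 <- (sum((m - mean(m))^2) + nu * s2) / (k + nu)
      lam <- if (sig0 > 0) pi / (2 * (pi - 2)) * max(b0) / sig0 else Inf
      if (max(b0) > 1e-12 && lam > qchisq(1 - alpha, df = k / (pi - 2))) {
        rec(idx[1:i_star])
        rec(idx[(i_star + 1):k])
        return(invisible())
      }
    }
    counter <<- counter + 1L
    groups[idx] <<- counter
    invisible()
  }
  rec(seq_along(means))
  setNames(groups, names(means))
}

# Minimal stand-in for oneWayAnova() output, for driving scottKnott()
# with exactly specified means / MSE / design.
dzAnovaStub <- function(means, mse, r, nu) {
  structure(list(k = length(means), r = r, balanced = TRUE, F = NA_real_,
                 mse = mse, df_error = nu,
                 means = means[order(names(means))],
                 n_per_group = rep(r, length(means)), response = "rdw"),
            class = "dzAnova")
}
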