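# Independent oracles used across the suite. These deliberately avoid the
# package's production code paths (modal sums, closed antiderivatives) so
# that agreement is a genuine cross-check.

# Dense finite-difference solve of the stationary splitting-probability BVP
# u'' = Da u, u(1) = 1, u'(0) = pi_surf u(0), averaged over the deposit.
bvp_abs_oracle <- function(Da, pi_surf, beta, n = 4001) {
  dxx <- 1 / (n - 1)
  x <- seq(0, 1, length.out = n)
  m <- n - 1L                                 # unknowns: nodes 1..n-1; u_n = 1
  diag_ <- rep(-2 / dxx^2 - Da, m)
  lower <- rep(1 / dxx^2, m)                  # lower[i] multiplies u_{i-1}
  upper <- rep(1 / dxx^2, m)                  # upper[i] multiplies u_{i+1}
  diag_[1] <- -2 / dxx^2 - Da - 2 * pi_surf / dxx   # ghost-node Robin
  upper[1] <- 2 / dxx^2
  b <- numeric(m)
  b[m] <- -1 / dxx^2                          # Dirichlet u(1) = 1
  # Thomas algorithm
  for (i in 2:m) {
    w <- lower[i] / diag_[i - 1]
    diag_[i] <- diag_[i] - w * upper[i - 1]
    b[i] <- b[i] - w * b[i - 1]
  }
  u <- numeric(m)
  u[m] <- b[m] / diag_[m]
  for (i in (m - 1):1) u[i] <- (b[i] - upper[i] * u[i + 1]) / diag_[i]
  u <- c(u, 1)
  idx <- which(x <= beta + 1e-12)
  xi <- x[idx]; ui <- u[idx]
  sum((ui[-1] + ui[-length(ui)]) / 2 * diff(xi)) / beta
}

# Projection coefficient of the deposit onto mode k by numerical quadrature.
projection_oracle <- function(lambda_k, beta) {
  num <- stats::integrate(function(x) (1 / beta) * sin(lambda_k * (1 - x)),
                          0, beta, rel.tol = 1e-12)$value
  den <- stats::integrate(function(x) sin(lambda_k * (1 - x))^2,
                          0, 1, rel.tol = 1e-12)$value
  num / den
}

expect_increasing <- function(x, strictly = TRUE) {
  d <- diff(x)
  if (strictly) expect_true(all(d > 0)) else expect_true(all(d >= 0))
}
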