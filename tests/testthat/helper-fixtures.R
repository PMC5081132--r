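# shared fixtures, built in code at test time

# two well-separated spherical Gaussian clusters; trivially separable
separableXY <- function(n = 20, p = 3, gap = 10, seed = 99) {
  set.seed(seed)
  n1 <- n %/% 2
  X <- matrix(rnorm(n * p), n, p)
  X[(n1 + 1):n, ] <- X[(n1 + 1):n, ] + gap
  y <- factor(rep(c("G1", "G2"), c(n1, n - n1)), levels = c("G1", "G2"))
  list(X = X, y = y)
}

# independent numerical-integration oracle for the truncated-normal mean:
# integrates delta * f(delta | delta >= alpha) directly from the density
truncMeanByIntegration <- function(alpha, tau) {
  dens <- function(d) (1 / tau) * dnorm(d / tau) / (1 - pnorm(alpha / tau))
  stats::integrate(function(d) d * dens(d), alpha, Inf, rel.tol = 1e-10)$value
}

# near-noiseless simulation config (sigma ~ 0 within validity bounds)
noiselessConfig <- function(n, p, thetaMin = 2, seed = 1) {
  SimConfig(n = n, p = p, sigmaB = 1e-8, sigmaE = 1e-8, r = 1,
            thetaMin = thetaMin, corrKind = "independent", seed = seed)
}

writeFixtureTSV <- function(df, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}
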