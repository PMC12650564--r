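# Independent oracles shared by the unit and acceptance suites.

# RR-BLUP oracle: ridge-regression marker effects with the GBLUP-equivalent
# penalty lambda = sigma_e2 / (sigma_a2 / sum(2pq)), plus a GLS intercept.
# Deliberately written against the marker-effect parameterization so it
# shares no code path with solve_mme().
rrblup_oracle <- function(g, y, obs, vc) {
  M <- g$values
  storage.mode(M) <- "double"
  p <- colMeans(M) / 2
  W <- sweep(M, 2, 2 * p)
  s2pq <- sum(2 * p * (1 - p))
  Wo <- W[obs, , drop = FALSE]
  V <- tcrossprod(Wo) * vc$sigma_a2 / s2pq +
    diag(vc$sigma_e2, length(obs))
  Vi <- solve(V)
  X <- matrix(1, length(obs))
  b <- drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y[obs]))
  lambda <- vc$sigma_e2 / (vc$sigma_a2 / s2pq)
  beta <- solve(crossprod(Wo) + diag(lambda, ncol(W)),
                crossprod(Wo, y[obs] - b))
  list(b = b, gebv = unname(drop(W %*% beta)))
}
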