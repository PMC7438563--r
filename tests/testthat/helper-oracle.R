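# Independent brute-force oracle for the optimal-contribution problem:
# maximize c'g subject to c'Gc/2 = K, per-sex sums 1/2, c >= 0.
#
# Inner solver: for a fixed Lagrange multiplier lambda on the quadratic
# term, the concave program max c'g - lambda c'Gc/2 over the per-sex
# simplices is solved exactly by exhaustive enumeration of active sets
# (supports): on each candidate support the equality-constrained
# stationary point is a linear solve, and the KKT conditions
# (nonnegativity on the support, nonpositive reduced gradients off it)
# identify the optimum. Outer loop: the achieved coancestry decreases
# monotonically in lambda, so bisection on lambda hits the target K.
# Shares nothing with solve_oc() beyond base linear algebra.

oracle_fixed_lambda <- function(g, G, sex, lambda) {
  n <- length(g)
  m_idx <- which(sex == "M")
  f_idx <- which(sex == "F")
  best <- NULL
  best_obj <- -Inf
  for (mask in seq_len(2^n) - 1) {
    A <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!length(intersect(A, m_idx)) || !length(intersect(A, f_idx))) next
    Q <- cbind(as.numeric(sex[A] == "M"), as.numeric(sex[A] == "F"))
    kkt <- rbind(cbind(lambda * G[A, A, drop = FALSE], Q),
                 cbind(t(Q), matrix(0, 2, 2)))
    sol <- tryCatch(solve(kkt, c(g[A], 0.5, 0.5)), error = function(e) NULL)
    if (is.null(sol)) next
    cA <- sol[seq_along(A)]
    mu <- sol[length(A) + 1:2]
    if (any(cA < -1e-10)) next
    # reduced gradient of excluded candidates must be nonpositive
    out <- setdiff(seq_len(n), A)
    if (length(out)) {
      cc <- numeric(n); cc[A] <- cA
      red <- g[out] - lambda * as.vector(G[out, , drop = FALSE] %*% cc) -
        mu[1] * (sex[out] == "M") - mu[2] * (sex[out] == "F")
      if (any(red > 1e-10)) next
    }
    cc <- numeric(n); cc[A] <- pmax(cA, 0)
    obj <- sum(cc * g) - lambda * 0.5 * sum(cc * (G %*% cc))
    if (obj > best_obj) { best_obj <- obj; best <- cc }
  }
  best
}

oracle_coancestry <- function(cc, G) 0.5 * sum(cc * (G %*% cc))

oracle_oc <- function(g, G, sex, K, iters = 60) {
  lo <- 0
  hi <- 1
  while (oracle_coancestry(oracle_fixed_lambda(g, G, sex, hi), G) > K) {
    hi <- hi * 4
    if (hi > 1e10) stop("oracle: K below the minimum achievable coancestry")
  }
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    cc <- oracle_fixed_lambda(g, G, sex, mid)
    if (oracle_coancestry(cc, G) > K) lo <- mid else hi <- mid
  }
  oracle_fixed_lambda(g, G, sex, (lo + hi) / 2)
}

# random positive-definite relationship-like matrix
random_pd_matrix <- function(n) {
  B <- matrix(rnorm(n * (n + 2)), n)
  G <- tcrossprod(B) / (n + 2)
  d <- sqrt(diag(G))
  G <- G / (d %o% d)           # correlation-like
  diag(G) <- diag(G) + runif(n, 0, 0.3)
  G
}
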