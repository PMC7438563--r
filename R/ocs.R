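#' Group-coancestry constraint schedule
#'
#' The target group coancestry follows `K_t = K_{t-1} + dF (1 - K_{t-1})`,
#' i.e. a fixed rate of inbreeding `dF` per generation relative to the
#' remaining diversity; `K_0` is half the average relationship among the
#' candidates of the first GOC generation.
#'
#' @param K0 starting group coancestry
#' @param dF target rate of inbreeding per generation (default 0.005,
#'   effective population size 100)
#' @param horizon number of generations
#' @return numeric vector `K_1 .. K_horizon`
#' @export
constraint_schedule <- function(K0, dF = 0.005, horizon = 20) {
  stopifnot(dF >= 0, dF < 1, horizon >= 1)
  K <- numeric(horizon)
  prev <- K0
  for (t in seq_len(horizon)) {
    prev <- prev + dF * (1 - prev)
    K[t] <- prev
  }
  K
}

#' Optimal contributions under a group-coancestry constraint
#'
#' Maximizes the contribution-weighted mean breeding value `c'g` subject to
#' `c'Gc/2 = K`, per-sex contribution sums of 1/2 and `c >= 0`, by the
#' classical Lagrangian solution with iterative elimination of candidates
#' whose unconstrained-sign contribution is negative. On the active set the
#' stationary point is `c = c_min + P g / lambda0` with
#' `c_min = G^-1 Q (Q'G^-1 Q)^-1 s` the minimum-coancestry solution,
#' `P = G^-1 - G^-1 Q (Q'G^-1 Q)^-1 Q' G^-1` and
#' `lambda0 = sqrt(g'Pg / (2 (K - K_min)))`. If even `K_min` (the smallest
#' achievable group coancestry over the sex-constrained simplex) exceeds
#' `K`, the minimum-coancestry solution is returned flagged infeasible.
#'
#' @param gebv breeding-value vector of the candidates
#' @param G positive-definite `relationship_matrix` (run
#'   [make_positive_definite()] first)
#' @param sex character vector "M"/"F" per candidate
#' @param K target group coancestry
#' @param tol feasibility tolerance on contributions
#' @return a `contribution_solution`: contributions `c`, selected set,
#'   achieved `c'Gc/2`, objective, feasibility flag
#' @export
solve_oc <- function(gebv, G, sex, K, tol = 1e-12) {
  n <- length(gebv)
  stopifnot(nrow(G) == n, length(sex) == n)
  if (!any(sex == "M") || !any(sex == "F")) {
    stop("need candidates of both sexes")
  }
  if (inherits(tryCatch(chol(G), error = function(e) e), "error")) {
    stop("G is not positive definite; apply make_positive_definite() first")
  }
  Gm <- unclass(G)
  s <- c(0.5, 0.5)
  active <- seq_len(n)
  cfull <- numeric(n)
  feasible <- TRUE
  iter <- 0L
  gscale <- 1 + max(abs(gebv))
  repeat {
    iter <- iter + 1L
    ga <- gebv[active]
    Ga <- Gm[active, active, drop = FALSE]
    Q <- cbind(as.numeric(sex[active] == "M"), as.numeric(sex[active] == "F"))
    R <- chol(Ga)
    GiQ <- backsolve(R, forwardsolve(t(R), Q))
    Gig <- backsolve(R, forwardsolve(t(R), ga))
    QGQ <- crossprod(Q, GiQ)
    QGQi_s <- solve(QGQ, s)
    cmin <- as.vector(GiQ %*% QGQi_s)
    Kmin <- 0.5 * sum(s * QGQi_s)
    Pg <- Gig - GiQ %*% solve(QGQ, crossprod(Q, Gig))
    gPg <- sum(ga * Pg)
    binding <- TRUE
    lambda0 <- Inf
    if (K < Kmin - 1e-9) {
      cc <- cmin
      feasible <- FALSE
      binding <- FALSE
    } else if (gPg <= 1e-12 || K - Kmin <= 1e-12) {
      cc <- cmin
      binding <- FALSE
    } else {
      lambda0 <- sqrt(gPg / (2 * (K - Kmin)))
      cc <- cmin + as.vector(Pg) / lambda0
    }
    neg <- which(cc < -tol)
    if (length(neg)) {
      # drop all negative candidates, but never empty a sex class
      drop <- active[neg]
      for (sx in c("M", "F")) {
        in_sex <- active[sex[active] == sx]
        if (all(in_sex %in% drop)) {
          keep <- in_sex[which.max(cc[match(in_sex, active)])]
          drop <- setdiff(drop, keep)
        }
      }
      active <- setdiff(active, drop)
      next
    }
    cc[cc < 0] <- 0
    cfull[] <- 0
    cfull[active] <- cc
    # optimality check for the excluded candidates: with multipliers
    # (lambda, mu) recovered from the active stationarity conditions, an
    # excluded candidate whose reduced gradient is positive would improve
    # the objective and is re-admitted (prevents over-aggressive drops)
    excl <- setdiff(seq_len(n), active)
    if (!length(excl) || iter > 100L) break
    lam <- if (binding) lambda0 else 1
    geff <- if (binding) gebv else numeric(n)
    Gc <- as.vector(Gm %*% cfull)
    mu <- vapply(c("M", "F"), function(sx) {
      a <- active[sex[active] == sx & cfull[active] > 1e-10]
      mean(geff[a] - lam * Gc[a])
    }, numeric(1))
    r <- geff[excl] - lam * Gc[excl] - mu[ifelse(sex[excl] == "M", 1L, 2L)]
    if (max(r) <= 1e-9 * gscale * max(1, lam)) break
    active <- sort(c(active, excl[which.max(r)]))
  }
  achieved <- 0.5 * sum(cfull * (Gm %*% cfull))
  structure(list(
    c = cfull, sex = sex,
    selected = which(cfull > 1e-9),
    objective = sum(cfull * gebv),
    coancestry = achieved, K = K,
    feasible = feasible, iterations = iter
  ), class = "contribution_solution")
}

#' @export
print.contribution_solution <- function(x, ...) {
  cat(sprintf("contribution_solution: %d parents, objective %.4f, c'Gc/2 = %.5f (target %.5f)%s\n",
              length(x$selected), x$objective, x$coancestry, x$K,
              if (x$feasible) "" else " [infeasible: minimum-coancestry fallback]"))
  invisible(x)
}

#' Number of selected parents
#'
#' @param solution a [solve_oc()] result
#' @param tol contributions above this count as selected
#' @return integer count of candidates with positive contributions
#' @export
count_parents <- function(solution, tol = 1e-9) {
  sum(solution$c > tol)
}
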