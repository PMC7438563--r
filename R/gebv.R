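#' Standardized and centred genotype codings
#'
#' Codes 0/1/2 reference-allele dosages against the frozen generation-0
#' frequencies `p0`: the standardized matrix has entries
#' `(m - 2 p0) / sqrt(2 p0 (1 - p0))` (used for SNP-BLUP and the VanRaden
#' Model-2 matrix) and the centred matrix has entries `m - 2 p0` (VanRaden
#' Model 1).
#'
#' @param dosage dosage matrix (individuals x loci)
#' @param p0 base reference-allele frequencies, strictly inside (0, 1)
#' @return list with `X` (standardized) and `Z` (centred)
#' @export
standardize_genotypes <- function(dosage, p0) {
  if (any(p0 <= 0 | p0 >= 1)) {
    stop("p0 must lie strictly in (0,1): fixed base loci cannot be standardized")
  }
  Z <- sweep(dosage, 2, 2 * p0, "-")
  X <- sweep(Z, 2, sqrt(2 * p0 * (1 - p0)), "/")
  list(X = X, Z = Z)
}

#' SNP-BLUP fit
#'
#' Random regression of phenotypes on standardized marker genotypes,
#' `y = 1 mu + X b + e` with `b ~ MVN(0, sigma_g2 / N_SNP I)` and
#' `e ~ N(0, sigma_e2 I)`, i.e. ridge regression with
#' `lambda = N_SNP * sigma_e2 / sigma_g2`. Solved exactly through the
#' record-dimensional equivalent system (`V = X X' + lambda I`), which for
#' fewer records than markers is both cheaper and identical to the full
#' mixed-model equations; `method = "mme"` solves the dense
#' (N_SNP + 1)-dimensional equations directly (used as a cross-check on
#' small problems).
#'
#' @param y phenotype vector (test sibs)
#' @param X standardized genotypes of the phenotyped individuals
#' @param sigma_g2,sigma_e2 variance components (simulation truths)
#' @param method "records" (default) or "mme"
#' @param loci_in_rows set TRUE when `X` is stored loci x individuals (the
#'   simulator's native layout); identical fit, no copy
#' @return a `snp_blup_fit` with `mu`, SNP effects `b` and `lambda`
#' @export
fit_snp_blup <- function(y, X, sigma_g2 = 1, sigma_e2 = 1.5,
                         method = c("records", "mme"), loci_in_rows = FALSE) {
  method <- match.arg(method)
  n <- length(y)
  if (n < 2) stop("need at least 2 records to fit SNP-BLUP")
  if (sigma_g2 <= 0 || sigma_e2 <= 0) stop("variance components must be positive")
  p <- if (loci_in_rows) nrow(X) else ncol(X)
  lambda <- p * sigma_e2 / sigma_g2
  if (method == "records") {
    V <- if (loci_in_rows) crossprod(X) else tcrossprod(X)
    diag(V) <- diag(V) + lambda
    R <- chol(V)
    sol <- backsolve(R, forwardsolve(t(R), cbind(1, y)))
    mu <- sum(sol[, 2]) / sum(sol[, 1])   # GLS mean: (1'V^-1 y)/(1'V^-1 1)
    w <- backsolve(R, forwardsolve(t(R), y - mu))
    b <- as.vector(if (loci_in_rows) X %*% w else crossprod(X, w))
  } else {
    if (loci_in_rows) X <- t(X)
    C <- rbind(cbind(n, t(colSums(X))),
               cbind(colSums(X), crossprod(X) + diag(lambda, p)))
    rhs <- c(sum(y), as.vector(crossprod(X, y)))
    sol <- solve(C, rhs)
    mu <- unname(sol[1])
    b <- unname(sol[-1])
  }
  structure(list(mu = mu, b = b, lambda = lambda,
                 sigma_g2 = sigma_g2, sigma_e2 = sigma_e2),
            class = "snp_blup_fit")
}

#' Genomic estimated breeding values from a SNP-BLUP fit
#'
#' @param fit a [fit_snp_blup()] result
#' @param X standardized genotypes of the individuals to predict
#' @param loci_in_rows set TRUE when `X` is stored loci x individuals
#' @return numeric vector `X %*% b`
#' @export
predict_gebv <- function(fit, X, loci_in_rows = FALSE) {
  as.vector(if (loci_in_rows) crossprod(X, fit$b) else X %*% fit$b)
}

#' Random GEBVs (no-selection control)
#'
#' Independent standard-normal pseudo-EBVs, one per candidate, redrawn each
#' generation; used to separate the effects of directional selection from
#' those of diversity management.
#'
#' @param n number of candidates
#' @param seed optional integer seed
#' @return numeric vector of length `n`
#' @export
random_gebv <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rnorm(n)
}
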