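#' Homozygosity-based inbreeding coefficient
#'
#' Proportional loss of heterozygosity relative to generation 0, averaged
#' over panel loci: `F_hom = 1 - mean_k[ H_t,k / H_0,k ]` with
#' `H = 2 p (1 - p)`. Negative when heterozygosity has increased (allele
#' frequencies moving toward 0.5). Loci fixed by generation t contribute
#' `H_t = 0` and stay in the average; the base denominators `H_0` are
#' positive by panel construction.
#'
#' @param p0 base (t = 0) reference-allele frequencies
#' @param pt current reference-allele frequencies
#' @return scalar F_hom
#' @export
f_hom <- function(p0, pt) {
  1 - mean((2 * pt * (1 - pt)) / (2 * p0 * (1 - p0)))
}

#' Drift-based inbreeding coefficient
#'
#' Mean squared standardized allele-frequency change from generation 0:
#' `F_drift = mean_k[ (p_t,k - p_0,k)^2 / (p_0,k (1 - p_0,k)) ]`;
#' nonnegative by construction.
#'
#' @inheritParams f_hom
#' @return scalar F_drift
#' @export
f_drift <- function(p0, pt) {
  mean((pt - p0)^2 / (p0 * (1 - p0)))
}

#' Exact decomposition of the homozygosity/drift discrepancy
#'
#' Per-locus algebra gives `H_t/H_0 = 1 + delta (1 - 2 p0)/(p0(1-p0))
#' - delta^2/(p0(1-p0))`, so averaging over loci,
#' `F_hom - F_drift = 2 mean_k\[ delta_k (p0_k - 1/2) / (p0_k (1 - p0_k)) \]`
#' exactly: the discrepancy is twice the mean cross-product between the
#' standardized frequency change and the standardized deviation of the
#' initial frequency from 1/2. Returns both sides of the identity.
#'
#' @inheritParams f_hom
#' @return named vector: `difference` (F_hom - F_drift) and `cross_term`
#'   (twice the mean standardized cross-product); equal to machine
#'   precision for every input
#' @export
hom_drift_decomposition <- function(p0, pt) {
  d <- pt - p0
  c(difference = f_hom(p0, pt) - f_drift(p0, pt),
    cross_term = 2 * mean(d * (p0 - 0.5) / (p0 * (1 - p0))))
}

#' Rate of inbreeding by log-regression
#'
#' Under a constant rate, `1 - F_t = (1 - dF)^t`, so ordinary least squares
#' of `log(1 - F_t)` on generation (natural log, intercept included)
#' estimates the rate as `dF = 1 - exp(slope)`; the small-rate
#' approximation `-slope` is reported alongside, and the regression R^2
#' serves as the diagnostic for constancy of the rate.
#'
#' @param f vector of inbreeding coefficients F_t
#' @param t generations (default `0, 1, ...`)
#' @return list with `dF` (= 1 - exp(slope)), `dF_approx` (= -slope),
#'   `slope`, `intercept`, `r_squared`, `residuals`
#' @export
delta_f_regression <- function(f, t = seq_along(f) - 1) {
  stopifnot(length(f) == length(t), length(f) >= 2)
  if (any(f >= 1)) stop("F values >= 1: log(1 - F) undefined")
  y <- log(1 - f)
  fit <- lm(y ~ t)
  sl <- unname(coef(fit)[2])
  # R^2 computed directly (summary.lm warns on perfect fits)
  tss <- sum((y - mean(y))^2)
  rss <- sum(resid(fit)^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  list(dF = 1 - exp(sl), dF_approx = -sl, slope = sl,
       intercept = unname(coef(fit)[1]),
       r_squared = r2, residuals = unname(resid(fit)))
}

#' Per-generation response metrics from a scheme trajectory
#'
#' Gain is the mean true breeding value of the generation's candidates
#' minus the founder mean (zero by centring), in base genetic SD units;
#' genetic variance is the variance of TBVs; parent counts come from the
#' contribution solutions.
#'
#' @param pergen the per-generation table of a [run_scheme()] result
#' @return data.frame (generation, gain, var_tbv, n_parents)
#' @export
response_metrics <- function(pergen) {
  pergen[, c("generation", "gain", "var_tbv", "n_parents")]
}
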