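#' Assign additive QTL effects
#'
#' Draws one allelic effect per QTL-panel locus from the standard Normal
#' distribution and applies a single multiplicative rescaling so that the
#' variance of true breeding values among the founders equals
#' `sigma_g2` (1 by default). TBVs are reported centred at the founder
#' mean, so founder mean TBV is 0 and gains are in base genetic SD units.
#'
#' @param qtl_dosage founder dosage matrix (individuals x QTL loci, 0/1/2
#'   on the reference allele)
#' @param sigma_g2 target base genetic variance
#' @param sigma_e2 environmental variance (stored for phenotyping;
#'   default gives heritability `sigma_g2 / (sigma_g2 + sigma_e2)` = 0.4)
#' @param seed optional integer seed
#' @return a `trait_model`: scaled allelic effects, centring constant and
#'   variance components
#' @export
assign_qtl_effects <- function(qtl_dosage, sigma_g2 = 1, sigma_e2 = 1.5,
                               seed = NULL) {
  stopifnot(nrow(qtl_dosage) >= 2)
  if (!is.null(seed)) set.seed(seed)
  a <- rnorm(ncol(qtl_dosage))
  raw <- as.vector(qtl_dosage %*% a)
  v <- var(raw)
  if (v <= .Machine$double.eps) {
    stop("founder TBV variance is zero (QTL panel monomorphic or founders identical); cannot scale effects")
  }
  scale <- sqrt(sigma_g2 / v)
  eff <- a * scale
  structure(list(effects = eff, center = mean(raw * scale),
                 sigma_g2 = sigma_g2, sigma_e2 = sigma_e2),
            class = "trait_model")
}

#' True breeding values
#'
#' Additive sum of QTL allele dosages times scaled effects, centred so the
#' founder mean is zero.
#'
#' @param qtl_dosage dosage matrix (individuals x QTL loci)
#' @param model a [assign_qtl_effects()] result
#' @param loci_in_rows set TRUE when `qtl_dosage` is stored loci x
#'   individuals (the simulator's native layout)
#' @return numeric vector of TBVs in base genetic SD units
#' @export
true_bv <- function(qtl_dosage, model, loci_in_rows = FALSE) {
  v <- if (loci_in_rows) crossprod(qtl_dosage, model$effects)
       else qtl_dosage %*% model$effects
  as.vector(v) - model$center
}

#' Phenotypes
#'
#' `y = TBV + e` with `e ~ Normal(0, sigma_e2)`.
#'
#' @param tbv vector of true breeding values
#' @param model trait model (supplies `sigma_e2`)
#' @param seed optional integer seed
#' @return numeric vector of phenotypes
#' @export
phenotype <- function(tbv, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tbv + rnorm(length(tbv), 0, sqrt(model$sigma_e2))
}
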