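#' Relationship-matrix container
#'
#' Tags a symmetric candidate-by-candidate matrix with its label, the type
#' of diversity measure it represents (drift, homozygosity, hybrid or IBD),
#' the repair class used by [make_positive_definite()] and the diagonal
#' value `alpha` already added.
#'
#' @param M symmetric numeric matrix
#' @param label matrix name, e.g. "G_VR2"
#' @param measure one of "drift", "homozygosity", "hybrid", "IBD"
#' @param repair one of "xxt" (positive semi-definite cross-product types),
#'   "ibd" (guaranteed positive definite) or "roh" (indefinite, needs
#'   escalation)
#' @param panel marker panel used (or NA)
#' @return a `relationship_matrix`
#' @export
relationship_matrix <- function(M, label, measure, repair, panel = NA_character_) {
  structure(M, class = c("relationship_matrix", "matrix", "array"),
            label = label, measure = measure, repair = repair,
            panel = panel, alpha = 0)
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("%s relationship matrix (%s measure), %d candidates, alpha = %g\n",
              attr(x, "label"), attr(x, "measure"), nrow(x), attr(x, "alpha")))
  invisible(x)
}

#' Pedigree numerator relationship matrix
#'
#' Tabular recursion over a pedigree whose founders (NA parents) are
#' treated as unrelated and non-inbred: `a_ij = (a_i,sire(j) + a_i,dam(j))/2`
#' and `a_jj = 1 + a_sire(j),dam(j)/2`.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam`; ids are
#'   1..n in an order where parents precede offspring, parents NA for
#'   founders
#' @return a `relationship_matrix` (IBD measure)
#' @export
pedigree_A <- function(ped) {
  n <- nrow(ped)
  s <- ped$sire
  d <- ped$dam
  bad <- which((!is.na(s) & s >= ped$id) | (!is.na(d) & d >= ped$id))
  if (length(bad)) {
    stop("pedigree not sorted: individual(s) ", paste(ped$id[bad], collapse = ", "),
         " precede their parents")
  }
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    if (is.na(s[j]) && is.na(d[j])) {
      A[j, j] <- 1
    } else {
      sj <- s[j]; dj <- d[j]
      i <- seq_len(j - 1)
      as_ <- if (is.na(sj)) rep(0, j - 1) else A[i, sj]
      ad_ <- if (is.na(dj)) rep(0, j - 1) else A[i, dj]
      A[i, j] <- A[j, i] <- 0.5 * (as_ + ad_)
      A[j, j] <- 1 + 0.5 * if (is.na(sj) || is.na(dj)) 0 else A[sj, dj]
    }
  }
  relationship_matrix(A, "A", "IBD", "ibd")
}

#' One-generation update of the numerator relationship matrix
#'
#' Given A among the parental candidates and the sire/dam index of each
#' offspring, returns A among the offspring (the only block needed when
#' generations do not overlap).
#'
#' @param A_par relationship matrix among potential parents
#' @param sire,dam integer indices into `A_par` per offspring
#' @return numeric matrix among offspring
#' @export
pedigree_A_offspring <- function(A_par, sire, dam) {
  A <- 0.25 * (A_par[sire, sire, drop = FALSE] + A_par[sire, dam, drop = FALSE] +
               A_par[dam, sire, drop = FALSE] + A_par[dam, dam, drop = FALSE])
  diag(A) <- 1 + 0.5 * A_par[cbind(sire, dam)]
  A
}

#' VanRaden Model-2 genomic relationship matrix
#'
#' `G_VR2 = X X' / N_SNP` on standardized genotypes (base-frequency
#' standardization), the drift-based matrix: its entries accumulate squared
#' standardized allele-frequency changes.
#'
#' @param X standardized genotype matrix (candidates x loci)
#' @param panel panel tag
#' @param loci_in_rows set TRUE when the matrix is stored loci x
#'   individuals (the simulator's native layout)
#' @return a `relationship_matrix`
#' @export
g_vr2 <- function(X, panel = NA_character_, loci_in_rows = FALSE) {
  relationship_matrix(gram(X, loci_in_rows) / nloci(X, loci_in_rows),
                      "G_VR2", "drift", "xxt", panel)
}

# cross-product over individuals / locus count, both storage orientations
gram <- function(M, loci_in_rows) if (loci_in_rows) crossprod(M) else tcrossprod(M)
nloci <- function(M, loci_in_rows) if (loci_in_rows) nrow(M) else ncol(M)

#' VanRaden Model-1 genomic relationship matrix
#'
#' `G_VR1 = Z Z' / sum_k H0_k` on centred genotypes, with
#' `H0_k = 2 p0_k (1 - p0_k)`: the `2 p0 (1 - p0)`-weighted mean of the
#' single-locus Model-2 estimates.
#'
#' @param Z centred genotype matrix (`dosage - 2 p0`)
#' @param p0 base reference-allele frequencies
#' @param panel panel tag
#' @inheritParams g_vr2
#' @return a `relationship_matrix`
#' @export
g_vr1 <- function(Z, p0, panel = NA_character_, loci_in_rows = FALSE) {
  H0 <- 2 * p0 * (1 - p0)
  relationship_matrix(gram(Z, loci_in_rows) / sum(H0), "G_VR1", "drift",
                      "xxt", panel)
}

#' Homozygosity-based relationship matrix
#'
#' VanRaden Model-2 form with all reference frequencies fixed at 0.5:
#' entries `(1/N) sum_k 2 (m_ik - 1)(m_jk - 1)`, proportional to expected
#' progeny homozygosity; the diagonal equals twice the individual's
#' homozygous fraction.
#'
#' @param dosage dosage matrix (candidates x loci)
#' @param panel panel tag
#' @inheritParams g_vr2
#' @return a `relationship_matrix`
#' @export
g_05 <- function(dosage, panel = NA_character_, loci_in_rows = FALSE) {
  M <- dosage - 1
  relationship_matrix(2 * gram(M, loci_in_rows) / nloci(M, loci_in_rows),
                      "G_0.5", "homozygosity", "xxt", panel)
}

#' Intensity-based relationship matrix (angular transform)
#'
#' Relationship matrix built on cumulative selection intensities rather
#' than raw frequency changes. Because `di/dp = [p(1-p)]^(-1/2)`, the
#' integral of intensity with frequency is the angular (arcsine-square-root)
#' transform, so each genotype contributes
#' `iota_ik = 2[arcsin(sqrt(m_ik / 2)) - arcsin(sqrt(p0_k))]` and
#' `G_i(p) = Upsilon Upsilon' / N_SNP`. To first order in the frequency
#' change this is proportional to the Model-2 standardization; beyond first
#' order it penalises moves toward the extremes more heavily.
#'
#' @param dosage dosage matrix (candidates x loci)
#' @param p0 base reference-allele frequencies
#' @param panel panel tag
#' @inheritParams g_vr2
#' @return a `relationship_matrix`
#' @export
g_ip <- function(dosage, p0, panel = NA_character_, loci_in_rows = FALSE) {
  U <- 2 * (asin(sqrt(dosage / 2)) -
              matrix(asin(sqrt(p0)), nrow(dosage), ncol(dosage),
                     byrow = !loci_in_rows))
  relationship_matrix(gram(U, loci_in_rows) / nloci(U, loci_in_rows),
                      "G_i(p)", "drift", "xxt", panel)
}

#' Shared (identical) segments between two haplotypes
#'
#' Maximal runs of loci at which the two haplotypes carry the same allele,
#' reported as intervals. Run boundaries are placed at the midpoint between
#' the last agreeing and the first disagreeing locus, and extended to the
#' chromosome ends when terminal, so two identical haplotypes share each
#' chromosome entirely. Only segments of at least `min_mb` megabases are
#' returned; no heterozygous interruptions are allowed.
#'
#' @param hapA,hapB 0/1 allele vectors over the same loci
#' @param pos global genetic positions of the loci (Morgans)
#' @param map a [genome_map()]
#' @param min_mb minimum segment length in Mb (default 7)
#' @return data.frame (chr, start, end, length_morgan, length_mb),
#'   positions within chromosome in Morgans
#' @export
shared_segments <- function(hapA, hapB, pos, map, min_mb = 7) {
  stopifnot(length(hapA) == length(hapB), length(hapA) == length(pos))
  H <- matrix(as.raw(c(hapA, hapB)), ncol = 2)
  min_len <- min_mb / map$chr_mb[1] * map$chr_len[1]  # uniform map: Mb -> Morgans
  seg <- cpp_pair_segments(H, 1L, 2L, pos, map$chr_start, map$chr_len, min_len)
  out <- data.frame(chr = as.integer(seg[, 1]), start = seg[, 2], end = seg[, 3])
  out$length_morgan <- out$end - out$start
  out$length_mb <- out$length_morgan / map$chr_len[out$chr] * map$chr_mb[out$chr]
  out
}

#' ROH-based relationship matrix
#'
#' Pairwise similarity from runs of homozygosity that the progeny of two
#' candidates would exhibit: the off-diagonal entry is the mean over the
#' four inter-individual haplotype pairings of the genome fraction covered
#' by shared segments of at least the minimum length, and the diagonal is
#' `1 + F_ROH` where `F_ROH` uses the individual's own two haplotypes. Not
#' guaranteed positive (semi-)definite; see [make_positive_definite()].
#'
#' @param hap phased raw haplotype matrix (loci x 2n) on the management
#'   panel
#' @param ind 1-based individual indices (columns `2i-1`, `2i`)
#' @param pos global genetic positions of the panel loci
#' @param map a [genome_map()]
#' @param min_mb minimum ROH length in Mb (default 7)
#' @param panel panel tag
#' @return a `relationship_matrix` (hybrid measure)
#' @export
g_roh <- function(hap, ind, pos, map, min_mb = 7, panel = NA_character_) {
  min_len <- min_mb / map$chr_mb[1] * map$chr_len[1]
  G <- cpp_roh_gmat(hap, as.integer(ind), pos, map$chr_start, map$chr_len, min_len)
  relationship_matrix(G, "G_ROH", "hybrid", "roh", panel)
}

#' Linkage-analysis (IBD) relationship matrix, true-descent evaluator
#'
#' IBD relationships relative to the generation-0 base, whose gametes are
#' mutually non-IBD: entry (i, j) is twice the mean over the evaluation
#' grid of the probability that randomly drawn alleles of i and j descend
#' from the same founder haplotype. In simulation the descent of every
#' gamete is tracked exactly, so this evaluator reads the recorded founder
#' origins; the diagonal equals `1 + F_IBD`, the genome fraction where the
#' two gametes of the individual share founder origin.
#'
#' @param state a `population_state` with a founder-origin matrix
#' @param ind candidate individual indices
#' @param panel panel tag
#' @return a `relationship_matrix` (IBD measure)
#' @export
g_la <- function(state, ind = seq_len(state$n), panel = NA_character_) {
  if (is.null(state$origin) || nrow(state$origin) == 0) {
    stop("population state carries no founder-origin grid; cannot build G_LA")
  }
  G <- cpp_origin_gmat(state$origin, as.integer(ind))
  relationship_matrix(G, "G_LA", "IBD", "ibd", panel)
}

#' Linkage-analysis relationship matrix, marker-HMM evaluator
#'
#' Marker-based estimator of the same IBD contract as [g_la()], usable when
#' true descent is not recorded: for every non-founder gamete a two-state
#' (grand-paternal / grand-maternal) hidden Markov chain runs along each
#' chromosome, with transition probabilities given by Haldane recombination
#' fractions between adjacent loci and emissions comparing the gamete
#' allele with the two phased parental haplotypes. Posterior origin
#' probabilities propagate the founder-gamete distribution of each gamete
#' down the pedigree; relationships are averaged products of those
#' distributions. Requires phased parents.
#'
#' @param ped data.frame (`id`, `sire`, `dam`), parents before offspring,
#'   NA parents for founders; ids are 1..n
#' @param haps list indexed by id: each element `list(h1, h2)` of 0/1
#'   allele vectors at the evaluation loci; by convention `h1` descends
#'   from the sire and `h2` from the dam
#' @param pos global genetic positions of the evaluation loci (Morgans)
#' @param map a [genome_map()]
#' @param eps marker-emission error rate
#' @return a `relationship_matrix` (IBD measure)
#' @export
g_la_hmm <- function(ped, haps, pos, map, eps = 1e-3) {
  n <- nrow(ped)
  if (any(vapply(haps, function(h) is.null(h$h1) || is.null(h$h2), logical(1)))) {
    stop("g_la_hmm requires phased haplotypes (h1/h2) for every individual")
  }
  L <- length(pos)
  founders <- which(is.na(ped$sire) & is.na(ped$dam))
  nf <- 2 * length(founders)
  fid <- integer(n)          # founder index per founder individual
  fid[founders] <- seq_along(founders)
  chr <- findInterval(pos, c(map$chr_start, map$total_morgans), rightmost.closed = TRUE)
  dist <- c(Inf, diff(pos))
  dist[c(1, which(diff(chr) != 0) + 1)] <- Inf   # chromosome breaks: free recombination
  rfrac <- 0.5 * (1 - exp(-2 * dist))
  rfrac[!is.finite(dist)] <- 0.5

  post_origin <- function(child_allele, par) {
    # forward-backward over states 1 = parental h1, 2 = parental h2
    e1 <- ifelse(child_allele == par$h1, 1 - eps, eps)
    e2 <- ifelse(child_allele == par$h2, 1 - eps, eps)
    fwd <- matrix(0, L, 2)
    f <- c(0.5 * e1[1], 0.5 * e2[1])
    fwd[1, ] <- f / sum(f)
    for (k in 2:L) {
      r <- rfrac[k]
      f <- c((fwd[k - 1, 1] * (1 - r) + fwd[k - 1, 2] * r) * e1[k],
             (fwd[k - 1, 1] * r + fwd[k - 1, 2] * (1 - r)) * e2[k])
      fwd[k, ] <- f / sum(f)
    }
    bwd <- matrix(0, L, 2)
    bwd[L, ] <- 1
    for (k in (L - 1):1) {
      r <- rfrac[k + 1]
      b <- c((1 - r) * e1[k + 1] * bwd[k + 1, 1] + r * e2[k + 1] * bwd[k + 1, 2],
             r * e1[k + 1] * bwd[k + 1, 1] + (1 - r) * e2[k + 1] * bwd[k + 1, 2])
      bwd[k, ] <- b / sum(b)
    }
    p <- fwd * bwd
    p[, 1] / rowSums(p)
  }

  # founder-gamete distribution per gamete: L x nf
  dist_g <- vector("list", n)
  for (i in seq_len(n)) {
    if (i %in% founders) {
      d1 <- matrix(0, L, nf); d1[, 2 * fid[i] - 1] <- 1
      d2 <- matrix(0, L, nf); d2[, 2 * fid[i]] <- 1
      dist_g[[i]] <- list(d1, d2)
    } else {
      ds <- dist_g[[ped$sire[i]]]
      dd <- dist_g[[ped$dam[i]]]
      p1 <- post_origin(haps[[i]]$h1, haps[[ped$sire[i]]])
      p2 <- post_origin(haps[[i]]$h2, haps[[ped$dam[i]]])
      dist_g[[i]] <- list(ds[[1]] * p1 + ds[[2]] * (1 - p1),
                          dd[[1]] * p2 + dd[[2]] * (1 - p2))
    }
  }
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- 0
      for (a in 1:2) for (b in 1:2) {
        s <- s + mean(rowSums(dist_g[[i]][[a]] * dist_g[[j]][[b]]))
      }
      G[i, j] <- G[j, i] <- 2 * s / 4
    }
  }
  relationship_matrix(G, "G_LA", "IBD", "ibd")
}

#' Positive-definite repair of a relationship matrix
#'
#' Cross-product (`XX'`-type) matrices are positive semi-definite with at
#' least one zero eigenvalue from genotype centring, so a small constant
#' `alpha = 0.01` is added to the diagonal unconditionally. IBD matrices
#' (A, G_LA) are positive definite already and are tagged with `alpha = 0`.
#' ROH matrices can be indefinite: starting from `alpha = 0.05`, positive
#' definiteness is tested by Cholesky factorization and on failure `alpha`
#' is doubled while `alpha < 1` and increased by 1 afterwards, until the
#' factorization succeeds.
#'
#' @param G a `relationship_matrix` (or plain matrix with `repair` given)
#' @param repair override of the repair class ("xxt", "ibd", "roh")
#' @param alpha starting alpha for the "xxt" (added once) or "roh"
#'   (escalation start) policies
#' @return the repaired `relationship_matrix`, `alpha` attribute recording
#'   the total added
#' @export
make_positive_definite <- function(G, repair = attr(G, "repair"),
                                   alpha = switch(repair, xxt = 0.01, roh = 0.05, 0)) {
  if (is.null(repair)) stop("no repair class: supply `repair`")
  chol_ok <- function(M) {
    R <- tryCatch(chol(M), error = function(e) NULL)
    !is.null(R) && all(diag(R) > 1e-8)
  }
  added <- 0
  if (repair == "xxt") {
    diag(G) <- diag(G) + alpha
    added <- alpha
  } else if (repair == "roh") {
    a <- alpha
    repeat {
      M <- G
      diag(M) <- diag(M) + a
      if (chol_ok(M)) { G <- M; added <- a; break }
      a <- if (a < 1) 2 * a else a + 1
    }
  } else if (repair != "ibd") {
    stop("unknown repair class: ", repair)
  }
  attr(G, "alpha") <- added
  G
}
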