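test_that("pedigree A reproduces textbook full-sib and inbred values", {
  # founders 1,2; full sibs 3,4; 5 = offspring of the sib mating
  ped <- data.frame(id = 1:5, sire = c(NA, NA, 1, 1, 3), dam = c(NA, NA, 2, 2, 4))
  A <- pedigree_A(ped)
  expect_equal(unclass(A)[1, 2], 0)
  expect_equal(unclass(A)[3, 4], 0.5)         # full sibs
  expect_equal(unclass(A)[1, 3], 0.5)         # parent-offspring
  expect_equal(diag(unclass(A))[1:4], rep(1, 4))
  expect_equal(unclass(A)[5, 5], 1.25)        # F = 0.25 from sib mating
  expect_equal(attr(A, "measure"), "IBD")
})

test_that("pedigree A rejects offspring listed before their parents", {
  ped <- data.frame(id = 1:3, sire = c(2, NA, NA), dam = c(3, NA, NA))
  expect_error(pedigree_A(ped), "not sorted")
})

test_that("one-generation A update matches the full tabular recursion", {
  ped <- data.frame(id = 1:4, sire = c(NA, NA, 1, 1), dam = c(NA, NA, 2, 2))
  A_par <- unclass(pedigree_A(ped))
  # offspring: 3x4, 3x4 again (full sibs), and 3x2 (half-avuncular)
  sire <- c(3L, 3L, 3L); dam <- c(4L, 4L, 2L)
  A_off <- pedigree_A_offspring(A_par, sire, dam)
  ped2 <- rbind(ped, data.frame(id = 5:7, sire = sire, dam = dam))
  A_full <- unclass(pedigree_A(ped2))
  expect_equal(A_off, A_full[5:7, 5:7])
})

test_that("VanRaden matrices follow their defining cross-products", {
  X <- matrix(c(1, -1, 0, 2, 0.5, -0.5), 2, 3)
  G <- g_vr2(X)
  expect_equal(unclass(G), tcrossprod(X) / 3, ignore_attr = TRUE)
  expect_equal(attr(G, "measure"), "drift")
  # VR1 equals VR2 when every locus has the same base frequency
  set.seed(51)
  D <- matrix(rbinom(60, 2, 0.3), 10, 6)
  p0 <- rep(0.3, 6)
  s <- standardize_genotypes(D, p0)
  expect_equal(unclass(g_vr1(s$Z, p0)), unclass(g_vr2(s$X)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("mean genomic relationship among founders is near zero with unit diagonal", {
  base <- toy_base()
  st <- base$state0
  p <- base$tracked$panels$M
  D <- panel_dosage(st, base$tracked, "M")
  G <- unclass(g_vr2(standardize_genotypes(D, p$p0)$X))
  # exact: standardized genotypes are centred at the founder mean, so the
  # contribution-weighted mean relationship is 0 by construction
  expect_equal(mean(G), 0, tolerance = 1e-10)
  expect_equal(mean(diag(G)), 1, tolerance = 0.15)
})

test_that("the 0.5-reference matrix measures homozygosity directly", {
  # one locus: opposite homozygotes get -2, homozygote with itself +2,
  # heterozygotes contribute nothing
  D <- matrix(c(2, 0, 1), 3, 1)
  G <- unclass(g_05(D))
  expect_equal(G[1, 1], 2)
  expect_equal(G[1, 2], -2)
  expect_equal(G[3, 3], 0)
  # diagonal identity: 2 x homozygous fraction
  set.seed(52)
  D2 <- matrix(rbinom(5 * 40, 2, 0.5), 5, 40)
  expect_equal(diag(unclass(g_05(D2))), 2 * rowMeans(D2 != 1))
})

test_that("angular intensity coding matches its arcsine closed form", {
  # p0 = 0.25, dosage 2: iota = 2[arcsin(1) - arcsin(0.5)] = 2(pi/2 - pi/6)
  G <- unclass(g_ip(matrix(2, 1, 1), p0 = 0.25))
  expect_equal(G[1, 1], (2 * pi / 3)^2, tolerance = 1e-12)
  # p0 = 0.5, dosage 1: iota = 0, so a population at p0 with all hets is null
  expect_equal(unclass(g_ip(matrix(1, 3, 1), p0 = 0.5)),
               matrix(0, 3, 3), ignore_attr = TRUE)
})

test_that("shared segments cover whole chromosomes for identical haplotypes", {
  map <- genome_map(n_chr = 2, chr_morgans = 1, chr_mb = 140)
  pos <- sort(runif(100, 0, 2))
  h <- rbinom(100, 1, 0.5)
  seg <- shared_segments(h, h, pos, map, min_mb = 7)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$start, c(0, 0))
  expect_equal(seg$end, c(1, 1))
  expect_equal(seg$length_mb, c(140, 140))
})

test_that("a single mismatch splits a segment at the midpoint", {
  map <- genome_map(n_chr = 1, chr_morgans = 1, chr_mb = 140)
  pos <- seq(0.1, 0.9, by = 0.1)
  a <- rep(1L, 9)
  b <- a; b[5] <- 0L      # mismatch at 0.5
  seg <- shared_segments(a, b, pos, map, min_mb = 7)
  # boundaries at the midpoints 0.45 and 0.55, extended to chromosome ends
  expect_equal(seg$start, c(0, 0.55))
  expect_equal(seg$end, c(0.45, 1))
  # a high threshold removes both
  expect_equal(nrow(shared_segments(a, b, pos, map, min_mb = 80)), 0)
})

test_that("ROH matrix diagonal is one plus the own-haplotype sharing", {
  map <- genome_map(n_chr = 2, chr_morgans = 1, chr_mb = 140)
  set.seed(53)
  pos <- sort(runif(80, 0, 2))
  h <- as.raw(rbinom(80, 1, 0.5))
  other <- as.raw(rbinom(80, 1, 0.5))
  # individual 1 fully autozygous (identical haplotypes), individual 2 not
  hap <- cbind(h, h, h, other)
  G <- g_roh(hap, 1:2, pos, map, min_mb = 7)
  expect_equal(unclass(G)[1, 1], 2)
  expect_lt(unclass(G)[2, 2], 2)
  expect_equal(attr(G, "repair"), "roh")
  # off-diagonal: average of the four pairings, each a genome fraction
  expect_true(unclass(G)[1, 2] >= 0 && unclass(G)[1, 2] <= 1.01)
})

test_that("true-descent IBD matrix is exact for founders and parent-offspring", {
  # founders carry unique origins -> identity matrix
  Lg <- 50
  org <- matrix(rep(1:8, each = Lg), Lg)
  st <- list(n = 4, origin = org)
  G0 <- unclass(g_la(st, 1:4))
  expect_equal(G0, diag(4), ignore_attr = TRUE)
  # an offspring gamete mosaics its parent's two gametes: relationship to
  # that parent is exactly 0.5 whatever the recombination pattern
  child_s <- ifelse(runif(Lg) < 0.5, 1L, 2L)   # from founder 1's gametes
  child_d <- ifelse(runif(Lg) < 0.5, 3L, 4L)
  org2 <- cbind(org, child_s, child_d)
  st2 <- list(n = 5, origin = org2)
  G <- unclass(g_la(st2, 1:5))
  expect_equal(G[1, 5], 0.5)
  expect_equal(G[2, 5], 0.5)
  expect_equal(G[3, 5], 0)
  # non-inbred child of unrelated founders
  expect_equal(G[5, 5], 1)
})

test_that("population states without an origin grid refuse to build G_LA", {
  st <- list(n = 2, origin = matrix(integer(0), 0, 4))
  expect_error(g_la(st, 1:2), "no founder-origin grid")
})

test_that("marker-HMM IBD estimates track true descent closely", {
  set.seed(54)
  map <- genome_map(n_chr = 2, chr_morgans = 1)
  L <- 400
  pos <- sort(runif(L, 0, 2))
  # 4 founders with dense informative markers, 2 children, 1 grandchild
  founders <- lapply(1:4, function(i) {
    list(h1 = rbinom(L, 1, 0.5), h2 = rbinom(L, 1, 0.5))
  })
  mate <- function(pa, pb) {
    gam <- function(p) {
      g <- meiosis(phased_individual(p$h1, p$h2, pos, map))
      g
    }
    gs <- gam(pa); gd <- gam(pb)
    list(h1 = gs$alleles, h2 = gd$alleles, m1 = gs$mosaic, m2 = gd$mosaic)
  }
  # rebuild phased individuals with founder-labelled mosaics for true IBD
  fi <- lapply(seq_along(founders), function(i) {
    phased_individual(founders[[i]]$h1, founders[[i]]$h2, pos, map,
      mosaic1 = data.frame(chr = 1:2, start = 0, end = 1, founder = 2 * i - 1),
      mosaic2 = data.frame(chr = 1:2, start = 0, end = 1, founder = 2 * i))
  })
  child <- function(a, b) {
    ga <- meiosis(a); gb <- meiosis(b)
    phased_individual(ga$alleles, gb$alleles, pos, map,
                      mosaic1 = ga$mosaic, mosaic2 = gb$mosaic)
  }
  c5 <- child(fi[[1]], fi[[2]])
  c6 <- child(fi[[3]], fi[[4]])
  c7 <- child(c5, c6)
  all_ind <- c(fi, list(c5, c6, c7))
  ped <- data.frame(id = 1:7, sire = c(NA, NA, NA, NA, 1, 3, 5),
                    dam = c(NA, NA, NA, NA, 2, 4, 6))
  haps <- lapply(all_ind, function(x) list(h1 = x$h1, h2 = x$h2))
  G_hmm <- unclass(g_la_hmm(ped, haps, pos, map))
  # truth from the descent mosaics at the marker positions
  origin_of <- function(mos) {
    vapply(pos, function(p) {
      lt <- locus_table(map, p)
      seg <- mos[mos$chr == lt$chr & mos$start <= lt$gen_pos & mos$end > lt$gen_pos, ]
      seg$founder[1]
    }, numeric(1))
  }
  org <- do.call(cbind, lapply(all_ind, function(x) {
    cbind(origin_of(x$mosaic1), origin_of(x$mosaic2))
  }))
  G_true <- unclass(g_la(list(n = 7, origin = org), 1:7))
  expect_lt(max(abs(G_hmm - G_true)), 0.05)
})

test_that("positive-definite repair follows the per-class policy", {
  # cross-product class: 0.01 added unconditionally
  X <- matrix(rnorm(12), 4, 3)
  G <- make_positive_definite(g_vr2(X))
  expect_equal(attr(G, "alpha"), 0.01)
  expect_equal(diag(unclass(G)), diag(tcrossprod(X) / 3) + 0.01)
  # IBD class: untouched
  ped <- data.frame(id = 1:2, sire = c(NA, NA), dam = c(NA, NA))
  A <- make_positive_definite(pedigree_A(ped))
  expect_equal(attr(A, "alpha"), 0)
  # ROH class: escalation 0.05 -> 0.1 -> 0.2 -> 0.4 for a minimum
  # eigenvalue of -0.3 (first doubling step that clears it is 0.4)
  M <- relationship_matrix(matrix(c(0.1, 0.4, 0.4, 0.1), 2), "G_ROH",
                           "hybrid", "roh")
  expect_equal(min(eigen(unclass(M))$values), -0.3)
  R <- make_positive_definite(M)
  expect_equal(attr(R, "alpha"), 0.4)
  expect_true(all(eigen(unclass(R))$values > 0))
  expect_error(make_positive_definite(matrix(1)), "no repair class")
})
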