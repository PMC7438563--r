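test_that("genome map accumulates chromosome starts and totals", {
  map <- genome_map(n_chr = 4, chr_morgans = c(1, 0.5, 2, 1), chr_mb = 100)
  expect_equal(map$chr_start, c(0, 1, 1.5, 3.5))
  expect_equal(map$total_morgans, 4.5)
  expect_equal(map$total_bp, 4e8)
})

test_that("locus table maps global positions to chromosome and bp scales", {
  map <- genome_map(n_chr = 2, chr_morgans = 1, chr_mb = 140)
  lt <- locus_table(map, c(0, 0.5, 1, 1.25, 1.999999))
  expect_equal(lt$chr, c(1, 1, 2, 2, 2))
  expect_equal(lt$gen_pos, c(0, 0.5, 0, 0.25, 0.999999))
  # uniform map: 0.25 Morgan on a 1 Morgan / 140 Mb chromosome = 35 Mb
  expect_equal(lt$phys_pos[4], 35e6)
})

test_that("base simulation returns sorted segregating sites with consistent counts", {
  map <- genome_map(n_chr = 2, chr_morgans = 1, chr_mb = 50)
  pool <- simulate_base_genomes(ne = 20, n_generations = 10, mu = 1e-8,
                                map = map, n_founders = 30, seed = 11)
  S <- length(pool$pos)
  expect_gt(S, 0)
  expect_equal(ncol(pool$hap), 60)            # loci x gametes layout
  expect_equal(nrow(pool$hap), S)
  expect_false(is.unsorted(pool$pos))
  expect_true(all(pool$pos >= 0 & pool$pos < map$total_morgans))
  # stored derived counts match the haplotype matrix, all sites segregating
  counts <- rowSums(matrix(as.integer(pool$hap), S))
  expect_equal(counts, pool$count)
  expect_true(all(pool$count >= 1 & pool$count <= 59))
  expect_equal(pool$freq, pool$count / 60)
})

test_that("equilibrium initialisation matches neutral-theory diversity", {
  # At stationarity E[S] = theta * sum_{i=1}^{2n-1} 1/i with
  # theta = 4 Ne u; one round of random-mating expansion loses only a
  # little rare variation, so S should land near that expectation.
  map <- genome_map(n_chr = 3, chr_morgans = 1, chr_mb = 140)
  ne <- 100
  u <- 1e-8 * map$total_bp
  theta <- 4 * ne * u
  expS <- theta * sum(1 / seq_len(2 * ne - 1))
  pool <- simulate_base_genomes(ne = ne, n_generations = 0, mu = 1e-8,
                                map = map, n_founders = ne, seed = 5)
  S <- length(pool$pos)
  expect_gt(S, 0.6 * expS)
  expect_lt(S, 1.1 * expS)
  # site-frequency spectrum: singletons are the modal class
  tab <- tabulate(pool$count, nbins = 2 * ne - 1)
  expect_equal(which.max(tab), 1L)
  # and low-frequency classes dominate high-frequency ones
  expect_gt(sum(tab[1:10]), sum(tab[101:199]))
})

test_that("panel sampling is disjoint with frozen base frequencies", {
  base <- toy_base()
  pool <- simulate_base_genomes(ne = 30, n_generations = 20,
                                map = genome_map(n_chr = 3),
                                n_founders = 100, seed = 3)
  panels <- sample_panels(pool, panel_sizes = c(M = 50, Q = 50, N = 50, D = 50),
                          seed = 4)
  sites <- lapply(panels, `[[`, "sites")
  expect_equal(lengths(sites), c(M = 50L, Q = 50L, N = 50L, D = 50L))
  expect_equal(length(unique(unlist(sites))), 200L)   # pairwise disjoint
  for (p in panels) {
    p_derived <- pool$freq[p$sites]
    expect_equal(p$p0, ifelse(p$ref_derived, p_derived, 1 - p_derived))
    expect_true(all(p$p0 > 0 & p$p0 < 1))
  }
})

test_that("panel sampling reports the shortfall when the pool is too small", {
  pool <- simulate_base_genomes(ne = 10, n_generations = 5,
                                map = genome_map(n_chr = 1, chr_mb = 5),
                                n_founders = 10, seed = 1)
  S <- length(pool$pos)
  expect_error(sample_panels(pool, panel_sizes = c(M = S, Q = S, N = S, D = S)),
               "shortfall")
})

test_that("tracked loci index panels consistently into the union", {
  base <- toy_base()
  tr <- base$tracked
  expect_false(is.unsorted(tr$pos))
  for (pn in names(tr$panels)) {
    p <- tr$panels[[pn]]
    expect_equal(length(p$cols), 120L)
    expect_false(is.unsorted(tr$pos[p$cols]))
  }
  # evaluation grid: every 5th M column (toy grid_step = 5)
  expect_equal(tr$grid_cols, tr$panels$M$cols[seq(1, 120, by = 5)])
  expect_equal(tr$grid_pos, tr$pos[tr$grid_cols])
  # panels are disjoint in the union too
  expect_equal(anyDuplicated(unlist(lapply(tr$panels, `[[`, "cols"))), 0L)
})

test_that("dosages, frequencies and base population agree with each other", {
  base <- toy_base()
  st <- base$state0
  D <- panel_dosage(st, base$tracked, "M")
  expect_equal(dim(D), c(120, 120))
  expect_true(all(D %in% 0:2))
  f <- panel_freq(st, base$tracked, "M")
  expect_equal(colMeans(D) / 2, f)
  # generation-0 frequencies are exactly the frozen p0
  expect_equal(f, base$tracked$panels$M$p0)
  # founder origins: each gamete its own identifier, constant along the genome
  expect_equal(dim(st$origin), c(length(base$tracked$grid_cols), 240))
  expect_equal(as.vector(st$origin[1, ]), 1:240)
  expect_true(all(apply(st$origin, 2, function(x) length(unique(x))) == 1))
})

test_that("single meiosis emits a parental mosaic that tiles every chromosome", {
  map <- genome_map(n_chr = 2, chr_morgans = 1.5)
  pos <- sort(runif(200, 0, map$total_morgans))
  set.seed(8)
  par <- phased_individual(h1 = rbinom(200, 1, 0.5), h2 = rbinom(200, 1, 0.5),
                           pos = pos, map = map)
  for (rep in 1:5) {
    g <- meiosis(par)
    # every allele is copied from one of the two parental haplotypes
    expect_true(all(g$alleles == par$h1 | g$alleles == par$h2))
    # the mosaic tiles each chromosome exactly: contiguous, no gaps/overlap
    for (ch in 1:2) {
      m <- g$mosaic[g$mosaic$chr == ch, ]
      expect_equal(m$start[1], 0)
      expect_equal(m$end[nrow(m)], map$chr_len[ch])
      if (nrow(m) > 1) expect_equal(m$start[-1], m$end[-nrow(m)])
      expect_true(all(m$founder %in% 1:2))
    }
  }
})

test_that("meiosis respects the founder mosaic composition of the parent", {
  # a parent whose first haplotype is founder 7 and second founder 9
  map <- genome_map(n_chr = 1, chr_morgans = 1)
  pos <- seq(0.05, 0.95, length.out = 50)
  par <- phased_individual(h1 = rep(1L, 50), h2 = rep(0L, 50), pos = pos, map = map,
                           mosaic1 = data.frame(chr = 1, start = 0, end = 1, founder = 7L),
                           mosaic2 = data.frame(chr = 1, start = 0, end = 1, founder = 9L))
  g <- meiosis(par, seed = 21)
  expect_true(all(g$mosaic$founder %in% c(7L, 9L)))
  # alleles identify the source haplotype: founder label must agree
  for (k in seq_along(pos)) {
    seg <- g$mosaic[g$mosaic$start <= pos[k] & g$mosaic$end > pos[k], ]
    expect_equal(seg$founder, if (g$alleles[k] == 1L) 7L else 9L)
  }
})
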