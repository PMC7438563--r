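#' Genome map
#'
#' Defines the chromosome layout used throughout the simulator: a set of
#' chromosomes with a genetic length in Morgans and a physical length in
#' base pairs, with a uniform (co-monotone) correspondence between the two
#' scales. The default is 10 chromosomes of 1 Morgan / 140 Mb each; the
#' physical scale is calibrated so that a population of effective size 100
#' at a mutation rate of 1e-8 per bp yields on the order of 33,000
#' segregating SNPs (see the methods vignette).
#'
#' @param n_chr number of chromosomes
#' @param chr_morgans genetic length per chromosome (Morgans); scalar or
#'   vector of length `n_chr`
#' @param chr_mb physical length per chromosome (megabases); scalar or
#'   vector of length `n_chr`
#' @return an object of class `genome_map`
#' @export
genome_map <- function(n_chr = 10, chr_morgans = 1, chr_mb = 140) {
  stopifnot(n_chr >= 1, all(chr_morgans > 0), all(chr_mb > 0))
  len <- rep_len(chr_morgans, n_chr)
  mb <- rep_len(chr_mb, n_chr)
  start <- cumsum(c(0, len[-n_chr]))
  structure(list(
    n_chr = n_chr,
    chr_len = len,            # Morgans
    chr_start = start,        # global genetic coordinate of chromosome start
    chr_mb = mb,
    total_morgans = sum(len),
    total_bp = sum(mb) * 1e6
  ), class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("genome_map: %d chromosomes, %.3g Morgans, %.4g Mb total\n",
              x$n_chr, x$total_morgans, x$total_bp / 1e6))
  invisible(x)
}

#' Locus table for a set of global genetic positions
#'
#' Maps global genetic coordinates (Morgans, chromosomes laid end to end)
#' to per-chromosome genetic and physical positions under the uniform map.
#'
#' @param map a [genome_map()]
#' @param pos numeric vector of global genetic positions
#' @return data.frame with chromosome, genetic position (Morgans, within
#'   chromosome) and physical position (bp)
#' @export
locus_table <- function(map, pos) {
  chr <- findInterval(pos, c(map$chr_start, map$total_morgans),
                      rightmost.closed = TRUE)
  within <- pos - map$chr_start[chr]
  bp <- within / map$chr_len[chr] * map$chr_mb[chr] * 1e6
  data.frame(chr = chr, gen_pos = within, phys_pos = bp)
}

#' Simulate base-population genomes
#'
#' Forward Wright-Fisher simulation of a monoecious population of effective
#' size `ne` with infinite-sites mutation and Poisson recombination (no
#' interference), run for `n_generations` generations. By default the
#' population is initialised at the stationary neutral site-frequency
#' spectrum (so the forward phase builds linkage structure on top of
#' equilibrium diversity); set `equilibrium_init = FALSE` for a monomorphic
#' start. The final generation is expanded by one round of random mating
#' into `n_founders` diploid founders, and all sites segregating among
#' their `2 * n_founders` haplotypes are returned.
#'
#' @param ne effective (census) size of the historical population
#' @param n_generations forward generations (default 4 * ne)
#' @param mu mutation rate per base pair per generation
#' @param map a [genome_map()]
#' @param n_founders number of diploid founder individuals to emit
#' @param equilibrium_init start from the stationary SFS (default) or from
#'   a monomorphic population
#' @param seed optional integer seed
#' @return an object of class `haplotype_pool`: haplotype matrix (loci x
#'   founder gametes, raw 0/1), site positions (global Morgans), derived
#'   allele counts and frequencies, and the map
#' @export
simulate_base_genomes <- function(ne = 100, n_generations = 4 * ne, mu = 1e-8,
                                  map = genome_map(), n_founders = 2000,
                                  equilibrium_init = TRUE, seed = NULL) {
  stopifnot(ne >= 2, mu >= 0, n_generations >= 0, n_founders >= 1)
  if (!is.null(seed)) set.seed(seed)
  u_gamete <- mu * map$total_bp   # genome-wide mutation rate per gamete
  res <- cpp_wf_sim(as.integer(ne), as.integer(n_generations), u_gamete,
                    map$chr_len, as.integer(n_founders), equilibrium_init)
  freq <- res$count / (2 * n_founders)
  structure(list(
    hap = res$hap, pos = res$pos, count = res$count, freq = freq,
    n_founders = n_founders, map = map
  ), class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("haplotype_pool: %d founder gametes, %d segregating sites\n",
              ncol(x$hap), length(x$pos)))
  invisible(x)
}

#' Sample disjoint SNP panels from a haplotype pool
#'
#' Draws the marker (M), QTL (Q), neutral-monitor (N) and alternative
#' diversity (D) panels uniformly without replacement from the segregating
#' sites of the pool, pairwise disjoint. For every panel locus a reference
#' allele is chosen at random and its founder (t = 0) frequency `p0` is
#' recorded; all downstream genotype codings and inbreeding metrics use
#' these frozen base frequencies.
#'
#' @param pool a [simulate_base_genomes()] result
#' @param panel_sizes named integer vector of panel sizes
#' @param seed optional integer seed
#' @return an object of class `panel_assignment`: per panel the site
#'   indices into the pool, reference-allele indicator (TRUE = derived
#'   allele is the reference) and `p0`
#' @export
sample_panels <- function(pool, panel_sizes = c(M = 7000, Q = 7000, N = 7000, D = 7000),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- length(pool$pos)
  need <- sum(panel_sizes)
  if (S < need) {
    stop(sprintf("pool has %d segregating sites but the requested panels need %d (shortfall %d)",
                 S, need, need - S))
  }
  picked <- sample.int(S, need)
  split_idx <- split(picked, rep(seq_along(panel_sizes), panel_sizes))
  panels <- lapply(seq_along(panel_sizes), function(i) {
    idx <- sort(split_idx[[i]])
    ref_derived <- runif(length(idx)) < 0.5
    p_derived <- pool$freq[idx]
    p0 <- ifelse(ref_derived, p_derived, 1 - p_derived)
    list(sites = idx, ref_derived = ref_derived, p0 = p0)
  })
  names(panels) <- names(panel_sizes)
  structure(panels, class = "panel_assignment")
}

#' Build the tracked-locus layout for a breeding run
#'
#' Collapses the union of the panel loci into a single position-ordered
#' tracked-locus set (the only loci carried through the breeding
#' generations) and records, per panel, its column indices, reference
#' orientation and base frequencies, plus the thinned evaluation grid used
#' for IBD (linkage-analysis) relationship matrices.
#'
#' @param pool haplotype pool
#' @param panels a [sample_panels()] result
#' @param grid_step keep every `grid_step`-th M-panel locus on the IBD
#'   evaluation grid
#' @return a `tracked_loci` object
#' @export
tracked_loci <- function(pool, panels, grid_step = 10) {
  all_sites <- sort(unique(unlist(lapply(panels, `[[`, "sites"))))
  panel_info <- lapply(panels, function(p) {
    o <- order(p$sites)
    list(cols = match(p$sites[o], all_sites),
         ref_derived = p$ref_derived[o],
         p0 = p$p0[o])
  })
  m_cols <- panel_info$M$cols
  grid_cols <- m_cols[seq(1, length(m_cols), by = grid_step)]
  structure(list(
    sites = all_sites,
    pos = pool$pos[all_sites],
    map = pool$map,
    panels = panel_info,
    grid_cols = grid_cols,
    grid_pos = pool$pos[all_sites][grid_cols]
  ), class = "tracked_loci")
}

#' Reference-allele frequencies of a panel in a set of individuals
#'
#' @param state a `population_state`
#' @param tracked a [tracked_loci()] layout
#' @param panel panel name ("M", "Q", "N", "D")
#' @param ind individual indices (default all)
#' @return numeric vector of reference-allele frequencies
#' @export
panel_freq <- function(state, tracked, panel, ind = seq_len(state$n)) {
  pi <- tracked$panels[[panel]]
  f_derived <- cpp_col_freq(state$hap, as.integer(ind), as.integer(pi$cols))
  ifelse(pi$ref_derived, f_derived, 1 - f_derived)
}

#' Reference-allele dosage matrix of a panel
#'
#' @inheritParams panel_freq
#' @return numeric matrix, individuals x panel loci, entries 0/1/2 counted
#'   on the panel's reference allele
#' @export
panel_dosage <- function(state, tracked, panel, ind = seq_len(state$n)) {
  pi <- tracked$panels[[panel]]
  t(cpp_dosage_coded(state$hap, as.integer(ind), as.integer(pi$cols),
                     pi$ref_derived, pi$p0, 0L))
}

#' Base breeding population from a founder haplotype pool
#'
#' Forms generation 0 of the breeding scheme: the pool's founder gametes
#' are paired consecutively into diploid individuals, sexes are balanced at
#' random, and every gamete is labelled with its own founder-origin
#' identifier at the IBD evaluation grid (founders are mutually non-IBD by
#' definition).
#'
#' @param pool haplotype pool
#' @param tracked tracked-locus layout
#' @param seed optional integer seed
#' @return a `population_state` (generation 0)
#' @export
make_base_population <- function(pool, tracked, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- pool$n_founders
  hap <- pool$hap[tracked$sites, , drop = FALSE]
  origin <- matrix(rep(seq_len(2 * n), each = length(tracked$grid_cols)),
                   nrow = length(tracked$grid_cols))
  sex <- sample(rep(c("M", "F"), length.out = n))
  structure(list(
    gen = 0L, n = n, id = seq_len(n), sex = sex,
    sire = rep(NA_integer_, n), dam = rep(NA_integer_, n),
    role = rep("founder", n),
    hap = hap, origin = origin,
    tbv = NULL, pheno = rep(NA_real_, n),
    A = NULL  # founders unrelated: identity, represented implicitly
  ), class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population_state: generation %d, %d individuals (%d candidates)\n",
              x$gen, x$n, sum(x$role %in% c("candidate", "founder"))))
  invisible(x)
}

#' Phased individual for single-meiosis simulation
#'
#' Light container used by [meiosis()]: two phased haplotypes over a set of
#' tracked loci together with their founder-descent mosaics.
#'
#' @param h1,h2 0/1 allele vectors over the loci
#' @param pos global genetic positions of the loci (Morgans)
#' @param map a [genome_map()]
#' @param mosaic1,mosaic2 data.frames (chr, start, end, founder) tiling each
#'   chromosome; defaults label each whole haplotype as founder 1 / 2
#' @return a `phased_individual`
#' @export
phased_individual <- function(h1, h2, pos, map,
                              mosaic1 = NULL, mosaic2 = NULL) {
  stopifnot(length(h1) == length(h2), length(h1) == length(pos))
  whole <- function(f) data.frame(chr = seq_len(map$n_chr),
                                  start = 0, end = map$chr_len,
                                  founder = f)
  structure(list(h1 = h1, h2 = h2, pos = pos, map = map,
                 mosaic1 = if (is.null(mosaic1)) whole(1L) else mosaic1,
                 mosaic2 = if (is.null(mosaic2)) whole(2L) else mosaic2),
            class = "phased_individual")
}

#' Single meiosis with descent tracking
#'
#' Simulates one gamete from a phased parent: crossover counts are Poisson
#' with mean equal to the chromosome map length (no interference),
#' crossover positions are uniform, and chromosomes assort independently.
#' Returns the recombinant allele vector and the founder-descent mosaic of
#' the gamete (intervals tiling each chromosome exactly).
#'
#' @param parent a [phased_individual()]
#' @param map genome map (defaults to the parent's)
#' @param seed optional integer seed
#' @return list with `alleles` and `mosaic` (chr, start, end, founder)
#' @export
meiosis <- function(parent, map = parent$map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_chr <- map$n_chr
  alleles <- integer(length(parent$pos))
  mosaic <- vector("list", n_chr)
  for (ch in seq_len(n_chr)) {
    len <- map$chr_len[ch]
    start <- map$chr_start[ch]
    k <- rpois(1, len)
    bp <- sort(runif(k, 0, len))           # within-chromosome coords
    first <- sample(c(1L, 2L), 1)
    bounds <- c(0, bp, len)
    src <- rep(c(first, 3L - first), length.out = length(bounds) - 1)
    on_chr <- which(parent$pos >= start & parent$pos < start + len)
    if (length(on_chr)) {
      within <- parent$pos[on_chr] - start
      seg <- findInterval(within, bounds, rightmost.closed = TRUE)
      seg[seg < 1] <- 1
      from1 <- src[seg] == 1L
      alleles[on_chr] <- ifelse(from1, parent$h1[on_chr], parent$h2[on_chr])
    }
    # compose descent mosaic: intersect each copied segment with the
    # corresponding parental mosaic
    pieces <- list()
    for (s in seq_len(length(bounds) - 1)) {
      a <- bounds[s]; b <- bounds[s + 1]
      if (b <= a) next
      pm <- if (src[s] == 1L) parent$mosaic1 else parent$mosaic2
      pm <- pm[pm$chr == ch & pm$end > a & pm$start < b, , drop = FALSE]
      if (nrow(pm)) {
        pm$start <- pmax(pm$start, a)
        pm$end <- pmin(pm$end, b)
        pieces[[length(pieces) + 1]] <- pm
      }
    }
    mosaic[[ch]] <- do.call(rbind, pieces)
  }
  mosaic <- do.call(rbind, mosaic)
  rownames(mosaic) <- NULL
  list(alleles = alleles, mosaic = mosaic)
}
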