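#' Simulation constants of the base population
#'
#' Bundles the base-genome and trait constants shared by every scheme run
#' on a replicate: historical effective size 100 for 400 generations at a
#' mutation rate of 1e-8/bp on 10 x 1 Morgan chromosomes, 2000 base
#' individuals, four disjoint 7000-SNP panels, base genetic variance 1 and
#' environmental variance 1.5 (heritability 0.4).
#'
#' @param ne historical effective population size
#' @param base_generations forward generations of the base simulation
#' @param mu mutation rate per bp per generation
#' @param map a [genome_map()]
#' @param n_base number of base (generation-0) individuals
#' @param panel_size loci per panel (M, Q, N, D)
#' @param grid_step IBD evaluation-grid thinning of Panel M
#' @param sigma_g2,sigma_e2 genetic and environmental variances
#' @return a `sim_config`
#' @export
sim_config <- function(ne = 100, base_generations = 4 * ne, mu = 1e-8,
                       map = genome_map(), n_base = 2000, panel_size = 7000,
                       grid_step = 10, sigma_g2 = 1, sigma_e2 = 1.5) {
  structure(list(ne = ne, base_generations = base_generations, mu = mu,
                 map = map, n_base = n_base, panel_size = panel_size,
                 grid_step = grid_step, sigma_g2 = sigma_g2,
                 sigma_e2 = sigma_e2),
            class = "sim_config")
}

#' Shared replicate base: genomes, panels and trait
#'
#' Builds everything that must be identical across the alternative schemes
#' within one replicate: the base-population haplotype pool, the four
#' disjoint panels with their frozen generation-0 frequencies, the
#' generation-0 population and the QTL effects.
#'
#' @param seed integer replicate seed
#' @param sim a [sim_config()]
#' @return a `replicate_base`: `state0`, `tracked`, `trait`, `sim`
#' @export
replicate_base <- function(seed, sim = sim_config()) {
  set.seed(seed)
  pool <- simulate_base_genomes(ne = sim$ne, n_generations = sim$base_generations,
                                mu = sim$mu, map = sim$map,
                                n_founders = sim$n_base)
  panels <- sample_panels(pool, panel_sizes = c(M = sim$panel_size, Q = sim$panel_size,
                                                N = sim$panel_size, D = sim$panel_size))
  tracked <- tracked_loci(pool, panels, grid_step = sim$grid_step)
  state0 <- make_base_population(pool, tracked)
  rm(pool)
  qtl <- panel_dosage(state0, tracked, "Q")
  trait <- assign_qtl_effects(qtl, sigma_g2 = sim$sigma_g2, sigma_e2 = sim$sigma_e2)
  state0$tbv <- true_bv(qtl, trait)
  structure(list(state0 = state0, tracked = tracked, trait = trait, sim = sim),
            class = "replicate_base")
}

#' Breeding-scheme configuration
#'
#' One standard scheme: which relationship matrix manages
#' diversity, where the EBVs come from, and which panel the matrix is built
#' on. The scheme label follows the `Matrix(EBV panel, management panel)`
#' convention, `~` denoting random EBVs / no marker panel.
#'
#' @param matrix relationship matrix: "A", "G_VR1", "G_VR2", "G_0.5",
#'   "G_i(p)", "G_LA" or "G_ROH"
#' @param ebv "M" (SNP-BLUP on Panel M) or "random"
#' @param management_panel "M", "D", or "none" (pedigree A)
#' @param selection "goc" or "random_mating" (uniform contributions over a
#'   fixed number of randomly drawn parents; no EBVs, no constraint)
#' @param dF target rate of inbreeding per generation
#' @param n_offspring offspring born per generation
#' @param generations number of breeding generations (the first is random
#'   selection to create the sib-family structure)
#' @param n_init_per_sex parents per sex in the initial random generation
#' @param n_random_per_sex parents per sex under `selection = "random_mating"`
#' @param roh_min_mb minimum ROH length (Mb) for G_ROH
#' @return a `scheme_config`
#' @export
scheme_config <- function(matrix = "G_VR2", ebv = c("M", "random"),
                          management_panel = c("M", "D", "none"),
                          selection = c("goc", "random_mating"),
                          dF = 0.005, n_offspring = 2000, generations = 20,
                          n_init_per_sex = 100, n_random_per_sex = 50,
                          roh_min_mb = 7) {
  ebv <- match.arg(ebv)
  management_panel <- match.arg(management_panel)
  selection <- match.arg(selection)
  matrix <- match.arg(matrix, c("A", "G_VR1", "G_VR2", "G_0.5", "G_i(p)",
                                "G_LA", "G_ROH"))
  if (matrix == "A" && management_panel != "none") management_panel <- "none"
  if (matrix != "A" && management_panel == "none") {
    stop("genomic matrices need a management panel")
  }
  label <- if (selection == "random_mating") {
    sprintf("random_mating(%d+%d)", n_random_per_sex, n_random_per_sex)
  } else {
    sprintf("%s(%s,%s)", matrix, if (ebv == "M") "M" else "~",
            if (management_panel == "none") "~" else management_panel)
  }
  structure(list(matrix = matrix, ebv = ebv,
                 management_panel = management_panel, selection = selection,
                 dF = dF, n_offspring = n_offspring, generations = generations,
                 n_init_per_sex = n_init_per_sex,
                 n_random_per_sex = n_random_per_sex,
                 roh_min_mb = roh_min_mb, label = label),
            class = "scheme_config")
}

#' The nine study schemes
#'
#' @param ... overrides passed to every [scheme_config()] (e.g.
#'   `n_offspring`, `generations`)
#' @return named list of nine `scheme_config`s
#' @export
standard_schemes <- function(...) {
  mk <- function(matrix, ebv, panel) scheme_config(matrix, ebv, panel, ...)
  out <- list(
    mk("G_VR2", "M", "M"),
    mk("G_VR2", "M", "D"),
    mk("G_VR2", "random", "M"),
    mk("G_VR1", "M", "M"),
    mk("G_i(p)", "M", "M"),
    mk("G_0.5", "M", "M"),
    mk("G_ROH", "M", "M"),
    mk("G_LA", "M", "M"),
    mk("A", "M", "none")
  )
  names(out) <- vapply(out, `[[`, "", "label")
  out
}

# --- internal helpers --------------------------------------------------

# split offspring of each full-sib family into candidates and test sibs as
# evenly as possible; the odd member goes either way by a coin flip
split_roles <- function(sire, dam) {
  n <- length(sire)
  role <- character(n)
  fam <- split(seq_len(n), paste(sire, dam))
  for (f in fam) {
    m <- length(f)
    k <- m %/% 2 + (m %% 2 == 1 && runif(1) < 0.5)
    pick <- if (length(f) == 1) {
      if (k == 1) f else integer(0)
    } else {
      sample(f, k)
    }
    role[f] <- "testsib"
    role[pick] <- "candidate"
  }
  role
}

# offspring of the given matings: meiosis over tracked loci plus the new
# population_state bookkeeping (roles, sexes, TBVs, phenotypes, candidate A)
make_offspring <- function(state, base, sire, dam, gen) {
  tracked <- base$tracked
  n_off <- length(sire)
  off <- cpp_meiosis_batch(state$hap, state$origin, tracked$pos,
                           tracked$grid_pos, tracked$map$chr_start,
                           tracked$map$chr_len,
                           as.integer(sire), as.integer(dam))
  role <- split_roles(sire, dam)
  sex <- sample(rep(c("M", "F"), length.out = n_off))
  new <- structure(list(
    gen = gen, n = n_off, id = seq_len(n_off), sex = sex,
    sire = sire, dam = dam, role = role,
    hap = off$hap, origin = off$origin,
    tbv = NULL, pheno = rep(NA_real_, n_off), A = NULL
  ), class = "population_state")
  pQ <- tracked$panels$Q
  qtl <- cpp_dosage_coded(new$hap, seq_len(n_off), as.integer(pQ$cols),
                          pQ$ref_derived, pQ$p0, 0L)
  new$tbv <- true_bv(qtl, base$trait, loci_in_rows = TRUE)
  ts <- new$role == "testsib"
  new$pheno[ts] <- phenotype(new$tbv[ts], base$trait)
  # A among the new candidates from A among the previous candidates
  cand <- which(new$role == "candidate")
  if (!any(new$sex[cand] == "M") || !any(new$sex[cand] == "F")) {
    stop("candidate set lost a sex class")
  }
  prev_cand <- if (state$gen == 0) seq_len(state$n) else which(state$role == "candidate")
  A_prev <- if (is.null(state$A)) diag(length(prev_cand)) else state$A
  si <- match(sire[cand], prev_cand)
  di <- match(dam[cand], prev_cand)
  new$A <- pedigree_A_offspring(A_prev, si, di)
  new
}

#' Initial random-selection generation
#'
#' Creates the sib-family structure: `n_init_per_sex` sires and dams drawn
#' uniformly from the base population, paired monogamously at random, each
#' pair contributing an equal share of the `n_offspring` offspring; full-sib
#' families are split evenly into candidates and test sibs, and sexes are
#' balanced at random.
#'
#' @param base a [replicate_base()]
#' @param config a [scheme_config()]
#' @param seed optional integer seed
#' @return generation-1 `population_state`
#' @export
initial_random_generation <- function(base, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- base$state0
  np <- config$n_init_per_sex
  sires <- sample(which(state$sex == "M"), np)
  dams <- sample(which(state$sex == "F"), np)
  per_pair <- rep(config$n_offspring %/% np, np) +
    (seq_len(np) <= config$n_offspring %% np)
  sire <- rep(sires, per_pair)
  dam <- rep(dams, per_pair)
  make_offspring(state, base, sire, dam, gen = 1L)
}

# build (and repair) the management relationship matrix over the candidates
management_matrix <- function(state, base, config, cand) {
  tracked <- base$tracked
  pn <- config$management_panel
  G <- switch(config$matrix,
    "A" = relationship_matrix(state$A, "A", "IBD", "ibd"),
    "G_LA" = g_la(state, cand, panel = pn),
    "G_VR2" = {
      p <- tracked$panels[[pn]]
      X <- cpp_dosage_coded(state$hap, as.integer(cand), as.integer(p$cols),
                            p$ref_derived, p$p0, 2L)
      g_vr2(X, panel = pn, loci_in_rows = TRUE)
    },
    "G_VR1" = {
      p <- tracked$panels[[pn]]
      Z <- cpp_dosage_coded(state$hap, as.integer(cand), as.integer(p$cols),
                            p$ref_derived, p$p0, 1L)
      g_vr1(Z, p$p0, panel = pn, loci_in_rows = TRUE)
    },
    "G_0.5" = {
      p <- tracked$panels[[pn]]
      D <- cpp_dosage_coded(state$hap, as.integer(cand), as.integer(p$cols),
                            p$ref_derived, p$p0, 0L)
      g_05(D, panel = pn, loci_in_rows = TRUE)
    },
    "G_i(p)" = {
      p <- tracked$panels[[pn]]
      D <- cpp_dosage_coded(state$hap, as.integer(cand), as.integer(p$cols),
                            p$ref_derived, p$p0, 0L)
      g_ip(D, p$p0, panel = pn, loci_in_rows = TRUE)
    },
    "G_ROH" = {
      cols <- tracked$panels[[pn]]$cols
      g_roh(state$hap[cols, , drop = FALSE], cand, tracked$pos[cols],
            tracked$map, min_mb = config$roh_min_mb, panel = pn)
    }
  )
  make_positive_definite(G)
}

#' Advance one generation under genomic optimal contribution selection
#'
#' Pipeline: GEBVs for the candidates (SNP-BLUP trained on the current
#' generation's test sibs, or random), relationship matrix per the scheme
#' (with positive-definite repair), optimal contributions at the target
#' group coancestry `K`, then `n_offspring` matings with sires and dams
#' drawn independently with probabilities `2 c_j`, family splitting,
#' phenotyping of test sibs.
#'
#' @param state current `population_state`
#' @param base the shared [replicate_base()]
#' @param config a [scheme_config()]
#' @param K target group coancestry for this selection round (ignored under
#'   random mating)
#' @return list: `state` (next generation), `log` (one-row data.frame with
#'   parent count, achieved coancestry, objective, alpha, feasibility)
#' @export
advance_generation <- function(state, base, config, K = NA_real_) {
  cand <- which(state$role == "candidate")
  if (config$selection == "random_mating") {
    males <- cand[state$sex[cand] == "M"]
    females <- cand[state$sex[cand] == "F"]
    sires_pool <- sample(males, config$n_random_per_sex)
    dams_pool <- sample(females, config$n_random_per_sex)
    sire <- sample(sires_pool, config$n_offspring, replace = TRUE)
    dam <- sample(dams_pool, config$n_offspring, replace = TRUE)
    new <- make_offspring(state, base, sire, dam, gen = state$gen + 1L)
    log <- data.frame(generation = state$gen + 1L,
                      n_parents = 2 * config$n_random_per_sex,
                      K_target = NA_real_, K_achieved = NA_real_,
                      objective = NA_real_, alpha = 0, feasible = TRUE)
    return(list(state = new, log = log))
  }
  ghat <- if (config$ebv == "M") {
    pM <- base$tracked$panels$M
    ts <- which(state$role == "testsib")
    code_M <- function(ind) {
      cpp_dosage_coded(state$hap, as.integer(ind), as.integer(pM$cols),
                       pM$ref_derived, pM$p0, 2L)
    }
    fit <- fit_snp_blup(state$pheno[ts], code_M(ts),
                        sigma_g2 = base$sim$sigma_g2,
                        sigma_e2 = base$sim$sigma_e2, loci_in_rows = TRUE)
    predict_gebv(fit, code_M(cand), loci_in_rows = TRUE)
  } else {
    random_gebv(length(cand))
  }
  G <- management_matrix(state, base, config, cand)
  sol <- solve_oc(ghat, G, state$sex[cand], K)
  cm <- sol$c
  males <- state$sex[cand] == "M"
  sire <- sample(cand[males], config$n_offspring, replace = TRUE,
                 prob = cm[males])
  dam <- sample(cand[!males], config$n_offspring, replace = TRUE,
                prob = cm[!males])
  new <- make_offspring(state, base, sire, dam, gen = state$gen + 1L)
  log <- data.frame(generation = state$gen + 1L,
                    n_parents = count_parents(sol),
                    K_target = K, K_achieved = sol$coancestry,
                    objective = sol$objective,
                    alpha = attr(G, "alpha"), feasible = sol$feasible)
  list(state = new, log = log, G = G)
}

# diversity metrics of one generation, all panels, all individuals born
generation_metrics <- function(state, base) {
  panels <- intersect(c("M", "N", "D"), names(base$tracked$panels))
  do.call(rbind, lapply(panels, function(pn) {
    p0 <- base$tracked$panels[[pn]]$p0
    pt <- panel_freq(state, base$tracked, pn)
    dec <- hom_drift_decomposition(p0, pt)
    data.frame(generation = state$gen, panel = pn,
               F_hom = f_hom(p0, pt), F_drift = f_drift(p0, pt),
               cross_term = unname(dec["cross_term"]))
  }))
}

#' Run a breeding scheme for its full horizon
#'
#' Runs the sib-testing scheme: one random-selection generation to create
#' the family structure, then GOC selection to the configured horizon with
#' the group-coancestry schedule `K_t = K_{t-1} + dF (1 - K_{t-1})` anchored
#' at `K_0` = half the mean (repaired) relationship among the generation-1
#' candidates. Deterministic given the replicate base and `seed`.
#'
#' @param config a [scheme_config()]
#' @param base a [replicate_base()]
#' @param seed integer seed for all scheme-specific randomness
#' @return a `scheme_run`: `traj` (generation x panel diversity metrics),
#'   `pergen` (gain, TBV variance, parent counts, constraint bookkeeping),
#'   `state` (final generation), `config`
#' @export
run_scheme <- function(config, base, seed) {
  set.seed(seed)
  state <- initial_random_generation(base, config)
  cand <- which(state$role == "candidate")
  traj <- list(generation_metrics(base$state0, base),
               generation_metrics(state, base))
  pergen <- list(data.frame(
    generation = c(0L, 1L),
    gain = c(mean(base$state0$tbv), mean(state$tbv[cand])),
    var_tbv = c(var(base$state0$tbv), var(state$tbv)),
    n_parents = c(NA_integer_, 2L * config$n_init_per_sex),
    K_target = NA_real_, K_achieved = NA_real_,
    alpha = NA_real_, feasible = TRUE))
  Ks <- NULL
  for (g in seq(2, length.out = config$generations - 1)) {
    if (config$selection == "goc" && is.null(Ks)) {
      G1 <- management_matrix(state, base, config, cand)
      K0 <- 0.5 * mean(G1)
      Ks <- constraint_schedule(K0, config$dF, horizon = config$generations - 1)
    }
    step <- advance_generation(state, base, config,
                               K = if (is.null(Ks)) NA_real_ else Ks[g - 1])
    state <- step$state
    cand <- which(state$role == "candidate")
    traj[[length(traj) + 1]] <- generation_metrics(state, base)
    pergen[[length(pergen) + 1]] <- data.frame(
      generation = g, gain = mean(state$tbv[cand]), var_tbv = var(state$tbv),
      n_parents = step$log$n_parents, K_target = step$log$K_target,
      K_achieved = step$log$K_achieved, alpha = step$log$alpha,
      feasible = step$log$feasible)
  }
  structure(list(traj = do.call(rbind, traj),
                 pergen = do.call(rbind, pergen),
                 state = state, config = config, seed = seed),
            class = "scheme_run")
}

#' @export
print.scheme_run <- function(x, ...) {
  last <- x$pergen[nrow(x$pergen), ]
  cat(sprintf("scheme_run %s: %d generations, final gain %.3f, %s parents\n",
              x$config$label, max(x$pergen$generation), last$gain,
              ifelse(is.na(last$n_parents), "?", last$n_parents)))
  invisible(x)
}
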