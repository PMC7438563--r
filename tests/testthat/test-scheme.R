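test_that("scheme labels follow the Matrix(EBV, management) convention", {
  expect_equal(scheme_config("G_VR2", "M", "M")$label, "G_VR2(M,M)")
  expect_equal(scheme_config("G_VR2", "random", "M")$label, "G_VR2(~,M)")
  expect_equal(scheme_config("G_VR2", "M", "D")$label, "G_VR2(M,D)")
  expect_equal(scheme_config("A", "M")$label, "A(M,~)")
  expect_equal(scheme_config(selection = "random_mating",
                             n_random_per_sex = 50)$label,
               "random_mating(50+50)")
  expect_error(scheme_config("G_VR2", "M", "none"),
               "need a management panel")
})

test_that("the nine standard schemes are distinct and well named", {
  tab <- standard_schemes(n_offspring = 100, generations = 4)
  expect_length(tab, 9)
  expect_equal(anyDuplicated(names(tab)), 0L)
  expect_true("G_LA(M,M)" %in% names(tab))
  expect_true("A(M,~)" %in% names(tab))
  expect_true(all(vapply(tab, `[[`, 0, "n_offspring") == 100))
})

test_that("families split evenly into candidates and test sibs", {
  base <- toy_base()
  set.seed(81)
  st <- initial_random_generation(base, toy_scheme())
  expect_equal(st$n, 120)
  expect_equal(st$gen, 1L)
  # 20 monogamous pairs, 6 offspring each
  fam <- paste(st$sire, st$dam)
  expect_equal(length(unique(fam)), 20)
  expect_true(all(table(fam) == 6))
  for (f in unique(fam)) {
    expect_equal(sum(st$role[fam == f] == "candidate"), 3)
  }
  # sexes balanced overall
  expect_equal(sum(st$sex == "M"), 60)
  # only test sibs are phenotyped
  expect_true(all(is.na(st$pheno[st$role == "candidate"])))
  expect_true(all(!is.na(st$pheno[st$role == "testsib"])))
})

test_that("incremental pedigree A matches the tabular recursion over two generations", {
  base <- toy_base()
  set.seed(82)
  st1 <- initial_random_generation(base, toy_scheme())
  cand1 <- which(st1$role == "candidate")
  # generation 2 from explicit matings among candidates
  males <- cand1[st1$sex[cand1] == "M"]
  females <- cand1[st1$sex[cand1] == "F"]
  sire <- sample(males, 40, replace = TRUE)
  dam <- sample(females, 40, replace = TRUE)
  st2 <- gocsim:::make_offspring(st1, base, sire, dam, gen = 2L)
  cand2 <- which(st2$role == "candidate")
  # independent oracle: one flat pedigree from the (unrelated) founders
  # through both generations, run through the full tabular recursion
  n0 <- base$state0$n
  ped <- data.frame(
    id = seq_len(n0 + st1$n + st2$n),
    sire = c(rep(NA, n0), st1$sire, n0 + st2$sire),
    dam = c(rep(NA, n0), st1$dam, n0 + st2$dam))
  A_full <- unclass(pedigree_A(ped))
  idx2 <- n0 + st1$n + cand2
  expect_equal(st2$A, A_full[idx2, idx2, drop = FALSE],
               ignore_attr = TRUE)
  idx1 <- n0 + cand1
  expect_equal(st1$A, A_full[idx1, idx1, drop = FALSE], ignore_attr = TRUE)
})

test_that("a full toy scheme run hits its coancestry targets exactly", {
  base <- toy_base()
  run <- run_scheme(toy_scheme(), base, seed = 83)
  pg <- run$pergen
  expect_equal(pg$generation, 0:5)
  goc <- pg[pg$generation >= 2, ]
  expect_true(all(goc$feasible))
  expect_equal(goc$K_achieved, goc$K_target, tolerance = 1e-8)
  # the schedule itself follows K_t = K_{t-1} + dF(1 - K_{t-1})
  expect_equal(diff(goc$K_target) / (1 - goc$K_target[-nrow(goc)]),
               rep(0.005, nrow(goc) - 1), tolerance = 1e-10)
  # trajectories cover generations 0..5 on three panels
  expect_equal(sort(unique(run$traj$generation)), 0:5)
  expect_setequal(unique(run$traj$panel), c("M", "N", "D"))
  # reproducibility
  run2 <- run_scheme(toy_scheme(), base, seed = 83)
  expect_identical(run$pergen, run2$pergen)
  expect_identical(run$traj, run2$traj)
})

test_that("random-mating schemes use the configured parent numbers", {
  base <- toy_base()
  cfg <- scheme_config(selection = "random_mating", n_offspring = 120,
                       generations = 4, n_init_per_sex = 20,
                       n_random_per_sex = 10)
  run <- run_scheme(cfg, base, seed = 84)
  pg <- run$pergen
  expect_equal(pg$n_parents[pg$generation >= 2], rep(20L, 3))
  expect_true(all(is.na(pg$K_target[pg$generation >= 2])))
})

test_that("every relationship matrix choice produces a valid management matrix", {
  base <- toy_base()
  set.seed(85)
  st <- initial_random_generation(base, toy_scheme())
  cand <- which(st$role == "candidate")
  for (m in c("A", "G_VR1", "G_VR2", "G_0.5", "G_i(p)", "G_LA", "G_ROH")) {
    cfg <- toy_scheme(matrix = m)
    G <- gocsim:::management_matrix(st, base, cfg, cand)
    expect_equal(dim(unclass(G)), c(length(cand), length(cand)))
    expect_true(isSymmetric(unclass(G), tol = 1e-12))
    # positive definite after repair
    expect_true(all(diag(chol(unclass(G))) > 0))
  }
})

test_that("management matrices agree with the standalone builders", {
  base <- toy_base()
  set.seed(86)
  st <- initial_random_generation(base, toy_scheme())
  cand <- which(st$role == "candidate")
  p <- base$tracked$panels$M
  D <- panel_dosage(st, base$tracked, "M", cand)
  s <- standardize_genotypes(D, p$p0)
  for (case in list(
    list(m = "G_VR2", ref = g_vr2(s$X, panel = "M")),
    list(m = "G_VR1", ref = g_vr1(s$Z, p$p0, panel = "M")),
    list(m = "G_0.5", ref = g_05(D, panel = "M")),
    list(m = "G_i(p)", ref = g_ip(D, p$p0, panel = "M")))) {
    G <- gocsim:::management_matrix(st, base, toy_scheme(matrix = case$m), cand)
    ref <- make_positive_definite(case$ref)
    expect_equal(unclass(G), unclass(ref), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})
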