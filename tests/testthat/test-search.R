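test_that("local search is a monotone fixed-point iteration", {
  g <- candidateGrid(4)
  m <- gpModel(expKernel(3))
  obj <- jAlphaObjective(m, g, 0.75)
  d <- design(g, c(1, 6, 16))
  out <- localOptimize(d, obj, g)
  expect_gte(obj(out), obj(d))
  # the output is a rook-move local optimum: no neighbour swap improves
  for (i in seq_along(out$idx)) {
    for (y in g$neighbours[[out$idx[i]]]) {
      if (y %in% out$idx) next
      trial <- out$idx; trial[i] <- y
      expect_lte(obj(design(g, trial)), obj(out))
    }
  }
  # a local optimum is returned unchanged
  again <- localOptimize(out, obj, g)
  expect_identical(again$idx, out$idx)
})

test_that("compiled and plain-R local search agree", {
  g <- candidateGrid(5)
  m <- gpModel(expKernel(4))
  compiled <- jAlphaObjective(m, g, 0.6)
  plain <- function(des) jAlpha(des, m, 0.6)   # independent criterion route
  for (seed in 1:4) {
    d <- randomDesign(g, 4, seed)
    a <- localOptimize(d, compiled, g)
    b <- localOptimize(d, plain, g)
    expect_identical(a$idx, b$idx)
    expect_equal(compiled(a), plain(b), tolerance = 1e-10)
  }
})

test_that("annealing keeps its contracts: monotone best, cooling, reproducibility", {
  g <- candidateGrid(5)
  m <- gpModel(expKernel(4))
  obj <- jAlphaObjective(m, g, 0.75)
  cfg <- saConfig(T0 = 0.6, r = 0.93, Nmax = 300, seed = 5)
  r1 <- saOptimize(obj, g, 4, cfg)
  r2 <- saOptimize(obj, g, 4, cfg)
  expect_identical(r1$best_design$idx, r2$best_design$idx)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace$best) >= 0))
  expect_equal(r1$best_value, obj(r1$best_design), tolerance = 1e-12)
  # temperature multiplied by r exactly at rejected iterations
  tr <- r1$trace
  tprev <- c(cfg$T0, tr$temperature[-nrow(tr)])
  rejected <- !tr$accepted
  expect_equal(tr$temperature[rejected], tprev[rejected] * cfg$r,
               tolerance = 1e-14)
  expect_true(all(tr$temperature[tr$accepted] <= tprev[tr$accepted] + 1e-14))
  # starting design value is never beaten downwards
  init <- design(g, c(1, 5, 21, 25))
  r3 <- saOptimize(obj, g, 4, cfg, init = init)
  expect_gte(r3$best_value, obj(init))
})

test_that("the plain-R annealing path honours the same contracts", {
  g <- candidateGrid(4)
  m <- gpModel(expKernel(3))
  plain <- function(des) jAlpha(des, m, 0.75)
  cfg <- saConfig(T0 = 0.6, r = 0.9, Nmax = 60, seed = 17)
  r1 <- saOptimize(plain, g, 3, cfg)
  r2 <- saOptimize(plain, g, 3, cfg)
  expect_identical(r1$best_design$idx, r2$best_design$idx)
  expect_true(all(diff(r1$trace$best) >= 0))
  tr <- r1$trace
  tprev <- c(cfg$T0, tr$temperature[-nrow(tr)])
  expect_equal(tr$temperature[!tr$accepted], tprev[!tr$accepted] * cfg$r,
               tolerance = 1e-14)
})

test_that("Pareto sampling selects the EK-minimum and degenerates cleanly", {
  g <- candidateGrid(5)
  m <- gpModel(expKernel(4))
  cfg <- saConfig(Nmax = 200, seed = 3)
  ps <- paretoSampleSA(m, g, 4, c(0.5, 0.75, 1), cfg)
  vals <- vapply(ps$designs, function(d) mek(d, m, g)$value, numeric(1))
  expect_equal(ps$selected$best_value, min(vals))
  expect_equal(ps$selected$counters[["ek_evaluations"]], nrow(ps$points))
  single <- paretoSampleSA(m, g, 4, 1.0, cfg)
  expect_equal(nrow(single$points), 1L)
  sa_only <- saOptimize(jAlphaObjective(m, g, 1), g, 4,
                        saConfig(Nmax = 200, seed = 3))
  expect_identical(single$selected$best_design$idx, sa_only$best_design$idx)
})

test_that("exchange search stops at one-exchange optima and hull never costs more", {
  g <- candidateGrid(4)
  m <- gpModel(expKernel(3))
  # brute-force global EK optimum among all 3-point designs
  designs <- allDesigns(16, 3)
  vals <- apply(designs, 1, function(ix) mek(design(g, ix), m, g)$value)
  star <- design(g, designs[which.min(vals), ])
  res <- exchangeSearch(star, m, g, "front")
  expect_identical(sort(res$best_design$idx), sort(star$idx))
  expect_equal(res$counters[["iterations"]], 0)
  expect_equal(res$counters[["scans"]], 1)
  # from a poor start, both restrictions improve and hull evaluates less
  d0 <- design(g, c(1, 2, 5))
  rf <- exchangeSearch(d0, m, g, "front")
  rh <- exchangeSearch(d0, m, g, "hull")
  expect_lte(rf$best_value, mek(d0, m, g)$value)
  expect_lte(rh$trace$evaluated[1], rf$trace$evaluated[1])
  expect_lte(rh$counters[["ek_evaluations"]], rf$counters[["ek_evaluations"]])
  # the front-restricted run ends in a one-exchange local optimum
  fin <- rf$best_design$idx
  improving <- FALSE
  for (i in seq_along(fin)) for (y in setdiff(seq_len(16), fin)) {
    trial <- fin; trial[i] <- y
    if (mek(design(g, trial), m, g)$value < rf$best_value - 1e-12)
      improving <- TRUE
  }
  expect_false(improving)
})

test_that("greedy augmentation interpolates and spreads out", {
  g <- candidateGrid(7)
  m <- gpModel(expKernel(5))
  d0 <- randomDesign(g, 3, seed = 6)
  for (strat in c("S1", "S2")) {
    seqs <- greedyAugment(d0, m, g, strat, k_max = 5)
    expect_length(seqs, 6)
    for (k in 2:6) {
      added <- setdiff(seqs[[k]]$idx, seqs[[k - 1]]$idx)
      # freshly added site is interpolated: its kriging variance drops to 0
      expect_lt(krigingWeights(g$coords[added, ], seqs[[k]], m)$rho2, 1e-6)
    }
  }
  # the max kriging variance shrinks along the S1 sequence
  seqs <- greedyAugment(d0, m, g, "S1", k_max = 6)
  maxr <- vapply(seqs, function(d)
    max(mek(d, m, g, per_site = TRUE)$per_site$rho2), numeric(1))
  expect_true(all(diff(maxr) <= 1e-10))
})

test_that("the exhaustive Latin hypercube search returns the known optima", {
  d2 <- maximinLh(2, m_per_axis = 5)
  expect_equal(min(dist(d2$coords)), sqrt(2))
  d5 <- maximinLh(5, m_per_axis = 9)
  # Latin hypercube property: every level used exactly once per axis
  expect_setequal(d5$coords[, 1], (0:4) / 4)
  expect_setequal(d5$coords[, 2], (0:4) / 4)
  expect_equal(anyDuplicated(d5$coords[, 2]), 0L)
  # the classical 7-point maximin/minimax design (regression, from the
  # exhaustive 7!-permutation search; unique up to the square's symmetries)
  d7 <- maximinLh(7)
  ref <- cbind(c(0, 1, 2, 3, 4, 5, 6) / 6, c(2, 5, 0, 3, 6, 1, 4) / 6)
  expect_equal(unname(d7$coords), unname(ref), tolerance = 1e-12)
  expect_equal(min(dist(d7$coords)), sqrt(8) / 6, tolerance = 1e-12)
  expect_error(maximinLh(10), "n = 9")
})

test_that("perturbed Latin hypercubes are clamped, seeded and exact at sd 0", {
  p0 <- perturbedLhSample(7, sd = 0, seed = 42)
  expect_setequal(p0[, 1], (0:6) / 6)
  expect_setequal(p0[, 2], (0:6) / 6)
  p1 <- perturbedLhSample(7, sd = 0.3, seed = 42)
  p2 <- perturbedLhSample(7, sd = 0.3, seed = 42)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
})
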