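test_that("field evaluation interpolates and rewards larger designs", {
  g <- fxSmallGrid(5)
  m <- gpModel(expKernel(3))
  full <- design(g, seq_len(g$n_sites))
  rep_full <- fieldEval(list(full = full), m, g, n_real = 50, seed = 2)
  expect_true(all(rep_full$per_realization$E_j < 1e-16))
  sub <- design(g, c(1, 5, 13, 21, 25))
  sup <- design(g, c(1, 5, 13, 21, 25, 8, 18))
  rep2 <- fieldEval(list(sub = sub, sup = sup), m, g, n_real = 4000, seed = 4)
  mse <- rep2$summaries$max_mse
  expect_lte(mse[rep2$summaries$design == "sup"],
             mse[rep2$summaries$design == "sub"] * 1.05)
  # determinism
  rep3 <- fieldEval(list(sub = sub, sup = sup), m, g, n_real = 4000, seed = 4)
  expect_identical(rep2$summaries, rep3$summaries)
})

test_that("prediction errors at a fixed site reproduce the kriging variance", {
  g <- fxSmallGrid(5)
  m <- gpModel(expKernel(3))
  d <- design(g, c(1, 5, 13, 21, 25))
  site <- 8
  kw <- krigingWeights(g$coords[site, ], d, m)
  Y <- simulateField(g, m, 50000, seed = 10)
  err <- drop(Y[, d$idx] %*% kw$w - Y[, site])
  expect_lt(abs(mean(err^2) - m$sigma2 * kw$rho2),
            3 * sqrt(2 / 50000) * m$sigma2 * kw$rho2)
})

test_that("the random-design baseline is seeded and brackets good designs", {
  g <- candidateGrid(13)
  m <- fxModel()
  b1 <- randomBaselineStudy(m, g, n = 7, n_sets = 30, set_size = 3, seed = 5)
  b2 <- randomBaselineStudy(m, g, n = 7, n_sets = 30, set_size = 3, seed = 5)
  expect_identical(b1$minima, b2$minima)
  expect_length(b1$minima, 30)
  # on the reference grid, a Pareto-tuned design beats the large majority of
  # best-of-seven random sets (sign/level check at reduced set count)
  g25 <- fxGrid()
  tuned <- exchangeSearch(fxLh(), m, g25, "hull")$best_design
  b3 <- randomBaselineStudy(m, g25, n = 7, n_sets = 100, set_size = 7,
                            seed = 6, reference = tuned)
  expect_gt(b3$fraction_beaten, 0.9)
})

test_that("criterion scatter shows antagonism and surrogate correlation", {
  g <- candidateGrid(13)
  m <- fxModel()
  sc <- scatterStudy(m, g, n = 7, n_designs = 300, sd = 0.1, seed = 7,
                     alpha = 0.75)
  expect_lt(cor(sc$table$c_beta, sc$table$c_nu), 0)
  expect_gt(sc$rank_correlation, 0)
  # the space-filling Latin hypercube is among the worst for both orderings
  lh <- maximinLh(7, m_per_axis = 13, cands = g)
  info <- informationBundle(lh, m)
  j_lh <- 0.75 * info$log_det_beta + 0.25 * info$log_det_nu
  mek_lh <- mek(lh, m, g)$value
  expect_gt(mean(-j_lh > -sc$table$j_alpha), 0.99)
  expect_gt(mean(mek_lh > sc$table$mek), 0.99)
})

test_that("the synthetic bay grid is a valid non-convex candidate set", {
  bay <- syntheticBayCandidates()
  expect_lt(bay$n_sites, 441)                  # mask removed sites
  expect_s3_class(bay, "ekCandidates")         # constructor validated symmetry
  m <- gpModel(maternKernel(0.25), trend = "linear", sigma2 = 0.8)
  d <- randomDesign(bay, 8, seed = 1)
  expect_gt(mek(d, m, bay)$value, 0)
  # search machinery runs on the masked grid
  obj <- jAlphaObjective(m, bay, 0.8)
  out <- localOptimize(d, obj, bay)
  expect_gte(obj(out), obj(d))
})

test_that("candidate, design, model and front files round-trip", {
  tmp <- withr::local_tempdir()
  g <- candidateGrid(6)
  p_csv <- file.path(tmp, "cands.csv")
  writeCandidates(g, p_csv)
  g2 <- readCandidates(p_csv)
  expect_equal(g2$coords, g$coords, ignore_attr = TRUE)
  p_json <- file.path(tmp, "grid.json")
  jsonlite::write_json(list(type = "grid", m = 6, lo = 0, hi = 1), p_json,
                       auto_unbox = TRUE)
  g3 <- readCandidates(p_json)
  expect_equal(g3$coords, g$coords, ignore_attr = TRUE)
  d <- randomDesign(g, 4, seed = 3)
  p_des <- file.path(tmp, "design.csv")
  writeDesign(d, p_des)
  d2 <- readDesign(g, p_des)
  expect_identical(d2$idx, d$idx)
  p_yaml <- file.path(tmp, "model.yaml")
  writeLines(c("family: matern", "phi: 0.3", "kappa: 2.5", "angle: 0.2",
               "ratio: 1.5", "trend: linear", "sigma2: 2.0"), p_yaml)
  mod <- readModelSpec(p_yaml)
  expect_equal(mod$kernel$params[["phi"]], 0.3)
  expect_equal(mod$kernel$ratio, 1.5)
  expect_identical(mod$trend, "linear")
  front <- nondominatedFilter(data.frame(c_beta = rnorm(20), c_nu = rnorm(20)))
  front <- upperConvexHull(front)
  p_front <- file.path(tmp, "front.csv")
  writeFront(front, p_front)
  back <- utils::read.csv(p_front)
  expect_equal(back$c_beta, front$c_beta)
  res <- exchangeSearch(randomDesign(g, 4, seed = 9), fxModel(), g, "hull")
  p_res <- file.path(tmp, "result.json")
  writeResultJson(res, p_res)
  blob <- jsonlite::read_json(p_res, simplifyVector = TRUE)
  expect_equal(blob$best_value, res$best_value)
  expect_equal(blob$counters$ek_evaluations,
               unname(res$counters[["ek_evaluations"]]))
  info <- informationBundle(randomDesign(g, 4, seed = 2), fxModel())
  p_bundle <- file.path(tmp, "bundle.json")
  writeBundleJson(info, p_bundle)
  bj <- jsonlite::read_json(p_bundle, simplifyVector = TRUE)
  expect_equal(bj$log_det_nu, info$log_det_nu)
})
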