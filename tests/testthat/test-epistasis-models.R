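test_that("beneficial_rate follows each model's rate law", {
  dr <- model_declining_rate(mu0 = 1e-5, alpha = 20, g = 2)
  expect_equal(beneficial_rate(dr, 1), 1e-5)
  expect_equal(beneficial_rate(dr, 2), 2.5e-6)     # mu0 * w^-g
  dr0 <- model_declining_rate(mu0 = 1e-5, alpha = 20, g = 0)
  expect_equal(beneficial_rate(dr0, 0.37), 1e-5)
  expect_equal(beneficial_rate(dr0, 5), 1e-5)
  de <- model_diminishing_effects(mu = 3e-4)
  expect_equal(beneficial_rate(de, c(0.5, 1, 2)), rep(3e-4, 3))
  set.seed(1)
  fs <- model_finite_sites(mu = 2e-4)
  expect_equal(beneficial_rate(fs, 0.9), 2e-4)
  # a computed rate above 1 is an error, never clipped
  hot <- model_declining_rate(mu0 = 0.5, alpha = 20, g = 3)
  expect_error(beneficial_rate(hot, 0.05), "exceeds 1")
  expect_error(beneficial_rate(de, -1), "positive")
})

test_that("beneficial effect draws have the model's exponential law", {
  set.seed(11)
  de <- model_diminishing_effects(mu = 1e-5, alpha0 = 50, g = 0)
  parent <- genotype_class(1.7, 1L)
  s <- replicate(1e5, draw_mutant(de, parent)$w / parent$w - 1)
  se <- (1 / 50) / sqrt(1e5)
  expect_lt(abs(mean(s) - 1 / 50), 3 * se)   # Exp(alpha0), g = 0

  # alpha_w = alpha0 * w^g: mean effect 1/(alpha0 w^g)
  de1 <- model_diminishing_effects(mu = 1e-5, alpha0 = 100, g = 1)
  parent2 <- genotype_class(2, 1L)
  s2 <- replicate(1e5, draw_mutant(de1, parent2)$w / 2 - 1)
  se2 <- (1 / 200) / sqrt(1e5)
  expect_lt(abs(mean(s2) - 1 / 200), 3 * se2)

  # with g = 0 the diminishing-effects DFE is the constant DFE of the
  # declining-rate model
  dr <- model_declining_rate(mu0 = 1e-5, alpha = 50, g = 1)
  s3 <- replicate(1e4, draw_mutant(dr, parent)$w / parent$w - 1)
  ks <- suppressWarnings(stats::ks.test(sample(s, 1e4), s3))
  expect_gt(ks$p.value, 0.01)
})

test_that("finite-sites mutation uses fixed per-site effects and depletes", {
  set.seed(3)
  fs <- model_finite_sites(mu = 1e-4, L = 5, alpha = 10)
  parent <- genotype_class(1, 1L, state = integer(0))
  child <- draw_mutant(fs, parent)
  j <- child$state
  expect_length(j, 1)
  expect_equal(child$w, 1 + fs$params$site_effects[j])
  # exhausted supply: mutation is a no-op
  full <- genotype_class(2, 1L, state = 1:5)
  same <- draw_mutant(fs, full)
  expect_equal(same$w, 2)
  expect_equal(sort(same$state), 1:5)
  # fitness never exceeds founder times the full-supply product
  cap <- prod(1 + fs$params$site_effects)
  w <- 1
  st <- integer(0)
  for (k in 1:10) {
    cl <- draw_mutant(fs, genotype_class(w, 1L, state = st))
    w <- cl$w
    st <- cl$state
  }
  expect_lte(w, cap + 1e-12)
})

test_that("FGM fitness is Gaussian in distance with optimum at 1", {
  expect_equal(fgm_fitness(rep(0, 10)), 1)
  expect_equal(fgm_fitness(c(1, rep(0, 9))), exp(-1 / 2))
  z <- matrix(rnorm(30), nrow = 3)
  expect_equal(fgm_fitness(z), exp(-rowSums(z^2) / 2))
  fgm <- model_fgm(n = 4, sigma = 0.1)
  set.seed(5)
  kids <- replicate(2000, draw_mutant(fgm, founder_at_fitness(fgm, 1))$w)
  expect_true(all(kids <= 1))
})

test_that("FGM mean mutant fitness matches the closed-form oracle", {
  fgm <- model_fgm(mu = 1e-5, n = 10, sigma = 0.05)
  parent <- founder_at_fitness(fgm, 0.6)
  set.seed(21)
  draws <- replicate(2e4, draw_mutant(fgm, parent)$w)
  expected <- fgm_expected_mutant_fitness(parent$state, 0.05)
  expect_lt(abs(mean(draws) / expected - 1), 0.01)
})

test_that("founder_at_fitness inverts each model's fitness assignment", {
  fgm <- model_fgm(n = 6)
  expect_equal(founder_at_fitness(fgm, 1)$state, rep(0, 6))
  f <- founder_at_fitness(fgm, exp(-1 / 2))
  expect_equal(sqrt(sum(f$state^2)), 1)            # d = 1
  for (w0 in c(0.999, 0.9, 0.5, 0.1))
    expect_equal(founder_at_fitness(fgm, w0)$w, w0, tolerance = 1e-12)
  expect_error(founder_at_fitness(fgm, 1.1), "cannot exceed 1")
  set.seed(2)
  fs <- model_finite_sites(L = 10)
  f2 <- founder_at_fitness(fs, 0.8)
  expect_equal(f2$w, 0.8)
  expect_length(f2$state, 0)
  de <- model_diminishing_effects()
  expect_equal(founder_at_fitness(de, 0.33)$w, 0.33)
  expect_error(founder_at_fitness(de, 0), "positive")
})

test_that("founder ladders climb in fitness; finite-sites rungs deplete", {
  defs <- seq(5e-3, 0, length.out = 6)
  for (m in list(model_diminishing_effects(), model_declining_rate())) {
    lad <- founder_ladder(m, defs, generations = 500, w_top = 1)
    w <- vapply(lad, function(cl) cl$w, numeric(1))
    expect_equal(w, exp(-defs * 500), tolerance = 1e-12)
  }
  fgm <- model_fgm(n = 10)
  ladf <- founder_ladder(fgm, defs, generations = 500, w_top = 0.9)
  wf <- vapply(ladf, function(cl) cl$w, numeric(1))
  expect_equal(wf, 0.9 * exp(-defs * 500), tolerance = 1e-12)

  set.seed(8)
  fs <- model_finite_sites(L = 200, alpha = 20)
  lads <- founder_ladder(fs, defs, generations = 500, w_top = 1)
  ws <- vapply(lads, function(cl) cl$w, numeric(1))
  nmut <- vapply(lads, function(cl) length(cl$state), numeric(1))
  expect_true(all(diff(ws) >= 0))        # ordered least to most fit
  expect_true(all(diff(nmut) >= 0))      # fitter rungs used more sites
  expect_equal(nmut[1], 0)               # base rung has full supply
  # realised fitness reaches each target (L = 200 gives ample supply)
  expect_true(all(ws >= exp(-defs * 500) - 1e-12))
})
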