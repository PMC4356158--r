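test_that("noise-free power-law data are recovered exactly", {
  x <- -exp(seq(log(2e-4), log(5e-3), length.out = 12))
  pts <- powerlaw_points(x, a = 0.5, b = 0.87)
  fit <- fit_loglog(pts)
  expect_equal(fit$slope, 0.87, tolerance = 1e-9)
  expect_equal(fit$beta, 0.87, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$r^2, fit$r_squared, tolerance = 1e-12)
  expect_lt(fit$f_pvalue, 1e-12)
  expect_equal(fit$n_used, 12)
})

test_that("reference and non-positive-gain points are excluded and logged", {
  x <- -exp(seq(log(1e-3), log(5e-3), length.out = 6))
  pts <- powerlaw_points(x, a = 0, b = 0.8)
  with_ref <- rbind(pts,
                    data.frame(genotype_id = "reference", x = 0, y = 0,
                               reference_flag = TRUE))
  fit0 <- fit_loglog(pts)
  fit1 <- fit_loglog(with_ref)
  expect_equal(fit1$slope, fit0$slope)
  expect_equal(fit1$n_used, fit0$n_used)
  expect_equal(nrow(fit1$excluded), 1)
  expect_identical(fit1$excluded$genotype_id, "reference")
  expect_match(fit1$excluded$reason, "x = 0")

  neg <- with_ref
  neg$y[2] <- -neg$y[2]
  fit2 <- fit_loglog(neg)
  expect_equal(fit2$n_used, 5)
  expect_setequal(fit2$excluded$genotype_id,
                  c("reference", neg$genotype_id[2]))
  expect_equal(fit2$n_used + nrow(fit2$excluded), nrow(neg))

  # exponential form keeps x = 0 eligible but still drops y <= 0
  expfit <- fit_exponential(with_ref)
  expect_equal(expfit$n_used, 6)
  expect_identical(expfit$excluded$genotype_id, "reference")
  expect_match(expfit$excluded$reason, "y <= 0")
})

test_that("too few eligible points is an explicit error", {
  x <- c(-1e-3, -2e-3)
  pts <- powerlaw_points(x, a = 0, b = 1)
  expect_error(fit_loglog(pts), "insufficient data")
  flat <- data.frame(genotype_id = c("a", "b", "c"),
                     x = c(0, 0, 0), y = c(0, 0, 0),
                     reference_flag = FALSE)
  expect_error(fit_loglog(flat), "insufficient data")
})

test_that("exponential fit recovers ln-linear data and flat slopes", {
  x <- seq(-5e-3, -5e-4, length.out = 10)
  pts <- data.frame(genotype_id = letters[1:10], x = x,
                    y = exp(-1 + 200 * x), reference_flag = FALSE)
  fit <- fit_exponential(pts)
  expect_equal(fit$slope, 200, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  flat <- data.frame(genotype_id = letters[1:5],
                     x = seq(-5e-3, -1e-3, length.out = 5),
                     y = 0.02, reference_flag = FALSE)
  expect_equal(fit_exponential(flat)$slope, 0, tolerance = 1e-12)
})

test_that("model discrimination prefers the generating form", {
  set.seed(31)
  x <- -exp(seq(log(1e-4), log(1e-2), length.out = 40))  # wide range
  ll_pts <- powerlaw_points(x, a = 0, b = 0.8)
  cmp <- compare_fits(ll_pts)
  expect_identical(cmp$preferred, "loglog")
  expect_lt(cmp$exponential$r_squared, cmp$loglog$r_squared)

  ex_pts <- data.frame(genotype_id = sprintf("e%02d", seq_along(x)),
                       x = x, y = exp(1 + 300 * x),
                       reference_flag = FALSE)
  cmp2 <- compare_fits(ex_pts)
  expect_identical(cmp2$preferred, "exponential")
})

test_that("an exact tie is broken toward loglog and flagged", {
  # two coincident points plus one: both forms interpolate exactly
  pts <- data.frame(genotype_id = c("a", "b", "c"),
                    x = c(-1, -1, -2),
                    y = c(exp(1), exp(1), exp(2)),
                    reference_flag = FALSE)
  cmp <- compare_fits(pts)
  expect_equal(cmp$loglog$r_squared, 1, tolerance = 1e-12)
  expect_equal(cmp$exponential$r_squared, 1, tolerance = 1e-12)
  expect_identical(cmp$preferred, "loglog")
  expect_true(cmp$tie)
})

test_that("slope and r^2 are invariant to rescaling fitness values", {
  rec <- generate_collection(32, c(5e-4, 5e-3), true_beta = 0.7,
                             noise_sd = 0.1, generations = 500,
                             seed = 12)
  fit0 <- fit_loglog(standardize(rec))
  scaled <- rec
  scaled$w_start <- rec$w_start * 5.3
  scaled$w_final <- rec$w_final * 5.3
  fit1 <- fit_loglog(standardize(scaled))
  expect_equal(fit1$slope, fit0$slope, tolerance = 1e-12)
  expect_equal(fit1$r_squared, fit0$r_squared, tolerance = 1e-12)
})

test_that("noisy synthetic collections recover the generating slope", {
  set.seed(32)
  slopes <- vapply(1:50, function(s) {
    rec <- generate_collection(64, c(5e-4, 5e-3), true_beta = 0.8,
                               noise_sd = 0.2, generations = 500,
                               seed = 5000 + s)
    fit_loglog(standardize(rec))$slope
  }, numeric(1))
  expect_gt(mean(abs(slopes - 0.8) <= 0.1), 0.9)
  expect_lt(abs(mean(slopes) - 0.8), 0.05)
})

test_that("regression reports serialise to JSON with exclusions", {
  x <- -exp(seq(log(1e-3), log(5e-3), length.out = 8))
  pts <- rbind(powerlaw_points(x, a = 0, b = 0.9),
               data.frame(genotype_id = "reference", x = 0, y = 0,
                          reference_flag = TRUE))
  path <- withr::local_tempfile(fileext = ".json")
  write_regression_report(compare_fits(pts), path)
  back <- jsonlite::read_json(path)
  expect_equal(back$loglog$slope, 0.9, tolerance = 1e-9)
  expect_identical(back$loglog$excluded[[1]]$genotype_id, "reference")
  expect_identical(back$preferred, "loglog")
})
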