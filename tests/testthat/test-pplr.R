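test_that("posterior mean and variance follow the precision-weighted algebra", {
  # effectively fixed lambda = 0 via a degenerate search interval
  near_zero <- c(0, 1e-14)
  m1 <- fit_molecule_model(list(A = c(1, 3)), list(A = c(0.5, 0.5)),
                           lambda_bounds = near_zero)
  expect_equal(unname(m1$m["A"]), 2, tolerance = 1e-10)
  expect_equal(unname(m1$v["A"]), 0.25, tolerance = 1e-10)

  m2 <- fit_molecule_model(list(A = c(0, 3)), list(A = c(1, 2)),
                           lambda_bounds = near_zero)
  expect_equal(unname(m2$m["A"]), 1, tolerance = 1e-8)
  expect_equal(unname(m2$v["A"]), 2 / 3, tolerance = 1e-8)

  # random instances at the fitted lambda, against the closed form
  set.seed(123)
  for (r in 1:25) {
    sim <- sim_molecule(sample(2:6, 1), mu = rnorm(2, 8), lambda = runif(1, 0, 1),
                        nu_range = c(0.05, 0.5), seed = 1000 + r)
    model <- fit_molecule_model(sim$y, sim$nu)
    for (ci in names(sim$y)) {
      w <- 1 / (model$lambda_hat + sim$nu[[ci]] + 1e-12)
      expect_equal(unname(model$m[ci]), sum(w * sim$y[[ci]]) / sum(w),
                   tolerance = 1e-10)
      expect_equal(unname(model$v[ci]), 1 / sum(w), tolerance = 1e-10)
    }
  }
})

test_that("with nu = 0 and free lambda the posterior mean is the sample mean", {
  set.seed(9)
  y <- list(A = rnorm(6, 5), B = rnorm(4, 7))
  nu <- list(A = rep(0, 6), B = rep(0, 4))
  model <- fit_molecule_model(y, nu)
  expect_equal(unname(model$m["A"]), mean(y$A), tolerance = 1e-9)
  expect_equal(unname(model$m["B"]), mean(y$B), tolerance = 1e-9)
})

test_that("lambda estimate matches a dense grid-search oracle", {
  set.seed(77)
  for (r in 1:30) {
    sim <- sim_molecule(sample(3:8, 1), mu = rnorm(2, 8),
                        lambda = runif(1, 0.05, 1.5),
                        nu_range = c(0.02, 0.4), seed = 2000 + r)
    model <- fit_molecule_model(sim$y, sim$nu)
    oracle <- lambda_grid_oracle(sim$y, sim$nu)
    expect_lt(abs(model$lambda_hat - oracle$lambda), 2 * oracle$step + 1e-6)
  }
})

test_that("lambda is recovered on data simulated from the model", {
  sim <- sim_molecule(50, mu = c(0, 1), lambda = 0.5,
                      nu_range = c(0.05, 0.2), seed = 11)
  model <- fit_molecule_model(sim$y, sim$nu)
  expect_lt(abs(model$lambda_hat - 0.5), 0.15)
  expect_true(is.finite(model$loglik))
})

test_that("PPLR is the normal probability of a positive contrast", {
  model <- structure(list(lambda_hat = 0.1,
                          m = c(A = 1, B = 0), v = c(A = 0.5, B = 0.5)),
                     class = "molecule_model")
  sc <- pplr_score(model, "A", "B")
  expect_equal(sc$pplr, pnorm(1 / sqrt(1)))
  expect_equal(sc$log_fc, 1)

  # equal means: exactly one half
  model$m <- c(A = 2, B = 2)
  sc <- pplr_score(model, "A", "B")
  expect_equal(sc$pplr, 0.5)
  expect_equal(sc$significance, 0)

  # contrast of one posterior SD: Phi(1)
  model$m <- c(A = 1, B = 0); model$v <- c(A = 0.3, B = 0.7)
  expect_equal(pplr_score(model, "A", "B")$pplr, pnorm(1),
               tolerance = 1e-12)

  # degenerate zero-variance limit
  model$v <- c(A = 0, B = 0)
  expect_equal(pplr_score(model, "A", "B")$pplr, 1)
  expect_true(pplr_score(model, "A", "B")$degenerate)
})

test_that("PPLR antisymmetry is exact and monotone in the contrast", {
  set.seed(21)
  for (r in 1:50) {
    model <- structure(list(m = c(A = rnorm(1), B = rnorm(1)),
                            v = c(A = runif(1, .01, 2), B = runif(1, .01, 2))),
                       class = "molecule_model")
    ab <- pplr_score(model, "A", "B")$pplr
    ba <- pplr_score(model, "B", "A")$pplr
    expect_identical(ab + ba, 1)
  }
  v <- c(A = 0.4, B = 0.6)
  p <- vapply(seq(-2, 2, by = 0.25), function(d) {
    pplr_score(structure(list(m = c(A = d, B = 0), v = v),
                         class = "molecule_model"), "A", "B")$pplr
  }, numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("PPLR matches a Monte-Carlo posterior draw oracle", {
  set.seed(314)
  m <- c(A = 1, B = 0); v <- c(A = 0.5, B = 0.5)
  draws <- rnorm(1e6, m["A"], sqrt(v["A"])) - rnorm(1e6, m["B"], sqrt(v["B"]))
  mc <- mean(draws > 0)
  sc <- pplr_score(structure(list(m = m, v = v), class = "molecule_model"),
                   "A", "B")
  expect_lt(abs(sc$pplr - mc), 0.005)
})

test_that("ranking orders by significance with deterministic tie-breaks", {
  res <- data.frame(molecule_id = c("mA", "mB", "mC"),
                    pplr = c(0.99, 0.50, 0.01),
                    pplr_significance = c(0.49, 0.0, 0.49),
                    log_fc = c(1.0, 0.0, -2.0), stringsAsFactors = FALSE)
  ranked <- rank_by_pplr(res)
  # 0.99 and 0.01 tie on significance; |lfc| 2 beats 1
  expect_equal(ranked$molecule_id, c("mC", "mA", "mB"))
  expect_equal(ranked$rank, 1:3)
  single <- rank_by_pplr(res[2, ])
  expect_equal(single$rank, 1L)
})

test_that("pplr_analysis scores every testable molecule of a dataset", {
  sim <- generate_dataset(p = 40, n_bio = 4, n_tech = 3, frac_de = 0.25,
                          delta = 2, seed = 5)
  ds <- validate_dataset(sim$table, sim$design)
  summ <- summarize_technical(ds, "mean")
  res <- pplr_analysis(summ, "c1", "c2")
  expect_equal(nrow(res), 40L)
  expect_true(all(res$pplr >= 0 & res$pplr <= 1))
  expect_true(all(res$pplr_significance >= 0 & res$pplr_significance <= 0.5))
  expect_true(all(res$lambda_hat >= 0))
  expect_error(pplr_analysis(summ, "c1", "c9"), "available")
})
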