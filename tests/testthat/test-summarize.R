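test_that("technical summarization gives the variance of the point estimate", {
  vals <- toy_values()
  vals[1, 1:3] <- c(2, 4, 6)   # mean 4, unbiased var 4, nu = 4/3
  vals[2, 1:3] <- c(5, 5, 5)   # zero variance
  ds <- validate_dataset(intensity_table(vals), toy_design())
  summ <- summarize_technical(ds, "mean")
  expect_equal(summ$y["m1", "A.b1"], 4)
  expect_equal(summ$nu["m1", "A.b1"], 4 / 3)
  expect_equal(summ$y["m2", "A.b1"], 5)
  expect_equal(summ$nu["m2", "A.b1"], 0)
  expect_true(all(summ$nu >= 0))
  expect_true(all(summ$nu_source == "observed"))
})

test_that("single-replicate samples fall back to pooled technical variance", {
  vals <- matrix(c(1, 2, 3, 3.1, 4, 5, 6, 2.0,
                   1, 1, 1, 9.9, 2, 2, 2, 8.8), nrow = 2, byrow = TRUE,
                 dimnames = list(c("m1", "m2"),
                                 c("A_b1_t1", "A_b1_t2", "A_b1_t3", "A_b2_t1",
                                   "B_b1_t1", "B_b1_t2", "B_b1_t3", "B_b2_t1")))
  design <- replicate_design(
    colnames(vals),
    condition = rep(c("A", "B"), each = 4),
    bio_rep = rep(c("b1", "b1", "b1", "b2"), 2),
    tech_rep = rep(c("t1", "t2", "t3", "t1"), 2))
  ds <- validate_dataset(intensity_table(vals), design)
  summ <- summarize_technical(ds, "mean")
  expect_equal(summ$y["m1", "A.b2"], 3.1)
  # molecule m1's observed nu values: var(1:3)/3 = 1/3 and var(4:6)/3 = 1/3
  expect_equal(summ$nu["m1", "A.b2"], 1 / 3)
  expect_equal(summ$nu_source["m1", "A.b2"], "pooled_molecule")
  expect_equal(summ$n_tech["m1", "A.b2"], 1L)
})

test_that("a molecule with no observed variance uses the global pooled nu", {
  # m2 has a single replicate everywhere -> global median of observed nu
  vals <- matrix(c(1, 3, 2, 6, 10, 8,
                   5, NA, NA, 7, NA, NA), nrow = 2, byrow = TRUE,
                 dimnames = list(c("m1", "m2"),
                                 c("A_b1_t1", "A_b1_t2", "A_b1_t3",
                                   "B_b1_t1", "B_b1_t2", "B_b1_t3")))
  ds <- validate_dataset(intensity_table(vals), toy_design())
  summ <- summarize_technical(ds, "mean")
  obs <- summ$nu[1, ]                      # m1: var(1,3,2)/3 = 1/3, var(6,10,8)/3 = 4/3
  expect_equal(unname(obs), c(1 / 3, 4 / 3))
  expect_equal(unname(summ$nu[2, ]), rep(stats::median(obs), 2))
  expect_true(all(summ$nu_source[2, ] == "pooled_global"))
})

test_that("summarization methods behave as documented", {
  set.seed(31)
  vals <- matrix(rnorm(5 * 12, 8), nrow = 5,
                 dimnames = list(paste0("m", 1:5), paste0("r", 1:12)))
  design <- replicate_design(paste0("r", 1:12),
                             condition = rep(c("A", "B"), each = 6),
                             bio_rep = rep(rep(c("b1", "b2"), each = 3), 2),
                             tech_rep = rep(c("t1", "t2", "t3"), 4))
  ds <- validate_dataset(intensity_table(vals), design)
  # trimmed_mean with trim = 0 equals mean exactly
  s_mean <- summarize_technical(ds, "mean")
  s_trim0 <- summarize_technical(ds, "trimmed_mean", trim = 0)
  expect_equal(s_trim0$y, s_mean$y)
  expect_equal(s_trim0$nu, s_mean$nu)
  # nu equals brute-force unbiased variance over n
  for (g in 1:5) for (s in seq_len(nrow(s_mean$samples))) {
    runs <- ds$groups[[s_mean$samples$condition[s]]][[s_mean$samples$bio_rep[s]]]
    v <- vals[g, runs]
    expect_equal(s_mean$nu[g, s], sum((v - mean(v))^2) / (length(v) - 1) / length(v))
  }
  # mean summarization commutes with per-run additive offsets (y only; the
  # within-sample variance legitimately changes when offsets differ per run)
  norm <- median_scale(ds$table)
  s_norm <- summarize_technical(validate_dataset(norm$table, design), "mean")
  for (s in seq_len(nrow(s_mean$samples))) {
    runs <- ds$groups[[s_mean$samples$condition[s]]][[s_mean$samples$bio_rep[s]]]
    expect_equal(s_norm$y[, s], s_mean$y[, s] + mean(norm$record$offsets[runs]))
  }
})

test_that("whisker data reports sample means and raw replicate SD", {
  vals <- toy_values()
  vals[3, 4:5] <- c(1, 3)
  vals[3, 6] <- NA
  ds <- validate_dataset(intensity_table(vals), toy_design())
  wd <- whisker_data(ds, "m3")
  expect_equal(nrow(wd), 2L)
  expect_equal(wd$technical_error[wd$condition == "B"], sqrt(2))
  expect_equal(wd$estimate[wd$condition == "B"], 2)
  # identical replicates give zero technical error
  wd2 <- whisker_data(ds, "m2")
  expect_equal(wd2$technical_error, c(0, 0))
  expect_error(whisker_data(ds, "nope"), "unknown molecule")
})

test_that("molecules absent from a whole condition are excluded with warning", {
  vals <- toy_values()
  vals[1, 4:6] <- NA
  ds <- validate_dataset(intensity_table(vals), toy_design())
  expect_warning(summ <- summarize_technical(ds, "mean"), "m1")
  expect_equal(summ$excluded, "m1")
})
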