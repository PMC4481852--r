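test_that("UPGMA merges follow the hand-computed example", {
  D <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3, 3)
  dg <- average_linkage(D)
  expect_equal(nrow(dg$merges), 2L)
  expect_equal(dg$merges$cluster_a, c(1L, 3L))
  expect_equal(dg$merges$cluster_b, c(2L, 4L))
  expect_equal(dg$merges$height, c(1, 4.5))
  expect_equal(sort(dg$leaf_order), 1:3)

  two <- average_linkage(matrix(c(0, 3, 3, 0), 2, 2))
  expect_equal(two$merges$height, 3)

  expect_error(average_linkage(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(average_linkage(matrix(c(0, -1, -1, 0), 2, 2)), "non-negative")
})

test_that("UPGMA matches the brute-force re-scan oracle on random matrices", {
  set.seed(404)
  for (r in 1:60) {
    n <- sample(4:9, 1)
    M <- matrix(runif(n * n, 0.1, 10), n, n)
    D <- (M + t(M)) / 2; diag(D) <- 0
    got <- average_linkage(D)$merges
    want <- upgma_oracle(D)
    expect_equal(got$cluster_a, want$cluster_a)
    expect_equal(got$cluster_b, want$cluster_b)
    expect_equal(got$height, want$height, tolerance = 1e-12)
    expect_equal(got$size, want$size)
  }
})

test_that("UPGMA heights agree with stats::hclust average linkage", {
  set.seed(42)
  n <- 12
  X <- matrix(rnorm(n * 5), n, 5)
  D <- as.matrix(dist(X))
  got <- average_linkage(D)
  ref <- hclust(dist(X), method = "average")
  expect_equal(sort(got$merges$height), sort(ref$height), tolerance = 1e-10)
})

test_that("UPGMA is permutation-equivariant", {
  set.seed(77)
  n <- 7
  M <- matrix(runif(n * n, 0.5, 5), n, n); D <- (M + t(M)) / 2; diag(D) <- 0
  perm <- sample(n)
  a <- average_linkage(D)
  b <- average_linkage(D[perm, perm])
  # merge heights are a permutation-invariant of the dendrogram
  expect_equal(sort(a$merges$height), sort(b$merges$height), tolerance = 1e-12)
  # leaves of the permuted problem map back to the original leaves
  expect_equal(sort(perm[b$leaf_order]), 1:n)
})

test_that("heatmap selects the ranking head and standardizes rows", {
  set.seed(3)
  y <- matrix(rnorm(8 * 6, 8), 8, 6,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:6)))
  y[1, ] <- c(10, 10, 10, 2, 2, 2)   # block structure
  y[2, ] <- c(2, 2, 2, 10, 10, 10)
  y[3, ] <- 5                        # zero variance row
  summ <- make_summ(y, matrix(0.1, 8, 6), rep(c("A", "B"), each = 3))
  ranking <- data.frame(molecule_id = paste0("g", 1:8),
                        pplr_significance = seq(0.5, 0.1, length.out = 8),
                        stringsAsFactors = FALSE)
  hm <- heatmap_matrix(summ, ranking, top_n = 4)
  expect_equal(rownames(hm$matrix), paste0("g", 1:4))
  expect_equal(hm$flat_rows, "g3")
  expect_true(all(hm$matrix["g3", ] == 0))
  expect_equal(unname(rowMeans(hm$matrix[c("g1", "g2"), ])), c(0, 0))
  # opposite-sign block rows end up on different sides of the top merge
  mg <- hm$row_dendrogram$merges
  members <- as.list(seq_len(4))
  for (s in seq_len(nrow(mg)))
    members[[4 + s]] <- c(members[[mg$cluster_a[s]]], members[[mg$cluster_b[s]]])
  left <- members[[mg$cluster_a[nrow(mg)]]]
  expect_true(xor(1 %in% left, 2 %in% left))
  expect_warning(heatmap_matrix(summ, ranking, top_n = 20), "available")
  expect_error(heatmap_matrix(summ, ranking, top_n = 1), "top_n")
})

test_that("report rendering writes the full artifact set", {
  sim <- generate_dataset(p = 30, n_bio = 3, n_tech = 2, seed = 12)
  ds <- validate_dataset(sim$table, sim$design)
  summ <- summarize_technical(ds, "mean")
  pp <- pplr_analysis(summ, "c1", "c2")
  eb <- moderated_t_test(summ, NULL, "c1", "c2")
  ranking <- ranking_table(pp, eb)
  hm <- heatmap_matrix(summ, ranking, top_n = 5)
  fit <- fit_noise_pca(summ$y, summ$nu, k = 2)
  sc <- pca_scores(fit, 2)
  sc$condition <- summ$samples$condition[match(sc$sample_id,
                                               summ$samples$sample_id)]
  wd <- list(m1 = whisker_data(ds, ranking$molecule_id[1]))
  names(wd) <- ranking$molecule_id[1]
  out <- withr::local_tempdir()
  files <- render_report(ranking, wd, sc, hm, out)
  expect_true(file.exists(file.path(out, "index.html")))
  expect_gte(length(setdiff(basename(files), "index.html")), 4L)
  # no whiskers requested still yields a valid report
  out2 <- withr::local_tempdir()
  render_report(ranking, list(), sc, hm, out2)
  expect_true(file.exists(file.path(out2, "index.html")))
  expect_false(any(grepl("whisker", list.files(out2))))
})

test_that("ranking table combines both tracks with linear fold changes", {
  sim <- generate_dataset(p = 25, n_bio = 3, n_tech = 3, seed = 9)
  summ <- summarize_technical(validate_dataset(sim$table, sim$design), "mean")
  pp <- pplr_analysis(summ, "c1", "c2")
  eb <- moderated_t_test(summ, NULL, "c1", "c2")
  rt <- ranking_table(pp, eb, log_base = 2)
  expect_equal(names(rt), c("molecule_id", "pplr", "pplr_significance",
                            "log_fc", "fold_change", "t_moderated",
                            "p_value", "fdr_bh", "rank"))
  expect_equal(rt$fold_change, 2^rt$log_fc)
  expect_true(all(diff(rt$pplr_significance) <= 0))
  expect_true(all(rt$fdr_bh >= rt$p_value - 1e-15))
})
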