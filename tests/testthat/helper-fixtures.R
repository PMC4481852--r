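# shared fixtures and independent brute-force oracles

toy_values <- function() {
  m <- matrix(c(1, 2, 3, 2, 3, 4,
                5, 5, 5, 8, 8, 8,
                2, 4, 6, 1, 1, 1), nrow = 3, byrow = TRUE)
  dimnames(m) <- list(c("m1", "m2", "m3"),
                      c("A_b1_t1", "A_b1_t2", "A_b1_t3",
                        "B_b1_t1", "B_b1_t2", "B_b1_t3"))
  m
}

toy_design <- function() {
  replicate_design(
    run_id = c("A_b1_t1", "A_b1_t2", "A_b1_t3",
               "B_b1_t1", "B_b1_t2", "B_b1_t3"),
    condition = rep(c("A", "B"), each = 3),
    bio_rep = rep("b1", 6),
    tech_rep = rep(c("t1", "t2", "t3"), 2))
}

write_matrix_tsv <- function(values, path) {
  df <- data.frame(molecule_id = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# build a summarized_dataset directly from y / nu matrices
make_summ <- function(y, nu, conditions, n_tech = 3L) {
  stopifnot(ncol(y) == length(conditions))
  ids <- rownames(y)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(y)))
  sample_ids <- colnames(y)
  if (is.null(sample_ids))
    sample_ids <- paste(conditions, ave(conditions, conditions,
                                        FUN = seq_along), sep = ".")
  dimnames(y) <- dimnames(nu) <- list(ids, sample_ids)
  structure(list(
    molecule_ids = ids,
    samples = data.frame(sample_id = sample_ids, condition = conditions,
                         bio_rep = as.character(seq_along(conditions)),
                         stringsAsFactors = FALSE),
    y = y, nu = nu,
    n_tech = matrix(n_tech, nrow(y), ncol(y), dimnames = dimnames(y)),
    nu_source = matrix("observed", nrow(y), ncol(y), dimnames = dimnames(y)),
    method = "mean", trim = NULL, excluded = character(0)),
    class = "summarized_dataset")
}

# Benjamini-Hochberg step-up, written straight from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in rev(seq_len(n))) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# UPGMA by O(n^3) re-scan over leaf members, independent of the implementation
upgma_oracle <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  ids <- seq_len(n)
  merges <- data.frame(cluster_a = integer(0), cluster_b = integer(0),
                       height = numeric(0), size = integer(0))
  for (s in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- NULL; best_key <- c(Inf, Inf, Inf)
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      dd <- mean(D[clusters[[a]], clusters[[b]]])
      key <- c(dd, min(ids[a], ids[b]), max(ids[a], ids[b]))
      if (key[1] < best_key[1] ||
          (key[1] == best_key[1] && (key[2] < best_key[2] ||
            (key[2] == best_key[2] && key[3] < best_key[3])))) {
        best <- c(a, b); best_key <- key
      }
    }
    merges <- rbind(merges, data.frame(
      cluster_a = best_key[2], cluster_b = best_key[3], height = best_key[1],
      size = length(clusters[[best[1]]]) + length(clusters[[best[2]]])))
    clusters <- c(clusters[-best],
                  list(c(clusters[[best[1]]], clusters[[best[2]]])))
    ids <- c(ids[-best], n + s)
  }
  merges
}

# AUC by explicit pair counting
auc_oracle <- function(score, flag) {
  pos <- score[flag]; neg <- score[!flag]
  tot <- 0
  for (x in pos) tot <- tot + sum(x > neg) + 0.5 * sum(x == neg)
  tot / (length(pos) * length(neg))
}

# profile-likelihood grid search for lambda, refined twice around the optimum
lambda_grid_oracle <- function(y, nu, lo = 0, hi = NULL, n_grid = 1000L) {
  if (is.null(hi)) hi <- max(1, 10 * max(vapply(y, function(v)
    if (length(v) >= 2) stats::var(v) else 0, numeric(1))))
  ll <- function(lambda) {
    tot <- 0
    for (ci in names(y)) {
      w <- 1 / (lambda + nu[[ci]] + 1e-12)
      m <- sum(w * y[[ci]]) / sum(w)
      tot <- tot + 0.5 * sum(log(w)) - 0.5 * log(sum(w)) -
        0.5 * sum(w * (y[[ci]] - m)^2)
    }
    tot
  }
  for (r in 1:3) {
    grid <- seq(lo, hi, length.out = n_grid)
    vals <- vapply(grid, ll, numeric(1))
    i <- which.max(vals)
    step <- grid[2] - grid[1]
    lo <- max(0, grid[i] - step); hi <- grid[i] + step
  }
  list(lambda = grid[i], step = step)
}

# simulate one molecule from the hierarchical measurement-error model
sim_molecule <- function(n_per_cond, mu, lambda, nu_range, seed) {
  set.seed(seed)
  y <- nu <- list()
  for (i in seq_along(mu)) {
    nm <- paste0("c", i)
    nu[[nm]] <- runif(n_per_cond, nu_range[1], nu_range[2])
    y[[nm]] <- rnorm(n_per_cond, mu[i], sqrt(lambda)) +
      rnorm(n_per_cond, 0, sqrt(nu[[nm]]))
  }
  list(y = y, nu = nu)
}
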