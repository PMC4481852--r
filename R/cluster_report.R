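#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering that at each step merges the pair of clusters
#' with the smallest unweighted average inter-cluster dissimilarity (the
#' mean over all cross-pairs of leaves). Ties are broken deterministically
#' by the lexicographically smallest pair of cluster indices. Leaves are
#' numbered `1..n`; the cluster created at merge `s` gets index `n + s`.
#'
#' @param D Symmetric, non-negative dissimilarity matrix with zero diagonal.
#' @return Object of class `dendrogram_al`: `merges` data frame
#'   (`cluster_a`, `cluster_b`, `height`, `size`; `n - 1` rows) and
#'   `leaf_order` (every leaf exactly once, dendrogram order).
#' @export
average_linkage <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || any(abs(D - t(D)) > 1e-12))
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  if (any(D < 0)) stop("dissimilarities must be non-negative", call. = FALSE)
  if (any(abs(diag(D)) > 1e-12))
    stop("dissimilarity matrix must have zero diagonal", call. = FALSE)
  if (n < 2L) stop("need at least two leaves", call. = FALSE)

  labels <- rownames(D)
  active <- as.list(seq_len(n))          # leaf members per active cluster
  ids <- seq_len(n)                      # public index of each active cluster
  d <- D
  merges <- data.frame(cluster_a = integer(n - 1L), cluster_b = integer(n - 1L),
                       height = numeric(n - 1L), size = integer(n - 1L))
  orders <- as.list(seq_len(n))

  for (s in seq_len(n - 1L)) {
    m <- length(active)
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      ia <- min(ids[a], ids[b]); ib <- max(ids[a], ids[b])
      if (d[a, b] < best_d ||
          (d[a, b] == best_d &&
           (ia < min(ids[best[1]], ids[best[2]]) ||
            (ia == min(ids[best[1]], ids[best[2]]) &&
             ib < max(ids[best[1]], ids[best[2]]))))) {
        best <- c(a, b); best_d <- d[a, b]
      }
    }
    a <- best[1]; b <- best[2]
    na_ <- length(active[[a]]); nb_ <- length(active[[b]])
    merges$cluster_a[s] <- min(ids[a], ids[b])
    merges$cluster_b[s] <- max(ids[a], ids[b])
    merges$height[s] <- best_d
    merges$size[s] <- na_ + nb_
    # UPGMA update: size-weighted average of the two merged rows
    new_row <- (na_ * d[a, ] + nb_ * d[b, ]) / (na_ + nb_)
    keep <- setdiff(seq_len(m), c(a, b))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], new_row[keep]),
               c(new_row[keep], 0))
    new_order <- if (ids[a] <= ids[b]) c(orders[[a]], orders[[b]]) else
      c(orders[[b]], orders[[a]])
    active <- c(active[keep], list(c(active[[a]], active[[b]])))
    orders <- c(orders[keep], list(new_order))
    ids <- c(ids[keep], n + s)
  }
  structure(list(merges = merges, leaf_order = orders[[1]],
                 n_leaves = n, labels = labels),
            class = "dendrogram_al")
}

#' @export
print.dendrogram_al <- function(x, ...) {
  cat(sprintf("average-linkage dendrogram: %d leaves, %d merges\n",
              x$n_leaves, nrow(x$merges)))
  invisible(x)
}

#' Combine the PPLR and moderated-t tracks into the ranking table
#'
#' Joins the PPLR track (replicate-variance aware) with the moderated-t
#' comparator track on molecule id, back-transforms the log fold change to
#' the linear scale, and ranks by PPLR significance (ties by `|log_fc|`,
#' then id).
#'
#' @param pplr_res Data frame from [pplr_analysis()].
#' @param ebayes_res Data frame from [moderated_t_test()].
#' @param log_base Base of the input log scale (2, `exp(1)` or 10); used
#'   only for the linear-scale fold change.
#' @return Data frame with columns `molecule_id`, `pplr`,
#'   `pplr_significance`, `log_fc`, `fold_change`, `t_moderated`,
#'   `p_value`, `fdr_bh`, `rank`.
#' @export
ranking_table <- function(pplr_res, ebayes_res, log_base = 2) {
  eb <- ebayes_res[, c("molecule_id", "t_moderated", "p_value", "fdr_bh")]
  out <- merge(pplr_res[, c("molecule_id", "pplr", "pplr_significance",
                            "log_fc")],
               eb, by = "molecule_id", all.x = TRUE, sort = FALSE)
  out$fold_change <- log_base^out$log_fc
  out <- rank_by_pplr(out)
  out[, c("molecule_id", "pplr", "pplr_significance", "log_fc",
          "fold_change", "t_moderated", "p_value", "fdr_bh", "rank")]
}

#' Heat-map matrix and dendrograms for the top-ranked molecules
#'
#' Selects the `top_n` molecules by PPLR significance from the ranking
#' table, row-standardizes their per-sample point estimates for display
#' (mean 0, SD 1; rows with zero variance become all zeros and are flagged),
#' and clusters both molecules and biological samples by average linkage.
#'
#' @param summ A `summarized_dataset`.
#' @param ranking Ranking table (see [ranking_table()]).
#' @param top_n Number of top-ranked molecules; if fewer are available all
#'   are used with a warning.
#' @param distance `"euclidean"` on the standardized rows, or
#'   `"correlation"` (1 - Pearson).
#' @return List of class `heatmap_data`: `matrix` (standardized,
#'   molecules x samples), `row_dendrogram`, `col_dendrogram`,
#'   `row_order`, `col_order`, `flat_rows` (ids of zero-variance rows).
#' @export
heatmap_matrix <- function(summ, ranking, top_n = 25L,
                           distance = c("euclidean", "correlation")) {
  stopifnot(inherits(summ, "summarized_dataset"))
  distance <- match.arg(distance)
  if (top_n < 2L) stop("top_n must be >= 2", call. = FALSE)
  if (nrow(ranking) < top_n) {
    warning("only ", nrow(ranking), " ranked molecules available; using all",
            call. = FALSE)
    top_n <- nrow(ranking)
  }
  ids <- ranking$molecule_id[seq_len(top_n)]
  M <- summ$y[ids, , drop = FALSE]
  mu <- rowMeans(M, na.rm = TRUE)
  sd_ <- apply(M, 1L, stats::sd, na.rm = TRUE)
  flat <- rownames(M)[!is.na(sd_) & sd_ == 0]
  sd_[sd_ == 0 | is.na(sd_)] <- 1
  Z <- (M - mu) / sd_
  Z[is.na(Z)] <- 0

  dfun <- function(X) {
    if (distance == "euclidean") as.matrix(stats::dist(X))
    else 1 - stats::cor(t(X))
  }
  Dr <- dfun(Z); Dr[Dr < 0] <- 0; diag(Dr) <- 0
  Dc <- dfun(t(Z)); Dc[Dc < 0] <- 0; diag(Dc) <- 0
  rd <- average_linkage(Dr)
  cd <- average_linkage(Dc)
  structure(list(matrix = Z, row_dendrogram = rd, col_dendrogram = cd,
                 row_order = rownames(Z)[rd$leaf_order],
                 col_order = colnames(Z)[cd$leaf_order],
                 flat_rows = flat, distance = distance),
            class = "heatmap_data")
}

#' Render the report artifacts
#'
#' Writes the ranking table TSV, PCA score TSVs, one whisker-plot image per
#' requested molecule (point = sample average, vertical line = technical
#' error), a clustered heat-map image and a 2D PCA scatter image, plus a
#' static `index.html` linking everything.
#'
#' @param ranking Ranking table data frame.
#' @param whiskers Named list of whisker data frames (names = molecule ids),
#'   possibly empty.
#' @param pca Optional data frame from [pca_scores()]; a `condition` column
#'   (added by the pipeline) colors the points.
#' @param heatmap Optional `heatmap_data` from [heatmap_matrix()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the vector of file paths written.
#' @export
render_report <- function(ranking, whiskers = list(), pca = NULL,
                          heatmap = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wr <- function(path) { written <<- c(written, path); path }

  write_ranking_table(ranking, wr(file.path(out_dir, "ranking.tsv")))

  for (id in names(whiskers)) {
    f <- wr(file.path(out_dir, paste0("whisker_", .safe_name(id), ".png")))
    grDevices::png(f, width = 640, height = 480)
    .plot_whisker(whiskers[[id]], id)
    grDevices::dev.off()
  }

  if (!is.null(pca)) {
    out <- pca
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], signif, digits = 6L)
    utils::write.table(out, wr(file.path(out_dir, "pca_scores.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    f <- wr(file.path(out_dir, "pca.png"))
    grDevices::png(f, width = 640, height = 560)
    .plot_pca(pca)
    grDevices::dev.off()
  }

  if (!is.null(heatmap)) {
    f <- wr(file.path(out_dir, "heatmap.png"))
    grDevices::png(f, width = 720, height = 640)
    .plot_heatmap(heatmap)
    grDevices::dev.off()
  }

  idx <- wr(file.path(out_dir, "index.html"))
  items <- sprintf('    <li><a href="%s">%s</a></li>',
                   basename(setdiff(written, idx)),
                   basename(setdiff(written, idx)))
  writeLines(c("<!DOCTYPE html>", "<html><head><title>repvar report</title></head>",
               "<body>", "<h1>Replicate-variance analysis report</h1>", "<ul>",
               items, "</ul>", "</body></html>"), idx)
  invisible(written)
}

.safe_name <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

.plot_whisker <- function(wd, molecule_id) {
  conds <- unique(wd$condition)
  pch <- c(16, 17, 15, 18)[(match(wd$condition, conds) - 1L) %% 4L + 1L]
  x <- seq_len(nrow(wd))
  ylim <- range(wd$estimate - wd$technical_error,
                wd$estimate + wd$technical_error)
  graphics::plot(x, wd$estimate, pch = pch, xaxt = "n",
                 xlab = "biological sample", ylab = "log intensity",
                 main = molecule_id, ylim = ylim,
                 xlim = c(0.5, nrow(wd) + 0.5))
  graphics::segments(x, wd$estimate - wd$technical_error,
                     x, wd$estimate + wd$technical_error)
  graphics::axis(1, at = x, labels = wd$sample_id, las = 2, cex.axis = 0.7)
  graphics::legend("topright", legend = conds,
                   pch = c(16, 17, 15, 18)[(seq_along(conds) - 1L) %% 4L + 1L])
}

.plot_pca <- function(pca) {
  col <- if ("condition" %in% names(pca))
    as.integer(factor(pca$condition)) + 1L else "black"
  graphics::plot(pca$PC1, pca$PC2, col = col, pch = 16,
                 xlab = "PC1", ylab = "PC2", main = "PCA scores")
  graphics::text(pca$PC1, pca$PC2, labels = pca$sample_id,
                 pos = 3, cex = 0.6)
  if ("condition" %in% names(pca)) {
    lv <- levels(factor(pca$condition))
    graphics::legend("topright", legend = lv, col = seq_along(lv) + 1L,
                     pch = 16)
  }
}

.plot_heatmap <- function(hm) {
  Z <- hm$matrix[hm$row_order, hm$col_order, drop = FALSE]
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  lim <- max(abs(Z), 1e-9)
  graphics::par(mar = c(7, 2, 2, 7))
  graphics::image(t(Z)[, rev(seq_len(nrow(Z))), drop = FALSE],
                  col = pal, zlim = c(-lim, lim), axes = FALSE,
                  main = "Top-ranked molecules (row-standardized)")
  graphics::axis(1, at = seq(0, 1, length.out = ncol(Z)),
                 labels = colnames(Z), las = 2, cex.axis = 0.7)
  graphics::axis(4, at = seq(0, 1, length.out = nrow(Z)),
                 labels = rev(rownames(Z)), las = 2, cex.axis = 0.6)
}
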