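#' Summarize technical replicates per biological sample
#'
#' Collapses the technical replicates of each biological sample to a point
#' estimate \eqn{y_{ij}} and a technical variance \eqn{\nu_{ij}}, the pair
#' consumed by the measurement-error model behind the PPLR score and by the
#' noise-aware PCA. The point estimate is the mean, median or trimmed mean of
#' the non-missing technical replicate values; the technical variance is the
#' variance of that point estimate, \eqn{s^2/n}, with \eqn{s^2} the unbiased
#' sample variance across the `n` technical replicates (for median and
#' trimmed mean the untrimmed variance is used — simple and conservative).
#'
#' Samples with a single technical replicate carry no variance information;
#' their \eqn{\nu_{ij}} is imputed by a fallback hierarchy — median of the
#' molecule's observed \eqn{\nu} values, else the global median of all
#' observed \eqn{\nu}, else (when the whole dataset has single technical
#' replicates, so no technical variance information exists) zero with a
#' warning — and `nu_source` records which source was used.
#'
#' @param ds A `replicate_dataset` from [validate_dataset()].
#' @param method Location estimate: `"mean"`, `"median"` or `"trimmed_mean"`.
#' @param trim Per-tail trim fraction in `[0, 0.25]` for `trimmed_mean`.
#' @return An object of class `summarized_dataset`: list with
#'   `molecule_ids`; `samples` (data frame: sample_id, condition, bio_rep);
#'   matrices `y`, `nu`, `n_tech` (molecules x biological samples);
#'   `nu_source` character matrix with values `observed`, `pooled_molecule`,
#'   `pooled_global` or `NA`; and `excluded` — molecule ids missing in an
#'   entire condition, excluded from differential testing.
#' @export
summarize_technical <- function(ds, method = c("mean", "median", "trimmed_mean"),
                                trim = 0.1) {
  stopifnot(inherits(ds, "replicate_dataset"))
  method <- match.arg(method)
  if (method == "trimmed_mean" && (trim < 0 || trim > 0.25))
    stop("trim must be in [0, 0.25]", call. = FALSE)
  loc <- switch(method,
    mean = function(v) mean(v),
    median = function(v) stats::median(v),
    trimmed_mean = function(v) mean(v, trim = trim))

  tab <- unclass(ds$table)
  samples <- do.call(rbind, lapply(names(ds$groups), function(ci) {
    data.frame(sample_id = paste(ci, names(ds$groups[[ci]]), sep = "."),
               condition = ci, bio_rep = names(ds$groups[[ci]]),
               stringsAsFactors = FALSE)
  }))
  n_s <- nrow(samples)
  p <- nrow(tab)
  y <- nu <- matrix(NA_real_, p, n_s, dimnames = list(rownames(tab), samples$sample_id))
  n_tech <- matrix(0L, p, n_s, dimnames = dimnames(y))
  nu_source <- matrix(NA_character_, p, n_s, dimnames = dimnames(y))

  runs_of <- vector("list", n_s)
  for (s in seq_len(n_s))
    runs_of[[s]] <- ds$groups[[samples$condition[s]]][[samples$bio_rep[s]]]

  for (s in seq_len(n_s)) {
    sub <- tab[, runs_of[[s]], drop = FALSE]
    n_ok <- rowSums(!is.na(sub))
    n_tech[, s] <- n_ok
    for (g in which(n_ok > 0L)) {
      v <- sub[g, !is.na(sub[g, ])]
      y[g, s] <- loc(v)
      if (length(v) >= 2L) {
        nu[g, s] <- stats::var(v) / length(v)
        nu_source[g, s] <- "observed"
      }
    }
  }

  # fallback for single-replicate samples: molecule median, else global median
  global_med <- stats::median(nu[nu_source == "observed"], na.rm = TRUE)
  if (!is.finite(global_med) && any(n_tech >= 1L & is.na(nu)))
    warning("no observed technical variance anywhere; using nu = 0 ",
            "(technical noise folded into the between-sample variance)",
            call. = FALSE)
  for (g in seq_len(p)) {
    need <- which(n_tech[g, ] >= 1L & is.na(nu[g, ]))
    if (!length(need)) next
    obs <- nu[g, which(nu_source[g, ] == "observed")]
    if (length(obs)) {
      nu[g, need] <- stats::median(obs)
      nu_source[g, need] <- "pooled_molecule"
    } else if (is.finite(global_med)) {
      nu[g, need] <- global_med
      nu_source[g, need] <- "pooled_global"
    } else {
      # no sample anywhere has >= 2 technical replicates: no technical
      # variance information exists; nu = 0 folds all noise into lambda
      nu[g, need] <- 0
      nu_source[g, need] <- "none"
    }
  }

  # molecules absent from an entire condition cannot be tested
  excluded <- character(0)
  for (ci in unique(samples$condition)) {
    cols <- which(samples$condition == ci)
    miss <- rowSums(!is.na(y[, cols, drop = FALSE])) == 0L
    excluded <- union(excluded, rownames(tab)[miss])
  }
  if (length(excluded))
    warning("molecule(s) missing in an entire condition, excluded from testing: ",
            paste(excluded, collapse = ", "), call. = FALSE)

  structure(list(molecule_ids = rownames(tab), samples = samples,
                 y = y, nu = nu, n_tech = n_tech, nu_source = nu_source,
                 method = method, trim = if (method == "trimmed_mean") trim else NULL,
                 excluded = excluded),
            class = "summarized_dataset")
}

#' @export
print.summarized_dataset <- function(x, ...) {
  cat(sprintf("summarized_dataset: %d molecules x %d biological samples (%s)\n",
              length(x$molecule_ids), nrow(x$samples), x$method))
  invisible(x)
}

#' Whisker-plot data for one molecule
#'
#' Returns, per biological sample, the mean of the technical replicates and
#' their standard deviation (the "technical error" drawn as a vertical line
#' in whisker plots; 0 when a sample has a single replicate), grouped by
#' condition. Note the whisker uses the raw replicate SD, not the SD of the
#' mean, to display the replicate spread itself.
#'
#' @param ds A `replicate_dataset` from [validate_dataset()].
#' @param molecule_id Molecule identifier.
#' @return Data frame with columns `sample_id`, `condition`, `bio_rep`,
#'   `estimate` (log-intensity) and `technical_error` (log-intensity SD).
#' @export
whisker_data <- function(ds, molecule_id) {
  stopifnot(inherits(ds, "replicate_dataset"))
  tab <- unclass(ds$table)
  if (!molecule_id %in% rownames(tab))
    stop("unknown molecule id: ", molecule_id, call. = FALSE)
  rows <- list()
  for (ci in names(ds$groups)) {
    for (bj in names(ds$groups[[ci]])) {
      v <- tab[molecule_id, ds$groups[[ci]][[bj]]]
      v <- v[!is.na(v)]
      if (!length(v)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste(ci, bj, sep = "."), condition = ci, bio_rep = bj,
        estimate = mean(v),
        technical_error = if (length(v) >= 2L) stats::sd(v) else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
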