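#' Fit the hierarchical measurement-error model for one molecule
#'
#' The measured per-sample signal for a molecule is modeled as
#' \deqn{y_{ij} \sim N(\mu_i, \lambda + \nu_{ij})}
#' where \eqn{\mu_i} is the condition mean, \eqn{\lambda} the between-sample
#' (biological) variance shared across conditions, and \eqn{\nu_{ij}} the
#' known technical variance of sample \eqn{j} in condition \eqn{i}. With a
#' flat prior on each \eqn{\mu_i}, the marginal likelihood of the data given
#' \eqn{\lambda} is available in closed form: for weights
#' \eqn{w_{ij} = 1/(\lambda + \nu_{ij})} the posterior of \eqn{\mu_i} is
#' Gaussian with mean \eqn{m_i = \sum_j w_{ij} y_{ij} / \sum_j w_{ij}} and
#' variance \eqn{v_i = 1/\sum_j w_{ij}}. \eqn{\hat\lambda} maximizes the
#' profile marginal log-likelihood over `lambda_bounds` by bounded
#' one-dimensional (Brent-style) search on \eqn{\log(\lambda + \epsilon)},
#' with both interval endpoints checked.
#'
#' @param y Named list, one numeric vector of per-sample point estimates per
#'   condition.
#' @param nu Matching named list of technical variances (same shapes as `y`,
#'   all entries `>= 0`).
#' @param lambda_bounds Interval searched for \eqn{\lambda}; default
#'   `c(0, 10 * max per-condition sample variance)` (at least `c(0, 1)`).
#' @param tol Relative tolerance of the 1-D search.
#' @param max_iter Cap on likelihood evaluations.
#' @return Object of class `molecule_model`: `lambda_hat`, named vectors `m`
#'   and `v` (posterior mean/variance of each condition mean at
#'   \eqn{\hat\lambda}), `loglik`, `converged`, `n_iterations`, `at_bound`.
#' @export
fit_molecule_model <- function(y, nu, lambda_bounds = NULL, tol = 1e-8,
                               max_iter = 500L) {
  if (is.null(names(y)) || is.null(names(nu)) ||
      !identical(sort(names(y)), sort(names(nu))))
    stop("y and nu must be named lists over the same conditions", call. = FALSE)
  nu <- nu[names(y)]
  yv <- unlist(y, use.names = FALSE)
  nv <- unlist(nu, use.names = FALSE)
  if (any(!is.finite(yv)) || any(!is.finite(nv)))
    stop("non-finite value in y or nu", call. = FALSE)
  if (any(nv < 0)) stop("technical variances must be >= 0", call. = FALSE)
  if (any(lengths(y) < 1L)) stop("each condition needs >= 1 sample", call. = FALSE)

  if (is.null(lambda_bounds)) {
    sv <- vapply(y, function(v) if (length(v) >= 2L) stats::var(v) else 0,
                 numeric(1))
    lambda_bounds <- c(0, max(1, 10 * max(sv)))
  }
  lo <- max(0, lambda_bounds[1]); hi <- lambda_bounds[2]
  if (!(hi > lo)) stop("invalid lambda_bounds", call. = FALSE)

  eps <- 1e-12
  n_eval <- 0L
  ll <- function(lambda) {
    n_eval <<- n_eval + 1L
    .pplr_profile_loglik(y, nu, lambda, eps)
  }
  # the profile likelihood can be bimodal at small n (a boundary mode at
  # lambda ~ 0 and an interior mode): bracket the global mode with a coarse
  # scan on log(lambda + eps), then refine by Brent within the bracket
  tgrid <- seq(log(lo + eps), log(hi + eps), length.out = 64L)
  lgrid <- exp(tgrid) - eps
  vals <- vapply(lgrid, ll, numeric(1))
  i <- which.max(vals)
  bracket <- tgrid[c(max(1L, i - 1L), min(length(tgrid), i + 1L))]
  opt <- stats::optimize(function(t) ll(exp(t) - eps),
                         interval = bracket, maximum = TRUE, tol = tol)
  cand_lambda <- c(max(lo, exp(opt$maximum) - eps), lgrid[i], lo, hi)
  cand_ll <- c(opt$objective, vals[i], ll(lo), ll(hi))
  best <- which.max(cand_ll)
  lambda_hat <- cand_lambda[best]

  w <- lapply(nu, function(v) 1 / (lambda_hat + v + eps))
  m <- mapply(function(wi, yi) sum(wi * yi) / sum(wi), w, y)
  v <- vapply(w, function(wi) 1 / sum(wi), numeric(1))
  structure(list(lambda_hat = lambda_hat, m = m, v = v,
                 loglik = cand_ll[best],
                 converged = n_eval <= max_iter,
                 n_iterations = n_eval,
                 at_bound = best > 2L || lambda_hat <= lo + eps),
            class = "molecule_model")
}

# flat-prior marginal log-likelihood of Eq-style model, profiled over mu
.pplr_profile_loglik <- function(y, nu, lambda, eps = 1e-12) {
  total <- 0
  for (ci in names(y)) {
    w <- 1 / (lambda + nu[[ci]] + eps)
    W <- sum(w)
    m <- sum(w * y[[ci]]) / W
    n <- length(w)
    total <- total - 0.5 * (n - 1L) * log(2 * pi) +
      0.5 * sum(log(w)) - 0.5 * log(W) -
      0.5 * sum(w * (y[[ci]] - m)^2)
  }
  total
}

#' @export
print.molecule_model <- function(x, ...) {
  cat(sprintf("molecule_model: lambda_hat = %.4g, conditions: %s\n",
              x$lambda_hat, paste(names(x$m), collapse = ", ")))
  invisible(x)
}

#' Probability of positive log ratio between two conditions
#'
#' Under the fitted model the condition means are independent Gaussians, so
#' the posterior probability that condition `a`'s mean exceeds condition
#' `b`'s is
#' \deqn{\mathrm{PPLR} = \Phi\!\left(\frac{m_a - m_b}{\sqrt{v_a + v_b}}\right).}
#' The ranking significance is `max(pplr, 1 - pplr) - 0.5`, in `[0, 0.5]`,
#' so both up- and down-regulated molecules rank high.
#'
#' @param model A `molecule_model` from [fit_molecule_model()].
#' @param condition_a,condition_b Condition labels present in the model.
#' @return List of class `pplr_result`: `pplr`, `significance`, `log_fc`
#'   (`m_a - m_b`), `contrast_sd`, `degenerate` flag.
#' @export
pplr_score <- function(model, condition_a, condition_b) {
  stopifnot(inherits(model, "molecule_model"))
  miss <- setdiff(c(condition_a, condition_b), names(model$m))
  if (length(miss))
    stop("condition(s) not in model: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- model$m[[condition_a]] - model$m[[condition_b]]
  s2 <- model$v[[condition_a]] + model$v[[condition_b]]
  degenerate <- s2 <= 0
  # computed through pnorm(|z|) in [0.5, 1] so that the pair (A,B) / (B,A)
  # sums to 1 exactly in floating point
  pplr <- if (degenerate) {
    if (d > 0) 1 else if (d < 0) 0 else 0.5
  } else {
    p_up <- stats::pnorm(abs(d) / sqrt(s2))
    if (d >= 0) p_up else 1 - p_up
  }
  structure(list(pplr = pplr, significance = max(pplr, 1 - pplr) - 0.5,
                 log_fc = d, contrast_sd = sqrt(max(s2, 0)),
                 degenerate = degenerate),
            class = "pplr_result")
}

#' Rank molecules by PPLR significance
#'
#' Sorts descending by significance; ties are broken by `|log_fc|`
#' descending, then molecule id ascending.
#'
#' @param results Data frame with columns `molecule_id`, `pplr`,
#'   `pplr_significance`, `log_fc` (one row per molecule).
#' @return The data frame sorted, with a `rank` column appended.
#' @export
rank_by_pplr <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("molecule_id", "pplr_significance", "log_fc") %in%
                  names(results)))
  ord <- order(-results$pplr_significance, -abs(results$log_fc),
               results$molecule_id)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the PPLR track over every molecule of a summarized dataset
#'
#' Fits the measurement-error model molecule by molecule and scores the
#' requested contrast. Molecules excluded at summarization (absent from an
#' entire condition) are skipped.
#'
#' @param summ A `summarized_dataset` from [summarize_technical()].
#' @param condition_a,condition_b Condition labels to contrast.
#' @param ... Passed to [fit_molecule_model()].
#' @return Data frame: `molecule_id`, `pplr`, `pplr_significance`, `log_fc`,
#'   `contrast_sd`, `lambda_hat`, `m_a`, `m_b`.
#' @export
pplr_analysis <- function(summ, condition_a, condition_b, ...) {
  stopifnot(inherits(summ, "summarized_dataset"))
  conds <- unique(summ$samples$condition)
  miss <- setdiff(c(condition_a, condition_b), conds)
  if (length(miss))
    stop("condition(s) not in design: ", paste(miss, collapse = ", "),
         "; available: ", paste(conds, collapse = ", "), call. = FALSE)
  keep <- setdiff(summ$molecule_ids, summ$excluded)
  cols_a <- which(summ$samples$condition == condition_a)
  cols_b <- which(summ$samples$condition == condition_b)
  res <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    g <- keep[i]
    ya <- summ$y[g, cols_a]; yb <- summ$y[g, cols_b]
    na_a <- is.na(ya); na_b <- is.na(yb)
    y <- list(a = ya[!na_a], b = yb[!na_b])
    nu <- list(a = summ$nu[g, cols_a][!na_a], b = summ$nu[g, cols_b][!na_b])
    names(y) <- names(nu) <- c(condition_a, condition_b)
    model <- fit_molecule_model(y, nu, ...)
    sc <- pplr_score(model, condition_a, condition_b)
    res[[i]] <- data.frame(molecule_id = g, pplr = sc$pplr,
                           pplr_significance = sc$significance,
                           log_fc = sc$log_fc, contrast_sd = sc$contrast_sd,
                           lambda_hat = model$lambda_hat,
                           m_a = model$m[[condition_a]],
                           m_b = model$m[[condition_b]],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
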