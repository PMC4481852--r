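#' Probabilistic PCA with per-observation technical noise
#'
#' Fits the linear-Gaussian latent factor model
#' \deqn{x_n = W z_n + c + \epsilon_n, \quad z_n \sim N(0, I_k), \quad
#'       \epsilon_n \sim N(0, \sigma^2 I + \mathrm{diag}(\nu_n))}
#' by EM, where \eqn{\nu_n} is the vector of known technical variances of
#' biological sample \eqn{n}. Samples measured with high technical noise are
#' automatically down-weighted when the principal subspace is estimated,
#' which reduces the influence of noisy samples relative to plain PCA. With
#' \eqn{\nu \equiv 0} the model is standard probabilistic PCA and the fitted
#' subspace coincides with the top-`k` SVD subspace.
#'
#' The E-step computes each sample's Gaussian score posterior under its own
#' diagonal noise covariance. The M-step updates each molecule row of `W` by
#' weighted least squares over samples with weights
#' \eqn{1/(\sigma^2 + \nu_{gn})} (rows decouple because the noise is
#' diagonal), then updates \eqn{\sigma^2} by maximizing the expected
#' complete-data log-likelihood over \eqn{\sigma^2} with a bounded 1-D
#' search (a generalized-EM step, since \eqn{\sigma^2} enters the weights
#' nonlinearly). Both half-steps increase the EM surrogate, so the marginal
#' log-likelihood is non-decreasing across iterations. The center `c` is the
#' per-molecule mean and is held fixed.
#'
#' @param Y Numeric matrix of per-sample point estimates, molecules x
#'   biological samples. Rows containing missing values are dropped with a
#'   warning.
#' @param V Matching matrix of technical variances (elementwise `>= 0`).
#' @param k Number of components, `1 <= k < ncol(Y)`.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations.
#' @param seed Integer used only to make degenerate initialization ties
#'   reproducible; the algorithm is otherwise deterministic.
#' @return Object of class `noise_pca_model`: `W` (molecules x k, components
#'   ordered by decreasing explained variance, sign fixed so each component's
#'   largest-magnitude loading is positive), `center`, `sigma_sq`, `k`,
#'   `scores` (k x samples posterior means), `score_cov` (list of k x k
#'   posterior covariances), `loglik`, `ll_trace`, `n_iterations`,
#'   `converged`, `sample_ids`, `molecule_ids`.
#' @export
fit_noise_pca <- function(Y, V, k = 3L, tol = 1e-8, max_iter = 1000L,
                          seed = NULL) {
  stopifnot(is.matrix(Y), is.matrix(V), all(dim(Y) == dim(V)))
  if (any(!is.na(V) & V < 0)) stop("technical variances must be >= 0", call. = FALSE)
  drop <- rowSums(is.na(Y) | is.na(V)) > 0L
  if (any(drop)) {
    warning(sum(drop), " molecule(s) with missing summaries dropped from PCA",
            call. = FALSE)
    Y <- Y[!drop, , drop = FALSE]; V <- V[!drop, , drop = FALSE]
  }
  if (any(!is.finite(Y)) || any(!is.finite(V)))
    stop("non-finite input to noise PCA", call. = FALSE)
  p <- nrow(Y); N <- ncol(Y)
  k <- as.integer(k)
  if (k < 1L || k >= N)
    stop("k must satisfy 1 <= k < number of samples", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)

  center <- rowMeans(Y)
  Xc <- Y - center
  sv <- svd(Xc, nu = k, nv = 0L)
  W <- sv$u * rep(sv$d[seq_len(k)] / sqrt(N), each = p)
  tot <- sum(Xc^2)
  sigma_sq <- max((tot - sum(sv$d[seq_len(k)]^2)) / (p * N), 1e-8)

  eps <- 1e-12
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  Ik <- diag(1, k)

  for (iter in seq_len(max_iter)) {
    ## E-step (and marginal log-likelihood at current parameters)
    Psi <- sigma_sq + V + eps               # p x N
    Zbar <- matrix(0, k, N)
    S <- matrix(0, N, k * k)                # row n = vec(E[z_n z_n'])
    covs <- vector("list", N)
    ll <- -0.5 * p * N * log(2 * pi)
    for (n in seq_len(N)) {
      psi <- Psi[, n]
      Wp <- W / psi                          # p x k
      M <- Ik + crossprod(Wp, W)
      C <- chol(M)
      Cinv <- chol2inv(C)
      b <- crossprod(Wp, Xc[, n])
      z <- Cinv %*% b
      Zbar[, n] <- z
      Ezz <- Cinv + tcrossprod(z)
      S[n, ] <- as.vector(Ezz)
      covs[[n]] <- Cinv
      ll <- ll - 0.5 * (sum(log(psi)) + 2 * sum(log(diag(C))) +
                          sum(Xc[, n]^2 / psi) - sum(b * z))
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) <= tol * (abs(ll_prev) + 1)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll

    ## M-step: per-row weighted least squares for W
    B <- 1 / Psi                             # weights
    A_all <- B %*% S                         # p x k^2
    b_all <- (B * Xc) %*% t(Zbar)            # p x k
    for (g in seq_len(p)) {
      A <- matrix(A_all[g, ], k, k)
      W[g, ] <- solve(A, b_all[g, ])
    }

    ## M-step: sigma^2 by bounded 1-D maximization of the EM surrogate
    WZ <- W %*% Zbar
    Wkron <- W[, rep(seq_len(k), each = k), drop = FALSE] *
      W[, rep(seq_len(k), times = k), drop = FALSE]     # p x k^2, vec(w w')
    R2 <- Xc^2 - 2 * Xc * WZ + Wkron %*% t(S)            # E[(x - c - Wz)^2]
    R2[R2 < 0] <- 0
    qfun <- function(s2) -0.5 * sum(log(s2 + V + eps) + R2 / (s2 + V + eps))
    up <- max(sigma_sq * 8, mean(pmax(R2 - V, 0)) * 4, 1e-8)
    opt <- stats::optimize(qfun, c(0, up), maximum = TRUE,
                           tol = .Machine$double.eps^0.5 * up)
    s2_new <- opt$maximum
    if (qfun(0) >= opt$objective) s2_new <- 0
    if (qfun(s2_new) >= qfun(sigma_sq)) sigma_sq <- s2_new
  }

  ## canonical ordering: decreasing explained variance; canonical sign
  Ezz_mean <- matrix(colMeans(S), k, k)
  expl <- colSums(W^2) * diag(Ezz_mean)
  ord <- order(expl, decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  Zbar <- Zbar[ord, , drop = FALSE]
  covs <- lapply(covs, function(C) C[ord, ord, drop = FALSE])
  sgn <- vapply(seq_len(k), function(a) {
    w <- W[, a]
    if (w[which.max(abs(w))] < 0) -1 else 1
  }, numeric(1))
  W <- sweep(W, 2L, sgn, `*`)
  Zbar <- Zbar * sgn
  covs <- lapply(covs, function(C) diag(sgn, k) %*% C %*% diag(sgn, k))

  structure(list(W = W, center = center, sigma_sq = sigma_sq, k = k,
                 scores = Zbar, score_cov = covs,
                 loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
                 n_iterations = iter, converged = converged,
                 sample_ids = colnames(Y), molecule_ids = rownames(Y)),
            class = "noise_pca_model")
}

#' @export
print.noise_pca_model <- function(x, ...) {
  cat(sprintf(
    "noise_pca_model: k = %d, %d molecules x %d samples, sigma_sq = %.4g, %s after %d iterations\n",
    x$k, nrow(x$W), ncol(x$scores), x$sigma_sq,
    if (x$converged) "converged" else "not converged", x$n_iterations))
  invisible(x)
}

#' Extract ordered PCA score coordinates
#'
#' Returns the posterior mean scores of the first `dims` components
#' (components are stored ordered by decreasing explained variance, with the
#' sign of each fixed so its largest-magnitude loading is positive).
#'
#' @param model A `noise_pca_model`.
#' @param dims Number of leading components to return (2 or 3 for the usual
#'   scatter plots); must not exceed `model$k`.
#' @return Data frame: `sample_id`, `PC1` ... `PC<dims>`.
#' @export
pca_scores <- function(model, dims = 2L) {
  stopifnot(inherits(model, "noise_pca_model"))
  dims <- as.integer(dims)
  if (dims < 1L || dims > model$k)
    stop("dims must be between 1 and k = ", model$k, call. = FALSE)
  sc <- t(model$scores[seq_len(dims), , drop = FALSE])
  colnames(sc) <- paste0("PC", seq_len(dims))
  ids <- model$sample_ids
  if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(sc)))
  data.frame(sample_id = ids, sc, stringsAsFactors = FALSE)
}

#' Largest principal angle between two column spaces
#'
#' Utility for comparing fitted subspaces (in radians).
#'
#' @param A,B Matrices whose column spaces are compared (same row count).
#' @return The largest principal angle in radians.
#' @export
principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(s))))
}
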