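#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled-inverse-chi-square prior \eqn{s_g^2 \sim s_0^2 d_0 /
#' \chi^2_{d_0}} to a set of per-molecule sample variances by moment
#' matching on the log scale. For \eqn{z_g = \log s_g^2} the centered
#' quantity \eqn{e_g = z_g - \psi(d_g/2) + \log(d_g/2)} has mean
#' \eqn{\log s_0^2 + \psi(d_0/2) - \log(d_0/2)} and variance
#' \eqn{\psi'(d_g/2) + \psi'(d_0/2)}; the prior degrees of freedom solve
#' \eqn{\psi'(d_0/2) = \mathrm{var}(e) - \overline{\psi'(d_g/2)}} by a
#' monotone Newton iteration on the trigamma function. When the right-hand
#' side is not positive the data show no excess variance heterogeneity and
#' the prior is degenerate: \eqn{d_0 = \infty}, \eqn{s_0^2 = \exp(\bar e)}.
#'
#' Molecules with zero variance or zero degrees of freedom are excluded
#' from the fit (but can still be scored with the fitted prior).
#'
#' @param s_sq Numeric vector of per-molecule sample variances.
#' @param d Matching residual degrees of freedom (recycled if length 1).
#' @return List of class `ebayes_prior`: `d0` (possibly `Inf`) and `s0_sq`.
#' @export
estimate_prior <- function(s_sq, d) {
  if (length(d) == 1L) d <- rep(d, length(s_sq))
  stopifnot(length(s_sq) == length(d))
  ok <- is.finite(s_sq) & s_sq > 0 & is.finite(d) & d >= 1
  if (sum(ok) < 2L)
    stop("need >= 2 molecules with positive variance and df >= 1", call. = FALSE)
  s_sq <- s_sq[ok]; d <- d[ok]
  e <- log(s_sq) - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - mean(trigamma(d / 2))
  if (!is.finite(evar) || evar <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    half_d0 <- .trigamma_inverse(evar)
    d0 <- 2 * half_d0
    s0_sq <- exp(mean(e) + digamma(half_d0) - log(half_d0))
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_used = length(e)),
            class = "ebayes_prior")
}

# solve trigamma(x) = y for x > 0; Newton on the monotone decreasing trigamma
.trigamma_inverse <- function(y, max_iter = 50L, tol = 1e-10) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < tol * x) break
  }
  x
}

#' @export
print.ebayes_prior <- function(x, ...) {
  cat(sprintf("ebayes_prior: d0 = %s, s0_sq = %.4g\n",
              format(x$d0), x$s0_sq))
  invisible(x)
}

#' Moderated two-sample t-test with variance shrinkage
#'
#' Classical pooled-variance two-sample t-statistics on the per-biological-
#' sample point estimates, with each molecule's variance shrunk toward the
#' empirical-Bayes prior:
#' \deqn{\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
#'       \tilde t_g = \frac{\bar y_a - \bar y_b}
#'                         {\tilde s_g \sqrt{1/n_a + 1/n_b}},}
#' with two-sided p-values from a t distribution on \eqn{d_0 + d_g} degrees
#' of freedom (the normal limit when \eqn{d_0 = \infty}).
#'
#' @param summ A `summarized_dataset`; for the comparator track this should
#'   be mean-summarized.
#' @param prior An `ebayes_prior`, or `NULL` to estimate it from the data
#'   with [estimate_prior()]. `d0 = 0` is accepted and gives the classical
#'   unmoderated pooled t.
#' @param condition_a,condition_b Condition labels to contrast.
#' @return Data frame, one row per testable molecule: `molecule_id`,
#'   `mean_a`, `mean_b`, `s_sq`, `df`, `s_tilde_sq`, `t_moderated`,
#'   `p_value`, `fdr_bh`.
#' @export
moderated_t_test <- function(summ, prior = NULL, condition_a, condition_b) {
  stopifnot(inherits(summ, "summarized_dataset"))
  cols_a <- which(summ$samples$condition == condition_a)
  cols_b <- which(summ$samples$condition == condition_b)
  if (!length(cols_a) || !length(cols_b))
    stop("contrast condition absent from dataset", call. = FALSE)
  ya <- summ$y[, cols_a, drop = FALSE]
  yb <- summ$y[, cols_b, drop = FALSE]
  na <- rowSums(!is.na(ya)); nb <- rowSums(!is.na(yb))
  keep <- na >= 1L & nb >= 1L & (na + nb) >= 3L &
    !(summ$molecule_ids %in% summ$excluded)
  if (!any(keep))
    stop("no molecule has enough samples for a pooled variance (df >= 1)",
         call. = FALSE)
  ma <- rowMeans(ya, na.rm = TRUE); mb <- rowMeans(yb, na.rm = TRUE)
  ssa <- rowSums((ya - ma)^2, na.rm = TRUE)
  ssb <- rowSums((yb - mb)^2, na.rm = TRUE)
  dg <- na + nb - 2L
  s_sq <- ifelse(dg > 0, (ssa + ssb) / pmax(dg, 1L), NA_real_)

  if (is.null(prior)) prior <- estimate_prior(s_sq[keep], dg[keep])
  stopifnot(inherits(prior, "ebayes_prior"))
  d0 <- prior$d0; s0 <- prior$s0_sq

  idx <- which(keep)
  s_tilde <- if (is.infinite(d0)) rep(s0, length(idx)) else
    (d0 * s0 + dg[idx] * s_sq[idx]) / (d0 + dg[idx])
  se <- sqrt(s_tilde * (1 / na[idx] + 1 / nb[idx]))
  tmod <- ifelse(se > 0, (ma[idx] - mb[idx]) / se,
                 ifelse(ma[idx] == mb[idx], 0, sign(ma[idx] - mb[idx]) * Inf))
  df_total <- d0 + dg[idx]
  p <- 2 * stats::pt(-abs(tmod), df = df_total)
  out <- data.frame(molecule_id = summ$molecule_ids[idx],
                    mean_a = ma[idx], mean_b = mb[idx],
                    s_sq = s_sq[idx], df = dg[idx], s_tilde_sq = s_tilde,
                    t_moderated = tmod, p_value = p,
                    fdr_bh = bh_adjust(p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "prior") <- prior
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
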