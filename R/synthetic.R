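#' Generate a synthetic replicate dataset with ground truth
#'
#' Simulates log-scale intensity data with the hierarchical structure the
#' package models: per molecule a baseline condition mean drawn from
#' N(8, 1) (a typical log2 intensity scale), a between-sample variance
#' \eqn{\lambda} drawn from a log-normal, per-biological-sample signals
#' \eqn{\sim N(\mu_i, \lambda)}, per-sample technical variances \eqn{\nu}
#' drawn from a log-normal, and `n_tech` technical-replicate runs per
#' sample drawn \eqn{\sim N(\mathrm{signal}, \nu \cdot n_{tech})} — so the
#' variance of the replicate mean is exactly \eqn{\nu}, keeping the
#' generative truth aligned with the summarization module's definition of
#' the technical variance. A fraction `frac_de` of molecules is truly
#' differential: their second-condition mean is shifted by `delta` with
#' random sign.
#'
#' @param p Number of molecules.
#' @param conditions Number of conditions (>= 2; only condition 2 receives
#'   the differential shift).
#' @param n_bio Biological samples per condition.
#' @param n_tech Technical replicates per biological sample.
#' @param frac_de Fraction of truly differential molecules in `[0, 1]`.
#' @param delta Absolute effect size (log-intensity units).
#' @param lambda_dist `c(mean, spread)` of the log-normal for \eqn{\lambda}
#'   (spread 0 gives a constant).
#' @param nu_dist `c(mean, spread)` of the log-normal for \eqn{\nu}.
#' @param seed Integer seed; the output is bit-for-bit reproducible.
#' @return List with `table` ([intensity_table()]), `design`
#'   ([replicate_design()]), and `truth` (class `synthetic_truth`: data
#'   frame `molecules` with `molecule_id`, `mu_<condition>`, `lambda`,
#'   `differential`, `delta`; matrices `signal` and `nu` per molecule x
#'   biological sample; the `seed`).
#' @export
generate_dataset <- function(p = 1000L, conditions = 2L, n_bio = 4L,
                             n_tech = 3L, frac_de = 0.1, delta = 1.0,
                             lambda_dist = c(0.3, 0.15),
                             nu_dist = c(0.3, 0.15), seed = 1L) {
  if (p < 1L || conditions < 2L || n_bio < 1L || n_tech < 1L)
    stop("need p >= 1, conditions >= 2, n_bio >= 1, n_tech >= 1", call. = FALSE)
  if (frac_de < 0 || frac_de > 1) stop("frac_de must be in [0, 1]", call. = FALSE)
  if (length(lambda_dist) != 2L || lambda_dist[1] < 0 || lambda_dist[2] < 0 ||
      length(nu_dist) != 2L || nu_dist[1] < 0 || nu_dist[2] < 0)
    stop("lambda_dist and nu_dist must be c(mean >= 0, spread >= 0)",
         call. = FALSE)
  set.seed(as.integer(seed))

  mol_ids <- sprintf("mol%0*d", nchar(p), seq_len(p))
  cond_ids <- paste0("c", seq_len(conditions))
  baseline <- stats::rnorm(p, 8, 1)
  n_de <- round(frac_de * p)
  de_idx <- if (n_de > 0) sort(sample.int(p, n_de)) else integer(0)
  delta_signed <- numeric(p)
  if (n_de > 0)
    delta_signed[de_idx] <- delta * sample(c(-1, 1), n_de, replace = TRUE)
  mu <- matrix(baseline, p, conditions,
               dimnames = list(mol_ids, paste0("mu_", cond_ids)))
  mu[, 2L] <- mu[, 2L] + delta_signed
  lambda <- .rlnorm_meansd(p, lambda_dist[1], lambda_dist[2])

  n_samples <- conditions * n_bio
  sample_cond <- rep(cond_ids, each = n_bio)
  sample_bio <- rep(paste0("b", seq_len(n_bio)), times = conditions)
  sample_ids <- paste(sample_cond, sample_bio, sep = ".")

  signal <- matrix(NA_real_, p, n_samples, dimnames = list(mol_ids, sample_ids))
  nu <- matrix(.rlnorm_meansd(p * n_samples, nu_dist[1], nu_dist[2]),
               p, n_samples, dimnames = list(mol_ids, sample_ids))
  for (s in seq_len(n_samples)) {
    ci <- match(sample_cond[s], cond_ids)
    signal[, s] <- stats::rnorm(p, mu[, ci], sqrt(lambda))
  }

  run_cond <- rep(sample_cond, each = n_tech)
  run_bio <- rep(sample_bio, each = n_tech)
  run_tech <- rep(paste0("t", seq_len(n_tech)), times = n_samples)
  run_ids <- paste(run_cond, run_bio, run_tech, sep = "_")
  vals <- matrix(NA_real_, p, length(run_ids),
                 dimnames = list(mol_ids, run_ids))
  for (s in seq_len(n_samples)) {
    cols <- ((s - 1L) * n_tech + 1L):(s * n_tech)
    sd_run <- sqrt(nu[, s] * n_tech)
    for (t in seq_len(n_tech))
      vals[, cols[t]] <- stats::rnorm(p, signal[, s], sd_run)
  }

  truth <- structure(list(
    molecules = data.frame(molecule_id = mol_ids, mu,
                           lambda = lambda,
                           differential = delta_signed != 0,
                           delta = delta_signed,
                           stringsAsFactors = FALSE),
    signal = signal, nu = nu, seed = as.integer(seed)),
    class = "synthetic_truth")
  list(table = intensity_table(vals),
       design = replicate_design(run_ids, run_cond, run_bio, run_tech),
       truth = truth)
}

# log-normal with given mean and SD on the natural scale; spread 0 -> constant
.rlnorm_meansd <- function(n, mean, spread) {
  if (mean == 0) return(rep(0, n))
  if (spread == 0) return(rep(mean, n))
  s2 <- log(1 + (spread / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Ranking accuracy against the synthetic ground truth
#'
#' Area under the ROC curve of the ranking's significance scores against
#' the true differential flags, via the Mann-Whitney formulation with ties
#' averaged: the probability that a randomly chosen truly differential
#' molecule scores above a randomly chosen null molecule.
#'
#' @param truth A `synthetic_truth` from [generate_dataset()].
#' @param ranking Data frame with `molecule_id` and a score column
#'   (`pplr_significance` by default).
#' @param score Name of the score column.
#' @return AUC in `[0, 1]`.
#' @export
benchmark_ranking <- function(truth, ranking, score = "pplr_significance") {
  stopifnot(inherits(truth, "synthetic_truth"),
            score %in% names(ranking))
  flags <- truth$molecules$differential[
    match(ranking$molecule_id, truth$molecules$molecule_id)]
  if (any(is.na(flags)))
    stop("ranking contains molecules unknown to the truth", call. = FALSE)
  n1 <- sum(flags); n0 <- sum(!flags)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: need both differential and null molecules",
         call. = FALSE)
  r <- rank(ranking[[score]], ties.method = "average")
  (sum(r[flags]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Write a synthetic dataset to disk
#'
#' Writes `matrix.tsv` (intensity table), `design.tsv` and `truth.tsv`
#' (per-molecule truth) into a directory, the on-disk form produced by the
#' `simulate` subcommand of the command-line interface.
#'
#' @param sim Output of [generate_dataset()].
#' @param out_dir Directory, created if needed.
#' @return Invisibly, the three file paths.
#' @export
write_synthetic <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(out_dir, "matrix.tsv")
  tab <- sim$table
  df <- data.frame(molecule_id = rownames(tab), unclass(tab),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  dpath <- file.path(out_dir, "design.tsv")
  utils::write.table(sim$design, dpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tpath <- file.path(out_dir, "truth.tsv")
  utils::write.table(sim$truth$molecules, tpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(mpath, dpath, tpath))
}
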