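#' Build a pipeline configuration
#'
#' All settings are optional and default to the typical analysis: mean
#' summarization, no extra normalization, contrast between the first two
#' conditions in design order, 3-component noise-aware PCA, top 25 molecules
#' in the heat map.
#'
#' @param matrix_path Path to the intensity TSV.
#' @param design_path Path to the design TSV.
#' @param out_dir Report output directory.
#' @param normalize `"none"`, `"median"` or `"vstab"`.
#' @param vstab_c glog constant for `vstab` (number or `"auto"`).
#' @param log_base Log base of the input intensities (2, `exp(1)` or 10);
#'   controls the fold-change back-transformation and the exponentiation
#'   applied before `vstab`.
#' @param summarize `"mean"`, `"median"` or `"trimmed_mean"`.
#' @param trim Per-tail trim fraction for `trimmed_mean`.
#' @param contrast `c(condition_a, condition_b)` or `NULL` for the first two
#'   conditions in design order.
#' @param pca Run the noise-aware PCA track?
#' @param pca_k Number of PCA components.
#' @param top_n Molecules in the heat map.
#' @param whisker_molecules Molecule ids to draw whisker plots for; `NULL`
#'   means the top 3 ranked molecules.
#' @param seed Integer seed (PCA initialization tie-breaks).
#' @param quiet Suppress stage log messages?
#' @return A list of class `run_config`.
#' @export
run_config <- function(matrix_path, design_path, out_dir,
                       normalize = c("none", "median", "vstab"),
                       vstab_c = "auto", log_base = 2,
                       summarize = c("mean", "median", "trimmed_mean"),
                       trim = 0.1, contrast = NULL, pca = TRUE, pca_k = 3L,
                       top_n = 25L, whisker_molecules = NULL, seed = 1L,
                       quiet = FALSE) {
  structure(list(matrix_path = matrix_path, design_path = design_path,
                 out_dir = out_dir, normalize = match.arg(normalize),
                 vstab_c = vstab_c, log_base = log_base,
                 summarize = match.arg(summarize), trim = trim,
                 contrast = contrast, pca = isTRUE(pca),
                 pca_k = as.integer(pca_k), top_n = as.integer(top_n),
                 whisker_molecules = whisker_molecules,
                 seed = as.integer(seed), quiet = isTRUE(quiet)),
            class = "run_config")
}

.stage <- function(config, name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(force(expr), error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  if (!config$quiet)
    message(sprintf("[%s] %s done in %.2fs",
                    format(Sys.time(), "%H:%M:%S"), name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full replicate-variance analysis pipeline
#'
#' Read, validate, optionally normalize, summarize technical replicates,
#' score the contrast with both the PPLR and the moderated-t track, fit the
#' noise-aware PCA, cluster the top molecules and render the report.
#' The moderated-t comparator always runs on mean-summarized data, whatever
#' summarization the PPLR track uses.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the main intermediate results (`dataset`,
#'   `summary`, `ranking`, `pca_model`, `pca_scores`, `heatmap`, `out_dir`,
#'   `contrast`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  table <- .stage(config, "read",
                  read_intensity_table(config$matrix_path))
  design <- .stage(config, "design", read_design(config$design_path))
  ds <- .stage(config, "validate", validate_dataset(table, design))

  if (config$normalize == "median") {
    ds <- .stage(config, "normalize", {
      norm <- median_scale(ds$table)
      validate_dataset(norm$table, design)
    })
  } else if (config$normalize == "vstab") {
    ds <- .stage(config, "normalize", {
      lin <- intensity_table(config$log_base^unclass(ds$table))
      norm <- vstab_transform(lin, config$vstab_c)
      validate_dataset(norm$table, design)
    })
  }

  conds <- unique(design$condition)
  contrast <- config$contrast
  if (is.null(contrast)) contrast <- conds[1:2]
  miss <- setdiff(contrast, conds)
  if (length(miss))
    stop(sprintf("[contrast] condition(s) %s not in design; available: %s",
                 paste(miss, collapse = ", "),
                 paste(conds, collapse = ", ")), call. = FALSE)

  summ <- .stage(config, "summarize",
                 summarize_technical(ds, config$summarize, config$trim))
  summ_mean <- if (config$summarize == "mean") summ else
    .stage(config, "summarize-mean", summarize_technical(ds, "mean"))

  pplr_res <- .stage(config, "pplr",
                     pplr_analysis(summ, contrast[1], contrast[2]))
  eb_res <- .stage(config, "ebayes",
                   moderated_t_test(summ_mean, NULL, contrast[1], contrast[2]))
  ranking <- .stage(config, "rank",
                    ranking_table(pplr_res, eb_res, config$log_base))

  pca_model <- NULL; scores <- NULL
  if (config$pca) {
    pca_model <- .stage(config, "noise-pca",
                        fit_noise_pca(summ$y, summ$nu, k = config$pca_k,
                                      seed = config$seed))
    scores <- .stage(config, "pca-scores", {
      sc <- pca_scores(pca_model, min(pca_model$k, 3L))
      sc$condition <- summ$samples$condition[
        match(sc$sample_id, summ$samples$sample_id)]
      sc
    })
  }

  hm <- .stage(config, "cluster",
               heatmap_matrix(summ, ranking, min(config$top_n, nrow(ranking))))

  wids <- config$whisker_molecules
  if (is.null(wids)) wids <- utils::head(ranking$molecule_id, 3L)
  whiskers <- lapply(wids, function(id) whisker_data(ds, id))
  names(whiskers) <- wids

  .stage(config, "report",
         render_report(ranking, whiskers, scores, hm, config$out_dir))
  invisible(list(dataset = ds, summary = summ, ranking = ranking,
                 pca_model = pca_model, pca_scores = scores, heatmap = hm,
                 out_dir = config$out_dir, contrast = contrast))
}
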