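#' Construct an intensity table
#'
#' An intensity table is a numeric matrix of log-scale intensities with
#' biomolecules (proteins or metabolites) as rows and measurement runs as
#' columns. Row and column names are the molecule and run identifiers and
#' must be unique; entries may be `NA` (missing) but non-missing entries
#' must be finite.
#'
#' @param values Numeric matrix with unique rownames (molecule ids) and
#'   unique colnames (run ids).
#' @return An object of class `intensity_table` (a validated numeric matrix).
#' @export
intensity_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("intensity table values must be a numeric matrix", call. = FALSE)
  mids <- rownames(values)
  rids <- colnames(values)
  if (is.null(mids) || is.null(rids))
    stop("intensity table requires molecule (row) and run (column) names",
         call. = FALSE)
  dup <- unique(mids[duplicated(mids)])
  if (length(dup))
    stop("duplicate molecule id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  dup <- unique(rids[duplicated(rids)])
  if (length(dup))
    stop("duplicate run id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  bad <- which(!is.na(values) & !is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite intensity at row %d, column %d",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  structure(values, class = c("intensity_table", class(values)))
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("intensity_table: %d molecules x %d runs (%d missing values)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Read a tab-delimited intensity matrix
#'
#' Reads the canonical input format: a plain TSV whose first row holds the
#' run ids and whose first column holds the molecule ids, all remaining cells
#' being log-scale intensities. Cells equal to one of `missing_token` are
#' treated as missing. Unix and Windows line endings are accepted; no
#' quoting is interpreted.
#'
#' @param path Path to the TSV file.
#' @param missing_token Character vector of cell values treated as missing;
#'   defaults to the empty cell and `"NA"`.
#' @return An [intensity_table()].
#' @export
read_intensity_table <- function(path, missing_token = c("", "NA")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty intensity file: ", path, call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  # tolerate an (empty or labelled) corner cell above the molecule-id column
  run_ids <- header[-1]
  if (!length(run_ids) || length(cells) < 2)
    stop("intensity file needs a header of run ids and at least one molecule row",
         call. = FALSE)
  n_col <- length(header)
  body <- cells[-1]
  mol_ids <- vapply(body, `[`, character(1), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(run_ids))
  for (r in seq_along(body)) {
    row <- body[[r]]
    if (length(row) != n_col)
      stop(sprintf("row %d has %d fields, expected %d", r + 1L,
                   length(row), n_col), call. = FALSE)
    cell <- row[-1]
    miss <- cell %in% missing_token
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at row %d, column %d",
                   cell[bad[1]], r + 1L, bad[1] + 1L), call. = FALSE)
    num[miss] <- NA_real_
    vals[r, ] <- num
  }
  dimnames(vals) <- list(mol_ids, run_ids)
  intensity_table(vals)
}

#' Construct a replicate design
#'
#' Maps every measurement run to its biological condition, biological
#' replicate and technical replicate. The (condition, bio_rep, tech_rep)
#' triples must be unique; run order is preserved.
#'
#' @param run_id,condition,bio_rep,tech_rep Character vectors of equal length.
#' @return A data frame of class `replicate_design`.
#' @export
replicate_design <- function(run_id, condition, bio_rep, tech_rep) {
  d <- data.frame(run_id = as.character(run_id),
                  condition = as.character(condition),
                  bio_rep = as.character(bio_rep),
                  tech_rep = as.character(tech_rep),
                  stringsAsFactors = FALSE)
  dup <- duplicated(d$run_id)
  if (any(dup))
    stop("duplicate run id(s): ", paste(unique(d$run_id[dup]), collapse = ", "),
         call. = FALSE)
  key <- paste(d$condition, d$bio_rep, d$tech_rep, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- d[which(dup)[1], ]
    stop(sprintf("duplicate (condition, bio_rep, tech_rep) triple: (%s, %s, %s)",
                 first$condition, first$bio_rep, first$tech_rep), call. = FALSE)
  }
  class(d) <- c("replicate_design", "data.frame")
  d
}

#' Read a design sheet
#'
#' The design sheet is a TSV with header columns `run_id`, `condition`,
#' `bio_rep` and `tech_rep`, one row per measurement run.
#'
#' @param path Path to the design TSV.
#' @return A [replicate_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  required <- c("run_id", "condition", "bio_rep", "tech_rep")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("design sheet is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  replicate_design(d$run_id, d$condition, d$bio_rep, d$tech_rep)
}

#' Reconcile an intensity table with its design
#'
#' Checks that the set of runs in the table and in the design coincide, and
#' builds the grouping index condition -> biological sample -> runs that the
#' summarization step consumes.
#'
#' @param table An [intensity_table()].
#' @param design A [replicate_design()].
#' @return A list of class `replicate_dataset` with elements `table`,
#'   `design` and `groups` (nested named list: condition, then biological
#'   sample label `condition.bio_rep`, holding run ids).
#' @export
validate_dataset <- function(table, design) {
  stopifnot(inherits(table, "intensity_table"),
            inherits(design, "replicate_design"))
  only_design <- setdiff(design$run_id, colnames(table))
  only_table <- setdiff(colnames(table), design$run_id)
  if (length(only_design) || length(only_table))
    stop("runs present in only one input: ",
         paste(c(only_design, only_table), collapse = ", "), call. = FALSE)
  conds <- unique(design$condition)
  groups <- lapply(conds, function(ci) {
    sub <- design[design$condition == ci, , drop = FALSE]
    bios <- unique(sub$bio_rep)
    g <- lapply(bios, function(bj) sub$run_id[sub$bio_rep == bj])
    names(g) <- bios
    g
  })
  names(groups) <- conds
  structure(list(table = table, design = design, groups = groups),
            class = "replicate_dataset")
}

#' @export
print.replicate_dataset <- function(x, ...) {
  cat(sprintf("replicate_dataset: %d molecules, %d runs, %d conditions\n",
              nrow(x$table), ncol(x$table), length(x$groups)))
  invisible(x)
}

#' Write a ranking table to TSV
#'
#' Writes the differential-abundance ranking table with numeric fields at six
#' significant digits, so that a write/read round trip preserves values at
#' that precision.
#'
#' @param results Ranking table data frame (see [ranking_table()]).
#' @param path Output path.
#' @export
write_ranking_table <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0)
    stop("ranking table is empty; nothing to write", call. = FALSE)
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6L)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a ranking table written by [write_ranking_table()]
#'
#' @param path Path to the ranking TSV.
#' @return A data frame.
#' @export
read_ranking_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
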