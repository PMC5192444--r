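table_sep <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a feature table (samples x variables) from CSV/TSV
#'
#' First column: sample ids; header row: variable names; body: numeric peak
#' areas/intensities, with empty cells read as missing (`NA`). Duplicate
#' sample ids and non-numeric cells are rejected with their coordinates.
#'
#' @param path CSV (default) or TSV (`.tsv`/`.txt`) file.
#' @return Numeric matrix with sample ids as row names.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  raw <- utils::read.table(path, sep = table_sep(path), header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("", "NA"), quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2L) stop("feature table needs sample ids plus >= 1 variable")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- raw[-1L]
  x <- matrix(NA_real_, nrow(raw), ncol(body),
              dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]))
    if (length(bad))
      stop("non-numeric cell at sample '", ids[bad[1L]], "', variable '",
           colnames(body)[j], "': '", body[[j]][bad[1L]], "'")
    x[, j] <- v
  }
  x
}

#' Write a feature table to CSV/TSV
#'
#' @param x Numeric matrix with sample ids as row names; `NA` cells are
#'   written empty.
#' @param path Output path (`.tsv`/`.txt` switches to tab separation).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  x <- as.matrix(x)
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = table_sep(path), row.names = FALSE,
                     na = "", qmethod = "double", quote = TRUE)
  invisible(path)
}

#' Read a design table from CSV/TSV
#'
#' Expected columns: `sample_id`, `replicate_id`, and one column per
#' experimental factor.
#'
#' @param path CSV/TSV file.
#' @return Data frame of character columns.
#' @export
read_design_table <- function(path) {
  if (!file.exists(path)) stop("design table not found: ", path)
  d <- utils::read.table(path, sep = table_sep(path), header = TRUE,
                         check.names = FALSE, colClasses = "character",
                         quote = "\"", comment.char = "")
  for (k in c("sample_id", "replicate_id"))
    if (!k %in% colnames(d)) stop("design table lacks column '", k, "'")
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample id(s) in design table")
  d
}

#' Write a design table to CSV/TSV
#' @param design Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(design, path) {
  utils::write.table(design, path, sep = table_sep(path), row.names = FALSE,
                     quote = TRUE, qmethod = "double")
  invisible(path)
}

#' Export a synthetic dataset to files
#'
#' Writes `features.csv`, `design.csv` and `truth.json` (affected-feature
#' masks, seed and the effect specification) into a directory.
#'
#' @param dataset A [generate()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(dataset$features, file.path(out_dir, "features.csv"))
  write_design_table(dataset$design, file.path(out_dir, "design.csv"))
  truth <- list(seed = dataset$seed, masks = dataset$masks,
                spec = dataset$spec[c("n_features", "replicates", "noise_sd")],
                factors = lapply(dataset$spec$factors, function(f)
                  f[c("name", "type", "effect_size", "affected_fraction")]))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a run configuration
#'
#' @param features,design,scheme In-memory objects (matrix / data frame /
#'   `coding_scheme`) or file paths.
#' @param n_iterations Outer double-CV iterations (default 1000).
#' @param max_lv Optional cap on latent variables.
#' @param seed Master seed, recorded in every output.
#' @param permutation Run the permutation test as well?
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param mode `"structured"` (use `scheme` as given), `"all-cells-binary"`
#'   (one-of-k over populated cells) or `"per-factor-binary"` (a separate
#'   one-of-k model per factor).
#' @param knn_k Neighbours for imputation when the feature table has
#'   missing cells.
#' @return A `run_config` list.
#' @export
run_config <- function(features, design, scheme = NULL,
                       n_iterations = 1000L, max_lv = NULL, seed = 1L,
                       permutation = FALSE, out_dir = NULL,
                       mode = c("structured", "all-cells-binary",
                                "per-factor-binary"),
                       knn_k = 5L) {
  mode <- match.arg(mode)
  if (mode == "structured" && is.null(scheme))
    stop("structured mode needs a coding scheme")
  structure(list(features = features, design = design, scheme = scheme,
                 n_iterations = as.integer(n_iterations), max_lv = max_lv,
                 seed = as.integer(seed), permutation = isTRUE(permutation),
                 out_dir = out_dir, mode = mode, knn_k = as.integer(knn_k)),
            class = "run_config")
}

resolve_input <- function(x, reader) if (is.character(x)) reader(x) else x

config_echo <- function(config) {
  list(n_iterations = config$n_iterations,
       max_lv = config$max_lv %||% NA,
       seed = config$seed, permutation = config$permutation,
       mode = config$mode, knn_k = config$knn_k,
       features = if (is.character(config$features)) config$features
                  else "<in-memory>",
       design = if (is.character(config$design)) config$design
                else "<in-memory>",
       scheme = if (is.character(config$scheme)) config$scheme
                else if (is.null(config$scheme)) NA else "<in-memory>")
}

#' Run the full validation pipeline from a configuration
#'
#' Loads (or takes in memory) the feature table, design table and coding
#' scheme, checks that sample ids match one-to-one, reorders the feature
#' rows to the design order, KNN-imputes any missing cells, encodes Y per
#' the requested comparison mode, runs [double_cv()] (and
#' [permutation_test()] if enabled), and -- when `out_dir` is set -- writes
#' one confusion CSV per block plus a JSON summary carrying CCRs,
#' conditional CCRs, p-values, the selected-LV histogram, the seed and a
#' config echo sufficient to reproduce the run.
#'
#' @param config A [run_config()].
#' @return The `validation_report` (structured / all-cells modes) or a
#'   named list of per-factor reports (`per-factor-binary`), invisibly
#'   when written to disk. All-cells runs carry the `cell_coding()` map as
#'   attribute `"cell_map"`.
#' @export
run_validate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  X <- resolve_input(config$features, read_feature_table)
  design <- resolve_input(config$design, read_design_table)
  X <- as.matrix(X)
  if (is.null(rownames(X))) stop("feature table needs sample ids as row names")
  orphans_x <- setdiff(rownames(X), design$sample_id)
  orphans_d <- setdiff(design$sample_id, rownames(X))
  if (length(orphans_x) || length(orphans_d))
    stop("sample ids do not match 1-1; only in features: [",
         paste(orphans_x, collapse = ", "), "]; only in design: [",
         paste(orphans_d, collapse = ", "), "]")
  X <- X[design$sample_id, , drop = FALSE]   # canonical order = design order
  if (anyNA(X)) X <- knn_impute(X, config$knn_k)

  mode <- config$mode
  if (mode == "structured") {
    scheme <- resolve_input(config$scheme, read_coding_scheme)
    report <- double_cv(X, design, scheme, config$n_iterations,
                        config$max_lv, config$seed)
    perm <- if (config$permutation)
      permutation_test(X, design, scheme, config$n_iterations,
                       config$max_lv, config$seed)
    if (!is.null(perm)) report$p_values <- perm$p_values
  } else if (mode == "all-cells-binary") {
    cc <- cell_coding(design)
    report <- double_cv(X, cc$design, cc$scheme, config$n_iterations,
                        config$max_lv, config$seed)
    perm <- if (config$permutation)
      permutation_test(X, cc$design, cc$scheme, config$n_iterations,
                       config$max_lv, config$seed)
    if (!is.null(perm)) report$p_values <- perm$p_values
    attr(report, "cell_map") <- cc$map
  } else {
    factors <- design_factors(design)
    report <- lapply(factors, function(f) {
      d1 <- design[c("sample_id", "replicate_id", f)]
      sc1 <- coding_scheme(factor_block(f, unique(as.character(design[[f]]))))
      r <- double_cv(X, d1, sc1, config$n_iterations, config$max_lv,
                     config$seed)
      if (config$permutation)
        r$p_values <- permutation_test(X, d1, sc1, config$n_iterations,
                                       config$max_lv, config$seed)$p_values
      r
    })
    names(report) <- factors
  }

  if (!is.null(config$out_dir)) {
    write_validation_report(report, config$out_dir, config)
    return(invisible(report))
  }
  report
}

format_confusion <- function(m) {
  df <- data.frame(level = rownames(m),
                   round(m, 2), check.names = FALSE,
                   stringsAsFactors = FALSE)
  df
}

report_summary_list <- function(report) {
  list(ccr = as.list(report$ccr),
       conditional = report$conditional,
       p_values = if (!is.null(report$p_values)) as.list(report$p_values)
                  else NULL,
       lv_histogram = as.list(table(report$lv_selected)),
       n_iterations = report$n_iterations,
       rng_seed = report$rng_seed,
       blocks = report$blocks)
}

#' Write a validation report to disk
#'
#' One `<block>_confusion.csv` per block (row/column labels are the factor
#' levels, percentages to 2 decimals) and a `summary.json` carrying the
#' full-precision CCRs, conditional CCRs, permutation p-values (when
#' present), the selected-LV histogram, the seed and the config echo.
#'
#' @param report A `validation_report` or named list of them
#'   (per-factor-binary mode).
#' @param out_dir Output directory (created if needed).
#' @param config Optional [run_config()] echoed into the summary.
#' @return `out_dir`, invisibly.
#' @export
write_validation_report <- function(report, out_dir, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- if (inherits(report, "validation_report"))
    list(report) else report
  summary <- list()
  for (k in seq_along(reports)) {
    r <- reports[[k]]
    prefix <- if (length(reports) > 1L) paste0(names(reports)[k], "_") else ""
    for (b in r$blocks)
      utils::write.csv(format_confusion(r$confusion[[b]]),
                       file.path(out_dir, paste0(prefix, b, "_confusion.csv")),
                       row.names = FALSE)
    summary[[if (prefix == "") "report" else names(reports)[k]]] <-
      report_summary_list(r)
  }
  if (!is.null(config)) summary$config <- config_echo(config)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}
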