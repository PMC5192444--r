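design_factors <- function(design) {
  setdiff(colnames(design), c("sample_id", "replicate_id"))
}

label_matrix <- function(design, scheme) {
  nms <- block_names(scheme)
  m <- vapply(nms, function(f) as.character(design[[f]]),
              character(nrow(design)))
  matrix(m, nrow = nrow(design), dimnames = list(NULL, nms))
}

cell_key <- function(design, factors) {
  do.call(paste, c(lapply(factors, function(f) as.character(design[[f]])),
                   sep = "\r"))
}

#' Split samples into training and test sets by biological replicate
#'
#' From every populated design cell (unique combination of all factor
#' levels) one biological replicate is drawn uniformly at random and its
#' samples form the blind test set; the remaining replicates train the
#' model. This keeps replicates of the same culture from straddling the
#' train/test boundary.
#'
#' @param design Data frame with a `replicate_id` column plus one column
#'   per factor (`sample_id` is carried along if present).
#' @param rng_seed Integer seed; the same seed always yields the same plan.
#' @return Object of class `split_plan`: list with integer row indices
#'   `test` and `train`, and `seed`.
#' @export
make_split <- function(design, rng_seed) {
  if (!"replicate_id" %in% colnames(design))
    stop("design table needs a 'replicate_id' column")
  factors <- design_factors(design)
  if (length(factors) == 0L) stop("design table has no factor columns")
  key <- cell_key(design, factors)
  cells <- unique(key)
  set.seed(rng_seed)
  test <- integer(0)
  for (cl in cells) {
    rows <- which(key == cl)
    reps <- unique(as.character(design$replicate_id[rows]))
    if (length(reps) < 2L)
      stop("cell '", gsub("\r", "/", cl),
           "' has a single replicate; cannot split it")
    pick <- reps[sample.int(length(reps), 1L)]
    test <- c(test, rows[design$replicate_id[rows] == pick])
  }
  test <- sort(test)
  structure(list(test = test,
                 train = setdiff(seq_len(nrow(design)), test),
                 seed = rng_seed),
            class = "split_plan")
}

default_max_lv <- function(n_train, p) max(1L, min(15L, n_train - 2L, p))

# Predictions of a fitted model for one sample at every component count
# 1..A; returns A x q matrix.
predict_all_ncomp <- function(model, x) {
  A <- model$n_components
  tn <- drop((x - model$x_mean) %*% model$projection)  # length A
  contrib <- model$y_loadings * matrix(tn, nrow(model$y_loadings), A,
                                       byrow = TRUE)   # q x A
  Yh <- apply(contrib, 1L, cumsum)                      # A x q
  if (is.null(dim(Yh))) Yh <- matrix(Yh, ncol = 1L)
  sweep(Yh, 2L, model$y_mean, `+`)
}

#' Choose the number of latent variables by leave-one-out cross-validation
#'
#' For every candidate component count `1..max_lv`, each training sample is
#' held out in turn, the model is fitted on the rest, the held-out sample's
#' prediction is crisped, and its block misassignment count is accumulated.
#' The component count with the smallest total error wins; ties go to the
#' smallest count.
#'
#' @param X_train,Y_train Training feature matrix and encoded target.
#' @param scheme The [coding_scheme()] used to encode `Y_train`.
#' @param max_lv Largest candidate count (clamped to `min(n - 2, p)` so
#'   every leave-one-out fit is well defined).
#' @return The chosen component count (integer), with the LOOCV error
#'   totals per candidate attached as attribute `"errors"`.
#' @export
select_n_components <- function(X_train, Y_train, scheme, max_lv) {
  X_train <- as.matrix(X_train); Y_train <- as.matrix(Y_train)
  n <- nrow(X_train)
  if (n < 3L) stop("training set must have at least 3 samples")
  if (max_lv < 1L) stop("max_lv must be >= 1")
  max_lv <- min(as.integer(max_lv), n - 2L, ncol(X_train))
  truth <- crisp(Y_train, scheme)
  truth <- as.matrix(truth)
  err <- integer(max_lv)
  for (i in seq_len(n)) {
    m <- fit_pls(X_train[-i, , drop = FALSE], Y_train[-i, , drop = FALSE],
                 max_lv)
    Yh <- predict_all_ncomp(m, X_train[i, ])
    for (a in seq_len(max_lv)) {
      pred <- crisp(Yh[min(a, m$n_components), ], scheme)
      err[a] <- err[a] + block_errors(pred, truth[i, ])
    }
  }
  best <- which.min(err)   # first minimum = smallest component count
  structure(as.integer(best), errors = err)
}

# One outer pass: LV selection on the training rows, fit, predict and crisp
# the test rows. Returns predictions, truth, chosen LV count and per-block
# test error counts.
run_split <- function(X, Y, labels, scheme, split, max_lv = NULL) {
  tr <- split$train; te <- split$test
  ml <- if (is.null(max_lv)) default_max_lv(length(tr), ncol(X))
        else min(max_lv, length(tr) - 2L, ncol(X))
  A <- select_n_components(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                           scheme, ml)
  m <- fit_pls(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], A)
  pred <- as.matrix(crisp(predict(m, X[te, , drop = FALSE]), scheme))
  truth <- labels[te, , drop = FALSE]
  errors <- colSums(pred != truth)
  list(pred = pred, truth = truth, n_components = A, errors = errors,
       test = te)
}

#' Replicate-aware double cross-validation of a structured PLS model
#'
#' Each iteration draws a replicate-stratified train/test split
#' ([make_split()]), picks the latent-variable count by leave-one-out
#' cross-validation on the training set ([select_n_components()]), fits the
#' model on the full training set, predicts and crisps the blind test set,
#' and tallies one confusion matrix per block (row percentages: true level
#' by predicted level). Confusion matrices, per-block correct
#' classification rates (CCR) and conditional CCRs are averaged over
#' iterations.
#'
#' @param X Feature matrix, samples x variables, rows aligned with `design`.
#' @param design Design data frame (`replicate_id` plus factor columns).
#' @param scheme The [coding_scheme()].
#' @param n_iterations Number of random splits (the reference workflow uses
#'   1000).
#' @param max_lv Cap on candidate latent variables (default
#'   `min(15, n_train - 2, p)`).
#' @param rng_seed Integer master seed; the full report is reproducible
#'   from it.
#' @return Object of class `validation_report`: `confusion` (named list of
#'   averaged row-percentage matrices), `ccr` (named, %),
#'   `ccr_iterations` (per-iteration CCR matrix), `conditional`
#'   (averaged CCR of each block within each true level of every other
#'   block), `lv_selected` (per-iteration counts), plus the call
#'   configuration.
#' @seealso [permutation_test()], [conditional_ccr()]
#' @export
double_cv <- function(X, design, scheme, n_iterations = 1000L,
                      max_lv = NULL, rng_seed = 1L) {
  X <- as.matrix(X)
  stopifnot(inherits(scheme, "coding_scheme"), nrow(X) == nrow(design))
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  Y <- encode_design(design, scheme)
  labels <- label_matrix(design, scheme)
  nms <- block_names(scheme)
  lev <- lapply(scheme$blocks, `[[`, "levels")
  set.seed(rng_seed)
  it_seeds <- sample.int(.Machine$integer.max, n_iterations)

  conf_sum <- lapply(lev, function(l) matrix(0, length(l), length(l),
                                             dimnames = list(l, l)))
  conf_cnt <- lapply(lev, function(l) matrix(0L, length(l), length(l),
                                             dimnames = list(l, l)))
  pairs <- expand.grid(a = nms, b = nms, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  cond_sum <- cond_cnt <- list()
  for (i in seq_len(nrow(pairs))) {
    key <- paste(pairs$a[i], pairs$b[i], sep = "|")
    lb <- lev[[pairs$b[i]]]
    cond_sum[[key]] <- stats::setNames(numeric(length(lb)), lb)
    cond_cnt[[key]] <- stats::setNames(integer(length(lb)), lb)
  }
  ccr_it <- matrix(NA_real_, n_iterations, length(nms),
                   dimnames = list(NULL, nms))
  lv_selected <- integer(n_iterations)

  for (it in seq_len(n_iterations)) {
    split <- make_split(design, it_seeds[it])
    res <- run_split(X, Y, labels, scheme, split, max_lv)
    lv_selected[it] <- res$n_components
    for (b in nms) {
      tb <- table(factor(res$truth[, b], levels = lev[[b]]),
                  factor(res$pred[, b], levels = lev[[b]]))
      rs <- rowSums(tb)
      present <- rs > 0
      pct <- tb
      pct[present, ] <- 100 * tb[present, , drop = FALSE] / rs[present]
      conf_sum[[b]][present, ] <- conf_sum[[b]][present, , drop = FALSE] +
        pct[present, , drop = FALSE]
      conf_cnt[[b]][present, ] <- conf_cnt[[b]][present, , drop = FALSE] + 1L
      ccr_it[it, b] <- 100 * mean(res$pred[, b] == res$truth[, b])
    }
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$a[i]; b <- pairs$b[i]
      key <- paste(a, b, sep = "|")
      for (lb in lev[[b]]) {
        in_str <- res$truth[, b] == lb
        if (any(in_str)) {
          cond_sum[[key]][lb] <- cond_sum[[key]][lb] +
            100 * mean(res$pred[in_str, a] == res$truth[in_str, a])
          cond_cnt[[key]][lb] <- cond_cnt[[key]][lb] + 1L
        }
      }
    }
  }

  confusion <- lapply(nms, function(b) {
    m <- conf_sum[[b]] / pmax(conf_cnt[[b]], 1L)
    m[conf_cnt[[b]] == 0L] <- NA_real_
    m
  })
  names(confusion) <- nms
  conditional <- lapply(names(cond_sum), function(key) {
    v <- cond_sum[[key]] / pmax(cond_cnt[[key]], 1L)
    v[cond_cnt[[key]] == 0L] <- NA_real_   # empty stratum: missing, not zero
    v
  })
  names(conditional) <- names(cond_sum)
  structure(list(confusion = confusion,
                 ccr = colMeans(ccr_it),
                 ccr_iterations = ccr_it,
                 conditional = conditional,
                 lv_selected = lv_selected,
                 n_iterations = n_iterations,
                 max_lv = max_lv,
                 rng_seed = rng_seed,
                 blocks = nms,
                 levels = lev),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report:", x$n_iterations, "iteration(s), blocks:",
      paste(x$blocks, collapse = ", "), "\n")
  for (b in x$blocks)
    cat(sprintf("  %s: CCR %.2f%%%s\n", b, x$ccr[b],
                if (!is.null(x$p_values) && b %in% names(x$p_values))
                  sprintf(", permutation p = %.4g", x$p_values[b]) else ""))
  lvs <- table(x$lv_selected)
  cat("  LVs selected:",
      paste(sprintf("%s (x%d)", names(lvs), as.integer(lvs)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Permutation test for the significance of each factor
#'
#' Each iteration runs the double-CV pipeline twice: once with the true
#' labels (observed errors) and once after permuting the label tuples --
#' whole design rows of factor levels and replicate id -- across samples
#' before splitting (null errors). The empirical p-value of a block is the
#' fraction of iterations in which the observed block error exceeded
#' (strictly) the null block error; ties count as non-exceedances, which
#' makes the estimate slightly anti-conservative.
#'
#' @inheritParams double_cv
#' @return List with `p_values` (named, per block), and the per-iteration
#'   `observed_errors` and `null_errors` count matrices.
#' @export
permutation_test <- function(X, design, scheme, n_iterations = 1000L,
                             max_lv = NULL, rng_seed = 1L) {
  X <- as.matrix(X)
  stopifnot(inherits(scheme, "coding_scheme"), nrow(X) == nrow(design))
  Y <- encode_design(design, scheme)
  labels <- label_matrix(design, scheme)
  nms <- block_names(scheme)
  set.seed(rng_seed)
  seeds <- matrix(sample.int(.Machine$integer.max, 3L * n_iterations),
                  ncol = 3L)
  obs <- null <- matrix(0L, n_iterations, length(nms),
                        dimnames = list(NULL, nms))
  perm_cols <- c(design_factors(design), "replicate_id")
  for (it in seq_len(n_iterations)) {
    split <- make_split(design, seeds[it, 1L])
    obs[it, ] <- run_split(X, Y, labels, scheme, split, max_lv)$errors
    set.seed(seeds[it, 2L])
    perm <- sample.int(nrow(design))
    design_null <- design
    design_null[perm_cols] <- design[perm, perm_cols]
    split_null <- make_split(design_null, seeds[it, 3L])
    null[it, ] <- run_split(X, Y[perm, , drop = FALSE], labels[perm, ,
                            drop = FALSE], scheme, split_null,
                            max_lv)$errors
  }
  p <- colMeans(obs > null)
  list(p_values = p, observed_errors = obs, null_errors = null)
}

#' Conditional CCR of one block within the levels of another
#'
#' Reads the averaged conditional tallies out of a [double_cv()] report:
#' the CCR of `block_a` restricted to test samples whose *true* `block_b`
#' level is fixed, averaged over iterations. Strata never populated are
#' reported as `NA`.
#'
#' @param report A `validation_report`.
#' @param block_a Block whose prediction accuracy is evaluated.
#' @param block_b Block whose true levels define the strata.
#' @return Data frame with columns `level` (of `block_b`) and `ccr` (%).
#' @export
conditional_ccr <- function(report, block_a, block_b) {
  stopifnot(inherits(report, "validation_report"))
  if (!block_a %in% report$blocks || !block_b %in% report$blocks)
    stop("both blocks must be in the report: ",
         paste(report$blocks, collapse = ", "))
  v <- report$conditional[[paste(block_a, block_b, sep = "|")]]
  data.frame(level = names(v), ccr = unname(v), stringsAsFactors = FALSE)
}

#' Most frequently selected latent-variable count of a report
#'
#' Convenience for fitting a final model (e.g. for VIP scores) with the
#' modal LV count across double-CV iterations; ties go to the smaller
#' count.
#'
#' @param report A `validation_report`.
#' @return Integer.
#' @export
modal_lv <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  tb <- table(report$lv_selected)
  as.integer(names(tb)[which.max(tb)])
}

#' Express an all-cells one-of-k ("binary") coding of a design
#'
#' Builds the classic PLS-DA comparison scheme: a single categorical block
#' whose levels are the populated factor combinations, so multi-class
#' binary coding runs through exactly the same pipeline as structured
#' coding.
#'
#' @param design Design data frame.
#' @param codes Off/on pair for the one-of-k block (default 0/1).
#' @param sep Separator used to build cell labels from factor levels.
#' @return List with `scheme` (single-block [coding_scheme()]), `design`
#'   (input design with the `cell` factor column replacing the original
#'   factor columns) and `map` (data frame linking each cell label to its
#'   factor levels).
#' @export
cell_coding <- function(design, codes = c(0, 1), sep = "/") {
  factors <- design_factors(design)
  lab <- do.call(paste, c(lapply(factors, function(f)
    as.character(design[[f]])), sep = sep))
  cells <- unique(lab)
  map <- unique(data.frame(cell = lab,
                           design[factors],
                           stringsAsFactors = FALSE))
  rownames(map) <- NULL
  d2 <- design[setdiff(colnames(design), factors)]
  d2$cell <- lab
  list(scheme = coding_scheme(factor_block("cell", cells, "categorical",
                                           codes)),
       design = d2, map = map)
}

#' Project an all-cells confusion matrix back onto one factor
#'
#' Given a [double_cv()] report run under [cell_coding()], aggregates the
#' cell-level averaged confusion matrix into a factor-level confusion
#' matrix: predicted cells are summed by their factor level and true cells
#' averaged by theirs (every populated cell contributes one test sample per
#' iteration, so cell rows carry equal weight).
#'
#' @param report `validation_report` with a single `cell` block.
#' @param map The `map` element returned by [cell_coding()].
#' @param factor_name Which original factor to recover.
#' @return List with `confusion` (factor-level row-percentage matrix) and
#'   `ccr` (%).
#' @export
recover_factor_confusion <- function(report, map, factor_name) {
  stopifnot(inherits(report, "validation_report"))
  if (!identical(report$blocks, "cell"))
    stop("report must come from an all-cells (cell_coding) run")
  if (!factor_name %in% colnames(map)) stop("unknown factor: ", factor_name)
  M <- report$confusion[["cell"]]
  fac <- map[[factor_name]][match(rownames(M), map$cell)]
  levs <- unique(map[[factor_name]])
  out <- matrix(0, length(levs), length(levs), dimnames = list(levs, levs))
  for (la in levs) {
    rows <- which(fac == la)
    for (lb in levs) {
      cols <- which(fac == lb)
      out[la, lb] <- mean(rowSums(M[rows, cols, drop = FALSE]))
    }
  }
  list(confusion = out, ccr = sum(diag(out) * table(fac)[levs]) /
         length(fac))
}
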