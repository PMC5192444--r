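#' Define one factor block of a structured target matrix
#'
#' A factor block describes how one experimental factor is written into the
#' target matrix Y. A *categorical* block occupies one column per level
#' (one-of-k sub-matrix): every column carries the block's `off` code except
#' the column of the sample's level, which carries the `on` code. An
#' *ordinal* block occupies a single column holding the level's coded value.
#'
#' @param name Character scalar, the factor name. Must match a column of the
#'   design table when encoding a dataset.
#' @param levels Character vector of unique level labels, in the order that
#'   defines the block's columns (categorical) or the code order (ordinal).
#' @param type `"categorical"` or `"ordinal"`.
#' @param codes For a categorical block, a numeric pair `c(off, on)`
#'   (default `c(0, 1)`). For an ordinal block, one coded value per level,
#'   strictly monotone in level order.
#'
#' @return An object of class `factor_block`.
#' @examples
#' factor_block("dosage", c("D0", "D1", "D2", "D3"), "ordinal",
#'              codes = c(0, 2, 4, 6))
#' @export
factor_block <- function(name, levels, type = c("categorical", "ordinal"),
                         codes = NULL) {
  type <- match.arg(type)
  levels <- as.character(levels)
  if (length(levels) < 1L) stop("block '", name, "': levels must be non-empty")
  if (anyDuplicated(levels)) stop("block '", name, "': levels must be unique")
  if (is.null(codes)) {
    if (type == "categorical") codes <- c(0, 1)
    else stop("block '", name, "': ordinal blocks need one code per level")
  }
  codes <- as.numeric(codes)
  if (type == "categorical") {
    if (length(codes) != 2L)
      stop("block '", name, "': categorical codes must be a pair (off, on)")
    if (codes[1L] == codes[2L])
      stop("block '", name, "': on code must differ from off code")
  } else {
    if (length(codes) != length(levels))
      stop("block '", name, "': ordinal codes must match the number of levels")
    d <- diff(codes)
    if (!(all(d > 0) || all(d < 0)))
      stop("block '", name, "': ordinal codes must be strictly monotone")
  }
  structure(list(name = as.character(name), type = type,
                 levels = levels, codes = codes),
            class = "factor_block")
}

block_width <- function(block) {
  if (block$type == "categorical") length(block$levels) else 1L
}

#' Assemble a coding scheme from factor blocks
#'
#' The scheme fixes the layout of the structured target matrix Y: blocks in
#' order, each owning a contiguous column range.
#'
#' @param ... `factor_block` objects, or a single list of them.
#' @return An object of class `coding_scheme` with elements `blocks`,
#'   `width`, `column_map` (named list of column index vectors) and
#'   `column_names`.
#' @examples
#' sc <- coding_scheme(
#'   factor_block("strain", c("S1", "S2", "S3"), codes = c(0, 6)),
#'   factor_block("dosage", c("D0", "D1", "D2", "D3"), "ordinal", c(0, 2, 4, 6))
#' )
#' sc$width
#' @export
coding_scheme <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1L && !inherits(blocks[[1L]], "factor_block"))
    blocks <- blocks[[1L]]
  if (length(blocks) == 0L) stop("a coding scheme needs at least one block")
  ok <- vapply(blocks, inherits, logical(1L), what = "factor_block")
  if (!all(ok)) stop("all arguments must be factor_block objects")
  nms <- vapply(blocks, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) stop("block names must be unique")
  names(blocks) <- nms
  widths <- vapply(blocks, block_width, integer(1L))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  column_map <- lapply(seq_along(blocks), function(b) starts[b]:ends[b])
  names(column_map) <- nms
  column_names <- unlist(lapply(blocks, function(b) {
    if (b$type == "categorical") paste(b$name, b$levels, sep = ".") else b$name
  }), use.names = FALSE)
  structure(list(blocks = blocks, width = sum(widths),
                 column_map = column_map, column_names = column_names),
            class = "coding_scheme")
}

#' @export
print.coding_scheme <- function(x, ...) {
  cat("coding_scheme:", length(x$blocks), "block(s),", x$width, "Y columns\n")
  for (b in x$blocks) {
    cat(sprintf("  %s [%s, %d col%s]: %s; codes %s\n", b$name, b$type,
                block_width(b), if (block_width(b) > 1L) "s" else "",
                paste(b$levels, collapse = ", "),
                paste(b$codes, collapse = "/")))
  }
  invisible(x)
}

block_names <- function(scheme) names(scheme$blocks)

#' Encode one sample's factor levels as a structured Y row
#'
#' @param labels Character vector with one level label per block, in block
#'   order (names, if present, are checked against the block names).
#' @param scheme A [coding_scheme()].
#' @return Numeric vector of length `scheme$width`.
#' @examples
#' sc <- coding_scheme(factor_block("f", c("a", "b")))
#' encode_sample("a", sc)  # c(1, 0)
#' @export
encode_sample <- function(labels, scheme) {
  stopifnot(inherits(scheme, "coding_scheme"))
  labels <- as.character(labels)
  if (length(labels) != length(scheme$blocks))
    stop("expected ", length(scheme$blocks), " labels, got ", length(labels))
  y <- numeric(scheme$width)
  for (b in seq_along(scheme$blocks)) {
    blk <- scheme$blocks[[b]]
    i <- match(labels[b], blk$levels)
    if (is.na(i))
      stop("block '", blk$name, "': unknown level '", labels[b], "'")
    cols <- scheme$column_map[[b]]
    if (blk$type == "categorical") {
      y[cols] <- blk$codes[1L]
      y[cols[i]] <- blk$codes[2L]
    } else {
      y[cols] <- blk$codes[i]
    }
  }
  names(y) <- scheme$column_names
  y
}

#' Encode a design table as a structured Y matrix
#'
#' @param design Data frame with one column per block (matched by block
#'   name); extra columns such as `sample_id` / `replicate_id` are ignored.
#' @param scheme A [coding_scheme()].
#' @return Numeric matrix, one encoded row per design row (row names taken
#'   from `design$sample_id` when present).
#' @export
encode_design <- function(design, scheme) {
  stopifnot(inherits(scheme, "coding_scheme"), is.data.frame(design))
  nms <- block_names(scheme)
  miss <- setdiff(nms, colnames(design))
  if (length(miss))
    stop("design table lacks factor column(s): ", paste(miss, collapse = ", "))
  Y <- matrix(0, nrow(design), scheme$width,
              dimnames = list(design$sample_id, scheme$column_names))
  for (i in seq_len(nrow(design))) {
    row <- vapply(nms, function(f) as.character(design[[f]][i]), character(1L))
    Y[i, ] <- tryCatch(encode_sample(row, scheme),
                       error = function(e) stop("design row ", i, ": ",
                                                conditionMessage(e)))
  }
  Y
}

crisp_block <- function(y, blk) {
  if (blk$type == "categorical") {
    # ties: first (lowest-index) level wins
    blk$levels[which.max(y)]
  } else {
    d <- abs(y - blk$codes)
    tol <- 1e-12 * max(1, abs(y), abs(blk$codes))
    cand <- which(d <= min(d) + tol)
    # equidistant midpoint: assign the lower coded level
    blk$levels[cand[which.min(blk$codes[cand])]]
  }
}

#' Crisp raw predictions back to factor levels
#'
#' Converts real-valued predicted Y rows into discrete level assignments:
#' within each categorical block the level of the arg-max column is taken
#' (ties to the lowest-index level); within each ordinal block the level
#' whose coded value is nearest in absolute difference (an exact midpoint is
#' assigned to the lower coded level).
#'
#' @param y_raw Numeric vector of length `scheme$width`, or a matrix with
#'   that many columns.
#' @param scheme A [coding_scheme()].
#' @return For a vector, a named character vector of level labels (one per
#'   block); for a matrix, a data frame with one column per block.
#' @examples
#' sc <- coding_scheme(
#'   factor_block("dosage", c("D0","D1","D2","D3"), "ordinal", c(0, 2, 4, 6)),
#'   factor_block("time", c("T0","T1","T2"), "ordinal", c(0, 1, 6)))
#' crisp(c(2.5, 0.8), sc)  # D1, T1
#' @export
crisp <- function(y_raw, scheme) {
  stopifnot(inherits(scheme, "coding_scheme"))
  if (is.matrix(y_raw)) {
    if (ncol(y_raw) != scheme$width)
      stop("expected ", scheme$width, " columns, got ", ncol(y_raw))
    out <- lapply(seq_along(scheme$blocks), function(b) {
      blk <- scheme$blocks[[b]]
      cols <- scheme$column_map[[b]]
      vapply(seq_len(nrow(y_raw)),
             function(i) crisp_block(y_raw[i, cols], blk), character(1L))
    })
    names(out) <- block_names(scheme)
    return(as.data.frame(out, optional = TRUE,
                         row.names = rownames(y_raw)))
  }
  if (length(y_raw) != scheme$width)
    stop("expected a vector of length ", scheme$width, ", got ", length(y_raw))
  out <- vapply(seq_along(scheme$blocks), function(b) {
    crisp_block(y_raw[scheme$column_map[[b]]], scheme$blocks[[b]])
  }, character(1L))
  names(out) <- block_names(scheme)
  out
}

#' Count misassigned blocks between predicted and true label tuples
#'
#' The structured-output error set: each sample's error is the number of
#' blocks whose predicted level differs from the true level, ranging over
#' 0..B for B blocks (Hamming distance on label tuples).
#'
#' @param predicted,truth Character vectors (one label per block) or data
#'   frames / matrices of labels with one column per block.
#' @return Integer vector of per-sample block error counts.
#' @export
block_errors <- function(predicted, truth) {
  p <- if (is.data.frame(predicted)) as.matrix(predicted) else predicted
  t_ <- if (is.data.frame(truth)) as.matrix(truth) else truth
  if (is.matrix(p) || is.matrix(t_)) {
    if (!is.matrix(p)) p <- matrix(p, 1L)
    if (!is.matrix(t_)) t_ <- matrix(t_, 1L)
    if (!all(dim(p) == dim(t_)))
      stop("predicted and truth must have matching dimensions")
    return(as.integer(rowSums(p != t_)))
  }
  if (length(p) != length(t_))
    stop("predicted and truth must have the same number of blocks")
  as.integer(sum(p != t_))
}

#' Check variance balance of an encoded design across blocks
#'
#' Because PLS minimises least-squares error on Y, a block whose coded
#' columns carry much more variance than the others dominates the fit. This
#' diagnostic encodes the design and reports each block's total column
#' variance and the max/min ratio, flagging schemes that are badly out of
#' balance.
#'
#' @param scheme A [coding_scheme()].
#' @param design Design data frame (at least two rows).
#' @param threshold Warn when the max/min block variance ratio exceeds this
#'   (default 10, an order-of-magnitude guard: a one-of-k block against an
#'   ordinal column easily differs several-fold without harm, e.g. the
#'   packaged propranolol scheme sits near 4.5 on its own design).
#' @return List with `block_variance` (named numeric), `ratio` and
#'   `warn` (logical). A warning condition is also signalled when flagged.
#' @export
variance_balance <- function(scheme, design, threshold = 10) {
  stopifnot(inherits(scheme, "coding_scheme"))
  if (nrow(design) < 2L)
    stop("variance is undefined for fewer than 2 samples")
  Y <- encode_design(design, scheme)
  v <- vapply(seq_along(scheme$blocks), function(b) {
    sum(apply(Y[, scheme$column_map[[b]], drop = FALSE], 2L, stats::var))
  }, numeric(1L))
  names(v) <- block_names(scheme)
  ratio <- max(v) / min(v)
  warn <- is.finite(ratio) && ratio > threshold
  if (warn)
    warning(sprintf(
      "block variance imbalance: max/min ratio %.3g exceeds threshold %g (%s)",
      ratio, threshold,
      paste(sprintf("%s=%.3g", names(v), v), collapse = ", ")))
  list(block_variance = v, ratio = ratio, warn = warn)
}

#' Enumerate the full label space of a scheme
#'
#' @param scheme A [coding_scheme()].
#' @return Data frame with one column per block and one row per combination.
#' @export
label_space <- function(scheme) {
  stopifnot(inherits(scheme, "coding_scheme"))
  g <- expand.grid(lapply(scheme$blocks, `[[`, "levels"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(g) <- block_names(scheme)
  g
}
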