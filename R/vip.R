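#' Variable importance in projection (VIP) scores, per response column
#'
#' Standard Wold/Chong-Jun VIP, computed separately for every Y column k:
#' \deqn{VIP_{jk} = \sqrt{p \sum_a SS_{ak} (w_{ja}/\|w_a\|)^2 / \sum_a SS_{ak}}}
#' with \eqn{SS_{ak} = q_{ak}^2 \, t_a' t_a}, the Y-variance of column k
#' explained by component a. The normalisation makes the mean squared VIP
#' over the p predictors equal 1 for every column, so VIP > 1 marks a
#' variable of above-average importance.
#'
#' @param model A fitted [fit_pls()] model.
#' @return Numeric p x q matrix of non-negative VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  W <- model$weights; Q <- model$y_loadings; Tm <- model$scores
  p <- nrow(W); q <- nrow(Q); A <- model$n_components
  tt <- colSums(Tm^2)                       # t_a' t_a
  W2 <- sweep(W^2, 2L, colSums(W^2), `/`)   # (w_ja / ||w_a||)^2
  SS <- Q^2 * matrix(tt, q, A, byrow = TRUE)  # q x A explained Y-variance
  tot <- rowSums(SS)
  bad <- tot <= 0
  if (any(bad))
    stop("zero explained variance for Y column(s): ",
         paste(if (!is.null(rownames(Q))) rownames(Q)[bad] else which(bad),
               collapse = ", "),
         "; VIP is undefined there")
  V <- sqrt(p * W2 %*% t(SS / tot))
  dimnames(V) <- list(rownames(W), rownames(Q))
  V
}

#' Summarise per-column VIP scores by factor block
#'
#' For each predictor, the block VIP is the maximum of its VIP scores over
#' the Y columns belonging to that block (a single-column ordinal block
#' passes through unchanged).
#'
#' @param vip p x q VIP matrix from [vip_scores()]; `q` must equal the
#'   scheme width.
#' @param scheme The [coding_scheme()] whose layout produced Y.
#' @return Numeric p x B matrix, one column per block.
#' @export
summarize_vip_by_block <- function(vip, scheme) {
  stopifnot(inherits(scheme, "coding_scheme"))
  vip <- as.matrix(vip)
  if (ncol(vip) != scheme$width)
    stop("VIP matrix has ", ncol(vip), " columns; scheme width is ",
         scheme$width)
  out <- vapply(seq_along(scheme$blocks), function(b) {
    apply(vip[, scheme$column_map[[b]], drop = FALSE], 1L, max)
  }, numeric(nrow(vip)))
  out <- matrix(out, nrow = nrow(vip),
                dimnames = list(rownames(vip), block_names(scheme)))
  out
}

#' Top-k variables of one block by VIP
#'
#' @param block_vip p x B block VIP matrix from [summarize_vip_by_block()].
#' @param block Block name (a column of `block_vip`).
#' @param k Number of variables to return, `1 <= k <= p`.
#' @return Data frame with `rank`, `variable` (name or index) and `vip`,
#'   sorted by descending block VIP; ties broken by ascending variable
#'   index.
#' @export
top_k_variables <- function(block_vip, block, k) {
  block_vip <- as.matrix(block_vip)
  if (!block %in% colnames(block_vip))
    stop("unknown block '", block, "'; available: ",
         paste(colnames(block_vip), collapse = ", "))
  p <- nrow(block_vip)
  k <- as.integer(k)
  if (k < 1L || k > p) stop("k must be between 1 and ", p)
  v <- block_vip[, block]
  ord <- order(-v, seq_len(p))[seq_len(k)]
  vars <- if (!is.null(rownames(block_vip))) rownames(block_vip)[ord] else ord
  data.frame(rank = seq_len(k), variable = vars, vip = unname(v[ord]),
             stringsAsFactors = FALSE)
}

#' Write a VIP table to CSV
#'
#' One row per predictor: per-column VIPs followed by per-block summaries.
#'
#' @param vip p x q VIP matrix.
#' @param scheme The matching [coding_scheme()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_vip_csv <- function(vip, scheme, path) {
  blocks <- summarize_vip_by_block(vip, scheme)
  colnames(blocks) <- paste0("block.", colnames(blocks))
  vars <- if (!is.null(rownames(vip))) rownames(vip) else
    paste0("V", seq_len(nrow(vip)))
  df <- data.frame(variable = vars, vip, blocks, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot block-summarised VIP scores against variable index
#'
#' One panel per block, bars at each variable's block VIP with the
#' conventional VIP = 1 reference line.
#'
#' @param block_vip p x B matrix from [summarize_vip_by_block()].
#' @param blocks Which blocks to draw (default: all columns).
#' @return Invisibly, `block_vip`.
#' @export
plot_block_vip <- function(block_vip, blocks = colnames(block_vip)) {
  block_vip <- as.matrix(block_vip)
  old <- graphics::par(mfrow = c(length(blocks), 1L),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (b in blocks) {
    v <- block_vip[, b]
    graphics::plot(seq_along(v), v, type = "h", xlab = "variable index",
                   ylab = "VIP", main = paste("block:", b))
    graphics::abline(h = 1, lty = 2, col = "grey40")
  }
  invisible(block_vip)
}
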