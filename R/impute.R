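#' KNN imputation of missing feature values
#'
#' Each missing cell is replaced by the mean of the feature's values over
#' the `k` nearest samples, where nearness is Euclidean distance computed
#' on the features observed in both samples and rescaled by the fraction
#' observed (`sqrt(p / m)` for `m` mutually observed of `p` features), so
#' sparsely overlapping pairs are not artificially close. Only samples that
#' actually observe the feature are candidate neighbours; if fewer than `k`
#' exist, all of them are used. Observed cells are never changed.
#'
#' @param x Numeric samples x features matrix with `NA` for missing cells.
#' @param k Number of neighbours (default 5).
#' @return The completed matrix.
#' @export
knn_impute <- function(x, k = 5L) {
  x <- as.matrix(x)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (!anyNA(x)) return(x)
  obs <- !is.na(x)
  dead <- colSums(obs) == 0L
  if (any(dead)) {
    nm <- if (!is.null(colnames(x))) colnames(x)[dead] else which(dead)
    stop("feature(s) with no observed values cannot be imputed: ",
         paste(nm, collapse = ", "))
  }
  p <- ncol(x)
  n <- nrow(x)
  out <- x
  dist_to <- function(i) {
    di <- rep(Inf, n)
    for (j in seq_len(n)) {
      if (j == i) next
      sh <- obs[i, ] & obs[j, ]
      m <- sum(sh)
      if (m == 0L) next
      di[j] <- sqrt(p / m * sum((x[i, sh] - x[j, sh])^2))
    }
    di
  }
  need <- which(rowSums(!obs) > 0L)
  for (i in need) {
    di <- dist_to(i)
    for (jf in which(!obs[i, ])) {
      cand <- which(obs[, jf] & is.finite(di))
      if (length(cand) == 0L)
        stop("no neighbour observes feature ",
             if (!is.null(colnames(x))) colnames(x)[jf] else jf,
             " for sample ", i)
      nb <- cand[order(di[cand], cand)][seq_len(min(k, length(cand)))]
      out[i, jf] <- mean(x[nb, jf])
    }
  }
  out
}
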