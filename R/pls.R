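#' Fit a mean-centred multi-response PLS (PLS2) model
#'
#' Classic NIPALS with deflation of both X and Y. Only mean centring is
#' applied (no unit-variance scaling): the column means of the training X
#' and Y are recorded and subtracted, components are extracted from the
#' centred matrices, and predictions add the Y mean back.
#'
#' The weight vector of each component is the NIPALS fixed point -- the
#' dominant eigenvector of \eqn{X_c' Y_c Y_c' X_c} -- computed exactly from
#' the small \eqn{q \times q} eigenproblem of \eqn{C'C} with
#' \eqn{C = X_c' Y_c}, rather than by cycling the u/w/t/q inner loop to a
#' finite tolerance; the extracted component is identical and the fit is
#' exactly reproducible. Each component's sign is fixed so that the
#' largest-magnitude entry of its weight vector is positive, which makes
#' repeated fits bit-identical. If the remaining X/Y covariance vanishes
#' before the requested number of components, extraction stops early with a
#' message and the model carries fewer components.
#'
#' @param X Numeric matrix, samples x variables (n x p), no missing values.
#' @param Y Numeric matrix (n x q) or vector; typically an encoded
#'   structured target from [encode_design()].
#' @param n_components Number of latent variables A, `1 <= A <= min(n-1, p)`.
#'
#' @return An object of class `pls_model`: list with `x_mean`, `y_mean`,
#'   `weights` (p x A), `x_loadings` (p x A), `y_loadings` (q x A),
#'   `scores` (n x A), `projection` (p x A, `W (P'W)^-1`),
#'   `coefficients` (p x q, for centred data), `fitted` (n x q, on the
#'   original Y scale) and `n_components`.
#' @seealso [predict.pls_model()], [vip_scores()]
#' @export
fit_pls <- function(X, Y, n_components) {
  X <- as.matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L,
                                   dimnames = list(NULL, "y"))
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (n < 2L) stop("need at least 2 samples")
  if (anyNA(X) || anyNA(Y)) stop("missing values are not allowed; impute first")
  A <- as.integer(n_components)
  if (A < 1L) stop("n_components must be >= 1")
  if (A > min(n - 1L, p))
    stop("n_components must not exceed min(n - 1, p) = ", min(n - 1L, p))

  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2L, x_mean); Yc <- sweep(Y, 2L, y_mean)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Q <- matrix(0, q, A); Tm <- matrix(0, n, A)
  scale0 <- sum(Xc^2) * sum(Yc^2)
  a <- 0L
  while (a < A) {
    C <- crossprod(Xc, Yc)                      # p x q covariance
    cn2 <- colSums(C^2)
    if (max(cn2) <= 1e-14 * max(scale0, 1)) {
      message("fit_pls: residual covariance exhausted after ", a,
              " component(s); returning a smaller model")
      break
    }
    v <- eigen(crossprod(C), symmetric = TRUE)$vectors[, 1L]
    w <- drop(C %*% v)
    w <- w / sqrt(sum(w^2))
    i_max <- which.max(abs(w))
    if (w[i_max] < 0) w <- -w                    # fixed sign convention
    t_ <- drop(Xc %*% w)
    tt <- sum(t_^2)
    if (tt <= 1e-14 * max(sum(Xc^2), 1)) {
      message("fit_pls: degenerate score vector at component ", a + 1L,
              "; returning a smaller model")
      break
    }
    p_ <- drop(crossprod(Xc, t_)) / tt
    q_ <- drop(crossprod(Yc, t_)) / tt
    Xc <- Xc - tcrossprod(t_, p_)
    Yc <- Yc - tcrossprod(t_, q_)
    a <- a + 1L
    W[, a] <- w; P[, a] <- p_; Q[, a] <- q_; Tm[, a] <- t_
  }
  if (a == 0L) stop("no PLS component could be extracted (zero covariance)")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  Q <- Q[, seq_len(a), drop = FALSE]; Tm <- Tm[, seq_len(a), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  B <- tcrossprod(R, Q)
  dimnames(W) <- dimnames(P) <- list(colnames(X), NULL)
  dimnames(Q) <- list(colnames(Y), NULL)
  fitted <- sweep(tcrossprod(Tm, Q), 2L, y_mean, `+`)
  dimnames(fitted) <- list(rownames(X), colnames(Y))
  structure(list(x_mean = x_mean, y_mean = y_mean, weights = W,
                 x_loadings = P, y_loadings = Q, scores = Tm,
                 projection = R, coefficients = B, fitted = fitted,
                 n_components = a),
            class = "pls_model")
}

#' Predict responses for new samples from a fitted PLS model
#'
#' Applies the training centring: the training X mean is subtracted from the
#' new rows, the centred coefficient matrix is applied, and the training Y
#' mean is added back.
#'
#' @param object A [fit_pls()] model.
#' @param newdata Numeric matrix (m x p) or a single row as a vector.
#' @param n_components Use only the first A components (default: all fitted
#'   components). Predictions for nested component counts come from the same
#'   decomposition.
#' @param ... Unused.
#' @return Numeric m x q matrix on the original Y scale.
#' @export
predict.pls_model <- function(object, newdata, n_components = NULL, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  p <- length(object$x_mean)
  if (ncol(newdata) != p)
    stop("newdata has ", ncol(newdata), " columns; model expects ", p)
  A <- object$n_components
  a <- if (is.null(n_components)) A else as.integer(n_components)
  if (a < 1L || a > A)
    stop("n_components must be between 1 and ", A)
  Xc <- sweep(newdata, 2L, object$x_mean)
  Tn <- Xc %*% object$projection[, seq_len(a), drop = FALSE]
  Yh <- tcrossprod(Tn, object$y_loadings[, seq_len(a), drop = FALSE])
  Yh <- sweep(Yh, 2L, object$y_mean, `+`)
  dimnames(Yh) <- list(rownames(newdata), rownames(object$y_loadings))
  Yh
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d component(s), p = %d predictors, q = %d responses\n",
              x$n_components, length(x$x_mean), length(x$y_mean)))
  invisible(x)
}

#' Save / load a fitted PLS model
#'
#' Serialises every field of the model exactly (round-trip identical).
#'
#' @param model A `pls_model`.
#' @param path File path.
#' @return `save_pls_model` returns `path` invisibly; `read_pls_model`
#'   returns the model.
#' @export
save_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_pls_model
#' @export
read_pls_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pls_model")) stop("not a saved pls_model: ", path)
  model
}
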