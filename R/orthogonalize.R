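# Multivariate source-leakage correction: find the set of mutually
# orthogonal parcel time courses closest (least squares) to the originals,
# by alternating an orthonormal Procrustes (polar) step with per-parcel
# rescaling (the closest-orthogonal-matrix iteration).

#' Symmetric orthogonalization of a parcel series
#'
#' Removes all shared zero-lag signal across parcels by replacing the parcel
#' time courses with the closest set of mutually orthogonal time courses in
#' the Frobenius sense. Rows are demeaned first, so zero inner products equal
#' zero Pearson correlations. The iteration alternates a polar-decomposition
#' step (best orthonormal frame) with per-parcel least-squares rescaling and
#' stops when the relative change in distortion falls below `tol`.
#'
#' @param series A [parcel_series()] (or plain parcels x samples matrix) with
#'   more samples than parcels and numerically full row rank.
#' @param tol Relative distortion-change convergence tolerance.
#' @param max_iter Iteration cap.
#' @return The input with orthogonalized rows plus fields `distortion`
#'   (Frobenius distance to the input), `converged` and `iterations`.
#'   A matrix input returns a matrix with those values as attributes.
#' @export
symmetric_orthogonalize <- function(series, tol = 1e-12, max_iter = 100) {
  is_series <- inherits(series, "parcel_series")
  X <- if (is_series) series$data else as.matrix(series)
  p <- nrow(X); n <- ncol(X)
  if (n <= p) stop("need more samples (", n, ") than parcels (", p, ")")
  X <- X - rowMeans(X)
  D <- t(X)  # samples x parcels
  sv <- svd(D)
  if (sv$d[p] < 1e-10 * sv$d[1]) {
    cm <- abs(suppressWarnings(cor(D)))
    diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    rn <- rownames(X) %||% paste0("row", seq_len(p))
    stop("rank-deficient input: rows are linearly dependent (closest pair: ",
         rn[worst[1]], " ~ ", rn[worst[2]], ", |r| = ",
         format(max(cm), digits = 4), ")")
  }
  O <- sv$u %*% t(sv$v)          # polar factor: best orthonormal frame
  r <- colSums(D * O)            # least-squares scale per parcel
  dist_prev <- sqrt(sum((D - O %*% diag(r))^2))
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    sv <- svd(D %*% diag(r))
    O <- sv$u %*% t(sv$v)
    r <- colSums(D * O)
    dist <- sqrt(sum((D - O %*% diag(r))^2))
    if (abs(dist_prev - dist) <= tol * max(dist, .Machine$double.eps)) {
      converged <- TRUE
      dist_prev <- dist
      break
    }
    dist_prev <- dist
  }
  out_mat <- t(O %*% diag(r))
  dimnames(out_mat) <- dimnames(X)
  if (is_series) {
    out <- series
    out$data <- out_mat
    out$distortion <- dist_prev
    out$converged <- converged
    out$iterations <- iter
    out
  } else {
    attr(out_mat, "distortion") <- dist_prev
    attr(out_mat, "converged") <- converged
    attr(out_mat, "iterations") <- iter
    out_mat
  }
}

#' Maximum residual zero-lag coupling
#'
#' Largest absolute pairwise Pearson correlation between parcel rows;
#' the verification metric for leakage correction (its output is < 1e-8
#' after [symmetric_orthogonalize()]).
#'
#' @param series A [parcel_series()] or parcels x samples matrix (>= 2 rows).
#' @return Scalar in `[0, 1]`.
#' @export
zero_lag_residual <- function(series) {
  X <- if (inherits(series, "parcel_series")) series$data else as.matrix(series)
  if (nrow(X) < 2) stop("need at least 2 rows")
  cm <- abs(suppressWarnings(cor(t(X))))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  max(cm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
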