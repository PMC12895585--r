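#' Principal-component decomposition of a window-wise connectivity matrix
#'
#' Treats the K = 15 ROI pairs as observations and the M windows as
#' variables: the covariance matrix is M x M, its eigenvalues are indexed by
#' window, and at most K - 1 of them are positive. Columns of X are centered
#' (each window-variable's mean over the 15 pairs subtracted) before the
#' covariance; the decomposition is computed by singular value decomposition
#' of the centered matrix for numerical stability. Each eigenvector's sign
#' is fixed so its largest-magnitude loading is positive, giving a
#' deterministic convention for cross-participant comparison.
#'
#' @param x a `dynamic_fc` object or a bare K x M numeric matrix.
#' @return Object of class `fc_pca`: list with `eigenvalues` (length M,
#'   descending, non-negative), `vectors` (M x M orthonormal columns),
#'   `ccr_curve` (cumulative contribution rate in percent for N = 1..M),
#'   `center` (column means), `X` (the original matrix), `id`, `group`.
#' @export
pca_decompose <- function(x) {
  X <- if (inherits(x, "dynamic_fc")) x$X else as.matrix(x)
  if (any(!is.finite(X))) stop("non-finite values in the connectivity matrix")
  K <- nrow(X); M <- ncol(X)
  if (M < 2) stop("need at least 2 windows")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = min(K, M))
  ev <- numeric(M)
  r <- min(K, M)
  ev[seq_len(r)] <- sv$d[seq_len(r)]^2 / (K - 1)
  U <- matrix(0, M, M)
  U[, seq_len(ncol(sv$v))] <- sv$v
  # complete the orthonormal basis for the null space
  if (ncol(sv$v) < M) {
    Q <- qr.Q(qr(cbind(U[, seq_len(ncol(sv$v)), drop = FALSE],
                       diag(M)[, seq_len(M)])))
    U[, (ncol(sv$v) + 1):M] <- Q[, (ncol(sv$v) + 1):M]
  }
  # deterministic sign: largest |loading| positive
  for (j in seq_len(M)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  ccr_curve <- cumsum(ev) / sum(ev) * 100
  structure(
    list(eigenvalues = ev, vectors = U, ccr_curve = ccr_curve, center = ctr,
         X = X,
         id = if (inherits(x, "dynamic_fc")) x$id else NULL,
         group = if (inherits(x, "dynamic_fc")) x$group else NULL),
    class = "fc_pca"
  )
}

#' @export
print.fc_pca <- function(x, ...) {
  r <- sum(x$eigenvalues > 1e-12 * max(x$eigenvalues))
  cat(sprintf("Window-wise FC PCA: %d eigenvalues (rank %d), CCR(1) = %.1f%%\n",
              length(x$eigenvalues), r, x$ccr_curve[1]))
  invisible(x)
}

#' Cumulative contribution rate of the first N eigenvalues
#'
#' `CCR(N) = 100 * sum(eigenvalues[1:N]) / sum(eigenvalues)`.
#'
#' @param eigenvalues non-negative eigenvalues in descending order.
#' @param N number of leading eigenvalues, `1 <= N <= length(eigenvalues)`.
#' @return percent of total variance.
#' @export
ccr <- function(eigenvalues, N) {
  if (N < 1 || N > length(eigenvalues)) stop("N out of range")
  sum(eigenvalues[seq_len(N)]) / sum(eigenvalues) * 100
}

#' Select the cohort-wide number of principal components
#'
#' The smallest N whose cohort-mean cumulative contribution rate reaches
#' `lo` percent (target band `lo`-`hi`); a warning is logged when the mean
#' CCR at the chosen N exceeds `hi`. One N is used for every participant so
#' feature tables align; N is capped at K - 1 = 14, the rank of the
#' window-wise covariance.
#'
#' @param decompositions list of `fc_pca` objects (one per participant).
#' @param lo,hi CCR band in percent (defaults 90 and 95).
#' @param n_max cap on N (default 14).
#' @return integer N; `attr(, "mean_ccr")` holds the cohort-mean CCR curve.
#' @export
select_n_components <- function(decompositions, lo = 90, hi = 95, n_max = 14L) {
  if (length(decompositions) == 0) stop("empty cohort")
  M <- length(decompositions[[1]]$ccr_curve)
  curves <- vapply(decompositions, function(d) d$ccr_curve, numeric(M))
  mean_ccr <- rowMeans(curves)
  N <- which(mean_ccr >= lo)[1]
  if (is.na(N)) N <- n_max
  N <- min(as.integer(N), as.integer(n_max))
  if (mean_ccr[N] > hi) {
    warning(sprintf("mean CCR at N = %d is %.1f%%, above the %g%% target band",
                    N, mean_ccr[N], hi))
  }
  attr(N, "mean_ccr") <- mean_ccr
  N
}

#' Project a connectivity matrix onto its first N principal components
#'
#' The reduced matrix D = Xc U[, 1..N] (centered projection; rows the 15 ROI
#' pairs, columns the first N components). `reconstruct_fc()` inverts the
#' projection, adding the column means back, so N = M reproduces X exactly
#' and the truncated reconstruction obeys the Eckart-Young bound.
#'
#' @param decomposition an `fc_pca`.
#' @param N number of components, `N <= M`.
#' @return K x N matrix with columns `PC1..PCN`.
#' @export
project_components <- function(decomposition, N) {
  stopifnot(inherits(decomposition, "fc_pca"))
  M <- length(decomposition$eigenvalues)
  if (N < 1 || N > M) stop("N out of range")
  Xc <- sweep(decomposition$X, 2, decomposition$center)
  D <- Xc %*% decomposition$vectors[, seq_len(N), drop = FALSE]
  colnames(D) <- paste0("PC", seq_len(N))
  rownames(D) <- rownames(decomposition$X)
  D
}

#' @rdname project_components
#' @param D a K x N score matrix from `project_components`.
#' @export
reconstruct_fc <- function(decomposition, D) {
  stopifnot(inherits(decomposition, "fc_pca"))
  N <- ncol(D)
  rec <- D %*% t(decomposition$vectors[, seq_len(N), drop = FALSE])
  sweep(rec, 2, decomposition$center, `+`)
}

#' Shift a cohort of score matrices to be non-negative
#'
#' Subtracts the single global minimum over all participants' D matrices
#' from every entry, so the cohort minimum becomes exactly zero while all
#' pairwise differences (and hence all rank statistics) are preserved.
#'
#' @param d_list list of K x N score matrices.
#' @param shift optional pre-computed shift constant (e.g. from a training
#'   subset inside cross-validation); default the global minimum.
#' @return list with `matrices` (shifted list) and `shift_constant` (the
#'   subtracted value).
#' @export
shift_nonnegative <- function(d_list, shift = NULL) {
  stopifnot(length(d_list) >= 1)
  if (is.null(shift)) shift <- min(vapply(d_list, min, numeric(1)))
  list(matrices = lapply(d_list, function(d) d - shift),
       shift_constant = shift)
}
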