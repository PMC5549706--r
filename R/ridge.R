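#' Automatic ridge-parameter selection from principal components
#'
#' Chooses the ridge penalty from the principal components of the centered
#' design matrix: with alpha_j the regression coefficients of the response on
#' the normalized principal components, k the smallest number of components
#' whose cumulative variance share reaches `variance_share`, and sigma^2 the
#' residual variance of the k-component fit, the penalty is
#' `lambda = k * sigma^2 / sum(alpha_1^2 ... alpha_k^2)`. Works for p >> n
#' designs; lambda is invariant to rescaling the response.
#'
#' @param X numeric matrix, samples x features (column-centered internally).
#' @param y numeric response vector.
#' @param variance_share cumulative variance proportion defining k
#'   (default 0.9).
#' @return nonnegative scalar lambda.
#' @export
select_ridge_lambda <- function(X, y, variance_share = 0.9) {
  n <- nrow(X)
  if (length(y) != n) stop("y length must match rows of X")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  if (!any(pos)) stop("zero-variance design matrix")
  d <- sv$d[pos]
  U <- sv$u[, pos, drop = FALSE]
  share <- cumsum(d^2) / sum(d^2)
  k <- which(share >= variance_share)[1L]
  uy <- drop(crossprod(U[, seq_len(k), drop = FALSE], yc))
  alpha <- uy / d[seq_len(k)]
  rss <- sum(yc^2) - sum(uy^2)
  rss <- max(rss, 0)
  sigma2 <- rss / max(n - k, 1L)
  if (sum(alpha^2) == 0) return(0)
  k * sigma2 / sum(alpha^2)
}

#' Fit a linear ridge regression with unpenalized intercept
#'
#' Minimizes `||y - b0 - X beta||^2 + lambda * ||beta||^2` on unscaled
#' features. Coefficients solve `(Xc'Xc + lambda I) beta = Xc' yc` on centered
#' data; for p > n the kernel (dual) form
#' `beta = Xc' (Xc Xc' + lambda I)^{-1} yc` is used, which gives the identical
#' solution at a fraction of the cost.
#'
#' @param X numeric matrix, samples x features.
#' @param y numeric response.
#' @param lambda nonnegative penalty.
#' @param method `"auto"` picks dual when p > n; `"primal"`/`"dual"` force a
#'   form (they agree to numerical precision).
#' @return list with `intercept`, `coefficients` (named by column), `fitted`,
#'   and `lambda`.
#' @export
fit_linear_ridge <- function(X, y, lambda, method = c("auto", "primal", "dual")) {
  method <- match.arg(method)
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 samples")
  if (length(y) != n) stop("y length must match rows of X")
  if (lambda < 0) stop("lambda must be nonnegative")
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  ybar <- mean(y)
  yc <- y - ybar
  if (method == "auto") method <- if (p > n) "dual" else "primal"
  beta <- tryCatch({
    if (method == "primal") {
      A <- crossprod(Xc)
      diag(A) <- diag(A) + lambda
      drop(solve(A, crossprod(Xc, yc)))
    } else {
      K <- tcrossprod(Xc)
      diag(K) <- diag(K) + lambda
      drop(crossprod(Xc, solve(K, yc)))
    }
  }, error = function(e) {
    if (lambda == 0)
      stop("singular system at lambda = 0; use lambda > 0", call. = FALSE)
    stop(e)
  })
  names(beta) <- colnames(X)
  intercept <- ybar - sum(xbar * beta)
  list(intercept = intercept, coefficients = beta,
       fitted = drop(intercept + X %*% beta), lambda = lambda)
}

# Apply a fitted ridge model to new expression rows (samples x same features).
predict_ridge <- function(fit, newX) {
  drop(fit$intercept + as.matrix(newX) %*% fit$coefficients)
}
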