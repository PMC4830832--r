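## Bivariate skew-normal (skew-Gaussian) fit to a 2-D point cloud and
## density-quantile outlier p-values.
##
## Density (direct parameterisation): f(y) = 2 phi_2(y - xi; Omega) *
## Phi(alpha' w^-1 (y - xi)), with w the diagonal of scale standard
## deviations.  Fitted by maximum likelihood over location xi, a Cholesky
## parameterisation of Omega and the skewness vector alpha.

dmsn2 <- function(y, xi, Omega, alpha, log = FALSE) {
  if (is.null(dim(y))) y <- matrix(y, ncol = 2)
  z <- sweep(y, 2, xi)
  Oinv <- solve(Omega)
  qf <- rowSums((z %*% Oinv) * z)
  logdet <- determinant(Omega, logarithm = TRUE)$modulus
  lphi2 <- -log(2 * pi) - 0.5 * logdet - 0.5 * qf
  w <- sqrt(diag(Omega))
  lin <- drop(z %*% (alpha / w))
  ld <- log(2) + lphi2 + stats::pnorm(lin, log.p = TRUE)
  if (log) ld else exp(ld)
}

#' Fit a bivariate skew-Gaussian distribution to a point cloud
#'
#' Maximum-likelihood fit of a two-dimensional skew-normal distribution
#' (location, 2x2 positive-definite scale matrix, 2-vector of skewness) to
#' the rows of \code{points}, e.g. an MDS embedding.  Initialised at the
#' moment estimates with zero skewness; optimised with \code{stats::optim}
#' (Nelder-Mead, then BFGS polish).
#'
#' @param points n x 2 matrix, n >= 10
#' @return object of class \code{"skew_gaussian_fit"} with elements
#'   \code{xi}, \code{Omega}, \code{alpha}, \code{logLik} and
#'   \code{density} (fitted density at each input point).
#' @export
fit_skew_gaussian <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  if (nrow(points) < 10) stop("need at least 10 points")
  S <- stats::cov(points)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev, 1e-300) || max(ev) <= 0)
    stop("degenerate point cloud (collinear or coincident points); ",
         "skew-Gaussian fit is not identifiable")
  ## parameters: xi1, xi2, log L11, L21, log L22, alpha1, alpha2
  Lc <- t(chol(S))
  p0 <- c(colMeans(points), log(Lc[1, 1]), Lc[2, 1], log(Lc[2, 2]), 0, 0)
  unpack <- function(p) {
    L <- matrix(c(exp(p[3]), p[4], 0, exp(p[5])), 2, 2)
    list(xi = p[1:2], Omega = L %*% t(L), alpha = p[6:7])
  }
  nll <- function(p) {
    th <- unpack(p)
    ld <- dmsn2(points, th$xi, th$Omega, th$alpha, log = TRUE)
    if (any(!is.finite(ld))) return(1e10)
    -sum(ld)
  }
  o1 <- stats::optim(p0, nll, method = "Nelder-Mead",
                     control = list(maxit = 2000))
  o2 <- stats::optim(o1$par, nll, method = "BFGS",
                     control = list(maxit = 500))
  best <- if (o2$value < o1$value) o2 else o1
  th <- unpack(best$par)
  structure(list(xi = th$xi, Omega = th$Omega, alpha = th$alpha,
                 logLik = -best$value,
                 density = dmsn2(points, th$xi, th$Omega, th$alpha)),
            class = "skew_gaussian_fit")
}

#' @export
print.skew_gaussian_fit <- function(x, ...) {
  cat("Bivariate skew-Gaussian fit\n")
  cat(sprintf("  location: (%.4g, %.4g)   skewness: (%.4g, %.4g)   logLik %.4g\n",
              x$xi[1], x$xi[2], x$alpha[1], x$alpha[2], x$logLik))
  invisible(x)
}

## draw from the fitted skew-normal via the hidden-truncation representation
rmsn2 <- function(n, xi, Omega, alpha) {
  w <- sqrt(diag(Omega))
  Obar <- Omega / tcrossprod(w)
  denom <- sqrt(1 + drop(t(alpha) %*% Obar %*% alpha))
  delta <- drop(Obar %*% alpha) / denom
  Sig <- rbind(cbind(Obar, delta), c(delta, 1))
  L <- t(chol(Sig))
  Z <- matrix(stats::rnorm(3 * n), n, 3) %*% t(L)
  flip <- Z[, 3] < 0
  Z[flip, 1:2] <- -Z[flip, 1:2]
  sweep(Z[, 1:2, drop = FALSE] * rep(w, each = n), 2, xi, "+")
}

#' Uniqueness p-values from a skew-Gaussian density fit
#'
#' Quantifies how unusual each point of a 2-D embedding is under the fitted
#' skew-Gaussian point density: the p-value of a point is the fraction of
#' the fitted probability mass lying at locations of density less than or
#' equal to the density at that point (a lowest-density-tail quantile), so
#' isolated outliers receive small p.  The mass fraction is evaluated by
#' Monte Carlo draws from the fitted distribution; p-values are bounded
#' below by 1/(n_mc + 1) so they stay in (0, 1].
#'
#' @param embedding a \code{\link{hitmds_embed}} result or an n x 2 matrix
#' @param fit optional existing \code{skew_gaussian_fit}; fitted if missing
#' @param n_mc Monte Carlo sample size, default 20000
#' @param seed RNG seed for the draws
#' @return named numeric vector of p-values in (0, 1].
#' @export
uniqueness_pvalue <- function(embedding, fit = NULL, n_mc = 20000L, seed = 1L) {
  pts <- if (inherits(embedding, "hitmds")) embedding$points else as.matrix(embedding)
  if (is.null(fit)) fit <- fit_skew_gaussian(pts)
  set.seed(seed)
  samp <- rmsn2(n_mc, fit$xi, fit$Omega, fit$alpha)
  ds <- dmsn2(samp, fit$xi, fit$Omega, fit$alpha)
  dp <- dmsn2(pts, fit$xi, fit$Omega, fit$alpha)
  p <- (vapply(dp, function(d) sum(ds <= d), numeric(1)) + 1) / (n_mc + 1)
  stats::setNames(pmin(p, 1), rownames(pts))
}
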