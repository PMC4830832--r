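## HiT-MDS: embed a distance matrix into the plane by maximising the Pearson
## correlation between input distances and embedded Euclidean distances.
## The optimiser is a seeded stochastic gradient ascent on the correlation
## objective, initialised from classical (Torgerson) scaling.

#' HiT-MDS embedding of a distance matrix
#'
#' Projects an n x n distance matrix onto two dimensions so that the Pearson
#' correlation r between the input distances and the embedded Euclidean
#' distances is maximal; the reported stress is 1 - r.  Profiles that vary
#' strongly and uniquely appear as outliers of the embedded point cloud.
#'
#' The optimisation starts from the classical-scaling configuration and
#' refines it by stochastic gradient ascent over point pairs; the step size
#' decays geometrically.  The stress trace over reported iterations is
#' non-increasing (the best configuration seen is kept).
#'
#' @param D symmetric non-negative distance matrix with zero diagonal
#' @param iterations gradient iterations, default 2000
#' @param seed RNG seed for the pair sampling
#' @param learning_rate initial step size, default 0.05
#' @return object of class \code{"hitmds"}: list with \code{points}
#'   (n x 2 matrix, row names preserved), \code{stress} (final 1 - r) and
#'   \code{stress_trace}.
#' @export
hitmds_embed <- function(D, iterations = 2000L, seed = 1L,
                         learning_rate = 0.05) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(n == ncol(D), n >= 3)
  if (any(D < 0) || any(abs(diag(D)) > 1e-12) || any(abs(D - t(D)) > 1e-8))
    stop("D must be a symmetric non-negative matrix with zero diagonal")
  if (all(D == 0)) stop("degenerate all-zero distance matrix")
  dv <- D[lower.tri(D)]

  set.seed(seed)
  ## classical scaling start (top-2 eigenvectors of the doubly centred
  ## squared-distance matrix); jitter breaks exact ties
  B <- -0.5 * scale(t(scale(t(D^2), scale = FALSE)), scale = FALSE)
  ev <- eigen(B, symmetric = TRUE)
  X <- ev$vectors[, 1:2, drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[1:2], 1e-12)), 2)
  X <- X + matrix(stats::rnorm(2 * n, sd = 1e-9), n, 2)

  embed_dist <- function(X) {
    dx <- outer(X[, 1], X[, 1], "-"); dy <- outer(X[, 2], X[, 2], "-")
    sqrt(dx^2 + dy^2)
  }
  corr_obj <- function(X) {
    e <- embed_dist(X)[lower.tri(D)]
    if (stats::sd(dv) == 0 || stats::sd(e) == 0) {
      ## constant target distances: correlation is undefined, score by
      ## relative mismatch instead (1 = exact match)
      return(1 - sqrt(mean((e - dv)^2)) / mean(dv))
    }
    stats::cor(dv, e)
  }

  best_X <- X
  best_r <- corr_obj(X)
  trace <- 1 - best_r
  eta <- learning_rate * mean(dv)
  batch <- max(8L, n %/% 2L)
  report_every <- max(1L, iterations %/% 50L)
  for (it in seq_len(iterations)) {
    i <- sample.int(n, 1L)
    js <- sample.int(n, min(batch, n - 1L))
    js <- js[js != i]
    if (!length(js)) next
    diff <- X[rep(i, length(js)), , drop = FALSE] - X[js, , drop = FALSE]
    dij <- sqrt(rowSums(diff^2))
    ok <- dij > 1e-12
    if (!any(ok)) next
    ## move point i so embedded distances track the target distances
    resid <- (D[i, js] - dij)[ok]
    grad <- colSums(resid * diff[ok, , drop = FALSE] / dij[ok])
    X[i, ] <- X[i, ] + eta * grad / length(js)
    eta <- eta * (1 - 1 / (2 * iterations))
    if (it %% report_every == 0L) {
      r <- corr_obj(X)
      if (r > best_r) { best_r <- r; best_X <- X }
      trace <- c(trace, 1 - best_r)
    }
  }
  r <- corr_obj(X)
  if (r > best_r) { best_r <- r; best_X <- X }
  trace <- c(trace, 1 - best_r)
  rownames(best_X) <- rownames(D)
  colnames(best_X) <- c("x", "y")
  structure(list(points = best_X, stress = 1 - best_r, stress_trace = trace),
            class = "hitmds")
}

#' @export
print.hitmds <- function(x, ...) {
  cat(sprintf("HiT-MDS embedding: %d points, distance correlation %.4f (stress %.4g)\n",
              nrow(x$points), 1 - x$stress, x$stress))
  invisible(x)
}

#' Plot an MDS embedding
#'
#' @param x a \code{hitmds}
#' @param pvalues optional per-point uniqueness p-values; points below 0.01
#'   are highlighted
#' @param ... passed to \code{plot}
#' @export
plot.hitmds <- function(x, pvalues = NULL, ...) {
  col <- if (is.null(pvalues)) "grey30"
         else ifelse(pvalues < 0.01, "firebrick", "grey60")
  graphics::plot(x$points, col = col, pch = 16, xlab = "MDS 1", ylab = "MDS 2", ...)
  invisible(x)
}

#' Write an embedding (with optional p-values) as TSV
#'
#' @param embedding a \code{hitmds}
#' @param path output file (columns gene, x, y, p_value)
#' @param pvalues optional vector aligned with the points
#' @export
write_embedding_tsv <- function(embedding, path, pvalues = NULL) {
  df <- data.frame(gene = rownames(embedding$points) %||%
                     paste0("g", seq_len(nrow(embedding$points))),
                   x = embedding$points[, 1], y = embedding$points[, 2])
  if (!is.null(pvalues)) df$p_value <- pvalues
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
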