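## Time-course transcriptome analytics: polynomial smoothing, top-regulation
## filtering, CAST clustering and inverse-regulation detection.

#' Polynomial smoothing of a time series
#'
#' Ordinary least-squares fit of a polynomial of the configured order over
#' the timepoints, evaluated back at the original timepoints.  With a dense
#' sampling grid this suppresses measurement noise while following the
#' response shape.
#'
#' @param values numeric vector, or a genes x timepoints matrix (rows are
#'   smoothed independently)
#' @param time_h numeric timepoints, strictly increasing; defaults to
#'   column names for matrix input
#' @param order polynomial order, default 5; must be < number of timepoints
#' @return smoothed object of the same shape.
#' @export
smooth_polynomial <- function(values, time_h = NULL, order = 5L) {
  if (is.matrix(values)) {
    if (is.null(time_h)) time_h <- as.numeric(colnames(values))
    out <- t(apply(values, 1, smooth_polynomial, time_h = time_h, order = order))
    dimnames(out) <- dimnames(values)
    return(out)
  }
  stopifnot(!is.null(time_h), length(time_h) == length(values),
            all(diff(time_h) > 0))
  if (order >= length(time_h))
    stop("polynomial order ", order, " needs more than ", order, " timepoints")
  fit <- stats::lm(values ~ stats::poly(time_h, degree = order, raw = FALSE))
  unname(stats::fitted(fit))
}

#' Select strongly regulated genes
#'
#' Keeps genes whose log2 fold change exceeds \code{+fc_threshold} or falls
#' below \code{-fc_threshold} at two consecutive timepoints with the same
#' sign at both (a single-timepoint spike, or a +/- flip across the
#' threshold, does not qualify).
#'
#' @param mat genes x timepoints matrix of log2 fold changes vs control
#' @param fc_threshold default 1.7
#' @return character vector of selected gene names (row names).
#' @export
select_top_regulated <- function(mat, fc_threshold = 1.7) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  up <- mat > fc_threshold
  dn <- mat < -fc_threshold
  hit <- function(b) apply(b[, -1, drop = FALSE] & b[, -ncol(b), drop = FALSE],
                           1, any)
  sel <- hit(up) | hit(dn)
  rownames(mat)[sel]
}

#' CAST clustering of expression profiles
#'
#' Cluster Affinity Search Technique: genes are nodes of a complete graph
#' weighted by pairwise affinity; clusters are grown greedily without a
#' preset cluster count.  The open cluster adds the unassigned gene of
#' maximal total affinity while that affinity is at least
#' \code{t * |cluster|}, removes members whose total affinity drops below
#' \code{t * |cluster|}, and closes when stable.
#'
#' Affinity is the Pearson correlation of the series mapped to [0,1] via
#' (r + 1) / 2, so the default threshold t = 0.8 corresponds to r = 0.6.
#' Genes with a constant series (undefined correlation) are excluded with a
#' warning.
#'
#' @param mat genes x timepoints matrix (ideally smoothed)
#' @param affinity_threshold t in (0,1], default 0.8
#' @return object of class \code{"cast_clusters"}: list with
#'   \code{clusters} (list of gene-name vectors), \code{assignment} (named
#'   integer vector) and \code{excluded}.
#' @export
cast_cluster <- function(mat, affinity_threshold = 0.8) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2, affinity_threshold > 0,
            affinity_threshold <= 1)
  genes <- rownames(mat) %||% paste0("g", seq_len(nrow(mat)))
  rownames(mat) <- genes
  sds <- apply(mat, 1, stats::sd)
  degenerate <- genes[sds == 0 | is.na(sds)]
  if (length(degenerate)) {
    warning("excluding ", length(degenerate),
            " constant series (undefined correlation)")
    mat <- mat[setdiff(genes, degenerate), , drop = FALSE]
    genes <- rownames(mat)
  }
  aff <- (stats::cor(t(mat)) + 1) / 2
  diag(aff) <- 1
  unassigned <- genes
  clusters <- list()
  t <- affinity_threshold
  while (length(unassigned)) {
    ## seed: unassigned gene with maximal total affinity to the rest
    if (length(unassigned) == 1L) {
      clusters[[length(clusters) + 1L]] <- unassigned
      break
    }
    tot <- rowSums(aff[unassigned, unassigned, drop = FALSE])
    open <- unassigned[which.max(tot)]
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      outside <- setdiff(unassigned, open)
      ## additions
      if (length(outside)) {
        gain <- rowSums(aff[outside, open, drop = FALSE])
        i <- which.max(gain)
        if (gain[i] >= t * length(open)) {
          open <- c(open, outside[i])
          changed <- TRUE
          next
        }
      }
      ## removals
      if (length(open) > 1L) {
        within <- rowSums(aff[open, open, drop = FALSE])
        j <- which.min(within)
        if (within[j] < t * length(open)) {
          open <- open[-j]
          changed <- TRUE
        }
      }
    }
    clusters[[length(clusters) + 1L]] <- open
    unassigned <- setdiff(unassigned, open)
  }
  assignment <- stats::setNames(rep(NA_integer_, length(genes)), genes)
  for (i in seq_along(clusters)) assignment[clusters[[i]]] <- i
  structure(list(clusters = clusters, assignment = assignment,
                 affinity_threshold = t, excluded = degenerate),
            class = "cast_clusters")
}

#' @export
print.cast_clusters <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("CAST clustering: %d clusters at t = %.2f (sizes: %s)\n",
              length(x$clusters), x$affinity_threshold,
              paste(sizes, collapse = ", ")))
  if (length(x$excluded))
    cat("  excluded constant series:", length(x$excluded), "\n")
  invisible(x)
}

#' Write cluster assignments as two-column TSV
#'
#' @param clusters a \code{cast_clusters}
#' @param path output file (columns gene, cluster_id)
#' @export
write_clusters_tsv <- function(clusters, path) {
  df <- data.frame(gene = names(clusters$assignment),
                   cluster_id = unname(clusters$assignment))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Detect inverse (anti-correlated) regulation between two series
#'
#' Fits a linear model over time to each smoothed series; the pair is
#' anti-correlated when both slopes are significant (slope t-test
#' p < \code{alpha}), the slopes have opposite signs, and both fits have
#' r-squared strictly above \code{r2_threshold}.
#'
#' @param series_a,series_b numeric vectors on the same timepoints
#' @param time_h timepoints
#' @param r2_threshold default 0.7
#' @param alpha slope-significance level, default 0.05
#' @return logical scalar.
#' @export
detect_anticorrelated <- function(series_a, series_b, time_h,
                                  r2_threshold = 0.7, alpha = 0.05) {
  stopifnot(length(series_a) == length(time_h),
            length(series_b) == length(time_h))
  f <- function(y) {
    fit <- stats::lm(y ~ time_h)
    co <- summary(fit)$coefficients
    list(slope = co[2, 1], p = co[2, 4], r2 = summary(fit)$r.squared)
  }
  a <- f(series_a); b <- f(series_b)
  (a$p < alpha) && (b$p < alpha) &&
    (sign(a$slope) * sign(b$slope) == -1) &&
    (a$r2 > r2_threshold) && (b$r2 > r2_threshold)
}

#' Read / write expression matrices as TSV
#'
#' Genes as rows, header row of timepoints in hours.
#'
#' @param path file path
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE,
                          fileEncoding = "UTF-8")
  m <- as.matrix(df)
  if (any(is.na(suppressWarnings(as.numeric(colnames(m))))))
    stop("column names must be timepoints in hours")
  m
}

#' @rdname read_expression_tsv
#' @param mat genes x timepoints matrix
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
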