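## Discretization of expression measurements for Boolean training.
##
## Fold changes (linear scale) are rescaled per node to [0,1] and passed
## through a Hill function f(x) = x^n / (x^n + k^n); binarization at a
## threshold then yields Boolean on/off calls comparable with simulated
## network states.

#' Relative expression by the 2^-ddCt method
#'
#' Computes the fold change of a target transcript in a treated sample
#' relative to a control sample, each normalised to a reference transcript:
#' ddCt = (Ct_target - Ct_reference)_treated - (Ct_target - Ct_reference)_control,
#' fold change = 2^(-ddCt).
#'
#' @param ct_target,ct_reference threshold cycles in the treated sample
#' @param ct_control_target,ct_control_reference threshold cycles in the
#'   control sample
#' @return fold change(s), linear scale.
#' @examples
#' ddct_fold_change(20, 15, 21, 15)  # one cycle earlier than control -> 2
#' @export
ddct_fold_change <- function(ct_target, ct_reference,
                             ct_control_target, ct_control_reference) {
  stopifnot(all(is.finite(c(ct_target, ct_reference,
                            ct_control_target, ct_control_reference))))
  ddct <- (ct_target - ct_reference) - (ct_control_target - ct_control_reference)
  2^(-ddct)
}

#' Hill transform configuration
#'
#' @param n Hill coefficient (>= 1); default 2.
#' @param k half-activation threshold in (0,1); a value above \code{k} maps
#'   above 0.5 and is considered "on" after binarization.  Default 0.5.
#' @export
hill_config <- function(n = 2, k = 0.5) {
  stopifnot(n >= 1, k > 0, k < 1)
  structure(list(n = n, k = k), class = "hill_config")
}

#' Rescale fold-change series to the unit interval
#'
#' Per-node affine rescaling (x - min) / (max - min) across all of the
#' node's conditions and timepoints jointly, so cross-condition contrast is
#' preserved.  A constant series has no scale; it maps to all zeros with a
#' warning rather than aborting whole-table processing.
#'
#' @param x numeric vector (one node's series) or a long-format data frame
#'   with columns \code{node}, \code{condition}, \code{time_h}, \code{value}.
#' @param per one of \code{"node"} (default) or \code{"node_condition"}:
#'   whether the min/max is taken across all conditions of a node or within
#'   each condition separately.  Only used for data-frame input.
#' @return object of the same shape with values in [0,1].
#' @export
rescale_unit_interval <- function(x, per = c("node", "node_condition")) {
  per <- match.arg(per)
  if (is.data.frame(x)) {
    stopifnot(all(c("node", "condition", "time_h", "value") %in% names(x)))
    grp <- if (per == "node") x$node else interaction(x$node, x$condition, drop = TRUE)
    x$value <- stats::ave(x$value, grp, FUN = rescale_vec)
    return(x)
  }
  rescale_vec(x)
}

rescale_vec <- function(v) {
  stopifnot(all(v > 0))
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("constant series: no scale, mapping to 0")
    return(rep(0, length(v)))
  }
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Hill transform
#'
#' Sigmoidal map x^n / (x^n + k^n) converting a normalised expression value
#' in [0,1] into quasi-Boolean activity.  Strictly increasing on (0,1],
#' equal to 0.5 exactly at x = k, with f(0) = 0 and f(1) = 1/(1 + k^n) < 1.
#'
#' @param x value(s) in [0,1]
#' @param config a \code{\link{hill_config}}
#' @return transformed value(s) in [0,1).
#' @examples
#' hill_transform(0.5)           # 0.5
#' hill_transform(1)             # 0.8 for n = 2, k = 0.5
#' @export
hill_transform <- function(x, config = hill_config()) {
  if (any(x < 0 | x > 1)) stop("hill_transform is defined on [0,1]")
  x^config$n / (x^config$n + config$k^config$n)
}

#' Binarize activity values
#'
#' A node is called "on" when its value lies strictly above the threshold.
#'
#' @param value value(s) in [0,1]
#' @param threshold default 0.5
#' @return integer 0/1 of the same shape.
#' @export
binarize <- function(value, threshold = 0.5) {
  stopifnot(all(value >= 0 & value <= 1))
  v <- as.integer(value > threshold)
  if (is.matrix(value)) v <- matrix(v, nrow = nrow(value), dimnames = dimnames(value))
  v
}

#' Read / write long-format fold-change tables
#'
#' TSV with columns \code{node}, \code{condition}, \code{time_h},
#' \code{value}; UTF-8, tab-delimited.
#'
#' @param path file path
#' @return data frame (reader) or \code{path} invisibly (writer).
#' @export
read_fold_change_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          fileEncoding = "UTF-8")
  need <- c("node", "condition", "time_h", "value")
  if (!all(need %in% names(df)))
    stop("fold-change TSV must have columns: ", paste(need, collapse = ", "))
  if (any(df$value <= 0)) stop("fold changes must be positive (linear scale)")
  df
}

#' @rdname read_fold_change_tsv
#' @param table long-format data frame
#' @export
write_fold_change_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
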