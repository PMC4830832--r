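## Synthetic ground-truth networks and noisy continuous time courses with
## the statistical structure the training and clustering methods assume, so
## topology recovery, discretization and clustering are testable without
## external downloads.

#' Generate a random ground-truth network inside a decoy-padded PKN
#'
#' Builds a layered acyclic true network: one stimulus source, a random
#' activating backbone guaranteeing a stimulus-to-node path for every node,
#' plus extra true edges; then pads the edge list with decoy edges that are
#' not part of the truth.  Backbone edges are marked fixed; the extra true
#' edges and the decoys together form the optional-edge hypothesis space.
#' Extra true edges are accepted only if they are essential, i.e. their
#' presence changes the noise-free simulated data under the generated
#' scenario set, which makes the planted topology identifiable from the
#' data.
#'
#' All non-stimulus nodes are designated as measured; up to
#' \code{n_inhibition_conditions} intermediate nodes are picked as
#' inhibition points, giving a scenario set of the stimulus alone plus one
#' inhibitor condition each.
#'
#' @param n_nodes total nodes (>= 3)
#' @param n_extra extra true edges beyond the backbone
#' @param n_decoys decoy (false) optional edges
#' @param inhibition_fraction fraction of non-backbone edges drawn as
#'   inhibiting, default 0.2
#' @param n_inhibition_conditions inhibition scenarios, default 2
#' @param timepoints measurement grid used for the essentiality check and
#'   by \code{\link{simulate_timecourse_expression}}
#' @param seed RNG seed (reproducible)
#' @return list with elements \code{pkn} (a \code{\link{pkn}}),
#'   \code{true_bitstring} (0/1 over the PKN's optional edges),
#'   \code{network} (the true \code{boolean_network}), \code{scenarios}
#'   (data frame condition/stimuli/inhibitors) and \code{timepoints}.
#' @export
random_network <- function(n_nodes, n_extra = 5L, n_decoys = 5L,
                           inhibition_fraction = 0.2,
                           n_inhibition_conditions = 2L,
                           timepoints = c(1, 2, 3, 4, 5, 6, 8, 12, 24),
                           seed = 1L) {
  stopifnot(n_nodes >= 3)
  max_pairs <- (n_nodes - 1) * (n_nodes - 2) / 2  # forward non-backbone slots
  if (n_extra + n_decoys > max_pairs)
    stop("requested optional edges exceed available node pairs")
  set.seed(seed)
  nodes <- c("S", sprintf("N%02d", seq_len(n_nodes - 1L)))
  ## activating backbone: every node reachable from the stimulus
  backbone <- data.frame(source = nodes[vapply(2:n_nodes, function(i)
                           sample.int(i - 1L, 1L), integer(1))],
                         sign = 1L, target = nodes[2:n_nodes], fixed = TRUE,
                         stringsAsFactors = FALSE)
  measured <- nodes[-1]
  inhib_nodes <- if (n_inhibition_conditions > 0 && n_nodes > 3)
    sample(nodes[2:(n_nodes - 1L)], min(n_inhibition_conditions, n_nodes - 2L))
  else character(0)
  scenarios <- data.frame(
    condition = c("stim", if (length(inhib_nodes)) paste0(inhib_nodes, "_i")),
    stimuli = "S",
    inhibitors = c("", inhib_nodes),
    stringsAsFactors = FALSE)

  edge_key <- function(e) paste(e$source, e$target)
  candidates <- do.call(rbind, lapply(3:n_nodes, function(i)
    data.frame(source = nodes[seq_len(i - 2L)], target = nodes[i],
               stringsAsFactors = FALSE)))
  candidates <- candidates[!paste(candidates$source, candidates$target) %in%
                             edge_key(backbone), ]
  candidates <- candidates[sample.int(nrow(candidates)), ]

  noise_free_data <- function(edges) {
    net <- model_from_edges(edges, nodes = nodes)
    out <- list()
    for (ci in seq_len(nrow(scenarios))) {
      sim <- simulate_condition(net, "S", split_nodes(scenarios$inhibitors[ci]),
                                length(timepoints))
      out[[ci]] <- sim[, measured, drop = FALSE]
    }
    out
  }

  ## an extra edge is acceptable only if, after adding it, every extra edge
  ## (including itself) remains individually essential: removing any one of
  ## them changes the noise-free data.  This keeps the planted topology
  ## identifiable edge by edge.
  all_essential <- function(edges, n_backbone) {
    full <- noise_free_data(edges)
    for (j in seq.int(n_backbone + 1L, nrow(edges))) {
      if (identical(noise_free_data(edges[-j, , drop = FALSE]), full))
        return(FALSE)
    }
    TRUE
  }
  true_edges <- backbone
  extra <- list(); ci <- 1L
  while (length(extra) < n_extra && ci <= nrow(candidates)) {
    e <- data.frame(source = candidates$source[ci],
                    sign = if (stats::runif(1) < inhibition_fraction) -1L else 1L,
                    target = candidates$target[ci], fixed = FALSE,
                    stringsAsFactors = FALSE)
    ci <- ci + 1L
    with_e <- rbind(true_edges, e)
    if (!all_essential(with_e, nrow(backbone))) next
    true_edges <- with_e
    extra[[length(extra) + 1L]] <- e
  }
  if (length(extra) < n_extra)
    stop("could not place ", n_extra, " essential extra edges; ",
         "lower n_extra or raise n_nodes")
  ## decoys come from any remaining forward pair (tried-and-rejected pairs
  ## included: an inessential or misleading decoy is exactly what the
  ## optimiser must learn to drop), except decoys that are dynamically
  ## substitutable for a planted extra edge -- swapping one in for one out
  ## must change the noise-free data, otherwise the truth is not
  ## identifiable even in principle and edge votes split between the two.
  remaining <- candidates[!paste(candidates$source, candidates$target) %in%
                            edge_key(true_edges), , drop = FALSE]
  truth_data <- noise_free_data(true_edges)
  extra_rows <- seq.int(nrow(backbone) + 1L, nrow(true_edges))
  substitutable <- function(d) {
    for (j in extra_rows) {
      swapped <- rbind(true_edges[-j, , drop = FALSE], d)
      if (identical(noise_free_data(swapped), truth_data)) return(TRUE)
    }
    FALSE
  }
  decoys <- list(); di <- 1L
  while (length(decoys) < n_decoys && di <= nrow(remaining)) {
    d <- data.frame(source = remaining$source[di],
                    sign = if (stats::runif(1) < inhibition_fraction) -1L else 1L,
                    target = remaining$target[di], fixed = FALSE,
                    stringsAsFactors = FALSE)
    di <- di + 1L
    if (length(extra_rows) && substitutable(d)) next
    decoys[[length(decoys) + 1L]] <- d
  }
  if (length(decoys) < n_decoys)
    stop("not enough candidate pairs for ", n_decoys, " decoys")
  decoys <- do.call(rbind, decoys)
  pkn_edges <- rbind(true_edges, decoys)
  roles <- stats::setNames(rep("measured", length(measured)), measured)
  roles["S"] <- "stimulus"
  roles[inhib_nodes] <- "inhibited"
  p <- pkn(pkn_edges, roles = roles)
  opt <- optional_edges(p)
  truth_key <- paste(true_edges$source, true_edges$target)
  bits <- as.integer(paste(p$edges$source[opt], p$edges$target[opt]) %in% truth_key)
  list(pkn = p, true_bitstring = bits,
       network = model_from_edges(true_edges, nodes = nodes),
       scenarios = scenarios, timepoints = timepoints, measured = measured)
}

#' Noise model for continuous rendering of Boolean trajectories
#'
#' @param sd Gaussian standard deviation added to the 0/1 signal before
#'   clipping to [0,1]; default 0.05
#' @param seed RNG seed
#' @export
noise_model <- function(sd = 0.05, seed = 1L) {
  stopifnot(sd >= 0)
  structure(list(sd = sd, seed = as.integer(seed)), class = "noise_model")
}

#' Simulate a noisy training dataset from a ground truth
#'
#' Runs every scenario of the ground truth, samples the Boolean node states
#' at synchronous steps aligned one-to-one with the sorted timepoints, and
#' renders each measured value as state + Gaussian noise clipped to [0,1].
#' With \code{sd = 0} the values are exactly 0/1 and binarize back to the
#' simulated states.
#'
#' @param truth result of \code{\link{random_network}} (or a compatible
#'   list with \code{network}, \code{scenarios}, \code{timepoints},
#'   \code{measured})
#' @param noise a \code{\link{noise_model}}
#' @param timepoints override the truth's measurement grid
#' @return a \code{\link{training_dataset}}
#' @export
simulate_timecourse_expression <- function(truth, noise = noise_model(),
                                           timepoints = truth$timepoints) {
  stopifnot(length(timepoints) >= 1, all(diff(timepoints) > 0))
  set.seed(noise$seed)
  meas <- list()
  for (ci in seq_len(nrow(truth$scenarios))) {
    sim <- simulate_condition(truth$network,
                              split_nodes(truth$scenarios$stimuli[ci]),
                              split_nodes(truth$scenarios$inhibitors[ci]),
                              length(timepoints))
    for (ti in seq_along(timepoints)) {
      v <- sim[ti, truth$measured] +
        stats::rnorm(length(truth$measured), sd = noise$sd)
      meas[[length(meas) + 1L]] <- data.frame(
        condition = truth$scenarios$condition[ci],
        time_h = timepoints[ti], node = truth$measured,
        value = pmin(1, pmax(0, v)), stringsAsFactors = FALSE)
    }
  }
  training_dataset(truth$scenarios, do.call(rbind, meas))
}

#' Planted-structure expression matrix for clustering benchmarks
#'
#' Generates gene clusters around pulse-shaped (rise-and-return) and
#' sustained (rise-and-hold) response templates, alternating between the
#' two shapes with cluster-specific peak/onset times, plus additive
#' Gaussian noise.  These emulate the impulse-like versus sustained
#' response classes seen in growth-factor time courses.
#'
#' @param n_clusters number of planted clusters
#' @param genes_per_cluster genes per cluster
#' @param timepoints sampling grid in hours
#' @param noise_sd additive Gaussian sd on the log2 scale, default 0.05
#' @param amplitude template peak height (log2 fold change), default 3
#' @param seed RNG seed
#' @return genes x timepoints matrix with a \code{"labels"} attribute
#'   (integer cluster id per gene).
#' @export
planted_cluster_matrix <- function(n_clusters, genes_per_cluster,
                                   timepoints = c(1, 2, 3, 4, 5, 6, 8, 12, 24),
                                   noise_sd = 0.05, amplitude = 3, seed = 1L) {
  stopifnot(n_clusters >= 1, genes_per_cluster >= 1)
  set.seed(seed)
  tmax <- max(timepoints)
  templates <- lapply(seq_len(n_clusters), function(i) {
    if (i %% 2L == 1L) {
      peak <- tmax * (0.15 + 0.5 * (i - 1) / max(1, n_clusters - 1))
      width <- tmax * 0.12
      amplitude * exp(-((timepoints - peak) / width)^2)   # pulse
    } else {
      onset <- tmax * (0.1 + 0.4 * (i - 1) / max(1, n_clusters - 1))
      amplitude / (1 + exp(-(timepoints - onset) / (tmax * 0.06)))  # sustained
    }
  })
  n_genes <- n_clusters * genes_per_cluster
  m <- matrix(0, nrow = n_genes, ncol = length(timepoints),
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              timepoints))
  labels <- rep(seq_len(n_clusters), each = genes_per_cluster)
  for (g in seq_len(n_genes))
    m[g, ] <- templates[[labels[g]]] +
      stats::rnorm(length(timepoints), sd = noise_sd)
  attr(m, "labels") <- stats::setNames(labels, rownames(m))
  m
}
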