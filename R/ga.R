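## Topology training: score candidate edge selections against perturbation
## time-course data and optimise by a genetic algorithm with multi-run
## consensus edge retention.

#' Genetic-algorithm configuration
#'
#' Defaults mirror a typical logic-model training setup: each run is capped
#' by wall time (100 s) and additionally stops when the best fitness has
#' improved by less than \code{rel_tolerance} (relative) over a patience
#' window; the full optimisation repeats \code{runs} times and an optional
#' edge enters the consensus when it appears in at least
#' \code{retention_fraction} of the runs.  The size penalty makes the
#' objective prefer sparser models at equal fit.
#'
#' @param max_cpu_time_s wall-time cap per run, seconds (default 100)
#' @param rel_tolerance relative improvement threshold for the plateau stop
#'   (default 0.01)
#' @param runs number of independent GA runs (default 100)
#' @param retention_fraction consensus retention cutoff in (0,1] (default 0.7)
#' @param size_penalty_weight weight of selected-edge-fraction penalty
#'   (default 1e-4)
#' @param population_size,crossover_rate,mutation_rate,elitism GA internals
#' @param patience stall window in generations for the plateau stop
#'   (default 100, the conventional stall window in binary-GA logic-model
#'   trainers; small windows stop before rare single-bit improvements are
#'   found)
#' @param max_generations hard cap on generations per run
#' @param seed master seed; run r uses seed + 1000 * r
#' @export
ga_config <- function(max_cpu_time_s = 100, rel_tolerance = 0.01, runs = 100L,
                      retention_fraction = 0.7, size_penalty_weight = 1e-4,
                      population_size = 50L, crossover_rate = 0.5,
                      mutation_rate = 0.01, elitism = 1L, patience = 100L,
                      max_generations = 500L, seed = 1L) {
  stopifnot(retention_fraction > 0, retention_fraction <= 1, runs >= 1,
            size_penalty_weight >= 0, population_size >= 2)
  structure(list(max_cpu_time_s = max_cpu_time_s, rel_tolerance = rel_tolerance,
                 runs = as.integer(runs), retention_fraction = retention_fraction,
                 size_penalty_weight = size_penalty_weight,
                 population_size = as.integer(population_size),
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 elitism = as.integer(elitism), patience = as.integer(patience),
                 max_generations = as.integer(max_generations),
                 seed = as.integer(seed)),
            class = "ga_config")
}

optional_edges <- function(p) which(!p$edges$fixed)

## Build the candidate Boolean model for a bitstring over the optional edges.
candidate_model <- function(p, bitstring, and_gates = list()) {
  opt <- optional_edges(p)
  stopifnot(length(bitstring) == length(opt))
  sel <- c(which(p$edges$fixed), opt[bitstring == 1L])
  model_from_edges(p$edges[sel, , drop = FALSE], and_gates = and_gates,
                   nodes = p$nodes$node)
}

## Simulate one condition: all nodes off, stimuli clamped on, inhibited
## nodes clamped off, one synchronous step per sorted measurement timepoint.
## Returns a step x node matrix aligned to the timepoints.
simulate_condition <- function(net, stimuli, inhibitors, n_steps) {
  clamps <- c(stats::setNames(rep(1, length(stimuli)), stimuli),
              stats::setNames(rep(0, length(inhibitors)), inhibitors))
  clamps <- clamps[names(clamps) %in% net$nodes]
  net <- set_clamps(net, clamps)
  s <- apply_clamps(net, stats::setNames(rep(0L, length(net$nodes)), net$nodes))
  out <- matrix(0L, nrow = n_steps, ncol = length(net$nodes),
                dimnames = list(NULL, net$nodes))
  for (i in seq_len(n_steps)) {
    s <- batch_step(net, matrix(s, nrow = 1L))[1L, ]
    out[i, ] <- s
  }
  out
}

#' Score a candidate topology against training data
#'
#' Builds the Boolean model from the fixed edges plus the optional edges
#' selected by \code{bitstring}, simulates every condition from the all-off
#' state with the condition's stimuli clamped on and inhibited nodes clamped
#' off, aligns synchronous update steps one-to-one with the sorted
#' measurement timepoints, and returns the mean squared deviation between
#' simulated 0/1 node values and the measured [0,1] values, plus
#' \code{size_penalty_weight * selected / optional} edges.  Lower is better.
#' A measured node absent from the candidate model is treated as constant 0
#' and contributes its squared data values.
#'
#' @param bitstring 0/1 vector over the PKN's optional edges
#' @param p a \code{\link{pkn}}
#' @param data a \code{\link{training_dataset}}
#' @param config a \code{\link{ga_config}}
#' @param and_gates AND-gate declarations, see \code{\link{model_from_edges}}
#' @return list with elements \code{fitness}, \code{mse}, \code{penalty}.
#' @export
score_model <- function(bitstring, p, data, config = ga_config(),
                        and_gates = list()) {
  net <- candidate_model(p, bitstring, and_gates)
  tps <- data$timepoints
  sq_err <- 0; n_pts <- 0L
  for (ci in seq_len(nrow(data$conditions))) {
    cond <- data$conditions$condition[ci]
    sim <- simulate_condition(net,
                              split_nodes(data$conditions$stimuli[ci]),
                              split_nodes(data$conditions$inhibitors[ci]),
                              length(tps))
    m <- data$measurements[data$measurements$condition == cond, ]
    step <- match(m$time_h, tps)
    node_col <- match(m$node, net$nodes)
    simv <- ifelse(is.na(node_col), 0, sim[cbind(step, node_col)])
    sq_err <- sq_err + sum((simv - m$value)^2)
    n_pts <- n_pts + nrow(m)
  }
  mse <- sq_err / n_pts
  n_opt <- length(bitstring)
  penalty <- if (n_opt > 0)
    config$size_penalty_weight * sum(bitstring) / n_opt else 0
  list(fitness = mse + penalty, mse = mse, penalty = penalty)
}

## One GA run: returns best bitstring, its fitness, and the per-generation
## best-fitness trace (non-increasing by elitism).
ga_run <- function(fitfun, nbits, config, seed) {
  set.seed(seed)
  pop <- matrix(stats::rbinom(config$population_size * nbits, 1L, 0.5),
                nrow = config$population_size)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  evalpop <- function(P) {
    vapply(seq_len(nrow(P)), function(i) {
      key <- paste(P[i, ], collapse = "")
      v <- cache[[key]]
      if (is.null(v)) { v <- fitfun(P[i, ]); cache[[key]] <- v }
      v
    }, numeric(1))
  }
  fit <- evalpop(pop)
  trace <- min(fit)
  t0 <- proc.time()[["elapsed"]]
  for (gen in seq_len(config$max_generations)) {
    ord <- order(fit)
    elite <- pop[ord[seq_len(config$elitism)], , drop = FALSE]
    ## binary tournament selection
    n <- config$population_size
    pick <- function() {
      ij <- sample.int(n, 2L)
      ij[which.min(fit[ij])]
    }
    children <- matrix(0L, nrow = n, ncol = nbits)
    for (i in seq_len(n)) {
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      child <- p1
      if (stats::runif(1) < config$crossover_rate && nbits > 0) {
        mask <- stats::rbinom(nbits, 1L, 0.5) == 1L
        child[mask] <- p2[mask]
      }
      flip <- stats::runif(nbits) < config$mutation_rate
      child[flip] <- 1L - child[flip]
      children[i, ] <- child
    }
    children[seq_len(config$elitism), ] <- elite
    pop <- children
    fit <- evalpop(pop)
    trace <- c(trace, min(min(fit), trace[length(trace)]))
    ## stopping: wall time or relative plateau
    if (proc.time()[["elapsed"]] - t0 > config$max_cpu_time_s) break
    if (length(trace) > config$patience) {
      prev <- trace[length(trace) - config$patience]
      now <- trace[length(trace)]
      if (prev - now < config$rel_tolerance * max(prev, .Machine$double.eps)) break
    }
  }
  best_i <- which.min(fit)
  best_fit <- fit[best_i]
  best <- pop[best_i, ]
  ## the trace is monotone; the returned best matches its final value
  list(bitstring = best, fitness = best_fit, trace = trace)
}

#' Train a PKN topology by multi-run genetic algorithm
#'
#' The central fitting function.  The GA searches over bitstrings selecting
#' optional PKN edges; fixed edges are present in every candidate.  The
#' optimisation is repeated \code{config$runs} times from distinct sub-seeds
#' (\code{seed + 1000 * run}); an optional edge enters the consensus when it
#' is selected in at least \code{retention_fraction} of the runs' best
#' models.
#'
#' @param p a \code{\link{pkn}} (typically compressed, see
#'   \code{\link{compress_pkn}})
#' @param data a \code{\link{training_dataset}}
#' @param config a \code{\link{ga_config}}
#' @param and_gates AND-gate declarations, see \code{\link{model_from_edges}}
#' @return object of class \code{"topology_fit"} with per-run best
#'   bitstrings and fitness traces, per-edge selection frequencies, and the
#'   consensus \code{pkn}.
#' @export
fit_topology <- function(p, data, config = ga_config(), and_gates = list()) {
  stopifnot(inherits(p, "pkn"), inherits(data, "training_dataset"))
  opt <- optional_edges(p)
  nbits <- length(opt)
  if (nbits == 0L) {
    cons <- p
    res <- structure(list(pkn = p, consensus = cons,
                          edge_frequency = numeric(0),
                          runs = list(), config = config, and_gates = and_gates,
                          data = data),
                     class = "topology_fit")
    return(res)
  }
  fitfun <- function(bits) score_model(bits, p, data, config, and_gates)$fitness
  runs <- vector("list", config$runs)
  for (r in seq_len(config$runs))
    runs[[r]] <- ga_run(fitfun, nbits, config, seed = config$seed + 1000L * r)
  sel <- do.call(rbind, lapply(runs, `[[`, "bitstring"))
  freq <- colMeans(sel)
  keep_opt <- opt[freq >= config$retention_fraction]
  keep <- sort(c(which(p$edges$fixed), keep_opt))
  cons <- pkn(p$edges[keep, , drop = FALSE], roles = node_roles(p))
  attr(cons, "compression") <- attr(p, "compression")
  structure(list(pkn = p, consensus = cons,
                 edge_frequency = stats::setNames(
                   freq, paste(p$edges$source[opt], p$edges$target[opt], sep = "->")),
                 runs = runs, config = config, and_gates = and_gates,
                 data = data),
            class = "topology_fit")
}

#' @export
print.topology_fit <- function(x, ...) {
  cat(sprintf("Topology fit: %d optional edges, %d GA runs, retention %.2f\n",
              length(x$edge_frequency), length(x$runs),
              x$config$retention_fraction))
  cat(sprintf("Consensus: %d of %d PKN edges retained (%d fixed)\n",
              nrow(x$consensus$edges), nrow(x$pkn$edges),
              sum(x$consensus$edges$fixed)))
  if (length(x$runs))
    cat(sprintf("Best fitness across runs: %.6g (median %.6g)\n",
                min(vapply(x$runs, `[[`, numeric(1), "fitness")),
                stats::median(vapply(x$runs, `[[`, numeric(1), "fitness"))))
  invisible(x)
}

#' @export
summary.topology_fit <- function(object, ...) {
  print(object)
  if (length(object$edge_frequency)) {
    cat("Optional-edge selection frequencies:\n")
    f <- sort(object$edge_frequency, decreasing = TRUE)
    for (i in seq_along(f)) cat(sprintf("  %-30s %.2f\n", names(f)[i], f[i]))
  }
  invisible(object)
}

#' Per-edge selection frequencies of a topology fit
#'
#' @param object a \code{topology_fit}
#' @param ... unused
#' @return named numeric vector, optional edge -> fraction of runs retained.
#' @export
coef.topology_fit <- function(object, ...) object$edge_frequency

#' Plot GA convergence traces
#'
#' One line per run: the best fitness reached by each generation
#' (non-increasing under elitism).
#'
#' @param x a \code{topology_fit}
#' @param ... passed to \code{matplot}
#' @export
plot.topology_fit <- function(x, ...) {
  if (!length(x$runs)) { message("no GA runs to plot"); return(invisible(x)) }
  traces <- lapply(x$runs, `[[`, "trace")
  len <- max(vapply(traces, length, integer(1)))
  m <- vapply(traces, function(tr) c(tr, rep(tr[length(tr)], len - length(tr))),
              numeric(len))
  graphics::matplot(seq_len(len) - 1L, m, type = "l", lty = 1,
                    col = grDevices::grey(0.2, alpha = 0.35),
                    xlab = "generation", ylab = "best fitness", ...)
  invisible(x)
}

#' Export a topology fit as JSON + consensus SIF
#'
#' @param fit a \code{topology_fit}
#' @param json_path edge frequencies and per-run fitness as JSON
#' @param sif_path consensus network as SIF
#' @export
write_fit <- function(fit, json_path, sif_path) {
  jsonlite::write_json(
    list(edge_frequency = as.list(fit$edge_frequency),
         run_fitness = vapply(fit$runs, `[[`, numeric(1), "fitness"),
         retention_fraction = fit$config$retention_fraction,
         runs = length(fit$runs), seed = fit$config$seed),
    json_path, auto_unbox = TRUE, digits = NA)
  write_sif(fit$consensus$edges, sif_path)
  invisible(json_path)
}
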