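## Synchronous Boolean network engine.
##
## Networks are stored with their rules both as text ("A & !B") and compiled
## to per-node truth tables over the node's parents, so that single steps,
## batched steps over many states, and exhaustive enumeration all share one
## transition representation.

MAX_PARENTS <- 16L

#' Construct a synchronous Boolean network
#'
#' A Boolean network is a set of named nodes, each carrying one transition
#' rule written as a logical expression over node names using \code{&},
#' \code{|}, \code{!}, parentheses and the constants \code{0}/\code{1}.
#' Under synchronous updating every node is replaced simultaneously by the
#' value of its rule on the current state, which makes the dynamics
#' deterministic.
#'
#' Nodes that are referenced by some rule but have no rule of their own
#' (input nodes, e.g. a growth-factor stimulus) default to self-maintenance:
#' their next value is their current value.  Clamped nodes ignore their rule
#' and hold the clamp value at every step.
#'
#' @param rules named character vector; names are node names, values are
#'   rule expressions.  Constants \code{"0"} and \code{"1"} are allowed.
#' @param nodes optional character vector fixing node order; defaults to the
#'   rule names followed by any referenced-only input nodes.
#' @param clamps named numeric/integer vector of 0/1 values forced onto
#'   nodes, overriding their rules.
#' @return an object of class \code{"boolean_network"}.
#' @examples
#' net <- boolean_network(c(B = "A", A = "!B"))
#' synchronous_step(net, c(A = 1, B = 0))
#' @export
boolean_network <- function(rules, nodes = NULL, clamps = NULL) {
  if (is.null(names(rules)) || any(!nzchar(names(rules))))
    stop("'rules' must be a named character vector")
  if (anyDuplicated(names(rules)))
    stop("duplicate rule for node(s): ",
         paste(unique(names(rules)[duplicated(names(rules))]), collapse = ", "))
  exprs <- lapply(rules, parse_rule)
  referenced <- unique(unlist(lapply(exprs, all.vars)))
  if (is.null(nodes)) {
    nodes <- union(names(rules), referenced)
  } else {
    missing_nodes <- setdiff(union(names(rules), referenced), nodes)
    if (length(missing_nodes))
      stop("rule references undeclared node(s): ",
           paste(missing_nodes, collapse = ", "))
  }
  bad <- setdiff(referenced, nodes)
  if (length(bad))
    stop("rule references unknown node(s): ", paste(bad, collapse = ", "))
  ## input nodes hold their value
  for (n in setdiff(nodes, names(rules))) {
    rules[[n]] <- n
    exprs[[n]] <- as.name(n)
  }
  rules <- rules[nodes]
  exprs <- exprs[nodes]
  net <- structure(list(nodes = nodes, rules = rules, exprs = exprs,
                        clamps = numeric(0)),
                   class = "boolean_network")
  net <- compile_network(net)
  if (!is.null(clamps)) net <- set_clamps(net, clamps)
  net
}

## Parse one rule string, allowing only logical connectives, parentheses,
## node names and 0/1 constants.
parse_rule <- function(text) {
  ex <- tryCatch(str2lang(text), error = function(e)
    stop("cannot parse rule '", text, "': ", conditionMessage(e)))
  check_rule_ast(ex, text)
  ex
}

check_rule_ast <- function(ex, text) {
  if (is.symbol(ex)) return(invisible(TRUE))
  if (is.numeric(ex) || is.logical(ex)) {
    if (!(as.numeric(ex) %in% c(0, 1)))
      stop("rule '", text, "': only constants 0 and 1 are allowed")
    return(invisible(TRUE))
  }
  if (is.call(ex)) {
    op <- as.character(ex[[1]])
    if (!op %in% c("&", "|", "!", "(", "&&", "||"))
      stop("rule '", text, "': operator '", op, "' not allowed")
    for (i in seq_along(ex)[-1]) check_rule_ast(ex[[i]], text)
    return(invisible(TRUE))
  }
  stop("rule '", text, "': unsupported construct")
}

## Build per-node parent index vectors and truth tables.
compile_network <- function(net) {
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  compiled <- vector("list", length(net$nodes))
  for (j in seq_along(net$nodes)) {
    vars <- all.vars(net$exprs[[j]])
    if (length(vars) > MAX_PARENTS)
      stop("node '", net$nodes[j], "' has more than ", MAX_PARENTS, " parents")
    parents <- unname(idx[vars])
    k <- length(vars)
    if (k == 0L) {
      tt <- as.integer(eval(net$exprs[[j]], envir = baseenv()) != 0)
    } else {
      combos <- lapply(seq_len(k), function(i)
        rep(rep(c(0L, 1L), each = 2L^(i - 1L)), length.out = 2L^k))
      names(combos) <- vars
      val <- eval(net$exprs[[j]], envir = combos, enclos = baseenv())
      tt <- as.integer(rep_len(as.logical(val), 2L^k))
    }
    compiled[[j]] <- list(parents = parents, tt = tt)
  }
  net$compiled <- compiled
  net
}

#' Clamp nodes of a Boolean network
#'
#' @param net a \code{boolean_network}
#' @param clamps named 0/1 vector; use \code{NULL} to clear all clamps.
#' @return the network with clamps replaced.
#' @export
set_clamps <- function(net, clamps) {
  stopifnot(inherits(net, "boolean_network"))
  if (is.null(clamps) || length(clamps) == 0L) {
    net$clamps <- numeric(0)
    return(net)
  }
  if (is.null(names(clamps))) stop("'clamps' must be named")
  bad <- setdiff(names(clamps), net$nodes)
  if (length(bad)) stop("clamp on unknown node(s): ", paste(bad, collapse = ", "))
  if (!all(clamps %in% c(0, 1))) stop("clamp values must be 0 or 1")
  net$clamps <- clamps
  net
}

## validate and order a state vector
as_state <- function(net, state) {
  if (is.null(names(state))) {
    if (length(state) != length(net$nodes))
      stop("unnamed state must cover all ", length(net$nodes), " nodes")
    names(state) <- net$nodes
  }
  miss <- setdiff(net$nodes, names(state))
  if (length(miss)) stop("state misses node(s): ", paste(miss, collapse = ", "))
  s <- as.integer(state[net$nodes])
  if (!all(s %in% c(0L, 1L))) stop("state values must be 0 or 1")
  stats::setNames(s, net$nodes)
}

apply_clamps <- function(net, s) {
  if (length(net$clamps)) s[names(net$clamps)] <- as.integer(net$clamps)
  s
}

#' One synchronous update step
#'
#' Every unclamped node simultaneously takes the value of its rule evaluated
#' on \code{state}; clamped nodes take their clamp value.
#'
#' @param net a \code{boolean_network}
#' @param state named 0/1 vector over all nodes
#' @return the successor state, in network node order.
#' @export
synchronous_step <- function(net, state) {
  s <- as_state(net, state)
  out <- s
  for (j in seq_along(net$nodes)) {
    cj <- net$compiled[[j]]
    out[j] <- if (length(cj$parents) == 0L) cj$tt[1L]
              else cj$tt[1L + sum(s[cj$parents] * 2L^(seq_along(cj$parents) - 1L))]
  }
  apply_clamps(net, out)
}

## Batched synchronous step: M is an n x N 0/1 integer matrix (one state per
## row).  Core of the robustness sampler.
batch_step <- function(net, M) {
  out <- M
  for (j in seq_along(net$nodes)) {
    cj <- net$compiled[[j]]
    if (length(cj$parents) == 0L) {
      out[, j] <- cj$tt[1L]
    } else {
      ind <- rep.int(1L, nrow(M))
      for (i in seq_along(cj$parents))
        ind <- ind + M[, cj$parents[i]] * 2L^(i - 1L)
      out[, j] <- cj$tt[ind]
    }
  }
  if (length(net$clamps))
    for (nm in names(net$clamps))
      out[, match(nm, net$nodes)] <- as.integer(net$clamps[[nm]])
  out
}

state_key <- function(M) {
  ## exact for up to 53 nodes (double mantissa)
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
  drop(M %*% 2^(seq_len(ncol(M)) - 1))
}

#' Simulation configuration
#'
#' @param max_steps safety bound on the number of synchronous updates before
#'   a repeated state must have been seen; for an N-node network any
#'   trajectory repeats within \code{2^N + 1} steps.
#' @param seed integer seed for operations that draw random states.
#' @export
sim_config <- function(max_steps = 10000L, seed = 1L) {
  stopifnot(max_steps >= 1)
  structure(list(max_steps = as.integer(max_steps), seed = as.integer(seed)),
            class = "sim_config")
}

#' Run a trajectory to its attractor
#'
#' Iterates synchronous updates from \code{initial}, recording every visited
#' state, and stops at the first state repetition.  The repeated state marks
#' the entry into the terminal cycle (the attractor); a cycle of length 1 is
#' a fixed point.
#'
#' @param net a \code{boolean_network}
#' @param initial named 0/1 state vector
#' @param config a \code{\link{sim_config}}
#' @return an object of class \code{"bn_trajectory"}: list with
#'   \code{states} (step x node 0/1 matrix, first row = initial state after
#'   clamping), \code{attractor_start} (1-based row index where the cycle
#'   begins) and \code{attractor} (a \code{bn_attractor}).
#' @export
run_to_attractor <- function(net, initial, config = sim_config()) {
  s <- apply_clamps(net, as_state(net, initial))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  states <- matrix(0L, nrow = 64L, ncol = length(net$nodes),
                   dimnames = list(NULL, net$nodes))
  nstored <- 0L
  repeat {
    key <- as.character(state_key(s))
    prev <- seen[[key]]
    if (!is.null(prev)) {
      states <- states[seq_len(nstored), , drop = FALSE]
      cyc <- states[seq.int(prev, nstored), , drop = FALSE]
      traj <- structure(list(states = states, attractor_start = prev,
                             attractor = new_attractor(cyc)),
                        class = "bn_trajectory")
      return(traj)
    }
    nstored <- nstored + 1L
    if (nstored > nrow(states))
      states <- rbind(states, matrix(0L, nrow = nrow(states), ncol = ncol(states)))
    states[nstored, ] <- s
    seen[[key]] <- nstored
    if (nstored > config$max_steps)
      stop("no repeated state within max_steps = ", config$max_steps,
           "; increase max_steps (2^N + 1 always suffices)")
    s <- batch_step(net, matrix(s, nrow = 1L))[1L, ]
    names(s) <- net$nodes
  }
}

new_attractor <- function(cycle_matrix, basin_fraction = NA_real_) {
  ## canonical rotation: start the cycle at its minimal state key
  keys <- state_key(cycle_matrix)
  rot <- which.min(keys)
  ord <- c(seq.int(rot, nrow(cycle_matrix)), seq_len(rot - 1L))
  cyc <- cycle_matrix[ord, , drop = FALSE]
  structure(list(cycle = cyc, basin_fraction = basin_fraction,
                 id = paste(state_key(cyc), collapse = "|")),
            class = "bn_attractor")
}

#' @export
print.bn_attractor <- function(x, ...) {
  cat(sprintf("Attractor: cycle length %d%s\n", nrow(x$cycle),
              if (!is.na(x$basin_fraction))
                sprintf(", basin fraction %.4g", x$basin_fraction) else ""))
  on_nodes <- colnames(x$cycle)[colSums(x$cycle) == nrow(x$cycle)]
  cat("  always-on nodes:", if (length(on_nodes)) paste(on_nodes, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Exhaustive attractor search
#'
#' Enumerates all \code{2^N} states of an N-node network (subject to any
#' clamps), follows each to its attractor, and returns the distinct
#' attractors with exact basin fractions.  Intended as an oracle for small
#' networks.
#'
#' @param net a \code{boolean_network}
#' @param max_nodes refuse beyond this many free (unclamped) nodes.
#' @return list of \code{bn_attractor}, basin fractions summing to 1,
#'   ordered by decreasing basin.
#' @export
brute_force_attractors <- function(net, max_nodes = 16L) {
  N <- length(net$nodes)
  free <- setdiff(net$nodes, names(net$clamps))
  if (length(free) > max_nodes)
    stop("network has ", length(free), " unclamped nodes; exhaustive ",
         "enumeration refused beyond ", max_nodes)
  nfree <- length(free)
  n_states <- 2L^nfree
  M <- matrix(0L, nrow = n_states, ncol = N, dimnames = list(NULL, net$nodes))
  if (nfree > 0) {
    for (i in seq_len(nfree))
      M[, match(free[i], net$nodes)] <-
        rep(rep(c(0L, 1L), each = 2L^(i - 1L)), length.out = n_states)
  }
  for (nm in names(net$clamps))
    M[, match(nm, net$nodes)] <- as.integer(net$clamps[[nm]])
  ## successor map over enumerated states, indexed by free-node key
  succ <- batch_step(net, M)
  free_idx <- match(free, net$nodes)
  enum_key <- function(S) if (nfree == 0) rep(0, nrow(S))
                          else drop(S[, free_idx, drop = FALSE] %*% 2^(seq_len(nfree) - 1))
  succ_key <- enum_key(succ) + 1  # 1-based index into enumeration
  ## functional-graph traversal with colouring
  assignment <- integer(n_states)      # attractor id per state, 0 = unknown
  attractors <- list()
  for (start in seq_len(n_states)) {
    if (assignment[start] != 0L) next
    path <- integer(0); pos <- new.env(hash = TRUE, parent = emptyenv())
    v <- start
    repeat {
      if (assignment[v] != 0L) { aid <- assignment[v]; break }
      p <- pos[[as.character(v)]]
      if (!is.null(p)) {
        ## new cycle found: states path[p..end]
        cyc_idx <- path[seq.int(p, length(path))]
        att <- new_attractor(M[cyc_idx, , drop = FALSE])
        attractors[[length(attractors) + 1L]] <- att
        aid <- length(attractors)
        break
      }
      path <- c(path, v)
      pos[[as.character(v)]] <- length(path)
      v <- succ_key[v]
    }
    assignment[path] <- aid
  }
  tab <- tabulate(assignment, nbins = length(attractors))
  for (i in seq_along(attractors))
    attractors[[i]]$basin_fraction <- tab[i] / n_states
  attractors[order(-tab)]
}

#' Sample basin fractions by random initialization
#'
#' Draws uniform random initial states over the unclamped nodes, runs each to
#' its attractor, and tallies attractor frequencies.  Trajectories are
#' advanced in one batched matrix with Brent-style cycle detection (a
#' snapshot state per trajectory, refreshed at doubling intervals), so the
#' cost is a few vectorised sweeps rather than one R loop per sample.
#'
#' @param net a \code{boolean_network}
#' @param clamps optional named 0/1 vector applied on top of the network's
#'   clamps for this experiment (e.g. a stimulus held on).
#' @param n_samples number of random initial states.
#' @param config \code{\link{sim_config}}; \code{seed} controls the draw.
#' @return list of \code{bn_attractor} with \code{basin_fraction} set to the
#'   sampled frequency, ordered by decreasing frequency.
#' @export
robustness_sample <- function(net, clamps = NULL, n_samples = 1000L,
                              config = sim_config()) {
  stopifnot(n_samples >= 1)
  if (!is.null(clamps)) {
    merged <- net$clamps
    merged[names(clamps)] <- clamps
    net <- set_clamps(net, merged)
  }
  N <- length(net$nodes)
  set.seed(config$seed)
  M <- matrix(sample(c(0L, 1L), n_samples * N, replace = TRUE),
              nrow = n_samples, ncol = N, dimnames = list(NULL, net$nodes))
  for (nm in names(net$clamps))
    M[, match(nm, net$nodes)] <- as.integer(net$clamps[[nm]])

  done <- logical(n_samples)
  snap <- M
  snap_age <- 0L; power <- 1L; total <- 0L
  final <- M
  while (any(!done)) {
    if (snap_age == power) {
      snap[!done, ] <- M[!done, , drop = FALSE]
      snap_age <- 0L
      power <- power * 2L
    }
    act <- which(!done)
    M[act, ] <- batch_step(net, M[act, , drop = FALSE])
    snap_age <- snap_age + 1L
    total <- total + 1L
    hit <- act[state_key(M[act, , drop = FALSE]) ==
               state_key(snap[act, , drop = FALSE])]
    if (length(hit)) {
      done[hit] <- TRUE
      final[hit, ] <- M[hit, , drop = FALSE]
    }
    if (total > config$max_steps + 2L * power)
      stop("cycle detection exceeded the safety bound; increase max_steps")
  }
  ## group by reached attractor state, canonicalise each unique one
  keys <- state_key(final)
  uk <- unique(keys)
  ids <- character(length(uk))
  atts <- vector("list", length(uk))
  for (i in seq_along(uk)) {
    s0 <- final[match(uk[i], keys), ]
    names(s0) <- net$nodes
    cyc <- enumerate_cycle(net, s0)
    atts[[i]] <- new_attractor(cyc)
    ids[i] <- atts[[i]]$id
  }
  ## merge unique states belonging to the same cycle
  counts <- tapply(tabulate(match(keys, uk), nbins = length(uk)), ids, sum)
  out <- list()
  for (id in names(counts)) {
    a <- atts[[match(id, ids)]]
    a$basin_fraction <- unname(counts[[id]]) / n_samples
    out[[length(out) + 1L]] <- a
  }
  out[order(-vapply(out, function(a) a$basin_fraction, numeric(1)))]
}

## walk the cycle containing state s0 (s0 must lie on its attractor)
enumerate_cycle <- function(net, s0) {
  k0 <- state_key(matrix(s0, nrow = 1L))
  cyc <- matrix(s0, nrow = 1L, dimnames = list(NULL, net$nodes))
  s <- s0
  repeat {
    s <- batch_step(net, matrix(s, nrow = 1L))[1L, ]
    if (state_key(matrix(s, nrow = 1L)) == k0) break
    cyc <- rbind(cyc, s)
    if (nrow(cyc) > 2^length(net$nodes)) stop("state is not on a cycle")
  }
  cyc
}

#' Node-by-step activity matrix of a trajectory
#'
#' Rows are nodes, columns are synchronous update steps from the initial
#' state up to and including the attractor entry; entries are 0/1 activity,
#' ready for heatmap display or TSV export.
#'
#' @param trajectory a \code{bn_trajectory}
#' @return 0/1 integer matrix, nodes x steps.
#' @export
path_to_attractor_matrix <- function(trajectory) {
  stopifnot(inherits(trajectory, "bn_trajectory"))
  m <- t(trajectory$states)
  colnames(m) <- paste0("step_", seq_len(ncol(m)) - 1L)
  m
}

#' First step at which a node is active in a trajectory
#'
#' @param trajectory a \code{bn_trajectory}
#' @param node node name
#' @return 0-based step index of first activity, or \code{Inf} if never on.
#' @export
first_on_step <- function(trajectory, node) {
  stopifnot(inherits(trajectory, "bn_trajectory"))
  col <- trajectory$states[, node]
  w <- which(col == 1L)
  if (length(w)) w[1L] - 1L else Inf
}

#' Remove edges from a Boolean network
#'
#' Deleting the edge source -> target removes the source's influence on the
#' target's rule by partially evaluating the rule with the source fixed to 0
#' (an activating occurrence then contributes FALSE, an inhibiting occurrence
#' \code{!0 = TRUE}), after which the rule is recompiled.
#'
#' @param net a \code{boolean_network}
#' @param edges data frame with columns \code{source}, \code{target}.
#' @return the modified network.
#' @export
remove_edges <- function(net, edges) {
  stopifnot(inherits(net, "boolean_network"),
            all(c("source", "target") %in% names(edges)))
  for (i in seq_len(nrow(edges))) {
    src <- edges$source[i]; tgt <- edges$target[i]
    if (!tgt %in% net$nodes) stop("unknown target node '", tgt, "'")
    ex <- net$exprs[[tgt]]
    if (!src %in% all.vars(ex))
      stop("no edge ", src, " -> ", tgt, " in the network rules")
    sub <- list(0); names(sub) <- src
    ex2 <- eval(call("substitute", ex, sub))
    net$exprs[[tgt]] <- ex2
    net$rules[[tgt]] <- paste(deparse(ex2), collapse = " ")
  }
  compile_network(net)
}

#' Signed edge list implied by the rules of a network
#'
#' An edge parent -> node is called activating if switching the parent on
#' never decreases the rule output over all contexts and increases it in at
#' least one, inhibiting in the mirrored case, and ambiguous (sign 0)
#' otherwise.
#'
#' @param net a \code{boolean_network}
#' @return data frame with columns \code{source}, \code{sign}, \code{target}.
#' @export
network_edges <- function(net) {
  out <- list()
  for (j in seq_along(net$nodes)) {
    cj <- net$compiled[[j]]
    k <- length(cj$parents)
    if (k == 0L) next
    for (i in seq_len(k)) {
      stride <- 2L^(i - 1L)
      base <- which(bitwAnd((seq_len(2L^k) - 1L), stride) == 0L)
      lo <- cj$tt[base]; hi <- cj$tt[base + stride]
      ## an input node's implicit self-maintenance is not an edge
      if (net$nodes[cj$parents[i]] == net$nodes[j] &&
          identical(net$rules[[j]], net$nodes[j])) next
      sgn <- if (all(hi >= lo) && any(hi > lo)) 1L
             else if (all(hi <= lo) && any(hi < lo)) -1L
             else if (all(hi == lo)) NA_integer_  # vacuous parent
             else 0L
      if (is.na(sgn)) next
      out[[length(out) + 1L]] <- data.frame(
        source = net$nodes[cj$parents[i]], sign = sgn,
        target = net$nodes[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(source = character(0), sign = integer(0),
                      target = character(0)))
  do.call(rbind, out)
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Synchronous Boolean network: %d nodes, %d edges\n",
              length(x$nodes), nrow(network_edges(x))))
  if (length(x$clamps))
    cat("  clamps:", paste0(names(x$clamps), "=", x$clamps, collapse = ", "), "\n")
  inputs <- x$nodes[vapply(x$nodes, function(n) identical(x$rules[[n]], n), logical(1))]
  if (length(inputs)) cat("  input nodes:", paste(inputs, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.boolean_network <- function(object, ...) {
  e <- network_edges(object)
  cat(sprintf("Synchronous Boolean network: %d nodes, %d edges (%d activating, %d inhibiting)\n",
              length(object$nodes), nrow(e), sum(e$sign == 1), sum(e$sign == -1)))
  cat("Rules:\n")
  for (n in object$nodes) cat(sprintf("  %s = %s\n", n, object$rules[[n]]))
  invisible(object)
}

#' Simulate a Boolean network
#'
#' \code{simulate} method running one trajectory per requested replicate from
#' random initial states (or a fixed initial state if supplied).
#'
#' @param object a \code{boolean_network}
#' @param nsim number of trajectories
#' @param seed RNG seed
#' @param initial optional fixed initial state used for every trajectory
#' @param ... unused
#' @return list of \code{bn_trajectory}
#' @export
simulate.boolean_network <- function(object, nsim = 1, seed = 1L,
                                     initial = NULL, ...) {
  set.seed(seed)
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    s <- if (is.null(initial))
      stats::setNames(sample(c(0L, 1L), length(object$nodes), replace = TRUE),
                      object$nodes)
    else initial
    out[[i]] <- run_to_attractor(object, s)
  }
  out
}

#' Plot a trajectory as a path-to-attractor heatmap
#'
#' @param x a \code{bn_trajectory}
#' @param ... passed to \code{image}
#' @export
plot.bn_trajectory <- function(x, ...) {
  m <- path_to_attractor_matrix(x)
  graphics::image(seq_len(ncol(m)) - 1L, seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ]),
                  col = c("grey95", "firebrick"), xlab = "synchronous update step",
                  ylab = "", axes = FALSE, ...)
  graphics::axis(1, at = seq_len(ncol(m)) - 1L)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.6)
  graphics::box()
  invisible(x)
}

#' Export a trajectory as a TSV node-by-step matrix
#'
#' @param trajectory a \code{bn_trajectory}
#' @param path output file
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  m <- path_to_attractor_matrix(trajectory)
  df <- data.frame(node = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
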