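## Prior-knowledge networks: signed directed edge lists with node roles,
## SIF-style I/O, compression against the experimental design, and logic
## synthesis into simulatable Boolean networks.

#' Construct a prior-knowledge network
#'
#' A PKN is the literature-derived hypothesis space for topology training:
#' signed directed edges between named nodes, each node annotated with its
#' experimental role and each edge flagged as fixed (kept in every candidate
#' model) or optional (subject to selection).
#'
#' @param edges data frame with columns \code{source}, \code{sign} (+1/-1),
#'   \code{target} and optionally \code{fixed} (logical, default FALSE).
#' @param roles named character vector node -> role, one of
#'   \code{"stimulus"}, \code{"inhibited"}, \code{"measured"},
#'   \code{"readout"} or \code{"hidden"}.  Unlisted nodes are hidden.
#' @return object of class \code{"pkn"}.
#' @export
pkn <- function(edges, roles = character(0)) {
  stopifnot(all(c("source", "sign", "target") %in% names(edges)))
  if (!"fixed" %in% names(edges)) edges$fixed <- FALSE
  edges <- edges[, c("source", "sign", "target", "fixed")]
  edges$sign <- as.integer(edges$sign)
  if (!all(edges$sign %in% c(-1L, 1L))) stop("edge signs must be +1 or -1")
  key <- paste(edges$source, edges$target)
  if (anyDuplicated(key))
    stop("duplicate edge(s): ", paste(unique(key[duplicated(key)]), collapse = "; "))
  nodes <- union(edges$source, edges$target)
  nodes <- union(nodes, names(roles))
  role <- stats::setNames(rep("hidden", length(nodes)), nodes)
  if (length(roles)) {
    bad <- setdiff(names(roles), nodes)
    if (length(bad)) stop("role for unknown node(s): ", paste(bad, collapse = ", "))
    ok <- c("stimulus", "inhibited", "measured", "readout", "hidden")
    if (!all(roles %in% ok)) stop("roles must be one of: ", paste(ok, collapse = ", "))
    role[names(roles)] <- roles
  }
  stim <- names(role)[role == "stimulus"]
  incoming <- edges$target %in% stim
  if (any(incoming))
    stop("stimulus node(s) with incoming edges: ",
         paste(unique(edges$target[incoming]), collapse = ", "))
  structure(list(nodes = data.frame(node = nodes, role = unname(role[nodes]),
                                    stringsAsFactors = FALSE),
                 edges = edges),
            class = "pkn")
}

#' @export
print.pkn <- function(x, ...) {
  cat(sprintf("Prior-knowledge network: %d nodes, %d edges (%d fixed)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$fixed)))
  tab <- table(x$nodes$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

node_roles <- function(p) stats::setNames(p$nodes$role, p$nodes$node)

## --- SIF-style I/O ---------------------------------------------------------

#' Read / write SIF-style signed edge files
#'
#' Tab-delimited: source, sign (+1/-1), target, and an optional fourth
#' column with a 0/1 fixed-edge flag.  Lines starting with '#' are comments.
#'
#' @param path file path
#' @return data frame with columns source, sign, target, fixed.
#' @export
read_sif <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  out <- list()
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed SIF line ", i, " in '", path, "': ", lines[i])
    sgn <- suppressWarnings(as.integer(f[2]))
    if (is.na(sgn) || !sgn %in% c(-1L, 1L))
      stop("malformed sign on SIF line ", i, " in '", path, "': ", f[2])
    fixed <- if (length(f) >= 4) f[4] %in% c("1", "TRUE", "true") else FALSE
    out[[length(out) + 1L]] <- data.frame(source = f[1], sign = sgn, target = f[3],
                                          fixed = fixed, stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no edges in '", path, "'")
  do.call(rbind, out)
}

#' @rdname read_sif
#' @param edges data frame with columns source, sign, target and optionally
#'   fixed
#' @param header optional comment line(s) written at the top of the file
#' @export
write_sif <- function(edges, path, header = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  fixed <- if ("fixed" %in% names(edges)) as.integer(edges$fixed) else NULL
  body <- paste(edges$source, edges$sign, edges$target, sep = "\t")
  if (!is.null(fixed)) body <- paste(body, fixed, sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read / write node-annotation tables
#'
#' Tab-delimited with columns \code{node}, \code{role} and optionally
#' further annotation columns (e.g. \code{late_gene}).
#'
#' @param path file path
#' @export
read_node_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          fileEncoding = "UTF-8")
  if (!all(c("node", "role") %in% names(df)))
    stop("node annotation needs columns 'node' and 'role'")
  df
}

#' Read a PKN from a SIF file plus node-annotation TSV
#'
#' @param sif_path SIF edge file (4th column = fixed flag)
#' @param nodes_path node annotation TSV with columns node, role
#' @return a \code{\link{pkn}}
#' @export
read_pkn <- function(sif_path, nodes_path) {
  edges <- read_sif(sif_path)
  ann <- read_node_annotation(nodes_path)
  pkn(edges, roles = stats::setNames(ann$role, ann$node))
}

#' Read a Boolean network from a SIF file plus a logic sidecar
#'
#' The sidecar maps each node to its transition rule, one
#' \code{node = expression} per line ('#' comments allowed).  The SIF edge
#' list is checked for consistency against the rule parents: every SIF edge
#' must appear in its target's rule and vice versa.
#'
#' @param sif_path SIF edge file
#' @param logic_path logic sidecar
#' @return a \code{\link{boolean_network}}
#' @export
read_boolean_network <- function(sif_path, logic_path) {
  edges <- read_sif(sif_path)
  lines <- readLines(logic_path, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  rules <- character(0)
  for (i in keep) {
    m <- regmatches(lines[i], regexec("^\\s*([A-Za-z0-9_./]+)\\s*=\\s*(.+?)\\s*$", lines[i]))[[1]]
    if (length(m) != 3)
      stop("malformed logic line ", i, " in '", logic_path, "': ", lines[i])
    rules[m[2]] <- m[3]
  }
  net <- boolean_network(rules, nodes = union(names(rules),
                                              union(edges$source, edges$target)))
  implied <- network_edges(net)
  a <- paste(edges$source, edges$target)
  b <- paste(implied$source, implied$target)
  if (length(setdiff(a, b)) || length(setdiff(b, a)))
    stop("SIF edges and logic rules disagree: only in SIF {",
         paste(setdiff(a, b), collapse = "; "), "}, only in rules {",
         paste(setdiff(b, a), collapse = "; "), "}")
  net
}

#' Write a Boolean network as SIF + logic sidecar
#'
#' @param net a \code{boolean_network}
#' @param sif_path,logic_path output files
#' @export
write_boolean_network <- function(net, sif_path, logic_path) {
  write_sif(network_edges(net), sif_path)
  con <- file(logic_path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%s = %s", net$nodes, unlist(net$rules[net$nodes])), con)
  invisible(sif_path)
}

## --- compression ----------------------------------------------------------

pkn_igraph <- function(p) {
  igraph::graph_from_data_frame(p$edges[, c("source", "target")],
                                vertices = p$nodes$node, directed = TRUE)
}

#' Compress a PKN against the experimental design
#'
#' Removes nodes that are unreachable from every stimulus or that reach no
#' measured/inhibited/readout node (unobservable), then collapses chains of
#' hidden nodes with exactly one incoming and one outgoing edge into a
#' single edge whose sign is the product of the collapsed signs and which is
#' fixed if every collapsed edge was fixed.  Designated nodes (stimulus,
#' inhibited, measured, readout) are never removed.
#'
#' The collapsed chains are recorded in \code{attr(, "compression")} so the
#' inverse operation (\code{\link{expand_network}}) can restore them.
#'
#' @param p a \code{\link{pkn}}
#' @return the compressed \code{pkn} with a \code{"compression"} attribute.
#' @export
compress_pkn <- function(p) {
  roles <- node_roles(p)
  stim <- names(roles)[roles == "stimulus"]
  obs <- names(roles)[roles %in% c("measured", "inhibited", "readout")]
  if (!length(stim) || !length(obs))
    stop("compression needs at least one stimulus and one measured node")
  g <- pkn_igraph(p)
  from_stim <- unique(names(unlist(igraph::ego(
    g, order = igraph::vcount(g), nodes = stim, mode = "out"))))
  to_obs <- unique(names(unlist(igraph::ego(
    g, order = igraph::vcount(g), nodes = obs, mode = "in"))))
  keep <- union(intersect(from_stim, to_obs), c(stim, obs))
  edges <- p$edges[p$edges$source %in% keep & p$edges$target %in% keep, ]
  if (!nrow(edges))
    stop("network is empty after pruning: no stimulus-to-measurement path")

  chains <- list()
  repeat {
    indeg <- table(factor(edges$target, levels = keep))
    outdeg <- table(factor(edges$source, levels = keep))
    cand <- keep[roles[keep] == "hidden" & indeg[keep] == 1L & outdeg[keep] == 1L]
    ## never collapse through a self-loop
    cand <- cand[vapply(cand, function(n) {
      ei <- which(edges$target == n); eo <- which(edges$source == n)
      edges$source[ei] != n && edges$target[eo] != n
    }, logical(1))]
    if (!length(cand)) break
    n <- cand[[1]]
    ei <- which(edges$target == n); eo <- which(edges$source == n)
    new_src <- edges$source[ei]; new_tgt <- edges$target[eo]
    new_sign <- edges$sign[ei] * edges$sign[eo]
    new_fixed <- edges$fixed[ei] && edges$fixed[eo]
    dup <- which(edges$source == new_src & edges$target == new_tgt)
    chains[[length(chains) + 1L]] <- list(
      through = n,
      chain = data.frame(source = c(new_src, n), sign = c(edges$sign[ei], edges$sign[eo]),
                         target = c(n, new_tgt), fixed = c(edges$fixed[ei], edges$fixed[eo]),
                         stringsAsFactors = FALSE),
      produced = data.frame(source = new_src, sign = new_sign, target = new_tgt,
                            stringsAsFactors = FALSE))
    edges <- edges[-c(ei, eo), ]
    if (!length(dup)) {
      edges <- rbind(edges, data.frame(source = new_src, sign = new_sign,
                                       target = new_tgt, fixed = new_fixed,
                                       stringsAsFactors = FALSE))
    }
    keep <- setdiff(keep, n)
  }
  out <- pkn(edges, roles = roles[keep])
  attr(out, "compression") <- chains
  out
}

## --- logic synthesis ------------------------------------------------------

#' Synthesize Boolean rules from a signed edge list
#'
#' Standard synthesis: a node's activating parents are OR-combined and every
#' inhibiting parent contributes an AND NOT term.  AND-gate hyperedges can
#' be declared explicitly (e.g. two transcription factors jointly required
#' for a dimeric complex); their members are conjoined instead of OR-ed.
#' Nodes without activating parents get the constant rule 0 (they stay off
#' unless clamped); source-only nodes become self-maintaining inputs.
#'
#' @param edges data frame with columns source, sign, target
#' @param and_gates named list: target -> character vector of parents that
#'   form one AND gate among the target's activators.
#' @param nodes optional full node set (to carry isolated nodes through)
#' @return a \code{\link{boolean_network}}
#' @export
model_from_edges <- function(edges, and_gates = list(), nodes = NULL) {
  all_nodes <- union(union(edges$source, edges$target), nodes)
  rules <- character(0)
  for (n in unique(edges$target)) {
    e <- edges[edges$target == n, ]
    act <- e$source[e$sign == 1L]
    inh <- e$source[e$sign == -1L]
    terms <- character(0)
    if (n %in% names(and_gates)) {
      gate <- and_gates[[n]]
      present <- gate[gate %in% act]
      if (length(present) >= 2L) {
        terms <- c(terms, paste0("(", paste(present, collapse = " & "), ")"))
        act <- setdiff(act, present)
      }
    }
    terms <- c(terms, act)
    body <- if (length(terms)) paste(terms, collapse = " | ") else "0"
    if (length(inh) && body != "0")
      body <- paste0("(", body, ")",
                     paste0(" & !", inh, collapse = ""))
    rules[[n]] <- body
  }
  if (!length(rules)) # no edges selected: every node is an input
    rules <- stats::setNames(as.character(all_nodes), all_nodes)
  boolean_network(rules, nodes = all_nodes)
}

## --- expansion ------------------------------------------------------------

#' Re-expand a consensus network
#'
#' Inverse of compression plus literature additions: restores collapsed
#' hidden chains whose produced edge survived in the consensus, appends
#' listed extra edges (e.g. downstream target genes), and attaches negative
#' autoregulation to designated transient nodes.  The result is synthesized
#' into a simulatable Boolean network.
#'
#' @param consensus a \code{pkn} (typically the trained consensus); if it
#'   carries a \code{"compression"} attribute those chains are restored for
#'   every surviving produced edge.
#' @param additions list with optional elements \code{edges} (data frame
#'   source, sign, target), \code{autoregulation} (character vector of nodes
#'   that receive a self-inhibition edge).
#' @param and_gates passed to \code{\link{model_from_edges}}
#' @return a \code{\link{boolean_network}}
#' @export
expand_network <- function(consensus, additions = list(), and_gates = list()) {
  edges <- consensus$edges[, c("source", "sign", "target")]
  for (ch in rev(attr(consensus, "compression") %||% list())) {
    hit <- which(edges$source == ch$produced$source &
                 edges$target == ch$produced$target &
                 edges$sign == ch$produced$sign)
    if (length(hit)) {
      edges <- edges[-hit[1], ]
      edges <- rbind(edges, ch$chain[, c("source", "sign", "target")])
    }
  }
  if (!is.null(additions$edges)) {
    add <- additions$edges[, c("source", "sign", "target")]
    key <- paste(edges$source, edges$target)
    addkey <- paste(add$source, add$target)
    if (any(addkey %in% key))
      stop("addition would duplicate edge(s): ",
           paste(addkey[addkey %in% key], collapse = "; "))
    edges <- rbind(edges, add)
  }
  for (n in additions$autoregulation %||% character(0)) {
    if (any(edges$source == n & edges$target == n))
      stop("addition would duplicate self-edge on ", n)
    edges <- rbind(edges, data.frame(source = n, sign = -1L, target = n,
                                     stringsAsFactors = FALSE))
  }
  edges <- unique(edges)
  model_from_edges(edges, and_gates = and_gates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## --- training data --------------------------------------------------------

#' Construct a perturbation time-course training dataset
#'
#' @param conditions data frame with columns \code{condition},
#'   \code{stimuli} and \code{inhibitors}; the latter two are
#'   comma-separated node lists ("" for none).
#' @param measurements long-format data frame with columns \code{condition},
#'   \code{time_h}, \code{node}, \code{value}, values in [0,1].
#' @return object of class \code{"training_dataset"}.
#' @export
training_dataset <- function(conditions, measurements) {
  stopifnot(all(c("condition", "stimuli", "inhibitors") %in% names(conditions)),
            all(c("condition", "time_h", "node", "value") %in% names(measurements)))
  if (any(measurements$value < 0 | measurements$value > 1))
    stop("measurement values must lie in [0,1]")
  if (!all(measurements$condition %in% conditions$condition))
    stop("measurement for undeclared condition")
  structure(list(conditions = conditions,
                 measurements = measurements[order(measurements$condition,
                                                   measurements$time_h,
                                                   measurements$node), ],
                 timepoints = sort(unique(measurements$time_h)),
                 measured_nodes = sort(unique(measurements$node))),
            class = "training_dataset")
}

split_nodes <- function(s) {
  if (is.na(s) || !nzchar(s)) character(0)
  else trimws(strsplit(s, ",", fixed = TRUE)[[1]])
}

#' @export
print.training_dataset <- function(x, ...) {
  cat(sprintf("Training dataset: %d conditions, %d timepoints, %d measured nodes\n",
              nrow(x$conditions), length(x$timepoints), length(x$measured_nodes)))
  invisible(x)
}

#' Write / read training data in MIDAS layout
#'
#' CSV with TR: columns for treatments (stimuli and inhibitors, the latter
#' suffixed "i"), one DA: column for acquisition time and DV: columns for
#' measured values — the interchange layout used by logic-model training
#' tools.
#'
#' @param data a \code{\link{training_dataset}}
#' @param path output CSV
#' @export
write_midas <- function(data, path) {
  stim_nodes <- sort(unique(unlist(lapply(data$conditions$stimuli, split_nodes))))
  inh_nodes <- sort(unique(unlist(lapply(data$conditions$inhibitors, split_nodes))))
  rows <- list()
  for (ci in seq_len(nrow(data$conditions))) {
    cond <- data$conditions$condition[ci]
    st <- split_nodes(data$conditions$stimuli[ci])
    ih <- split_nodes(data$conditions$inhibitors[ci])
    m <- data$measurements[data$measurements$condition == cond, ]
    for (tp in sort(unique(m$time_h))) {
      mt <- m[m$time_h == tp, ]
      row <- c(as.list(as.integer(stim_nodes %in% st)),
               as.list(as.integer(inh_nodes %in% ih)),
               list(tp),
               as.list(stats::setNames(mt$value[match(data$measured_nodes, mt$node)],
                                       NULL)))
      rows[[length(rows) + 1L]] <- row
    }
  }
  df <- as.data.frame(do.call(rbind, lapply(rows, function(r)
    unlist(r, use.names = FALSE))))
  names(df) <- c(paste0("TR:", stim_nodes),
                 if (length(inh_nodes)) paste0("TR:", inh_nodes, "i"),
                 "DA:ALL",
                 paste0("DV:", data$measured_nodes))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_midas
#' @export
read_midas <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  tr <- grep("^TR:", names(df), value = TRUE)
  dv <- grep("^DV:", names(df), value = TRUE)
  da <- grep("^DA:", names(df), value = TRUE)
  if (!length(dv) || length(da) != 1L) stop("not a MIDAS table: ", path)
  inh_cols <- tr[endsWith(tr, "i")]
  stim_cols <- setdiff(tr, inh_cols)
  cond_key <- apply(df[, tr, drop = FALSE], 1, paste, collapse = "_")
  conds <- unique(cond_key)
  cond_df <- data.frame(condition = paste0("c", seq_along(conds)),
                        stimuli = NA_character_, inhibitors = NA_character_,
                        stringsAsFactors = FALSE)
  meas <- list()
  for (i in seq_along(conds)) {
    rows <- which(cond_key == conds[i])
    r1 <- df[rows[1], ]
    cond_df$stimuli[i] <- paste(sub("^TR:", "", stim_cols[r1[stim_cols] == 1]),
                                collapse = ",")
    cond_df$inhibitors[i] <- paste(sub("i$", "", sub("^TR:", "", inh_cols[r1[inh_cols] == 1])),
                                   collapse = ",")
    for (r in rows) for (v in dv) {
      meas[[length(meas) + 1L]] <- data.frame(
        condition = cond_df$condition[i], time_h = df[[da]][r],
        node = sub("^DV:", "", v), value = df[[v]][r], stringsAsFactors = FALSE)
    }
  }
  training_dataset(cond_df, do.call(rbind, meas))
}
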