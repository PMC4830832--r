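## Packaged PC12 differentiation model: prior-knowledge network and final
## Boolean model fixtures, the four stimulus/inhibitor scenarios, the
## differentiation readout, and feedback/bistability analyses.
##
## The shipped fixtures are synthetic reconstructions assembled from the
## published main-text statements about the NGF signalling network (fixed
## edges, pathway structure, feedback loops and transient regulators); see
## the fixture file headers and the methods vignette.

fixture_path <- function(file)
  system.file("extdata", file, package = "booltrain", mustWork = TRUE)

#' Load a packaged PC12 network fixture
#'
#' \code{which = "pkn"} returns the 63-node / 109-edge prior-knowledge
#' network (a \code{\link{pkn}} with stimulus NGF, inhibition points MEK,
#' JNK and PI3K, and the transcriptionally measured genes annotated).
#' \code{which = "final"} returns the trained, re-expanded 32-node /
#' 52-edge Boolean model as a \code{\link{boolean_network}}.
#'
#' @param which \code{"pkn"} or \code{"final"}
#' @return a \code{pkn} or \code{boolean_network}
#' @export
load_fixture <- function(which = c("pkn", "final")) {
  which <- match.arg(which)
  if (which == "pkn") {
    read_pkn(fixture_path("pc12_pkn.sif"), fixture_path("pc12_pkn_nodes.tsv"))
  } else {
    read_boolean_network(fixture_path("pc12_final.sif"),
                         fixture_path("pc12_final_rules.txt"))
  }
}

#' Node annotations of the final PC12 model
#'
#' @return data frame with columns node, role, late_gene
#' @export
pc12_node_annotation <- function()
  read_node_annotation(fixture_path("pc12_final_nodes.tsv"))

#' Late differentiation gene set of the final model
#'
#' The gene nodes whose joint activation (strict majority, together with
#' active uPAR signalling) defines the differentiation readout.  Taken from
#' the \code{late_gene} column of the fixture annotation.
#'
#' @return character vector of node names.
#' @export
pc12_late_genes <- function() {
  ann <- pc12_node_annotation()
  ann$node[ann$late_gene == 1]
}

#' AND-gate declarations of the PC12 models
#'
#' The dimeric AP1 complex requires Fosl1 and Jund jointly; Jund and Junb
#' require coincident MEK/ERK and JNK activity.  Used when synthesizing
#' candidate models from PKN edge selections.
#'
#' @param compressed use the lumped MEK_ERK node name of the final model
#'   (\code{TRUE}) or the PKN's split MEK/ERK cascade (\code{FALSE}).
#' @return named list target -> parent vector.
#' @export
pc12_gates <- function(compressed = TRUE) {
  erk <- if (compressed) "MEK_ERK" else "ERK"
  list(AP1 = c("Fosl1", "Jund"),
       Jund = c(erk, "JNK"),
       Junb = c(erk, "JNK"))
}

#' Packaged synthetic qRT-PCR fold-change table
#'
#' Long-format linear-scale fold changes of the final model's measured
#' genes under the four scenarios (synthetic rendering, see the fixture
#' header), as produced by a 2^-ddCt quantification.  Useful as input for
#' the rescale/Hill/binarize discretization chain and for assembling a
#' training dataset.
#'
#' @return data frame with columns node, condition, time_h, value.
#' @export
pc12_fold_changes <- function()
  read_fold_change_tsv(fixture_path("pc12_qpcr_foldchange.tsv"))

#' Discretized PC12 training dataset
#'
#' Rescales the packaged fold changes per node to [0,1], applies the Hill
#' transform and assembles a \code{\link{training_dataset}} with the four
#' scenario conditions (NGF stimulation, inhibitor clamps per scenario).
#'
#' @param config a \code{\link{hill_config}}
#' @return a \code{\link{training_dataset}}
#' @export
pc12_training_data <- function(config = hill_config()) {
  fc <- rescale_unit_interval(pc12_fold_changes())
  fc$value <- hill_transform(fc$value, config)
  conds <- data.frame(
    condition = c("NGF", "NGF+MEKi", "NGF+JNKi", "NGF+PI3Ki"),
    stimuli = "NGF",
    inhibitors = c("", "MEK_ERK", "JNK", "PI3K"),
    stringsAsFactors = FALSE)
  training_dataset(conds, fc)
}

#' The four PC12 perturbation scenarios
#'
#' NGF stimulation alone or combined with MEK, JNK or PI3K inhibition.
#' Stimuli are clamped on and inhibited nodes clamped off for the whole run
#' (inhibitors are pre-incubated before stimulation).  In the final model
#' MEK inhibition clamps the lumped MEK_ERK node.
#'
#' @param name one of \code{"NGF"}, \code{"NGF+MEKi"}, \code{"NGF+JNKi"},
#'   \code{"NGF+PI3Ki"}
#' @return list with elements \code{name}, \code{stimuli},
#'   \code{inhibited}.
#' @export
scenario_spec <- function(name = c("NGF", "NGF+MEKi", "NGF+JNKi", "NGF+PI3Ki")) {
  name <- match.arg(name)
  inhibited <- switch(name,
                      "NGF" = character(0),
                      "NGF+MEKi" = "MEK_ERK",
                      "NGF+JNKi" = "JNK",
                      "NGF+PI3Ki" = "PI3K")
  list(name = name, stimuli = "NGF", inhibited = inhibited)
}

#' Differentiation readout from an attractor
#'
#' Differentiation is called when a strict majority of the late
#' differentiation genes is persistently active in the attractor (active in
#' every cycle state) together with active uPAR signalling; ties on an
#' even-sized gene set are conservatively called non-differentiating.
#'
#' @param attractor a \code{bn_attractor}
#' @param late_gene_set character vector of gene nodes (non-empty)
#' @param upar_node name of the uPAR signalling node, default "uPAR"
#' @return object of class \code{"phenotype_call"}: list with
#'   \code{differentiation}, \code{active_late_genes}, \code{attractor}.
#' @export
differentiation_readout <- function(attractor, late_gene_set = pc12_late_genes(),
                                    upar_node = "uPAR") {
  stopifnot(inherits(attractor, "bn_attractor"))
  if (!length(late_gene_set)) stop("late_gene_set must be non-empty")
  miss <- setdiff(c(late_gene_set, upar_node), colnames(attractor$cycle))
  if (length(miss)) stop("node(s) not in attractor: ", paste(miss, collapse = ", "))
  on <- colnames(attractor$cycle)[colSums(attractor$cycle) == nrow(attractor$cycle)]
  active <- intersect(late_gene_set, on)
  diff <- (length(active) > length(late_gene_set) / 2) && (upar_node %in% on)
  structure(list(differentiation = diff, active_late_genes = active,
                 late_gene_set = late_gene_set, upar_node = upar_node,
                 upar_active = upar_node %in% on, attractor = attractor),
            class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat(sprintf("Phenotype: %s (uPAR %s; %d/%d late genes active)\n",
              if (x$differentiation) "differentiation" else "no differentiation",
              if (x$upar_active) "active" else "inactive",
              length(x$active_late_genes), length(x$late_gene_set)))
  invisible(x)
}

#' Run a PC12 perturbation scenario
#'
#' All nodes start off, the scenario's clamps are applied, the network is
#' synchronously updated to its attractor and the differentiation phenotype
#' is called.
#'
#' @param spec a \code{\link{scenario_spec}} (or its name)
#' @param net the network, default the packaged final model
#' @param config a \code{\link{sim_config}}
#' @return list with elements \code{trajectory} (a \code{bn_trajectory})
#'   and \code{phenotype} (a \code{phenotype_call}).
#' @export
run_scenario <- function(spec = "NGF", net = load_fixture("final"),
                         config = sim_config()) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  clamps <- c(stats::setNames(rep(1, length(spec$stimuli)), spec$stimuli),
              stats::setNames(rep(0, length(spec$inhibited)), spec$inhibited))
  net <- set_clamps(net, clamps)
  init <- stats::setNames(rep(0L, length(net$nodes)), net$nodes)
  traj <- run_to_attractor(net, init, config)
  list(trajectory = traj,
       phenotype = differentiation_readout(traj$attractor))
}

#' Default uPAR autocrine feedback edge set
#'
#' The transcriptional entry into the autocrine uPAR loop: AP1-driven
#' induction of uPA.  Removing it disconnects uPA/uPAR/plasmin/MMP/integrin
#' signalling from the gene response.
#'
#' @return data frame with columns source, target.
#' @export
upar_feedback_edges <- function()
  data.frame(source = "AP1", target = "uPA", stringsAsFactors = FALSE)

#' Phenotype after feedback removal
#'
#' Removes the given feedback edges from the network, reruns the NGF
#' scenario and returns the phenotype call.
#'
#' @param net network, default the packaged final model
#' @param feedback_edges data frame source/target, default
#'   \code{\link{upar_feedback_edges}}
#' @return a \code{phenotype_call}
#' @export
feedback_knockout <- function(net = load_fixture("final"),
                              feedback_edges = upar_feedback_edges()) {
  net2 <- remove_edges(net, feedback_edges)
  run_scenario("NGF", net = net2)$phenotype
}

#' Bistability analysis of the PC12 model
#'
#' Reports (i) the resting attractor reached from the all-off state with
#' NGF clamped off, (ii) the differentiation attractor with NGF clamped on,
#' and (iii) whether the differentiation state persists after the NGF clamp
#' is released once the attractor has been reached (transcriptome-induced
#' positive-feedback memory), optionally contrasted with the same release
#' after removing the uPAR feedback.
#'
#' @param net network, default the packaged final model
#' @param feedback_edges feedback edges used for the contrast
#' @return list with elements \code{resting} (attractor),
#'   \code{stimulated} (attractor), \code{memory} (logical: differentiation
#'   persists after NGF release), \code{memory_without_feedback} (logical).
#' @export
bistability_check <- function(net = load_fixture("final"),
                              feedback_edges = upar_feedback_edges()) {
  init <- stats::setNames(rep(0L, length(net$nodes)), net$nodes)
  resting <- run_to_attractor(set_clamps(net, c(NGF = 0)), init)$attractor
  stim <- run_scenario("NGF", net = net)
  att_state <- stim$trajectory$attractor$cycle[1, ]
  release <- function(network) {
    s <- att_state
    s["NGF"] <- 0L
    run_to_attractor(set_clamps(network, NULL), s)$attractor
  }
  released <- release(net)
  mem <- differentiation_readout(released)$differentiation
  released_nf <- release(remove_edges(net, feedback_edges))
  mem_nf <- differentiation_readout(released_nf)$differentiation
  list(resting = resting, stimulated = stim$trajectory$attractor,
       released = released, memory = mem,
       memory_without_feedback = mem_nf)
}
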