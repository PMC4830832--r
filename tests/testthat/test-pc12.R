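final <- load_fixture("final")
late <- pc12_late_genes()

test_that("packaged fixtures load with the documented structure", {
  p <- load_fixture("pkn")
  expect_equal(nrow(p$nodes), 63)
  expect_equal(nrow(p$edges), 109)
  expect_equal(sum(p$nodes$role == "stimulus"), 1)
  expect_setequal(p$nodes$node[p$nodes$role == "inhibited"],
                  c("MEK", "JNK", "PI3K"))

  expect_length(final$nodes, 32)
  expect_equal(nrow(network_edges(final)), 52)

  # the literature-fixed edges are present in both networks
  fixed_final <- network_edges(final)
  key <- paste(fixed_final$source, fixed_final$target)
  for (e in c("NGF RAS", "NGF PI3K", "NGF PLC", "AP1 Npy", "Mmp10 RAS",
              "RAS MEK_ERK", "PLC MEK_ERK", "MEK_ERK Jund", "JNK Jund",
              "MEK_ERK Junb", "JNK Junb", "Fosl1 AP1", "Jund AP1"))
    expect_true(e %in% key, label = paste("final model edge", e))
  pkey <- paste(p$edges$source, p$edges$target)
  for (e in c("NGF RAS", "NGF PI3K", "NGF PLC", "AP1 Npy", "Mmp10 RAS",
              "RAS MEK", "PLC MEK", "ERK Jund", "JNK Jund", "Fosl1 AP1",
              "Jund AP1"))
    expect_true(e %in% pkey, label = paste("PKN edge", e))
  expect_true(all(p$edges$fixed[pkey %in%
    c("NGF RAS", "NGF PI3K", "NGF PLC")]))

  # every final-model node has a PKN counterpart, up to the documented lumps
  lumped <- c(MEK_ERK = "MEK", CellDiff = "CellDiff")
  mapped <- ifelse(final$nodes %in% names(lumped),
                   lumped[final$nodes], final$nodes)
  expect_true(all(mapped %in% p$nodes$node))
})

test_that("fixture parsing errors carry the offending line", {
  bad <- tempfile(fileext = ".sif")
  writeLines(c("A\t1\tB", "A\tx\tC"), bad)
  expect_error(read_sif(bad), "line 2")
})

test_that("the four scenarios reproduce the published phenotype table", {
  res <- lapply(c("NGF", "NGF+MEKi", "NGF+JNKi", "NGF+PI3Ki"),
                run_scenario, net = final)
  names(res) <- c("NGF", "NGF+MEKi", "NGF+JNKi", "NGF+PI3Ki")
  expect_true(res[["NGF"]]$phenotype$differentiation)
  expect_true(res[["NGF+PI3Ki"]]$phenotype$differentiation)
  expect_false(res[["NGF+MEKi"]]$phenotype$differentiation)
  expect_false(res[["NGF+JNKi"]]$phenotype$differentiation)

  # every scenario reaches a steady state (fixed point)
  for (r in res) expect_equal(nrow(r$trajectory$attractor$cycle), 1)

  # PI3K inhibition only silences the PI3K/AKT branch
  a_ngf <- res[["NGF"]]$trajectory$attractor$cycle[1, ]
  a_pi3 <- res[["NGF+PI3Ki"]]$trajectory$attractor$cycle[1, ]
  expect_setequal(names(a_ngf)[a_ngf != a_pi3],
                  c("PI3K", "AKT", "Maff", "Klf10"))

  # JNK inhibition silences all late target genes
  a_jnk <- res[["NGF+JNKi"]]$trajectory$attractor$cycle[1, ]
  expect_true(all(a_jnk[late] == 0))
})

test_that("differentiation readout uses strict majority plus uPAR", {
  nodes <- c("uPAR", "g1", "g2", "g3", "g4")
  att_all <- structure(list(
    cycle = matrix(1L, 1, 5, dimnames = list(NULL, nodes)),
    basin_fraction = NA_real_, id = "x"), class = "bn_attractor")
  expect_true(differentiation_readout(att_all, paste0("g", 1:4))$differentiation)

  # uPAR off vetoes differentiation
  att_no_upar <- att_all
  att_no_upar$cycle[1, "uPAR"] <- 0L
  expect_false(differentiation_readout(att_no_upar, paste0("g", 1:4))$differentiation)

  # exactly half of an even-sized set is not a majority
  att_half <- att_all
  att_half$cycle[1, c("g3", "g4")] <- 0L
  expect_false(differentiation_readout(att_half, paste0("g", 1:4))$differentiation)

  expect_error(differentiation_readout(att_all, character(0)), "non-empty")
})

test_that("Klf4, Btg2 and Zfp36 are transient and Zfp36 delays AP1", {
  tr <- run_scenario("NGF", net = final)$trajectory
  pre <- tr$states[seq_len(tr$attractor_start - 1L), , drop = FALSE]
  for (g in c("Klf4", "Btg2", "Zfp36")) {
    expect_true(any(pre[, g] == 1L), label = paste(g, "active before attractor"))
    expect_true(all(tr$attractor$cycle[, g] == 0L),
                label = paste(g, "silent in attractor"))
  }
  with_delay <- first_on_step(tr, "AP1")
  no_delay_net <- remove_edges(final, data.frame(source = "Zfp36",
                                                 target = "AP1"))
  tr2 <- run_scenario("NGF", net = no_delay_net)$trajectory
  expect_gt(with_delay, first_on_step(tr2, "AP1"))
})

test_that("uPAR feedback is necessary for the differentiation phenotype", {
  ko <- feedback_knockout(final)
  expect_false(ko$differentiation)

  # removing nothing reproduces the NGF run
  same <- feedback_knockout(final, feedback_edges = data.frame(
    source = character(0), target = character(0)))
  expect_true(same$differentiation)

  # an edge off every stimulus-to-readout path leaves the phenotype unchanged
  off_path <- feedback_knockout(final, feedback_edges = data.frame(
    source = "MEK_ERK", target = "Junb"))
  expect_true(off_path$differentiation)
})

test_that("the cell-fate switch is bistable with feedback-dependent memory", {
  bi <- bistability_check(final)
  # resting attractor: everything off without NGF
  expect_equal(nrow(bi$resting$cycle), 1)
  expect_true(all(bi$resting$cycle == 0L))
  # stimulated attractor differentiates
  expect_true(differentiation_readout(bi$stimulated)$differentiation)
  # the differentiated state survives NGF withdrawal only with feedback
  expect_true(bi$memory)
  expect_false(bi$memory_without_feedback)
})

test_that("random initialization always reaches the differentiation attractor", {
  rs <- robustness_sample(final, clamps = c(NGF = 1), n_samples = 2000,
                          config = sim_config(seed = 20160414))
  expect_length(rs, 1)
  expect_equal(rs[[1]]$basin_fraction, 1.0)
  expect_true(differentiation_readout(rs[[1]])$differentiation)
})

test_that("packaged fold changes discretize into a valid training set", {
  fc <- pc12_fold_changes()
  expect_true(all(fc$value > 0))
  td <- pc12_training_data()
  expect_s3_class(td, "training_dataset")
  expect_true(all(td$measurements$value >= 0 & td$measurements$value <= 1))
  expect_equal(nrow(td$conditions), 4)
})
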