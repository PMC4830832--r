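toy_pkn <- function() {
  # S(stim) -> A(hidden) -> B(measured), plus a decoy S -> B
  pkn(data.frame(source = c("S", "A", "S"),
                 sign = 1L,
                 target = c("A", "B", "B"),
                 fixed = c(TRUE, TRUE, FALSE)),
      roles = c(S = "stimulus", B = "measured"))
}

test_that("PKN construction enforces its invariants", {
  expect_error(pkn(data.frame(source = c("A", "A"), sign = 1,
                              target = c("B", "B"))),
               "duplicate")
  expect_error(pkn(data.frame(source = "A", sign = 1, target = "S"),
                   roles = c(S = "stimulus")),
               "incoming")
  expect_error(pkn(data.frame(source = "A", sign = 2, target = "B")), "sign")
})

test_that("compression collapses hidden chains and prunes unobservables", {
  # chain A(stim) -> B(hidden) -> C(measured) becomes one positive edge
  p <- pkn(data.frame(source = c("A", "B"), sign = 1L, target = c("B", "C")),
           roles = c(A = "stimulus", C = "measured"))
  cp <- compress_pkn(p)
  expect_equal(nrow(cp$edges), 1)
  expect_equal(cp$edges$source, "A")
  expect_equal(cp$edges$target, "C")
  expect_equal(cp$edges$sign, 1L)

  # sign multiplies through collapsed inhibitions
  p2 <- pkn(data.frame(source = c("A", "B"), sign = c(-1L, -1L),
                       target = c("B", "C")),
            roles = c(A = "stimulus", C = "measured"))
  expect_equal(compress_pkn(p2)$edges$sign, 1L)

  # hidden node with no path to a measured node is removed
  p3 <- pkn(data.frame(source = c("A", "A", "B"), sign = 1L,
                       target = c("B", "D", "C")),
            roles = c(A = "stimulus", C = "measured"))
  cp3 <- compress_pkn(p3)
  expect_false("D" %in% cp3$nodes$node)

  # fully measured network is unchanged
  p4 <- pkn(data.frame(source = c("A", "B"), sign = 1L, target = c("B", "C")),
            roles = c(A = "stimulus", B = "measured", C = "measured"))
  cp4 <- compress_pkn(p4)
  expect_equal(nrow(cp4$edges), 2)

  # disconnected designs error out
  p5 <- pkn(data.frame(source = "A", sign = 1L, target = "B"),
            roles = c(A = "stimulus", C = "measured"))
  expect_error(compress_pkn(p5), "empty|path")
})

test_that("logic synthesis ORs activators and AND-NOTs inhibitors", {
  net <- model_from_edges(data.frame(source = c("A", "B", "C"),
                                     sign = c(1L, 1L, -1L),
                                     target = "D"))
  expect_equal(unname(synchronous_step(net, c(A = 1, B = 0, C = 0, D = 0))["D"]), 1L)
  expect_equal(unname(synchronous_step(net, c(A = 1, B = 1, C = 1, D = 0))["D"]), 0L)
  # AND gate declaration conjoins its members
  net2 <- model_from_edges(data.frame(source = c("A", "B"), sign = 1L,
                                      target = "D"),
                           and_gates = list(D = c("A", "B")))
  expect_equal(unname(synchronous_step(net2, c(A = 1, B = 0, D = 0))["D"]), 0L)
  expect_equal(unname(synchronous_step(net2, c(A = 1, B = 1, D = 0))["D"]), 1L)
})

test_that("score_model matches hand-computed fitness", {
  p <- toy_pkn()
  cfg <- ga_config(size_penalty_weight = 1e-4)
  # 3-node toy: S -> A -> B, B measured at 2 timepoints
  data <- training_dataset(
    data.frame(condition = "c1", stimuli = "S", inhibitors = ""),
    data.frame(condition = "c1", time_h = c(1, 2), node = "B",
               value = c(0.2, 0.9)))
  # trajectory with decoy off: B = 0 after step 1, 1 after step 2
  sc <- score_model(c(0L), p, data, cfg)
  expect_equal(sc$mse, ((0 - 0.2)^2 + (1 - 0.9)^2) / 2)
  expect_equal(sc$penalty, 0)
  expect_equal(sc$fitness, sc$mse)
  # with the decoy S -> B on, B is already 1 at step 1
  sc2 <- score_model(c(1L), p, data, cfg)
  expect_equal(sc2$mse, ((1 - 0.2)^2 + (1 - 0.9)^2) / 2)
  expect_equal(sc2$penalty, 1e-4)

  # all-off candidate against all-one data gives deviation 1
  p2 <- pkn(data.frame(source = "S", sign = 1L, target = "B", fixed = FALSE),
            roles = c(S = "stimulus", B = "measured"))
  data1 <- training_dataset(
    data.frame(condition = "c1", stimuli = "S", inhibitors = ""),
    data.frame(condition = "c1", time_h = 1:2, node = "B", value = c(1, 1)))
  expect_equal(score_model(c(0L), p2, data1, cfg)$mse, 1.0)

  # self-consistency: noise-free data from the candidate itself scores 0 + penalty
  truth <- random_network(8, n_extra = 2, n_decoys = 2, seed = 31)
  nf <- simulate_timecourse_expression(truth, noise_model(sd = 0, seed = 1))
  sc3 <- score_model(truth$true_bitstring, truth$pkn, nf, cfg)
  expect_equal(sc3$mse, 0)
  expect_equal(sc3$fitness, sc3$penalty)
})

test_that("GA training preserves fixed edges and respects retention", {
  truth <- random_network(8, n_extra = 2, n_decoys = 2, seed = 31)
  data <- simulate_timecourse_expression(truth, noise_model(sd = 0.05, seed = 2))
  cfg <- ga_config(runs = 5, seed = 17, max_generations = 40,
                   population_size = 30)
  fit <- fit_topology(truth$pkn, data, cfg)

  # fixed edges appear in every run's best model and in the consensus
  fixed_keys <- with(truth$pkn$edges[truth$pkn$edges$fixed, ],
                     paste(source, target))
  cons_keys <- with(fit$consensus$edges, paste(source, target))
  expect_true(all(fixed_keys %in% cons_keys))

  # convergence: per-run best fitness trace is non-increasing
  for (r in fit$runs) expect_true(all(diff(r$trace) <= 0))

  # consensus monotonicity: raising retention never adds edges
  opt <- coef(fit)
  for (thr in c(0.5, 0.7, 0.9, 1.0)) {
    kept <- names(opt)[opt >= thr]
    kept_prev <- names(opt)[opt >= thr - 0.2]
    expect_true(all(kept %in% kept_prev))
  }

  # PKN with only fixed edges: consensus equals the input network
  pf <- pkn(data.frame(source = c("S", "A"), sign = 1L, target = c("A", "B"),
                       fixed = TRUE),
            roles = c(S = "stimulus", A = "measured", B = "measured"))
  dataf <- training_dataset(
    data.frame(condition = "c1", stimuli = "S", inhibitors = ""),
    data.frame(condition = "c1", time_h = 1, node = "A", value = 1))
  fitf <- fit_topology(pf, dataf, cfg)
  expect_equal(fitf$consensus$edges, pf$edges)
  expect_length(coef(fitf), 0)
})

test_that("small-scale topology recovery finds the planted edges", {
  truth <- random_network(10, n_extra = 3, n_decoys = 3, seed = 77)
  data <- simulate_timecourse_expression(truth, noise_model(sd = 0.05, seed = 78))
  cfg <- ga_config(runs = 5, seed = 79, max_generations = 60)
  fit <- fit_topology(truth$pkn, data, cfg)
  bits <- as.integer(coef(fit) >= cfg$retention_fraction)
  expect_equal(bits, truth$true_bitstring)
})

test_that("expansion restores collapsed chains and validates additions", {
  p <- pkn(data.frame(source = c("A", "B"), sign = 1L, target = c("B", "C")),
           roles = c(A = "stimulus", C = "measured"))
  cp <- compress_pkn(p)
  net <- expand_network(cp)
  e <- network_edges(net)
  expect_setequal(paste(e$source, e$target), c("A B", "B C"))

  # added autoregulation contributes a self-inhibition
  net2 <- expand_network(cp, additions = list(autoregulation = "C"))
  e2 <- network_edges(net2)
  expect_true(any(e2$source == "C" & e2$target == "C" & e2$sign == -1))

  # duplicate additions are rejected with a message
  expect_error(expand_network(cp, additions = list(
    edges = data.frame(source = "A", sign = 1L, target = "B"))),
    "duplicate")
})

test_that("MIDAS export and import round-trip a training dataset", {
  truth <- random_network(6, n_extra = 1, n_decoys = 1, seed = 3)
  data <- simulate_timecourse_expression(truth, noise_model(sd = 0.05, seed = 4))
  f <- tempfile(fileext = ".csv")
  write_midas(data, f)
  back <- read_midas(f)
  expect_equal(length(back$timepoints), length(data$timepoints))
  expect_equal(back$measured_nodes, data$measured_nodes)
  # values survive by condition signature (condition names are regenerated)
  key <- function(d) {
    cd <- d$conditions[match(d$measurements$condition, d$conditions$condition), ]
    ord <- order(cd$stimuli, cd$inhibitors, d$measurements$time_h,
                 d$measurements$node)
    d$measurements$value[ord]
  }
  expect_equal(key(back), key(data), tolerance = 1e-8)
})
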