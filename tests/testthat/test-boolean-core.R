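test_that("synchronous step evaluates rules simultaneously and deterministically", {
  # identity self-loop
  net1 <- boolean_network(c(A = "A"))
  expect_equal(synchronous_step(net1, c(A = 1)), c(A = 1L))

  # hand truth-table evaluation on the negative loop
  net <- negative_loop()
  expect_equal(synchronous_step(net, c(A = 1, B = 0))[c("A", "B")],
               c(A = 1L, B = 1L))
  expect_equal(synchronous_step(net, c(A = 1, B = 1))[c("A", "B")],
               c(A = 0L, B = 1L))

  # bit-identical across repeated calls
  net3 <- random_rule_network(8, seed = 42)
  s <- setNames(rep(c(0L, 1L), 4), net3$nodes)
  expect_identical(synchronous_step(net3, s), synchronous_step(net3, s))
})

test_that("network construction validates rules and defaults inputs to self-maintenance", {
  expect_error(boolean_network(c(A = "B & C"), nodes = c("A", "B")),
               "undeclared|unknown")
  expect_error(boolean_network(c(A = "B + C")), "not allowed")
  # input node persists
  net <- boolean_network(c(Y = "X"))
  expect_equal(unname(synchronous_step(net, c(X = 1, Y = 0))["X"]), 1L)
})

test_that("clamped nodes hold their value at every trajectory step", {
  net <- set_clamps(random_rule_network(6, seed = 7),
                    c(X01 = 1, X04 = 0))
  tr <- run_to_attractor(net, setNames(rep(0L, 6), net$nodes))
  expect_true(all(tr$states[, "X01"] == 1L))
  expect_true(all(tr$states[, "X04"] == 0L))
})

test_that("run_to_attractor finds fixed points and cycles", {
  # constant rules: all-zero fixed point within 2 steps
  netc <- boolean_network(c(A = "0", B = "0"))
  tr <- run_to_attractor(netc, c(A = 1, B = 1))
  expect_lte(nrow(tr$states), 3)
  expect_equal(nrow(tr$attractor$cycle), 1)
  expect_equal(unname(tr$attractor$cycle[1, ]), c(0L, 0L))

  # negative loop from (1,1): the 4-state synchronous orbit
  net <- negative_loop()
  tr4 <- run_to_attractor(net, c(A = 1, B = 1))
  expect_equal(nrow(tr4$attractor$cycle), 4)
  expect_equal(tr4$attractor_start, 1)  # starts inside the cycle

  # stepping the last cycle state yields the first (cycle property)
  cyc <- tr4$attractor$cycle
  back <- synchronous_step(net, cyc[nrow(cyc), ])
  expect_equal(unname(back[colnames(cyc)]), unname(cyc[1, ]))

  # max_steps misconfiguration signals an error
  expect_error(run_to_attractor(net, c(A = 1, B = 1), sim_config(max_steps = 2)),
               "max_steps")
})

test_that("brute force enumerates attractors with exact basins", {
  # single NOT node: one cycle of length 2, basin 1
  net1 <- boolean_network(c(A = "!A"))
  bf1 <- brute_force_attractors(net1)
  expect_length(bf1, 1)
  expect_equal(nrow(bf1[[1]]$cycle), 2)
  expect_equal(bf1[[1]]$basin_fraction, 1.0)

  # two independent self-activators: 4 fixed points, basin 1/4 each
  net2 <- boolean_network(c(A = "A", B = "B"))
  bf2 <- brute_force_attractors(net2)
  expect_length(bf2, 4)
  expect_true(all(vapply(bf2, function(a) nrow(a$cycle), integer(1)) == 1))
  expect_equal(vapply(bf2, `[[`, numeric(1), "basin_fraction"),
               rep(0.25, 4))

  # basin fractions always sum to one
  net3 <- random_rule_network(9, seed = 5)
  expect_equal(sum(vapply(brute_force_attractors(net3), `[[`, numeric(1),
                          "basin_fraction")), 1)

  expect_error(brute_force_attractors(random_rule_network(18, seed = 1)),
               "refused")
})

test_that("brute force agrees with per-state trajectory following", {
  for (seed in c(11, 12, 13)) {
    net <- random_rule_network(3, seed = seed)
    bf <- brute_force_attractors(net)
    ids <- attractor_ids(bf)
    states <- all_states(net)
    reached <- apply(states, 1, function(s)
      run_to_attractor(net, s)$attractor$id)
    expect_setequal(unique(reached), ids)
    counts <- table(factor(reached, levels = ids)) / nrow(states)
    expect_equal(as.numeric(counts),
                 vapply(bf, `[[`, numeric(1), "basin_fraction"))
  }
})

test_that("robustness sampling matches exact basins", {
  # unique attractor: frequency 1 regardless of n
  netc <- boolean_network(c(A = "0", B = "A"))
  rs <- robustness_sample(netc, n_samples = 50, config = sim_config(seed = 3))
  expect_length(rs, 1)
  expect_equal(rs[[1]]$basin_fraction, 1.0)

  # convergence to exact basins at large n (binomial error)
  net <- random_rule_network(8, seed = 21)
  bf <- brute_force_attractors(net)
  rs <- robustness_sample(net, n_samples = 1e5, config = sim_config(seed = 4))
  bf_ids <- attractor_ids(bf)
  expect_true(all(attractor_ids(rs) %in% bf_ids))
  for (a in rs) {
    p <- bf[[match(a$id, bf_ids)]]$basin_fraction
    expect_lt(abs(a$basin_fraction - p),
              3 * sqrt(p * (1 - p) / 1e5) + 1e-12)
  }

  # reproducible for fixed seed
  r1 <- robustness_sample(net, n_samples = 500, config = sim_config(seed = 9))
  r2 <- robustness_sample(net, n_samples = 500, config = sim_config(seed = 9))
  expect_identical(lapply(r1, `[[`, "cycle"), lapply(r2, `[[`, "cycle"))
  expect_identical(vapply(r1, `[[`, numeric(1), "basin_fraction"),
                   vapply(r2, `[[`, numeric(1), "basin_fraction"))

  # clamps restrict the sampled space
  rs_cl <- robustness_sample(negative_loop(), clamps = c(A = 1),
                             n_samples = 200, config = sim_config(seed = 2))
  expect_true(all(vapply(rs_cl, function(a) all(a$cycle[, "A"] == 1),
                         logical(1))))
})

test_that("path-to-attractor matrix reproduces the trajectory", {
  # fixed point at step 0: single column equal to the initial state
  net <- boolean_network(c(A = "A", B = "A"))
  tr <- run_to_attractor(net, c(A = 1, B = 1))
  m <- path_to_attractor_matrix(tr)
  expect_equal(ncol(m), 1)
  expect_equal(unname(m[, 1]), c(1L, 1L))

  # negative-loop orbit columns
  tr4 <- run_to_attractor(negative_loop(), c(A = 1, B = 1))
  m4 <- path_to_attractor_matrix(tr4)
  expect_equal(dim(m4), c(2L, 4L))
  expect_equal(unname(m4["A", ]), c(1L, 0L, 0L, 1L))
  expect_equal(unname(m4["B", ]), c(1L, 1L, 0L, 0L))

  # TSV export roundtrip
  f <- tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr4, f)
  back <- utils::read.delim(f)
  expect_equal(back$node, rownames(m4))
  expect_equal(unname(as.matrix(back[, -1])), unname(m4), ignore_attr = TRUE)
})

test_that("edge removal partially evaluates rules", {
  net <- boolean_network(c(A = "B | C", B = "B", C = "C"))
  net2 <- remove_edges(net, data.frame(source = "B", target = "A"))
  expect_equal(unname(synchronous_step(net2, c(A = 0, B = 1, C = 0))["A"]), 0L)
  expect_equal(unname(synchronous_step(net2, c(A = 0, B = 0, C = 1))["A"]), 1L)
  # removing an inhibiting edge makes the term vacuous
  net3 <- boolean_network(c(A = "B & !C", B = "B", C = "C"))
  net4 <- remove_edges(net3, data.frame(source = "C", target = "A"))
  expect_equal(unname(synchronous_step(net4, c(A = 0, B = 1, C = 1))["A"]), 1L)
  expect_error(remove_edges(net, data.frame(source = "Z", target = "A")),
               "no edge")
})

test_that("implied edge list carries monotone signs", {
  net <- boolean_network(c(A = "B & !C", B = "B", C = "C"))
  e <- network_edges(net)
  expect_equal(nrow(e), 2)
  expect_equal(e$sign[e$source == "B"], 1L)
  expect_equal(e$sign[e$source == "C"], -1L)
})
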