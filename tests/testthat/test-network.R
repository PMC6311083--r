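# Network construction, resources, level evolution, state-graph dynamics.

pseudo <- pseudomonas_model()
pseudo_K <- as_parametrization(pseudo$network,
                               list(x = c(0, 2, 1, 2), y = c(0, 1)))

test_that("network validation enforces the structural invariants", {
  ents <- data.frame(name = c("a", "b"), max_level = c(1L, 1L))
  expect_error(brn_network(data.frame(name = c("a", "a"), max_level = 1L)),
               "duplicate entity")
  expect_error(brn_network(data.frame(name = "a", max_level = 0L)),
               "max_level >= 1")
  expect_error(
    brn_network(ents, data.frame(source = "a", target = "c",
                                 threshold = 1L, sign = "+")),
    "not declared")
  expect_error(
    brn_network(ents, data.frame(source = "a", target = "b",
                                 threshold = 2L, sign = "+")),
    "threshold")
  expect_error(
    brn_network(ents, data.frame(source = c("a", "a"), target = c("b", "b"),
                                 threshold = 1L, sign = c("+", "-"))),
    "ordered pair")
  # declared range is authoritative; out-degree mismatch only warns
  expect_warning(
    brn_network(data.frame(name = c("a", "b"), max_level = c(2L, 1L)),
                data.frame(source = "a", target = "b",
                           threshold = 1L, sign = "+")),
    "out-degree")
})

test_that("state space size is the product of level-range widths", {
  expect_identical(state_space_size(hbp_like_model()$network), 512)
  expect_identical(
    state_space_size(brn_network(data.frame(name = "a", max_level = 1L))), 2)
  boolean23 <- brn_network(
    data.frame(name = paste0("g", 1:23), max_level = 1L),
    check_levels = FALSE)
  expect_identical(state_space_size(boolean23), 8388608)
})

test_that("resources follow the present-activator / absent-inhibitor rule", {
  net <- pseudo$network
  # self-activator at threshold; the present inhibitor y is excluded
  expect_identical(resources(net, c(2, 1), "x"), "x")
  # an absent inhibitor counts as a resource
  expect_identical(resources(net, c(0, 0), "x"), c("y"))
  expect_identical(resources(net, c(1, 0), "x"), c("y"))
  expect_identical(resources(net, c(2, 0), "x"), c("x", "y"))
  expect_identical(resources(net, c(0, 1), "y"), character())
  expect_identical(resources(net, c(1, 1), "y"), "x")
  # an entity with no regulators has an empty resource set in every state
  iso <- brn_network(data.frame(name = c("a", "b"), max_level = 1L))
  for (s in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
    expect_identical(resources(iso, s, "a"), character())
  }
  expect_error(resources(net, c(0, 0), "zz"), "not declared")
})

test_that("resource monotonicity: activators never drop out when raised,
           inhibitors never enter", {
  net <- pseudo$network
  for (x in 0:1) for (y in 0:1) {
    lo <- resources(net, c(x, y), "x")
    up_act <- resources(net, c(x + 1, y), "x")   # raise activator x
    expect_true("x" %in% up_act || !("x" %in% lo))
    if (y < 1) {
      up_inh <- resources(net, c(x, y + 1), "x") # raise inhibitor y
      expect_false("y" %in% up_inh && !("y" %in% lo) && y >= 0)
    }
  }
})

test_that("level evolution takes unit steps toward the target", {
  expect_identical(evolve_level(0, 2), 1L)
  expect_identical(evolve_level(1, 1), 1L)
  expect_identical(evolve_level(2, 0), 1L)
  expect_error(evolve_level(-1, 0), "non-negative")
  for (s in 0:3) for (k in 0:3) {
    expect_identical(evolve_level(s, k), as.integer(s + sign(k - s)))
  }
})

test_that("successors change one entity by one unit toward K", {
  net <- pseudo$network
  expect_identical(successors(net, pseudo_K, c(2, 1)), list())  # stable (2,1)
  expect_identical(successors(net, pseudo_K, c(1, 1)), list(c(0L, 1L)))
  expect_identical(successors(net, pseudo_K, c(0, 0)), list(c(1L, 0L)))
  # every entity at its target => no successor
  allzero <- as_parametrization(net, list(x = c(0, 0, 0, 0), y = c(0, 0)))
  expect_identical(successors(net, allzero, c(0, 0)), list())
  expect_error(successors(net, list(x = c(0, 1)), c(0, 0)),
               "incomplete parametrization")
})

test_that("the Pseudomonas state graph reproduces the homeostatic cycle and
           the pathogenic stable state", {
  g <- build_state_graph(pseudo$network, pseudo_K)
  expect_identical(g$n_states, 6L)
  expect_identical(state_space_size(pseudo$network), 6)
  # stable state (2,1)
  expect_identical(unname(g$levels[g$deadlocks, ]), c(2L, 1L))
  # the 4-cycle (0,0)->(1,0)->(1,1)->(0,1)->(0,0)
  edge_set <- paste(
    apply(g$levels[g$from, , drop = FALSE], 1L, paste, collapse = ","),
    apply(g$levels[g$to, , drop = FALSE], 1L, paste, collapse = ","),
    sep = "->")
  for (e in c("0,0->1,0", "1,0->1,1", "1,1->0,1", "0,1->0,0")) {
    expect_true(e %in% edge_set)
  }
  expect_true(has_cycle(g))
})

test_that("state graphs respect the unit-step, size and determinism
           invariants", {
  for (seed in 1:6) {
    fx <- random_brn(3, max_level = 2, edge_density = 0.6, seed = seed)
    slots <- parameter_slots(fx$network)
    idx <- (7 * seed) %% attr(slots, "total")
    K <- index_to_parametrization(slots, idx)
    g <- build_state_graph(fx$network, K)
    # |states| equals the cartesian product
    expect_identical(as.numeric(g$n_states), state_space_size(fx$network))
    # unit-step: L1 distance of every transition is exactly 1
    d <- abs(g$levels[g$from, , drop = FALSE] - g$levels[g$to, , drop = FALSE])
    expect_true(all(rowSums(d) == 1L))
    # out-degree bounded by the number of entities
    expect_true(all(tabulate(g$from, g$n_states) <= nrow(fx$network$entities)))
    # rebuilding yields the identical edge set
    g2 <- build_state_graph(fx$network, K)
    expect_identical(g$from, g2$from)
    expect_identical(g$to, g2$to)
    # deadlock characterization by independent re-evaluation of Def-style
    # membership: level == K(resources) for every entity
    for (s in seq_len(g$n_states)) {
      at_target <- all(vapply(seq_len(nrow(fx$network$entities)), function(i) {
        W <- resources(fx$network, g$levels[s, ], fx$network$entities$name[i])
        p <- fx$network$preds[[i]]
        mask <- sum(bitwShiftL(1L, seq_along(p$idx) - 1L)
                    [fx$network$entities$name[p$idx] %in% W])
        g$levels[s, i] == K$K[[i]][mask + 1L]
      }, TRUE))
      expect_identical(s %in% g$deadlocks, at_target)
    }
  }
})

test_that("the capacity cap refuses explicit construction of huge spaces", {
  big <- brn_network(data.frame(name = paste0("g", 1:23), max_level = 1L),
                     check_levels = FALSE)
  K <- as_parametrization(big, stats::setNames(
    rep(list(0L), 23), big$entities$name))
  expect_error(build_state_graph(big, K), "cap")
  # raising the cap admits the build (checked on a mid-sized 2^14 space)
  mid <- brn_network(data.frame(name = paste0("g", 1:14), max_level = 1L),
                     check_levels = FALSE)
  Kmid <- as_parametrization(mid, stats::setNames(
    rep(list(0L), 14), mid$entities$name))
  expect_error(build_state_graph(mid, Kmid, max_states = 100), "cap")
  g <- build_state_graph(mid, Kmid, max_states = 2^14)
  expect_identical(g$n_states, 16384L)
})
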