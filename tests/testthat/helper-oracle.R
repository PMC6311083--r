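# Independent reference machinery for the test suite.
#
# naive_sat() re-implements CTL semantics from the path-based definitions
# using igraph reachability and strongly connected components — no fixpoint
# iteration — so it can serve as an oracle for the package's labeling
# algorithm on small graphs.

naive_sat <- function(graph, node) {
  if (is.character(node)) node <- parse_ctl(node, graph$network)
  n <- graph$n_states
  et <- list(from = c(graph$from, as.numeric(graph$deadlocks)),
             to = c(graph$to, as.numeric(graph$deadlocks)))
  ig <- igraph::graph_from_edgelist(cbind(et$from, et$to), directed = TRUE)
  ig <- igraph::add_vertices(ig, max(0L, n - igraph::vcount(ig)))
  succ <- lapply(seq_len(n), function(s) et$to[et$from == s])

  # states that can reach `targets` (targets included), walking edges forward
  can_reach <- function(targets, sub_ok = rep(TRUE, n)) {
    # restrict to the induced subgraph on sub_ok (targets always kept)
    keep <- which(sub_ok | seq_len(n) %in% targets)
    h <- igraph::induced_subgraph(ig, keep)
    res <- logical(n)
    if (!length(targets)) return(res)
    tpos <- match(targets, keep)
    hit <- unique(unlist(lapply(tpos[!is.na(tpos)], function(t) {
      as.integer(igraph::subcomponent(h, t, mode = "in"))
    })))
    res[keep[hit]] <- TRUE
    res
  }

  # states with an infinite path staying inside `ok`: they must reach, within
  # the ok-induced subgraph, a vertex on a cycle (nontrivial SCC or self-loop)
  inf_path_within <- function(ok) {
    keep <- which(ok)
    res <- logical(n)
    if (!length(keep)) return(res)
    h <- igraph::induced_subgraph(ig, keep)
    comp <- igraph::components(h, mode = "strong")
    selfloop <- which(igraph::which_loop(h))
    loopy <- unique(c(
      which(comp$membership %in% which(tabulate(comp$membership) > 1L)),
      unlist(lapply(selfloop, function(e) igraph::ends(h, e, names = FALSE)[1L]))))
    if (!length(loopy)) return(res)
    hit <- unique(unlist(lapply(loopy, function(t) {
      as.integer(igraph::subcomponent(h, t, mode = "in"))
    })))
    res[keep[hit]] <- TRUE
    res
  }

  ev <- function(nd) naive_sat(graph, nd)
  switch(node$op,
    true = rep(TRUE, n),
    false = rep(FALSE, n),
    atom = graph$levels[, node$entity] == node$level,
    not = !ev(node$a),
    and = ev(node$a) & ev(node$b),
    or = ev(node$a) | ev(node$b),
    implies = !ev(node$a) | ev(node$b),
    EX = vapply(succ, function(s) any(ev(node$a)[s]), TRUE),
    AX = vapply(succ, function(s) all(ev(node$a)[s]), TRUE),
    EF = can_reach(which(ev(node$a))),
    AG = {  # every reachable state (self included) satisfies the body
      bad <- can_reach(which(!ev(node$a)))
      !bad
    },
    EG = inf_path_within(ev(node$a)),
    AF = !inf_path_within(!ev(node$a)),
    EU = {
      a <- ev(node$a); b <- ev(node$b)
      b | (a & can_reach(which(b), sub_ok = a))
    },
    AU = {
      a <- ev(node$a); b <- ev(node$b)
      stuck <- (!b) & (!a) # a state violating both ends every good prefix
      !((!b & can_reach(which(stuck), sub_ok = !b)) | inf_path_within(!b))
    },
    stop("oracle: unknown op ", node$op))
}

# random formula ASTs over a network, depth-limited, seeded by the caller
random_ctl <- function(network, depth = 3L) {
  ops <- c("atom", "atom", "not", "and", "or", "implies",
           "EX", "AX", "EF", "AF", "EG", "AG", "EU", "AU")
  gen <- function(d) {
    op <- if (d <= 0L) "atom" else sample(ops, 1L)
    if (op == "atom") {
      i <- sample.int(nrow(network$entities), 1L)
      return(list(op = "atom", entity = network$entities$name[i],
                  level = sample(0:network$entities$max_level[i], 1L)))
    }
    if (op %in% c("and", "or", "implies", "EU", "AU")) {
      return(list(op = op, a = gen(d - 1L), b = gen(d - 1L)))
    }
    list(op = op, a = gen(d - 1L))
  }
  structure(gen(depth), class = "ctl_formula")
}

# a random state graph: seeded random network plus a random parametrization
# (slot values drawn directly, so spaces too large to index still work)
random_state_graph <- function(seed) {
  shape <- (seed %% 4L) + 1L
  n <- c(2L, 3L, 3L, 6L)[shape]
  lv <- c(3L, 1L, 2L, 1L)[shape]   # state counts 16, 8, 27, 64
  fx <- random_brn(n, max_level = lv, edge_density = 0.6, seed = seed)
  set.seed(seed * 13L + 1L)
  K <- lapply(seq_len(n), function(i) {
    sample(0:lv, 2^length(fx$network$preds[[i]]$idx), replace = TRUE)
  })
  names(K) <- fx$network$entities$name
  build_state_graph(fx$network, K)
}

# single-loop brute-force parameter estimation, no indexing/partitioning:
# enumerate slot values with expand.grid and test each candidate directly
brute_force_accepted <- function(network, formulas, para = NULL) {
  slots <- parameter_slots(network, para)
  grid <- expand.grid(rev(lapply(slots, `[[`, "allowed")),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(slots)), drop = FALSE]
  hits <- list()
  for (r in seq_len(nrow(grid))) {
    K <- lapply(seq_len(nrow(network$entities)), function(i) {
      integer(2^length(network$preds[[i]]$idx))
    })
    names(K) <- network$entities$name
    for (j in seq_along(slots)) {
      K[[slots[[j]]$entity_idx]][slots[[j]]$mask + 1L] <- grid[r, j]
    }
    graph <- build_state_graph(network, K)
    if (all(vapply(formulas, function(f) all(sat_set(graph, f)$member), TRUE))) {
      hits[[length(hits) + 1L]] <- unlist(grid[r, ], use.names = FALSE)
    }
  }
  hits
}
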