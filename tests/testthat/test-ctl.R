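# CTL parsing and fixpoint model checking.

pseudo <- pseudomonas_model()
hbp <- hbp_like_model()

test_that("the parser builds the expected syntax trees", {
  f <- parse_ctl("x=0", pseudo$network)
  expect_identical(f$op, "atom")
  expect_identical(f$entity, "x")
  expect_identical(f$level, 0L)

  # the published HBP observation: implication of a conjunction into EF(AG(...))
  f <- parse_ctl(
    "(OGT=1,OGA=0) -> EF(AG(OGT=1,OGA=0,PI3K=1,FoXM1=1,P21=0,CMyc=1))",
    hbp$network)
  expect_identical(f$op, "implies")
  expect_identical(f$a$op, "and")
  expect_identical(f$b$op, "EF")
  expect_identical(f$b$a$op, "AG")
  count_atoms <- function(n) {
    if (n$op == "atom") return(1L)
    sum(vapply(n[names(n) %in% c("a", "b")], count_atoms, 1L))
  }
  expect_identical(count_atoms(f$b$a), 6L)
  expect_identical(count_atoms(f), 8L)

  # precedence ! > & > | > ->, implication right-associative
  g <- parse_ctl("!x=0 & y=1 | x=2 -> y=0 -> x=1", pseudo$network)
  expect_identical(g$op, "implies")
  expect_identical(g$a$op, "or")
  expect_identical(g$a$a$op, "and")
  expect_identical(g$a$a$a$op, "not")
  expect_identical(g$b$op, "implies")

  # until forms and the bare X (read as AX)
  u <- parse_ctl("E[x=0 U A[y=0 U x=2]]", pseudo$network)
  expect_identical(u$op, "EU")
  expect_identical(u$b$op, "AU")
  expect_identical(parse_ctl("X(x=1)", pseudo$network)$op, "AX")
})

test_that("parse errors carry positions and atom validation bites", {
  expect_error(parse_ctl("EF(x=9", pseudo$network), "position")
  expect_error(parse_ctl("EF(x=9)", pseudo$network), "range")
  expect_error(parse_ctl("EF(z=1)", pseudo$network), "unknown entity")
  expect_error(parse_ctl("x=0 y=1", pseudo$network), "after complete formula")
  expect_error(parse_ctl("E[x=0 & y=1]", pseudo$network), "U")
  expect_error(parse_ctl("", pseudo$network), "end of formula")
})

test_that("formulas survive a format/parse round trip", {
  for (src in c(pseudo$formulas, hbp$formulas,
                "E[x=0 U y=1]", "A[!x=2 U y=0]", "AX(EG(x=1 | y=0))")) {
    net <- if (grepl("OGT", src)) hbp$network else pseudo$network
    f <- parse_ctl(src, net)
    expect_equal(parse_ctl(format_ctl(f), net), f, ignore_attr = TRUE,
                 info = src)
  }
})

test_that("satisfaction sets on a two-state chain match path semantics", {
  # one Boolean entity driven upward: 0 -> 1, with 1 a deadlock (self-loop
  # after totalization)
  net <- brn_network(data.frame(name = "a", max_level = 1L))
  g <- build_state_graph(net, as_parametrization(net, list(a = 1L)))
  expect_identical(g$from, 1)
  expect_identical(g$to, 2)
  expect_identical(g$deadlocks, 2L)
  expect_identical(sat_set(g, "TRUE")$states, 1:2)
  expect_identical(sat_set(g, "FALSE")$states, integer())
  expect_identical(sat_set(g, "AF(a=1)")$states, 1:2)
  expect_identical(sat_set(g, "EG(a=1)")$states, 2L)
  expect_identical(sat_set(g, "EX(a=1)")$states, 1:2)
  expect_identical(sat_set(g, "AG(a=1)")$states, 2L)
  expect_identical(sat_set(g, "E[a=0 U a=1]")$states, 1:2)
})

test_that("the pathogenic stable state satisfies AG(x=2)", {
  K <- as_parametrization(pseudo$network, list(x = c(0, 2, 1, 2), y = c(0, 1)))
  g <- build_state_graph(pseudo$network, K)
  s21 <- state_index(pseudo$network, c(2, 1))
  expect_true(s21 %in% sat_set(g, "AG(x=2)")$states)
  expect_true(holds_everywhere(g, pseudo$formulas))
  expect_false(holds_everywhere(g, list("FALSE")))
  expect_true(holds_everywhere(g, list("TRUE")))
  expect_error(holds_everywhere(g, list()), "at least one")
  # violating-state diagnostics complement the satisfaction set
  v <- violating_states(g, "x=2")
  expect_identical(nrow(v), 4L)
  expect_true(all(v[, "x"] != 2L))
})

test_that("fixpoint labeling agrees with the naive path-semantics oracle on
           random graphs", {
  for (seed in 1:25) {
    g <- random_state_graph(seed)
    set.seed(1000 + seed)
    for (k in 1:4) {
      f <- random_ctl(g$network, depth = 3L)
      expect_identical(sat_set(g, f)$member, naive_sat(g, f),
                       info = paste0("seed ", seed, ": ", format_ctl(f)))
    }
  }
})

test_that("duality and fixpoint-soundness invariants hold on random graphs", {
  for (seed in 1:10) {
    g <- random_state_graph(seed)
    set.seed(2000 + seed)
    for (k in 1:3) {
      phi <- random_ctl(g$network, depth = 2L)
      psi <- random_ctl(g$network, depth = 2L)
      sphi <- format_ctl(phi)
      spsi <- format_ctl(psi)
      # AG = !EF!, AF = !EG!
      expect_identical(sat_set(g, paste0("AG(", sphi, ")"))$member,
                       !sat_set(g, paste0("EF(!(", sphi, "))"))$member)
      expect_identical(sat_set(g, paste0("AF(", sphi, ")"))$member,
                       !sat_set(g, paste0("EG(!(", sphi, "))"))$member)
      # monotonicity: EF(phi & psi) implies EF(phi)
      both <- sat_set(g, paste0("EF((", sphi, ") & (", spsi, "))"))$member
      expect_true(all(!both | sat_set(g, paste0("EF(", sphi, ")"))$member))
      # least-fixpoint soundness: one more iteration changes nothing
      eu <- sat_set(g, paste0("E[(", sphi, ") U (", spsi, ")]"))$member
      et <- list(from = c(g$from, as.numeric(g$deadlocks)),
                 to = c(g$to, as.numeric(g$deadlocks)))
      pre <- logical(g$n_states)
      pre[et$from[eu[et$to]]] <- TRUE
      again <- sat_set(g, spsi)$member | (sat_set(g, sphi)$member & pre)
      expect_identical(again, eu)
    }
  }
})

test_that("totalization gives every state an outgoing edge", {
  for (seed in 1:5) {
    g <- random_state_graph(seed)
    et_from <- c(g$from, as.numeric(g$deadlocks))
    expect_identical(sort(unique(et_from)), as.numeric(seq_len(g$n_states)))
  }
})
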