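# Explicit-state CTL model checking by fixpoint labeling.
#
# Semantics are over the TOTALIZED transition relation: a deadlock (stable
# state) receives a self-loop so that every state has an infinite run, the
# standard requirement of CTL path semantics. Biologically this is the right
# reading — a stable state stays where it is, so AG holds there for any
# property it satisfies.
#
# Only EX, EU and EG are primitive:
#   EX p          pre-image of Sat(p)
#   E[p U q]      least fixpoint   X = q | (p & pre(X))
#   EG p          greatest fixpoint X = p & pre(X)
# The universal forms reduce by duality: AX = !EX!, EF p = E[TRUE U p],
# AF p = !EG!p, AG p = !EF!p, A[p U q] = !(E[!q U (!p & !q)] | EG!q).

# states with at least one (totalized) successor inside `x`
.pre_image <- function(edges, x) {
  res <- logical(length(x))
  res[edges$from[x[edges$to]]] <- TRUE
  res
}

.ctl_eval <- function(node, graph, edges) {
  ev <- function(n) .ctl_eval(n, graph, edges)
  switch(node$op,
    true = rep(TRUE, graph$n_states),
    false = rep(FALSE, graph$n_states),
    atom = {
      i <- match(node$entity, graph$network$entities$name)
      if (is.na(i)) {
        stop("formula atom refers to entity \"", node$entity,
             "\" absent from the graph's network", call. = FALSE)
      }
      if (node$level > graph$network$entities$max_level[i]) {
        stop("formula atom level ", node$level, " outside the range of ",
             node$entity, call. = FALSE)
      }
      graph$levels[, i] == node$level
    },
    not = !ev(node$a),
    and = ev(node$a) & ev(node$b),
    or = ev(node$a) | ev(node$b),
    implies = !ev(node$a) | ev(node$b),
    EX = .pre_image(edges, ev(node$a)),
    AX = !.pre_image(edges, !ev(node$a)),
    EF = .lfp_until(edges, rep(TRUE, graph$n_states), ev(node$a)),
    AF = !.gfp_globally(edges, !ev(node$a)),
    EG = .gfp_globally(edges, ev(node$a)),
    AG = !.lfp_until(edges, rep(TRUE, graph$n_states), !ev(node$a)),
    EU = .lfp_until(edges, ev(node$a), ev(node$b)),
    AU = {
      p <- ev(node$a)
      q <- ev(node$b)
      !(.lfp_until(edges, !q, !p & !q) | .gfp_globally(edges, !q))
    },
    stop("unknown CTL operator: ", node$op, call. = FALSE))
}

.lfp_until <- function(edges, p, q) {
  x <- q
  repeat {
    nxt <- q | (p & .pre_image(edges, x))
    if (identical(nxt, x)) return(x)
    x <- nxt
  }
}

.gfp_globally <- function(edges, p) {
  x <- p
  repeat {
    nxt <- p & .pre_image(edges, x)
    if (identical(nxt, x)) return(x)
    x <- nxt
  }
}

#' Satisfaction set of a CTL formula over a state graph
#'
#' Labels every qualitative state with the truth of `formula` under standard
#' CTL semantics, computed bottom-up with fixpoint iteration on the totalized
#' transition relation (deadlocks get a self-loop first).
#'
#' @param graph a [build_state_graph()] object.
#' @param formula a [parse_ctl()] formula, or a string parsed against the
#'   graph's network.
#' @return An object of class `ctl_satset`: list with `formula`, `member`
#'   (logical vector over states, in state-row order) and `states` (the
#'   satisfying row indices).
#' @examples
#' fx <- pseudomonas_model()
#' g <- build_state_graph(fx$network,
#'   as_parametrization(fx$network, list(x = c(0, 2, 1, 2), y = c(0, 1))))
#' sat_set(g, "AG(x=2)")$states  # only the stable state (2,1)
#' @export
sat_set <- function(graph, formula) {
  stopifnot(inherits(graph, "brn_state_graph"))
  if (is.character(formula)) formula <- parse_ctl(formula, graph$network)
  member <- .ctl_eval(formula, graph, .totalized_edges(graph))
  structure(list(formula = formula, member = member, states = which(member)),
            class = "ctl_satset")
}

#' @export
print.ctl_satset <- function(x, ...) {
  cat("Sat(", format_ctl(x$formula), "): ", length(x$states), " of ",
      length(x$member), " states\n", sep = "")
  invisible(x)
}

#' Does a set of observations hold in every state?
#'
#' A candidate model is accepted when the conjunction of all CTL observations
#' holds in every qualitative state of its (totalized) state graph — the
#' natural acceptance rule for guard-style observations written as
#' implications, which are vacuously true outside their guard states.
#'
#' @param graph a [build_state_graph()] object.
#' @param formulas non-empty list of parsed formulas and/or strings.
#' @return `TRUE` or `FALSE`.
#' @export
holds_everywhere <- function(graph, formulas) {
  stopifnot(inherits(graph, "brn_state_graph"))
  if (inherits(formulas, "ctl_formula") || is.character(formulas)) {
    formulas <- as.list(formulas)
  }
  if (length(formulas) == 0L) {
    stop("at least one CTL formula is required", call. = FALSE)
  }
  for (f in formulas) {
    if (!all(sat_set(graph, f)$member)) return(FALSE)
  }
  TRUE
}

#' States violating a CTL observation
#'
#' Diagnostic counterpart of [holds_everywhere()]: lists the states in which
#' the formula fails, as a level matrix.
#'
#' @param graph a [build_state_graph()] object.
#' @param formula a parsed formula or string.
#' @return Integer matrix (one row per violating state) with entity columns.
#' @export
violating_states <- function(graph, formula) {
  member <- sat_set(graph, formula)$member
  graph$levels[!member, , drop = FALSE]
}
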