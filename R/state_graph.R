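# State indexing convention: states are rows of the cartesian product of the
# level ranges, in entity declaration order with the LAST entity varying
# fastest (lexicographic order of the tuples). Row r (1-based) has 0-based
# index r-1; flipping entity i by d moves the index by d * stride[i].

.state_sizes <- function(network) as.numeric(network$entities$max_level) + 1

.state_strides <- function(network) {
  sizes <- .state_sizes(network)
  rev(cumprod(rev(c(sizes[-1L], 1))))
}

# levels matrix for all states; N x n, lexicographic with last entity fastest
.all_states <- function(network) {
  sizes <- .state_sizes(network)
  n <- length(sizes)
  N <- prod(sizes)
  L <- matrix(0L, nrow = N, ncol = n, dimnames = list(NULL, network$entities$name))
  stride <- .state_strides(network)
  for (i in seq_len(n)) {
    L[, i] <- as.integer(rep(rep(0:(sizes[i] - 1L), each = stride[i]),
                             length.out = N))
  }
  L
}

#' Row index of a qualitative state
#'
#' States are ordered lexicographically in entity declaration order with the
#' last entity varying fastest; this is the row order of the state graph's
#' level matrix.
#'
#' @param network a [brn_network()] object.
#' @param state integer level vector in declaration order.
#' @return 1-based row index (double).
#' @export
state_index <- function(network, state) {
  state <- .check_state(network, state)
  sum(as.numeric(state) * .state_strides(network)) + 1
}

#' Build the full asynchronous state graph of a parametrized network
#'
#' Enumerates the complete cartesian state space and, for every state, adds
#' one transition per entity not at its logical-parameter target (unit step
#' toward the target). Self-transitions are never stored; states with no
#' outgoing transition are recorded as deadlocks (stable states). The
#' construction is deterministic: identical inputs give identical edge sets.
#'
#' @param network a [brn_network()] object.
#' @param parametrization a complete parametrization (see
#'   [as_parametrization()]).
#' @param max_states capacity cap on the number of states; explicit-state
#'   construction of very large spaces (millions of states) is refused unless
#'   the cap is raised.
#' @return An object of class `brn_state_graph` with elements `network`,
#'   `parametrization`, `n_states`, `levels` (state-by-entity level matrix),
#'   `from`/`to` (parallel transition vectors of row indices) and `deadlocks`
#'   (row indices of stable states).
#' @examples
#' fx <- pseudomonas_model()
#' K <- as_parametrization(fx$network, list(x = c(0, 2, 1, 2), y = c(0, 1)))
#' g <- build_state_graph(fx$network, K)
#' g$n_states                       # 6
#' g$levels[g$deadlocks, ]          # stable state (2, 1)
#' @export
build_state_graph <- function(network, parametrization,
                              max_states = getOption("brnest.max_states", 1e6)) {
  stopifnot(inherits(network, "brn"))
  K <- .check_parametrization(network, parametrization)
  N <- state_space_size(network)
  if (N > max_states) {
    stop("state space has ", format(N, big.mark = ","), " states, above the ",
         "cap of ", format(max_states, big.mark = ","),
         "; raise `max_states` to build it explicitly", call. = FALSE)
  }
  L <- .all_states(network)
  stride <- .state_strides(network)
  n <- nrow(network$entities)
  from <- to <- vector("list", n)
  outdeg <- numeric(nrow(L))
  for (i in seq_len(n)) {
    p <- network$preds[[i]]
    mask <- rep.int(0L, nrow(L))
    for (j in seq_along(p$idx)) {
      on <- if (p$activator[j]) L[, p$idx[j]] >= p$threshold[j]
            else                L[, p$idx[j]] <  p$threshold[j]
      mask <- mask + bitwShiftL(1L, j - 1L) * on
    }
    target <- K[[i]][mask + 1L]
    delta <- sign(target - L[, i])
    moving <- which(delta != 0L)
    from[[i]] <- as.numeric(moving)
    to[[i]] <- moving + delta[moving] * stride[i]
    outdeg[moving] <- outdeg[moving] + 1
  }
  from <- unlist(from, use.names = FALSE)
  to <- unlist(to, use.names = FALSE)
  o <- order(from, to)
  structure(
    list(network = network, parametrization = K, n_states = nrow(L),
         levels = L, from = from[o], to = to[o],
         deadlocks = which(outdeg == 0)),
    class = "brn_state_graph")
}

# Totalized transition relation: CTL semantics over infinite paths needs a
# total relation, so deadlocks get a self-loop. Never stored in the raw graph.
.totalized_edges <- function(graph) {
  list(from = c(graph$from, as.numeric(graph$deadlocks)),
       to = c(graph$to, as.numeric(graph$deadlocks)))
}

#' Does a state graph contain a cycle?
#'
#' Checks the raw transition relation (deadlock self-loops excluded) for a
#' directed cycle by iteratively peeling states without outgoing edges.
#' A cycle is the qualitative signature of sustained oscillation
#' (homeostasis).
#'
#' @param graph a [build_state_graph()] object.
#' @return `TRUE` or `FALSE`.
#' @export
has_cycle <- function(graph) {
  stopifnot(inherits(graph, "brn_state_graph"))
  from <- graph$from
  to <- graph$to
  repeat {
    if (length(from) == 0L) return(FALSE)
    # states that still have an outgoing edge
    alive <- logical(graph$n_states)
    alive[from] <- TRUE
    keep <- alive[to]   # keep edges whose head can still continue a path
    if (all(keep)) return(TRUE)
    from <- from[keep]
    to <- to[keep]
  }
}

#' @export
print.brn_state_graph <- function(x, ...) {
  cat("Asynchronous state graph: ", format(x$n_states, big.mark = ","),
      " states, ", format(length(x$from), big.mark = ","), " transitions, ",
      length(x$deadlocks), " deadlock(s)\n", sep = "")
  if (length(x$deadlocks) && length(x$deadlocks) <= 10L) {
    lab <- apply(x$levels[x$deadlocks, , drop = FALSE], 1L, paste, collapse = ",")
    cat("  stable: ", paste0("(", lab, ")", collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
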