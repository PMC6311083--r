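#' Construct a qualitative biological regulatory network
#'
#' A biological regulatory network (BRN) in the Thomas formalism is a signed,
#' thresholded directed graph. Each entity (gene, protein, ...) carries a
#' discrete expression range `0..max_level`; each interaction carries a
#' threshold `tau` (the source level at which the interaction becomes active)
#' and a sign (`"+"` activation, `"-"` inhibition).
#'
#' Entity declaration order is significant: qualitative states are tuples in
#' declaration order, and the parameter-slot ordering used everywhere
#' downstream (enumeration, result files) is derived from it.
#'
#' @param entities data frame with columns `name` (character, unique) and
#'   `max_level` (integer >= 1), one row per entity, in declaration order.
#' @param interactions data frame with columns `source`, `target` (declared
#'   entity names), `threshold` (integer, `1 <= threshold <= max_level` of the
#'   source) and `sign` (`"+"` or `"-"`). At most one interaction per ordered
#'   `(source, target)` pair. May have zero rows.
#' @param name optional model name used in result files.
#' @param check_levels warn when a declared `max_level` differs from the
#'   entity's out-degree (Thomas' convention ties the two; declared ranges
#'   stay authoritative either way). Disable for generated topologies.
#'
#' @return An object of class `brn`: a list with elements `name`, `entities`,
#'   `interactions`, and a precomputed per-entity predecessor table.
#'
#' @examples
#' net <- brn_network(
#'   entities = data.frame(name = c("x", "y"), max_level = c(2L, 1L)),
#'   interactions = data.frame(
#'     source = c("x", "x", "y"), target = c("x", "y", "x"),
#'     threshold = c(2L, 1L, 1L), sign = c("+", "+", "-")
#'   )
#' )
#' state_space_size(net)
#' @export
brn_network <- function(entities, interactions = NULL, name = "model",
                        check_levels = TRUE) {
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  if (!all(c("name", "max_level") %in% names(entities))) {
    stop("`entities` needs columns `name` and `max_level`", call. = FALSE)
  }
  entities$name <- as.character(entities$name)
  entities$max_level <- as.integer(entities$max_level)
  if (nrow(entities) < 1L) stop("at least one entity is required", call. = FALSE)
  if (anyDuplicated(entities$name)) {
    stop("duplicate entity name: ",
         paste(unique(entities$name[duplicated(entities$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(entities$max_level)) || any(entities$max_level < 1L)) {
    stop("every entity needs max_level >= 1 (levels {0..max_level})", call. = FALSE)
  }

  if (is.null(interactions) || NROW(interactions) == 0L) {
    interactions <- data.frame(source = character(), target = character(),
                               threshold = integer(), sign = character(),
                               stringsAsFactors = FALSE)
  } else {
    interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
    need <- c("source", "target", "threshold", "sign")
    if (!all(need %in% names(interactions))) {
      stop("`interactions` needs columns source, target, threshold, sign",
           call. = FALSE)
    }
    interactions <- interactions[need]
    interactions$source <- as.character(interactions$source)
    interactions$target <- as.character(interactions$target)
    interactions$threshold <- as.integer(interactions$threshold)
    interactions$sign <- as.character(interactions$sign)
  }

  bad <- setdiff(c(interactions$source, interactions$target), entities$name)
  if (length(bad)) {
    stop("interaction endpoint not declared as entity: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (!all(interactions$sign %in% c("+", "-"))) {
    stop("interaction sign must be \"+\" or \"-\"", call. = FALSE)
  }
  pair <- paste(interactions$source, interactions$target, sep = "\r")
  if (anyDuplicated(pair)) {
    dup <- interactions[duplicated(pair), , drop = FALSE]
    stop("multiple interactions for ordered pair (",
         dup$source[1L], ", ", dup$target[1L],
         "): the interaction set is a subset of V x V", call. = FALSE)
  }
  src_max <- entities$max_level[match(interactions$source, entities$name)]
  off <- which(is.na(interactions$threshold) | interactions$threshold < 1L |
                 interactions$threshold > src_max)
  if (length(off)) {
    stop("interaction ", interactions$source[off[1L]], " -> ",
         interactions$target[off[1L]], ": threshold must lie in 1..",
         src_max[off[1L]], " (max level of the source)", call. = FALSE)
  }

  net <- structure(
    list(name = as.character(name)[1L],
         entities = entities,
         interactions = interactions,
         preds = .predecessor_table(entities, interactions)),
    class = "brn")

  # Thomas' convention ties an entity's top level to its out-degree; declared
  # ranges are authoritative here, so a mismatch only warns.
  outdeg <- tabulate(match(interactions$source, entities$name),
                     nbins = nrow(entities))
  expected <- ifelse(outdeg == 0L, 1L, outdeg)
  mism <- if (check_levels) which(entities$max_level != expected) else integer()
  if (length(mism)) {
    warning("declared max_level differs from out-degree for: ",
            paste0(entities$name[mism], " (declared ",
                   entities$max_level[mism], ", out-degree ", outdeg[mism], ")",
                   collapse = ", "),
            call. = FALSE)
  }
  net
}

# Per-entity predecessor index table in declaration order: for entity i,
# preds[[i]] is a list(idx, threshold, activator) aligned vectors. Resource
# subsets are encoded as bitmasks over this ordering (bit j-1 <-> preds idx[j]).
.predecessor_table <- function(entities, interactions) {
  lapply(seq_len(nrow(entities)), function(i) {
    rows <- which(interactions$target == entities$name[i])
    idx <- match(interactions$source[rows], entities$name)
    o <- order(idx)
    list(idx = idx[o],
         threshold = interactions$threshold[rows][o],
         activator = interactions$sign[rows][o] == "+")
  })
}

.entity_index <- function(network, entity) {
  i <- match(entity, network$entities$name)
  if (is.na(i)) {
    stop("entity \"", entity, "\" is not declared in the network", call. = FALSE)
  }
  i
}

.check_state <- function(network, state) {
  state <- as.integer(state)
  n <- nrow(network$entities)
  if (length(state) != n) {
    stop("state must have one level per entity (", n, ")", call. = FALSE)
  }
  if (any(state < 0L) || any(state > network$entities$max_level)) {
    stop("state level outside declared range [0, max_level]", call. = FALSE)
  }
  state
}

#' Number of qualitative states of a network
#'
#' The state space is the cartesian product of the entity level ranges, so its
#' size is the product over entities of `max_level + 1`.
#'
#' @param network a [brn_network()] object.
#' @return A number (double, exact up to 2^53).
#' @examples
#' boolean9 <- brn_network(data.frame(name = paste0("g", 1:9), max_level = 1L))
#' state_space_size(boolean9)  # 512
#' @export
state_space_size <- function(network) {
  stopifnot(inherits(network, "brn"))
  prod(as.numeric(network$entities$max_level) + 1)
}

#' Resource set of an entity in a state
#'
#' The resources of entity `v` in state `s` are the regulators currently
#' "helping" it: activators at or above their threshold plus inhibitors below
#' their threshold (an absent inhibitor is a resource).
#'
#' @param network a [brn_network()] object.
#' @param state integer vector of levels in entity declaration order.
#' @param entity entity name.
#' @return Character vector of regulator names, in declaration order (the
#'   canonical resource-subset ordering).
#' @examples
#' net <- pseudomonas_model()$network
#' resources(net, c(2, 1), "x")  # "x": self-activation on, inhibitor y present
#' resources(net, c(0, 0), "x")  # "y": absent inhibitor counts as a resource
#' @export
resources <- function(network, state, entity) {
  stopifnot(inherits(network, "brn"))
  i <- .entity_index(network, entity)
  state <- .check_state(network, state)
  p <- network$preds[[i]]
  on <- ifelse(p$activator, state[p$idx] >= p$threshold, state[p$idx] < p$threshold)
  network$entities$name[p$idx[on]]
}

# Resource bitmask of entity i in a state: bit j-1 set iff the j-th
# (declaration-ordered) predecessor is a resource.
.resource_mask <- function(network, state, i) {
  p <- network$preds[[i]]
  if (length(p$idx) == 0L) return(0L)
  on <- ifelse(p$activator, state[p$idx] >= p$threshold, state[p$idx] < p$threshold)
  sum(bitwShiftL(1L, seq_along(p$idx) - 1L)[on])
}

#' One asynchronous evolution step of a level toward its target
#'
#' An entity at level `current` with logical-parameter target `k` moves one
#' unit toward `k` per transition: up if below, down if above, unchanged at
#' the target. Levels never jump.
#'
#' @param current,k non-negative integers (levels).
#' @return `current + sign(k - current)` as an integer.
#' @examples
#' evolve_level(0, 2)  # 1
#' evolve_level(1, 1)  # 1
#' evolve_level(2, 0)  # 1
#' @export
evolve_level <- function(current, k) {
  current <- as.integer(current)
  k <- as.integer(k)
  if (length(current) != 1L || length(k) != 1L ||
      is.na(current) || is.na(k) || current < 0L || k < 0L) {
    stop("levels must be single non-negative integers", call. = FALSE)
  }
  current + as.integer(sign(k - current))
}

#' Asynchronous successors of a qualitative state
#'
#' Each entity whose current level differs from its logical-parameter target
#' `K(entity, resources)` contributes exactly one successor in which only that
#' entity has moved one unit toward the target. A state where every entity
#' sits at its target has no successors (a deadlock / stable state).
#'
#' @param network a [brn_network()] object.
#' @param parametrization a parametrization as produced by
#'   [index_to_parametrization()] or [as_parametrization()].
#' @param state integer vector of levels in declaration order.
#' @return A list of integer state vectors (possibly empty).
#' @examples
#' fx <- pseudomonas_model()
#' K <- as_parametrization(fx$network, list(
#'   x = c(0, 2, 1, 2),  # K_x for resource subsets {}, {x}, {y}, {x,y}
#'   y = c(0, 1)         # K_y for {}, {x}
#' ))
#' successors(fx$network, K, c(2, 1))  # empty: the pathogenic stable state
#' successors(fx$network, K, c(1, 1))  # list(c(0, 1))
#' @export
successors <- function(network, parametrization, state) {
  stopifnot(inherits(network, "brn"))
  state <- .check_state(network, state)
  K <- .check_parametrization(network, parametrization)
  out <- list()
  for (i in seq_len(nrow(network$entities))) {
    mask <- .resource_mask(network, state, i)
    target <- K[[i]][mask + 1L]
    if (state[i] != target) {
      s2 <- state
      s2[i] <- state[i] + as.integer(sign(target - state[i]))
      out[[length(out) + 1L]] <- s2
    }
  }
  out
}

.check_parametrization <- function(network, parametrization) {
  if (inherits(parametrization, "brn_parametrization")) {
    parametrization <- unclass(parametrization)$K
  }
  n <- nrow(network$entities)
  if (!is.list(parametrization) || length(parametrization) != n) {
    stop("incomplete parametrization: expected one K vector per entity",
         call. = FALSE)
  }
  if (!is.null(names(parametrization))) {
    ord <- match(network$entities$name, names(parametrization))
    if (any(is.na(ord))) {
      stop("incomplete parametrization: missing entity ",
           network$entities$name[which(is.na(ord))[1L]], call. = FALSE)
    }
    parametrization <- parametrization[ord]
  }
  for (i in seq_len(n)) {
    want <- bitwShiftL(1L, length(network$preds[[i]]$idx))
    Ki <- as.integer(parametrization[[i]])
    if (length(Ki) != want || anyNA(Ki)) {
      stop("incomplete parametrization for entity ", network$entities$name[i],
           ": need ", want, " K values (one per resource subset)", call. = FALSE)
    }
    if (any(Ki < 0L) || any(Ki > network$entities$max_level[i])) {
      stop("K value out of range for entity ", network$entities$name[i],
           call. = FALSE)
    }
    parametrization[[i]] <- Ki
  }
  parametrization
}

#' @export
print.brn <- function(x, ...) {
  cat("Qualitative regulatory network \"", x$name, "\": ",
      nrow(x$entities), " entities, ", nrow(x$interactions),
      " interactions, ", format(state_space_size(x), big.mark = ","),
      " states\n", sep = "")
  lv <- paste0(x$entities$name, " in 0..", x$entities$max_level)
  cat("  ", paste(lv, collapse = ", "), "\n", sep = "")
  if (nrow(x$interactions)) {
    cat(paste0("  ", x$interactions$source, " -[", x$interactions$threshold,
               ",", x$interactions$sign, "]-> ", x$interactions$target,
               collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}
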