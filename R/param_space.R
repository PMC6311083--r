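# Parameter slots and mixed-radix enumeration.
#
# A parametrization assigns to every (entity, resource subset) pair a target
# level K. Slots are globally ordered by entity declaration order, then by
# resource-subset bitmask over declaration-ordered predecessors (empty subset
# first). With that fixed order, a parametrization is a tuple of slot values
# and the whole space enumerates in mixed radix, last slot varying fastest —
# so model indices are stable across runs and across worker counts.

.slot_key <- function(entity, members) {
  paste0("K_", entity, ":{", paste(members, collapse = ","), "}")
}

# normalize a user/PARA slot key to canonical form; members may come in any
# order, with or without the K_ prefix or blanks
.canon_slot_key <- function(network, key) {
  s <- gsub("[[:space:]]", "", key)
  s <- sub("^K_?", "", s)
  m <- regmatches(s, regexec("^([^:{}]+):?\\{([^{}]*)\\}$", s))[[1L]]
  if (length(m) != 3L) {
    stop("malformed parameter-slot key \"", key,
         "\" (expected K_entity:{r1,r2})", call. = FALSE)
  }
  entity <- m[2L]
  i <- .entity_index(network, entity)
  members <- if (nzchar(m[3L])) strsplit(m[3L], ",", fixed = TRUE)[[1L]] else character()
  pred_names <- network$entities$name[network$preds[[i]]$idx]
  bad <- setdiff(members, pred_names)
  if (length(bad)) {
    stop("slot ", key, ": ", paste(bad, collapse = ", "),
         " is not a regulator of ", entity, call. = FALSE)
  }
  if (anyDuplicated(members)) {
    stop("slot ", key, ": duplicated resource name", call. = FALSE)
  }
  .slot_key(entity, pred_names[sort(match(members, pred_names))])
}

#' Enumerate the logical-parameter slots of a network
#'
#' One slot exists per entity and per subset of its regulators; its default
#' allowed values are the full level range `0..max_level`, optionally
#' restricted by a PARA-style mapping. The product of the slot sizes is the
#' parametrization count; with no restrictions this is
#' `prod((max_level+1)^(2^n_regulators))` over entities.
#'
#' @param network a [brn_network()] object.
#' @param para optional named list of restrictions: names are slot keys like
#'   `"K_x:{y}"` (`"K_x:{}"` for the empty resource set), values integer
#'   vectors of allowed levels.
#' @return An object of class `brn_slots`: a list of slots (each with
#'   `entity`, `members`, `allowed`) with the network and the total
#'   parametrization count attached as attributes.
#' @examples
#' sl <- parameter_slots(pseudomonas_model()$network)
#' length(sl)                  # 6 slots (4 for x, 2 for y)
#' attr(sl, "total")           # 324 = 3^4 * 2^2
#' @export
parameter_slots <- function(network, para = NULL) {
  stopifnot(inherits(network, "brn"))
  slots <- list()
  for (i in seq_len(nrow(network$entities))) {
    pred_names <- network$entities$name[network$preds[[i]]$idx]
    p <- length(pred_names)
    for (mask in 0:(bitwShiftL(1L, p) - 1L)) {
      members <- pred_names[bitwAnd(bitwShiftL(1L, seq_len(p) - 1L), mask) > 0L]
      slots[[length(slots) + 1L]] <- list(
        entity = network$entities$name[i], entity_idx = i, mask = mask,
        members = members,
        allowed = 0:network$entities$max_level[i],
        key = .slot_key(network$entities$name[i], members))
    }
  }
  keys <- vapply(slots, `[[`, "", "key")
  if (!is.null(para) && length(para)) {
    if (is.null(names(para)) || any(!nzchar(names(para)))) {
      stop("`para` must be a named list of slot restrictions", call. = FALSE)
    }
    for (k in names(para)) {
      ck <- .canon_slot_key(network, k)
      j <- match(ck, keys)
      vals <- sort(unique(as.integer(para[[k]])))
      i <- slots[[j]]$entity_idx
      if (length(vals) == 0L) {
        stop("slot ", ck, ": empty allowed range", call. = FALSE)
      }
      if (any(vals < 0L) || any(vals > network$entities$max_level[i])) {
        stop("slot ", ck, ": allowed values outside 0..",
             network$entities$max_level[i], call. = FALSE)
      }
      slots[[j]]$allowed <- vals
    }
  }
  total <- prod(vapply(slots, function(s) length(s$allowed), numeric(1)))
  structure(slots, class = "brn_slots", network = network, total = total)
}

#' Total number of parametrizations
#' @param slots a [parameter_slots()] object.
#' @return A number (double; exact while below 2^53).
#' @export
parametrization_count <- function(slots) {
  stopifnot(inherits(slots, "brn_slots"))
  attr(slots, "total")
}

.check_indexable <- function(total) {
  if (total > 2^53) {
    stop("parametrization space too large to index exactly (",
         format(total), " > 2^53)", call. = FALSE)
  }
}

#' Construct a parametrization from per-entity K vectors or slot values
#'
#' @param network a [brn_network()] object.
#' @param values either a named list with one integer vector per entity
#'   (K values in resource-subset bitmask order: `{}`, first regulator, second
#'   regulator, both, ...) or a named list/vector keyed by slot keys like
#'   `"K_x:{y}"`.
#' @return An object of class `brn_parametrization`.
#' @export
as_parametrization <- function(network, values) {
  stopifnot(inherits(network, "brn"))
  if (!is.null(names(values)) && any(grepl("\\{", names(values)))) {
    slots <- parameter_slots(network)
    keys <- vapply(slots, `[[`, "", "key")
    K <- lapply(seq_len(nrow(network$entities)), function(i) {
      rep(NA_integer_, bitwShiftL(1L, length(network$preds[[i]]$idx)))
    })
    for (k in names(values)) {
      ck <- .canon_slot_key(network, k)
      j <- match(ck, keys)
      K[[slots[[j]]$entity_idx]][slots[[j]]$mask + 1L] <-
        as.integer(values[[k]])[1L]
    }
    names(K) <- network$entities$name
    values <- K
  }
  K <- .check_parametrization(network, values)
  names(K) <- network$entities$name
  structure(list(K = K, network = network), class = "brn_parametrization")
}

#' Decode a global model index into a parametrization
#'
#' Mixed-radix decomposition over the slot order, last slot varying fastest;
#' the exact inverse of [parametrization_to_index()].
#'
#' @param slots a [parameter_slots()] object.
#' @param index 0-based model index, `0 <= index < parametrization_count(slots)`.
#' @return A `brn_parametrization`.
#' @export
index_to_parametrization <- function(slots, index) {
  stopifnot(inherits(slots, "brn_slots"))
  network <- attr(slots, "network")
  total <- attr(slots, "total")
  .check_indexable(total)
  index <- as.numeric(index)
  if (length(index) != 1L || is.na(index) || index < 0 || index >= total ||
      index != floor(index)) {
    stop("index must be an integer in [0, ", format(total), ")", call. = FALSE)
  }
  K <- lapply(seq_len(nrow(network$entities)), function(i) {
    integer(bitwShiftL(1L, length(network$preds[[i]]$idx)))
  })
  for (j in rev(seq_along(slots))) {
    r <- length(slots[[j]]$allowed)
    d <- index %% r
    index <- (index - d) / r
    K[[slots[[j]]$entity_idx]][slots[[j]]$mask + 1L] <- slots[[j]]$allowed[d + 1]
  }
  names(K) <- network$entities$name
  structure(list(K = K, network = network), class = "brn_parametrization")
}

#' Encode a parametrization as its global model index
#' @param slots a [parameter_slots()] object.
#' @param parametrization a `brn_parametrization` (or per-entity K list).
#' @return 0-based index (double).
#' @export
parametrization_to_index <- function(slots, parametrization) {
  stopifnot(inherits(slots, "brn_slots"))
  network <- attr(slots, "network")
  .check_indexable(attr(slots, "total"))
  K <- .check_parametrization(network, parametrization)
  index <- 0
  for (j in seq_along(slots)) {
    s <- slots[[j]]
    v <- K[[s$entity_idx]][s$mask + 1L]
    pos <- match(v, s$allowed)
    if (is.na(pos)) {
      stop("value ", v, " for slot ", s$key, " is outside its allowed set {",
           paste(s$allowed, collapse = ","), "}", call. = FALSE)
    }
    index <- index * length(s$allowed) + (pos - 1)
  }
  index
}

#' Partition an index range into near-equal contiguous blocks
#'
#' Block domain decomposition for parallel workers: `parts` contiguous,
#' disjoint ranges covering `[0, total)`, sizes differing by at most one,
#' larger blocks first (deterministic remainder rule).
#'
#' @param total size of the index space (>= 0).
#' @param parts number of blocks (>= 1).
#' @return Data frame with columns `start` (inclusive) and `end` (exclusive),
#'   0-based.
#' @examples
#' block_partition(10, 3)  # sizes 4, 3, 3
#' @export
block_partition <- function(total, parts) {
  total <- as.numeric(total)
  parts <- as.integer(parts)
  if (is.na(parts) || parts < 1L) stop("`parts` must be >= 1", call. = FALSE)
  if (is.na(total) || total < 0 || total != floor(total)) {
    stop("`total` must be a non-negative integer", call. = FALSE)
  }
  base <- floor(total / parts)
  rem <- total - base * parts
  sizes <- base + as.numeric(seq_len(parts) <= rem)
  end <- cumsum(sizes)
  data.frame(start = end - sizes, end = end)
}

#' @export
print.brn_parametrization <- function(x, ...) {
  cat("Parametrization:\n")
  cat(paste0("  ", format_parametrization(x)), sep = "\n")
  invisible(x)
}

#' Format a parametrization as `K_entity:{resources} = v` lines
#'
#' One line per slot, in canonical slot order (the format used in result
#' files and PARA sections).
#'
#' @param parametrization a `brn_parametrization`.
#' @param network the network the parametrization belongs to; defaults to the
#'   one stored in the object.
#' @return Character vector of lines.
#' @export
format_parametrization <- function(parametrization, network = NULL) {
  if (is.null(network)) network <- parametrization$network
  stopifnot(inherits(network, "brn"))
  K <- .check_parametrization(network, parametrization)
  out <- character()
  for (i in seq_len(nrow(network$entities))) {
    pred_names <- network$entities$name[network$preds[[i]]$idx]
    np <- length(pred_names)
    for (mask in 0:(bitwShiftL(1L, np) - 1L)) {
      members <- pred_names[bitwAnd(bitwShiftL(1L, seq_len(np) - 1L), mask) > 0L]
      out <- c(out, paste0(.slot_key(network$entities$name[i], members),
                           " = ", K[[i]][mask + 1L]))
    }
  }
  out
}

#' @export
print.brn_slots <- function(x, ...) {
  cat("Parameter space: ", length(x), " slots, ",
      format(attr(x, "total"), big.mark = ","), " parametrizations\n", sep = "")
  for (s in x) {
    cat("  ", s$key, " in {", paste(s$allowed, collapse = ","), "}\n", sep = "")
  }
  invisible(x)
}
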