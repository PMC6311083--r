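#' Evaluate one candidate parametrization against the observations
#'
#' Builds the asynchronous state graph for the parametrization and tests
#' whether every CTL observation holds in every state (see
#' [holds_everywhere()]). Pure: no side effects, deterministic.
#'
#' @param network a [brn_network()] object.
#' @param parametrization a complete parametrization.
#' @param formulas non-empty list of parsed formulas and/or strings.
#' @param max_states capacity cap forwarded to [build_state_graph()].
#' @return `TRUE` (accepted) or `FALSE` (rejected).
#' @export
evaluate_parametrization <- function(network, parametrization, formulas,
                                     max_states = getOption("brnest.max_states", 1e6)) {
  graph <- build_state_graph(network, parametrization, max_states = max_states)
  holds_everywhere(graph, formulas)
}

#' Estimate the logical parameters of a regulatory network
#'
#' The central fitting routine: enumerates every parametrization of the
#' network (optionally restricted by PARA-style ranges), builds each
#' candidate's asynchronous state graph, model-checks the CTL observations,
#' and returns the accepted parametrizations. The index space is split into
#' contiguous blocks ([block_partition()]) evaluated by independent workers
#' (forked processes via the parallel package when `workers > 1`); because
#' candidates are evaluated independently and the reduction step merges
#' accepted lists by global index, the result is identical for every worker
#' count.
#'
#' @param network a [brn_network()] object.
#' @param formulas CTL observations: character vector and/or list of
#'   [parse_ctl()] formulas; a model is accepted iff all hold in all states.
#' @param para optional PARA-style slot restrictions (see
#'   [parameter_slots()]).
#' @param workers number of blocks / parallel workers (>= 1).
#' @param max_states capacity cap per state graph.
#' @param diagnostics if `TRUE`, count for each formula how many rejected
#'   models failed it first (evaluation short-circuits on the first failing
#'   formula).
#' @return An object of class `brn_estimate` with components
#'   `accepted_indices` (strictly increasing global model indices, 0-based),
#'   `accepted` (list of `brn_parametrization`), `total_evaluated`,
#'   `diagnostics`, `network`, `formulas` and `slots`. Methods: `print`,
#'   `summary`, [coef()] (slot-by-model K matrix) and `plot` (state graph of
#'   an accepted model).
#' @examples
#' fx <- pseudomonas_model()
#' fit <- brn_estimate(fx$network, fx$formulas)
#' fit
#' head(coef(fit))
#' @export
brn_estimate <- function(network, formulas, para = NULL, workers = 1L,
                         max_states = getOption("brnest.max_states", 1e6),
                         diagnostics = FALSE) {
  stopifnot(inherits(network, "brn"))
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L) stop("`workers` must be >= 1", call. = FALSE)
  formulas <- .as_formula_list(network, formulas)
  slots <- parameter_slots(network, para)
  total <- attr(slots, "total")
  .check_indexable(total)
  blocks <- block_partition(total, workers)

  run_block <- function(b) {
    .estimate_block(network, slots, formulas, blocks$start[b], blocks$end[b],
                    max_states, diagnostics)
  }
  partials <- if (workers == 1L || .Platform$OS.type != "unix") {
    lapply(seq_len(nrow(blocks)), run_block)
  } else {
    parallel::mclapply(seq_len(nrow(blocks)), run_block,
                       mc.cores = workers, mc.preschedule = FALSE)
  }
  for (b in seq_along(partials)) {
    if (inherits(partials[[b]], "try-error") || !inherits(partials[[b]], "brn_estimate")) {
      stop("worker for index range [", format(blocks$start[b]), ", ",
           format(blocks$end[b]), ") failed: ",
           paste(as.character(partials[[b]]), collapse = " "), call. = FALSE)
    }
  }
  fit <- merge_results(partials)
  fit$network <- network
  fit$formulas <- formulas
  fit$slots <- slots
  fit$workers <- workers
  fit
}

.as_formula_list <- function(network, formulas) {
  if (inherits(formulas, "ctl_formula")) formulas <- list(formulas)
  if (is.character(formulas)) formulas <- as.list(formulas)
  if (!is.list(formulas) || length(formulas) == 0L) {
    stop("at least one CTL formula is required", call. = FALSE)
  }
  lapply(formulas, function(f) {
    if (is.character(f)) parse_ctl(f, network) else f
  })
}

# evaluate indices [start, end) sequentially; the worker body of the
# coarse-grained decomposition: stateless, no communication until reduction
.estimate_block <- function(network, slots, formulas, start, end,
                            max_states, diagnostics) {
  accepted_indices <- numeric()
  accepted <- list()
  fail_counts <- if (diagnostics) {
    stats::setNames(numeric(length(formulas)),
                    vapply(formulas, format_ctl, ""))
  }
  idx <- start
  while (idx < end) {
    param <- index_to_parametrization(slots, idx)
    graph <- build_state_graph(network, param, max_states = max_states)
    ok <- TRUE
    for (fi in seq_along(formulas)) {
      if (!all(sat_set(graph, formulas[[fi]])$member)) {
        ok <- FALSE
        if (diagnostics) fail_counts[fi] <- fail_counts[fi] + 1
        break
      }
    }
    if (ok) {
      accepted_indices <- c(accepted_indices, idx)
      accepted[[length(accepted) + 1L]] <- param
    }
    idx <- idx + 1
  }
  structure(
    list(accepted_indices = accepted_indices, accepted = accepted,
         total_evaluated = end - start, diagnostics = fail_counts,
         ranges = data.frame(start = start, end = end)),
    class = "brn_estimate")
}

#' Merge partial estimation results from disjoint index ranges
#'
#' The reduction step of the master/worker scheme: concatenates accepted
#' lists sorted by global model index and sums evaluation counts. Linear in
#' the number of accepted models.
#'
#' @param partials list of `brn_estimate` objects covering pairwise disjoint
#'   index ranges.
#' @return A single `brn_estimate`.
#' @export
merge_results <- function(partials) {
  if (!length(partials) || !all(vapply(partials, inherits, TRUE, "brn_estimate"))) {
    stop("`partials` must be a non-empty list of brn_estimate objects",
         call. = FALSE)
  }
  ranges <- do.call(rbind, lapply(partials, `[[`, "ranges"))
  o <- order(ranges$start, ranges$end)
  ranges <- ranges[o, , drop = FALSE]
  nonempty <- ranges[ranges$end > ranges$start, , drop = FALSE]
  if (nrow(nonempty) > 1L &&
      any(nonempty$start[-1L] < nonempty$end[-nrow(nonempty)])) {
    stop("partial results cover overlapping index ranges", call. = FALSE)
  }
  idx <- unlist(lapply(partials, `[[`, "accepted_indices"), use.names = FALSE)
  params <- do.call(c, lapply(partials, `[[`, "accepted"))
  io <- order(idx)
  diags <- lapply(partials, `[[`, "diagnostics")
  diag <- if (all(vapply(diags, is.null, TRUE))) NULL else {
    Reduce(`+`, diags[!vapply(diags, is.null, TRUE)])
  }
  structure(
    list(accepted_indices = idx[io],
         accepted = if (length(io)) params[io] else list(),
         total_evaluated = sum(vapply(partials, `[[`, numeric(1), "total_evaluated")),
         diagnostics = diag,
         ranges = ranges),
    class = "brn_estimate")
}

#' @export
print.brn_estimate <- function(x, ...) {
  cat("Logical-parameter estimation\n")
  if (!is.null(x$network)) {
    cat("  network: ", x$network$name, " (", nrow(x$network$entities),
        " entities)\n", sep = "")
  }
  if (!is.null(x$formulas)) {
    cat("  observations:\n")
    cat(paste0("    ", vapply(x$formulas, format_ctl, "")), sep = "\n")
  }
  cat("  parametrizations evaluated: ",
      format(x$total_evaluated, big.mark = ","), "\n", sep = "")
  cat("  accepted: ", length(x$accepted_indices), "\n", sep = "")
  if (length(x$accepted_indices)) {
    shown <- utils::head(x$accepted_indices, 20L)
    cat("  model indices: ", paste(format(shown, trim = TRUE), collapse = " "),
        if (length(x$accepted_indices) > 20L) " ...", "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.brn_estimate <- function(object, ...) {
  print(object)
  K <- coef(object)
  if (!is.null(K) && nrow(K)) {
    cat("  accepted K values per slot:\n")
    for (j in seq_len(ncol(K))) {
      tab <- table(K[, j])
      cat("    ", colnames(K)[j], ": ",
          paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "),
          "\n", sep = "")
    }
  }
  if (!is.null(object$diagnostics)) {
    cat("  rejected first by formula:\n")
    for (nm in names(object$diagnostics)) {
      cat("    ", nm, ": ", object$diagnostics[[nm]], "\n", sep = "")
    }
  }
  invisible(object)
}

#' Accepted parametrizations as a K-value matrix
#'
#' @param object a [brn_estimate()] fit.
#' @param ... unused.
#' @return Numeric matrix, one row per accepted model (named by global
#'   index), one column per parameter slot in canonical order; `NULL` when
#'   the slot table is unavailable.
#' @export
coef.brn_estimate <- function(object, ...) {
  if (is.null(object$slots)) return(NULL)
  keys <- vapply(object$slots, `[[`, "", "key")
  K <- matrix(NA_integer_, nrow = length(object$accepted), ncol = length(keys),
              dimnames = list(format(object$accepted_indices, trim = TRUE), keys))
  for (r in seq_along(object$accepted)) {
    Kr <- object$accepted[[r]]$K
    for (j in seq_along(object$slots)) {
      s <- object$slots[[j]]
      K[r, j] <- Kr[[s$entity_idx]][s$mask + 1L]
    }
  }
  K
}

#' Plot the state graph of an accepted model
#'
#' Draws the asynchronous state graph of one accepted parametrization
#' (requires the igraph package); stable states are highlighted.
#'
#' @param x a [brn_estimate()] fit with at least one accepted model.
#' @param which which accepted model to draw (position in the accepted list).
#' @param ... forwarded to `plot.igraph`.
#' @export
plot.brn_estimate <- function(x, which = 1L, ...) {
  if (!length(x$accepted)) stop("no accepted model to plot", call. = FALSE)
  if (is.null(x$network)) stop("fit carries no network", call. = FALSE)
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("plotting the state graph requires the igraph package", call. = FALSE)
  }
  graph <- build_state_graph(x$network, x$accepted[[which]])
  lab <- apply(graph$levels, 1L, paste, collapse = ",")
  g <- igraph::graph_from_data_frame(
    data.frame(from = lab[graph$from], to = lab[graph$to]),
    vertices = data.frame(name = lab), directed = TRUE)
  cols <- ifelse(seq_len(graph$n_states) %in% graph$deadlocks,
                 "tomato", "skyblue")
  igraph::plot.igraph(g, vertex.color = cols, vertex.label = lab, ...)
  invisible(x)
}
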