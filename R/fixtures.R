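# Built-in example models. Each fixture bundles a validated network, CTL
# observation strings that parse against it, and a provenance note.

.fixture <- function(name, network, formulas, notes) {
  for (f in formulas) parse_ctl(f, network)   # fail fast if inconsistent
  structure(list(name = name, network = network, formulas = formulas,
                 notes = notes),
            class = "brn_fixture")
}

#' @export
print.brn_fixture <- function(x, ...) {
  cat("Fixture \"", x$name, "\"\n", sep = "")
  print(x$network)
  if (length(x$formulas)) {
    cat("observations:\n")
    cat(paste0("  ", x$formulas), sep = "\n")
  }
  cat("notes: ", x$notes, "\n", sep = "")
  invisible(x)
}

#' The two-gene Pseudomonas aeruginosa mucus-production network
#'
#' The textbook example of the Thomas formalism: `x` is the sigma factor AlgU
#' (three levels, with a self-activation at threshold 2 and an activation of
#' its inhibitor at threshold 1) and `y` its anti-sigma-factor inhibitor
#' (Boolean, inhibiting `x` at threshold 1). Two observations accompany it:
#' from the resting state the system must not over-express `x` (normal
#' mucoid homeostasis), and the over-expressed state `(2,1)` must be stable
#' (the pathogenic, irreversibly mucoid phenotype). Thresholds and formula
#' texts are reconstructions of the published figure, recorded as such in
#' the fixture's notes.
#'
#' @return A `brn_fixture`: list with `name`, `network`, `formulas`, `notes`.
#' @examples
#' fx <- pseudomonas_model()
#' state_space_size(fx$network)                      # 6
#' parametrization_count(parameter_slots(fx$network))  # 324
#' @export
pseudomonas_model <- function() {
  net <- brn_network(
    entities = data.frame(name = c("x", "y"), max_level = c(2L, 1L)),
    interactions = data.frame(
      source = c("x", "x", "y"),
      target = c("x", "y", "x"),
      threshold = c(2L, 1L, 1L),
      sign = c("+", "+", "-")),
    name = "pseudomonas")
  .fixture(
    "pseudomonas", net,
    c("(x=0 & y=0) -> AG(!(x=2))",
      "(x=2 & y=1) -> AG(x=2)"),
    paste("x = AlgU, y = anti-AlgU. Interaction thresholds and the two CTL",
          "observations are reconstructions of the published artwork, not",
          "printed ground truth."))
}

#' A nine-entity Boolean stand-in for the hexosamine pathway network
#'
#' A Boolean network over the entities
#' (NFkB, P21, FoXM1, PI3K, P53, MDM2, OGT, OGA, CMyc) — the declaration
#' order fixes the state-tuple coordinates — containing the motifs the
#' hexosamine biosynthetic pathway (HBP) case is built around: the P53-MDM2
#' negative feedback loop, CMyc activating OGT, OGA inhibiting OGT, and the
#' OGT-CMyc positive loop. The remaining entities are wired through a
#' plausible PI3K/FoXM1/P21 cascade. The topology is a documented stand-in
#' for structural tests (512 states, Boolean K values); it does not claim to
#' reproduce the published interaction map or its accepted-model counts.
#'
#' @return A `brn_fixture`.
#' @examples
#' state_space_size(hbp_like_model()$network)  # 512
#' @export
hbp_like_model <- function() {
  entities <- data.frame(
    name = c("NFkB", "P21", "FoXM1", "PI3K", "P53", "MDM2", "OGT", "OGA", "CMyc"),
    max_level = 1L)
  interactions <- data.frame(
    source    = c("P53",  "MDM2", "CMyc", "OGA", "OGT",  "NFkB", "PI3K",  "FoXM1"),
    target    = c("MDM2", "P53",  "OGT",  "OGT", "CMyc", "PI3K", "FoXM1", "P21"),
    threshold = 1L,
    sign      = c("+",    "-",    "+",    "-",   "+",    "+",    "+",     "-"))
  net <- brn_network(entities, interactions, name = "hbp_like")
  .fixture(
    "hbp_like", net,
    c("(OGT=1,OGA=0) -> EF(AG(OGT=1,OGA=0,PI3K=1,FoXM1=1,P21=0,CMyc=1))"),
    paste("Structural stand-in for the 9-entity HBP/PI3K-mTOR-Myc/P53-MDM2",
          "network: attested motifs only, invented wiring elsewhere. Not the",
          "published supplementary model."))
}

#' Generate a seeded random regulatory network
#'
#' Draws a random signed thresholded topology: every ordered entity pair
#' (self-loops included) receives an interaction with probability
#' `edge_density`; signs are uniform on `{+,-}` and thresholds uniform on
#' `1..max_level`. Deterministic for a fixed seed (local RNG state; the
#' caller's random stream is left untouched).
#'
#' @param n_entities number of entities (>= 1), named `g1..gn`.
#' @param max_level maximum expression level shared by all entities (>= 1).
#' @param edge_density probability of each ordered interaction, in `[0, 1]`.
#' @param seed integer seed.
#' @return A `brn_fixture` with no formulas.
#' @examples
#' fx <- random_brn(3, max_level = 1, edge_density = 0.5, seed = 7)
#' identical(fx$network, random_brn(3, 1, 0.5, seed = 7)$network)  # TRUE
#' @export
random_brn <- function(n_entities, max_level = 1L, edge_density = 0.3,
                       seed = 1L) {
  n_entities <- as.integer(n_entities)
  max_level <- as.integer(max_level)
  if (is.na(n_entities) || n_entities < 1L) {
    stop("`n_entities` must be >= 1", call. = FALSE)
  }
  if (is.na(max_level) || max_level < 1L) {
    stop("`max_level` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(edge_density) || is.na(edge_density) ||
      edge_density < 0 || edge_density > 1) {
    stop("`edge_density` must lie in [0, 1]", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  names <- paste0("g", seq_len(n_entities))
  pairs <- expand.grid(src = seq_len(n_entities), tgt = seq_len(n_entities))
  keep <- stats::runif(nrow(pairs)) < edge_density
  pairs <- pairs[keep, , drop = FALSE]
  interactions <- if (nrow(pairs)) {
    data.frame(
      source = names[pairs$src],
      target = names[pairs$tgt],
      threshold = sample.int(max_level, nrow(pairs), replace = TRUE),
      sign = sample(c("+", "-"), nrow(pairs), replace = TRUE))
  }
  net <- brn_network(
    data.frame(name = names, max_level = max_level),
    interactions,
    name = sprintf("random_n%d_l%d_seed%d", n_entities, max_level,
                   as.integer(seed)),
    check_levels = FALSE)
  .fixture(net$name, net, character(),
           sprintf("seeded random topology (density %.2f, seed %d)",
                   edge_density, as.integer(seed)))
}
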