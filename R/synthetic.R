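# Synthetic networks and experiment sets.
#
# These generators produce inputs with the dynamical structure the analysis
# modules assume - positive-feedback bistability, cascades, random signed
# networks - plus experiment records whose expected outcomes are computed by
# the exhaustive-enumeration oracle, so the whole pipeline is testable with no
# external data.

#' Built-in network motifs
#'
#' Available motifs:
#' \describe{
#'   \item{`tnf_autocrine`}{An autocrine positive feedback loop: secreted
#'     ligand `TNF` -> receptor `TNFR` -> transcription factor `TF` -> `TNF`,
#'     plus a residency proxy node `Residency` inhibited by the ligand. Two
#'     nonlinearities shape the loop: the receptor saturates
#'     (`min(max, 2*var(TNF))` - half-maximal ligand already signals fully)
#'     and the transcription factor reinforces its own activity
#'     (`max(var(TNFR), var(TF))`, as immediate-early factors such as cJUN
#'     induce their own promoters). Together these give exactly two attractors
#'     - all-off and all-on - at every range setting. With plain averaging
#'     the loop would also rest at intermediate levels, and without the
#'     self-reinforcement the synchronous update admits a rotating-wave loop
#'     in which activation chases around the ring.}
#'   \item{`mutual_activation`}{`A -> B`, `B -> A`, default functions: two
#'     stable fixed points plus one out-of-phase loop.}
#'   \item{`mutual_inhibition`}{`A -| B`, `B -| A`: a toggle switch.}
#'   \item{`negative_loop`}{`A -> B`, `B -| A`: sustained oscillation.}
#'   \item{`linear_cascade`}{`In -> N1 -> ... -> Nk`, default functions; `In`
#'     is unregulated (holds its level) until clamped.}
#' }
#'
#' @param name motif name.
#' @param range_max maximum level of every node (default 2; 1 gives the
#'   Boolean special case).
#' @param cascade_length number of downstream nodes for `linear_cascade`.
#' @return a validated `qn_network`.
#' @examples
#' qn_attractors(qn_motif("tnf_autocrine"))
#' @export
qn_motif <- function(name = c("tnf_autocrine", "mutual_activation",
                              "mutual_inhibition", "negative_loop",
                              "linear_cascade"),
                     range_max = 2, cascade_length = 3) {
  name <- match.arg(name)
  r <- as.integer(range_max)
  stopifnot(r >= 1)
  switch(name,
    tnf_autocrine = qn_network(
      nodes = data.frame(
        name = c("TNF", "TNFR", "TF", "Residency"),
        min = 0L, max = r,
        kind = c("secreted", "receptor", "protein", "process")),
      edges = data.frame(
        source = c("TNF", "TNFR", "TF", "TF", "TNF"),
        target = c("TNFR", "TF", "TF", "TNF", "Residency"),
        sign = c("activating", "activating", "activating", "activating",
                 "inhibiting")),
      functions = c(TNFR = sprintf("min(%d, 2 * var(TNF))", r),
                    TF = "max(var(TNFR), var(TF))"),
      name = "tnf_autocrine motif"),
    mutual_activation = qn_network(
      nodes = data.frame(name = c("A", "B"), min = 0L, max = pmin(r, 1L)),
      edges = data.frame(source = c("A", "B"), target = c("B", "A"),
                         sign = "activating"),
      name = "mutual_activation motif"),
    mutual_inhibition = qn_network(
      nodes = data.frame(name = c("A", "B"), min = 0L, max = pmin(r, 1L)),
      edges = data.frame(source = c("A", "B"), target = c("B", "A"),
                         sign = "inhibiting"),
      name = "mutual_inhibition motif"),
    negative_loop = qn_network(
      nodes = data.frame(name = c("A", "B"), min = 0L, max = pmin(r, 1L)),
      edges = data.frame(source = c("A", "B"), target = c("B", "A"),
                         sign = c("activating", "inhibiting")),
      name = "negative_loop motif"),
    linear_cascade = {
      k <- as.integer(cascade_length)
      stopifnot(k >= 1)
      nms <- c("In", paste0("N", seq_len(k)))
      qn_network(
        nodes = data.frame(name = nms, min = 0L, max = r),
        edges = data.frame(source = nms[-length(nms)], target = nms[-1],
                           sign = "activating"),
        name = sprintf("linear_cascade motif (length %d)", k))
    })
}

#' Generate a random qualitative network
#'
#' Signed edges are drawn independently with probability `edge_density` for
#' every ordered pair of distinct nodes (activating or inhibiting with equal
#' probability); every node gets the default target function and a range
#' `[0, m]` with `m` drawn uniformly from `1:max_range`. The draw is
#' reproducible for a fixed seed; the realised edge count and the seed are
#' recorded in the `provenance` attribute.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param edge_density probability of each directed edge, in (0, 1].
#' @param max_range maximum admissible upper level (1 gives Boolean networks).
#' @param seed integer seed.
#' @return a validated `qn_network`.
#' @export
qn_random_network <- function(n_nodes, edge_density = 0.3, max_range = 2,
                              seed) {
  stopifnot(n_nodes >= 1, edge_density > 0, edge_density <= 1, max_range >= 1)
  set.seed(seed)
  nms <- paste0("n", seq_len(n_nodes))
  maxes <- sample.int(max_range, n_nodes, replace = TRUE)
  pairs <- expand.grid(source = nms, target = nms, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  keep <- stats::runif(nrow(pairs)) < edge_density
  edges <- pairs[keep, , drop = FALSE]
  edges$sign <- sample(c("activating", "inhibiting"), nrow(edges), replace = TRUE)
  net <- qn_network(
    nodes = data.frame(name = nms, min = 0L, max = maxes),
    edges = if (nrow(edges)) edges else NULL,
    name = sprintf("random network (seed %d)", seed))
  attr(net, "provenance") <- list(seed = seed, n_nodes = n_nodes,
                                  edge_density = edge_density,
                                  max_range = max_range,
                                  n_edges = nrow(edges))
  net
}

#' Generate oracle-labelled synthetic experiment records
#'
#' Samples backgrounds (random clamps) and perturbations (random knockouts or
#' activations), computes the true reported levels with the exhaustive
#' enumeration oracle, and emits records whose expectations match the oracle -
#' mixing the three expectation dialects (absolute level when the reported
#' level is an integer, containing range, and direction relative to the
#' background-only baseline). An uncorrupted set therefore scores 100% by
#' construction; `corrupt_fraction > 0` instead flips the stated fraction of
#' measurements (rounded) to expectations guaranteed to fail, and the ids of
#' the corrupted records are returned in the `corrupted` attribute.
#'
#' @param network a `qn_network` small enough for [qn_attractors()].
#' @param n_records number of records (one measurement each).
#' @param seed integer seed.
#' @param corrupt_fraction fraction of measurements to corrupt, in [0, 1].
#' @param state_space_cap guard passed to the enumeration oracle.
#' @return a list of `qn_experiment`s with attribute `corrupted` (character
#'   ids).
#' @export
qn_synthetic_experiments <- function(network, n_records, seed,
                                     corrupt_fraction = 0,
                                     state_space_cap = 1e4) {
  if (qn_state_space_size(network) > state_space_cap)
    stop("network state space exceeds the enumeration cap; use a smaller network")
  set.seed(seed)
  nms <- names(network$nodes)
  records <- list()
  for (i in seq_len(n_records)) {
    bg_nodes <- sample(nms, sample.int(min(2, length(nms)), 1))
    clamps <- vapply(bg_nodes, function(nm) {
      nd <- network$nodes[[nm]]
      sample(nd$min:nd$max, 1)
    }, 0)
    bg <- qn_background(sprintf("bg_%d", i), clamps)
    pert_pool <- setdiff(nms, bg_nodes)
    pert <- if (length(pert_pool) && stats::runif(1) < 0.8) {
      nm <- sample(pert_pool, 1)
      if (stats::runif(1) < 0.5) list(qn_knockout(nm)) else list(qn_overexpress(nm))
    } else list()
    readout <- sample(nms, 1)

    truth <- qn_reported_level(
      qn_attractors(qn_apply(network, c(list(bg), pert)),
                    state_space_cap = state_space_cap),
      readout)
    dialect <- sample(c("level", "range", "direction"), 1)
    if (dialect == "level" && truth != round(truth)) dialect <- "range"
    m <- switch(dialect,
      level = list(node = readout, kind = "level", value = unname(truth)),
      range = list(node = readout, kind = "range",
                   value = c(floor(truth), ceiling(truth))),
      direction = {
        base <- qn_reported_level(
          qn_attractors(qn_apply(network, bg), state_space_cap = state_space_cap),
          readout)
        dirn <- if (truth > base) "increase" else if (truth < base) "decrease"
                else "unchanged"
        list(node = readout, kind = "direction", value = dirn)
      })
    records[[i]] <- qn_experiment(sprintf("syn_%d", i), bg, pert, list(m))
  }

  n_corrupt <- round(corrupt_fraction * n_records)
  corrupted <- character()
  if (n_corrupt > 0) {
    which_c <- sample(n_records, n_corrupt)
    for (i in which_c) {
      rec <- records[[i]]
      m <- rec$measurements[[1]]
      nd <- network$nodes[[m$node]]
      truth <- qn_reported_level(
        qn_attractors(qn_apply(network, c(list(rec$background), rec$perturbations)),
                      state_space_cap = state_space_cap),
        m$node)
      # replace with an absolute level that provably mismatches
      wrong_pool <- setdiff(nd$min:nd$max, truth)
      rec$measurements[[1]] <- list(node = m$node, kind = "level",
                                    value = wrong_pool[1])
      records[[i]] <- rec
      corrupted <- c(corrupted, rec$id)
    }
  }
  attr(records, "corrupted") <- sort(corrupted)
  records
}
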