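# Stable-state bounds by interval refinement.
#
# For networks whose state space is too large to enumerate, per-node intervals
# [lo, hi] are iterated to a greatest fixpoint: for each node the extremal
# attainable target values over the current box are computed, the interval is
# intersected with [floor(minT), ceil(maxT)] clamped to the node range, and
# sweeps repeat until nothing changes. Soundness: in any attractor, a node can
# only rise into level v if its target somewhere exceeded v - 1, and can only
# hold or revisit v if the target can reach it, so every attractor state lies
# inside the final box. floor/ceil widening keeps this sound under the
# one-step-toward-target semantics. Tightness is best effort.

# Extremal target values of node nd over box (named lists lo/hi of levels).
# Interval evaluation is exact when no regulator is referenced twice (all
# grammar operators are monotone per argument); with repeated references it is
# sound but may over-approximate, so small regulator grids fall back to
# exhaustive enumeration of regulator level combinations.
node_target_interval <- function(network, nd, box_lo, box_hi,
                                 grid_cap = 4096) {
  if (is.null(nd$ast))
    return(list(lo = c(box_lo[[nd$name]], 1), hi = c(box_hi[[nd$name]], 1)))
  if (nd$deps_repeat) {
    deps <- nd$deps
    sizes <- vapply(deps, function(d) box_hi[[d]] - box_lo[[d]] + 1, 0)
    if (prod(sizes) <= grid_cap) {
      combos <- do.call(expand.grid, lapply(deps, function(d) box_lo[[d]]:box_hi[[d]]))
      names(combos) <- deps
      lo <- NULL; hi <- NULL
      for (r in seq_len(nrow(combos))) {
        lv <- as.list(combos[r, , drop = FALSE])
        env <- function(nm) {
          src <- network$nodes[[nm]]
          scale_bare(lv[[nm]], src$min, src$max, nd$min, nd$max)
        }
        t <- ast_eval(nd$ast, env)
        if (is.null(lo) || qr_cmp(t, lo) < 0) lo <- t
        if (is.null(hi) || qr_cmp(t, hi) > 0) hi <- t
      }
      return(list(lo = lo, hi = hi))
    }
  }
  env <- function(nm) {
    src <- network$nodes[[nm]]
    list(lo = scale_bare(box_lo[[nm]], src$min, src$max, nd$min, nd$max),
         hi = scale_bare(box_hi[[nm]], src$min, src$max, nd$min, nd$max))
  }
  ast_eval_interval(nd$ast, env)
}

#' Bound the stable states of a network by interval refinement
#'
#' Shrinks a per-node interval box until it is invariant under the network's
#' target functions. The resulting box is guaranteed to contain every state of
#' every attractor (fixed point or loop) of the synchronous dynamics; when all
#' intervals are singletons the network provably has a unique attractor, the
#' fixed point given by the box.
#'
#' @param network a `qn_network`.
#' @param max_sweeps safety cap on refinement sweeps (defaults to the sum of
#'   range sizes plus one, which always suffices because intervals never grow).
#' @return an object of class `qn_bounds`: a data.frame-like table with one
#'   row per node (`node`, `lo`, `hi`) plus attributes `proven_unique` and the
#'   network name.
#' @examples
#' net <- qn_motif("linear_cascade", cascade_length = 3)
#' qn_stable_bounds(qn_apply(net, qn_set_level("In", 2)))
#' @export
qn_stable_bounds <- function(network, max_sweeps = NULL) {
  stopifnot(inherits(network, "qn_network"))
  nms <- names(network$nodes)
  lo <- lapply(network$nodes, `[[`, "min")
  hi <- lapply(network$nodes, `[[`, "max")
  if (is.null(max_sweeps))
    max_sweeps <- sum(vapply(network$nodes, function(n) n$max - n$min + 1, 0)) + 1

  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (nd in network$nodes) {
      nm <- nd$name
      ti <- node_target_interval(network, nd, lo, hi)
      t_lo <- qr_floor(ti$lo)[1]
      t_hi <- qr_ceil(ti$hi)[1]
      new_lo <- max(lo[[nm]], min(nd$max, max(nd$min, t_lo)))
      new_hi <- min(hi[[nm]], min(nd$max, max(nd$min, t_hi)))
      if (new_lo > new_hi)
        stop("internal error: interval refinement produced an empty interval for node ",
             nm)
      if (new_lo != lo[[nm]] || new_hi != hi[[nm]]) {
        lo[[nm]] <- new_lo
        hi[[nm]] <- new_hi
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  tab <- data.frame(node = nms, lo = unlist(lo), hi = unlist(hi),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(tab,
            proven_unique = all(tab$lo == tab$hi),
            network = network$name,
            class = c("qn_bounds", "data.frame"))
}

#' @export
print.qn_bounds <- function(x, ...) {
  cat(sprintf("Stable-state bounds for '%s' (%d nodes)\n",
              attr(x, "network"), nrow(x)))
  if (attr(x, "proven_unique")) {
    cat("  unique attractor proven: single fixed point\n")
  } else {
    free <- x$node[x$lo != x$hi]
    cat(sprintf("  uniqueness not proven; %d node(s) unresolved: %s\n",
                length(free), paste(free, collapse = ", ")))
  }
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Exhibit attractors by simulating from the corners of a bounds box
#'
#' When [qn_stable_bounds()] cannot prove uniqueness, simulation from the two
#' extreme corners of the box (all nodes at their lower bounds / all at their
#' upper bounds) often exhibits two distinct attractors, certifying a
#' bifurcation such as the on/off states of a positive feedback loop. Failure
#' to find two attractors leaves the question open ("not proven"), it never
#' proves uniqueness.
#'
#' @param network a `qn_network`.
#' @param bounds a `qn_bounds` for `network` (computed if omitted).
#' @param max_steps simulation budget per corner.
#' @return a list of distinct `qn_attractor`s reached from the corners.
#' @export
qn_corner_attractors <- function(network, bounds = NULL, max_steps = 10000) {
  if (is.null(bounds)) bounds <- qn_stable_bounds(network)
  lo <- stats::setNames(as.integer(bounds$lo), bounds$node)
  hi <- stats::setNames(as.integer(bounds$hi), bounds$node)
  found <- list()
  keys <- character()
  for (corner in list(lo, hi)) {
    sim <- qn_simulate(network, corner, max_steps = max_steps)
    if (!sim$converged) next
    k <- paste(sort(vapply(sim$attractor$states, state_key, "")), collapse = "|")
    if (!k %in% keys) {
      keys <- c(keys, k)
      found[[length(found) + 1L]] <- sim$attractor
    }
  }
  found
}

#' Reported level of a node (fixed value or interval midpoint)
#'
#' Implements the reporting rule used for model predictions: when the analysis
#' identifies a single fixed point, the node's level in that state is
#' reported; when a loop or bifurcation leaves an interval `[lo, hi]`, the
#' midpoint `(lo + hi) / 2` is reported (possibly a half-integer).
#'
#' @param x a `qn_bounds`, a `qn_attractor_set`, or a list of `qn_attractor`s.
#' @param node node name (or vector of names).
#' @return numeric reported level(s), named after `node`. Midpoints are exact
#'   because integer bounds give midpoints in halves.
#' @export
qn_reported_level <- function(x, node) {
  lims <- level_limits(x)
  miss <- setdiff(node, rownames(lims))
  if (length(miss)) stop("unknown node(s): ", paste(miss, collapse = ", "))
  out <- (lims[node, "lo"] + lims[node, "hi"]) / 2
  names(out) <- node
  out
}

level_limits <- function(x) {
  if (inherits(x, "qn_bounds")) {
    m <- cbind(lo = x$lo, hi = x$hi)
    rownames(m) <- x$node
    return(m)
  }
  atts <- if (inherits(x, "qn_attractor_set")) x$attractors
          else if (inherits(x, "qn_attractor")) list(x)
          else x
  states <- do.call(rbind, unlist(lapply(atts, `[[`, "states"), recursive = FALSE))
  m <- cbind(lo = apply(states, 2, min), hi = apply(states, 2, max))
  rownames(m) <- colnames(states)
  m
}
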