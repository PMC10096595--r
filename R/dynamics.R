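# Synchronous update semantics and exhaustive attractor enumeration.
#
# At each step every node compares its (exact rational) target value T with its
# current level v and moves to v+1 if T > v, v-1 if T < v, otherwise stays,
# clamped to the node's range. The comparison is strict: a fractional target
# such as v + 1/2 moves the node up, which is why loops (cycles) can arise and
# why reported levels use interval midpoints (see qn_reported_level).

state_key <- function(state) paste(state, collapse = ",")

#' One synchronous update step
#'
#' @param network a `qn_network`.
#' @param state a valid named integer state vector.
#' @return the successor state (named integer vector).
#' @examples
#' net <- qn_motif("mutual_activation")
#' qn_step(net, c(A = 1, B = 0))  # -> A = 0, B = 1
#' @export
qn_step <- function(network, state) {
  state <- check_state(network, state)
  step_bare(network, state)
}

step_bare <- function(network, state) {
  nxt <- state
  for (nd in network$nodes) {
    v <- state[[nd$name]]
    t <- node_target_bare(network, nd, state)
    cmp <- sign(t[1] - v * t[2])
    w <- v + as.integer(cmp)
    if (w < nd$min) w <- nd$min else if (w > nd$max) w <- nd$max
    nxt[[nd$name]] <- w
  }
  nxt
}

#' Simulate a trajectory to its attractor
#'
#' Iterates the synchronous step from `init`, recording every visited state,
#' until a state repeats; the cycle between the first revisit and its earlier
#' occurrence is the attractor (length 1 = fixed point, longer = loop). The
#' dynamics are deterministic, so every initial state reaches exactly one
#' attractor within at most state-space-size steps.
#'
#' @param network a `qn_network`.
#' @param init initial state (named integer vector).
#' @param max_steps step budget; the default (state-space size, capped at
#'   `1e6`) guarantees convergence.
#' @return a list of class `qn_trajectory` with elements `trajectory` (list of
#'   states), `attractor` (a `qn_attractor` or `NULL`), and `converged`.
#' @export
qn_simulate <- function(network, init, max_steps = NULL) {
  init <- check_state(network, init)
  if (is.null(max_steps))
    max_steps <- min(qn_state_space_size(network), 1e6)
  traj <- list(init)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(state_key(init), 1L, envir = seen)
  cur <- init
  attractor <- NULL
  for (i in seq_len(max_steps)) {
    cur <- step_bare(network, cur)
    k <- state_key(cur)
    at <- get0(k, envir = seen)
    if (!is.null(at)) {
      cyc <- traj[at:length(traj)]
      attractor <- qn_attractor(cyc, witness = init)
      break
    }
    traj[[length(traj) + 1L]] <- cur
    assign(k, length(traj), envir = seen)
  }
  structure(list(trajectory = traj, attractor = attractor,
                 converged = !is.null(attractor)),
            class = "qn_trajectory")
}

qn_attractor <- function(states, witness = NULL) {
  structure(list(states = states, witness = witness), class = "qn_attractor")
}

#' @export
print.qn_attractor <- function(x, ...) {
  if (length(x$states) == 1) {
    cat("Fixed-point attractor:\n")
    print(x$states[[1]])
  } else {
    cat(sprintf("Loop attractor of length %d:\n", length(x$states)))
    print(do.call(rbind, x$states))
  }
  invisible(x)
}

#' @export
print.qn_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory of %d state(s); converged: %s\n",
              length(x$trajectory), x$converged))
  if (!is.null(x$attractor)) print(x$attractor)
  invisible(x)
}

#' Size of a network's state space
#'
#' @param network a `qn_network`.
#' @return `prod(max - min + 1)` over nodes (a double, as this can be huge).
#' @export
qn_state_space_size <- function(network) {
  prod(vapply(network$nodes, function(n) n$max - n$min + 1, 0))
}

# index <-> state conversion (mixed radix, node order, 0-based index)
state_radices <- function(network) {
  vapply(network$nodes, function(n) n$max - n$min + 1L, 0L)
}

index_to_state2 <- function(idx, radices, mins, nms) {
  n <- length(radices)
  s <- integer(n)
  for (j in seq_len(n)) {
    s[j] <- as.integer(idx %% radices[j]) + mins[j]
    idx <- idx %/% radices[j]
  }
  names(s) <- nms
  s
}

state_to_index <- function(state, radices, mins) {
  idx <- 0
  mult <- 1
  for (j in seq_along(radices)) {
    idx <- idx + (state[[j]] - mins[j]) * mult
    mult <- mult * radices[j]
  }
  idx
}

#' Enumerate all attractors by exhaustive simulation
#'
#' Computes the successor of every state in the (finite) state space and
#' extracts every cycle of the resulting functional graph. This is the
#' brute-force oracle used to certify the interval-refinement stability
#' analysis on small networks; for large models use [qn_stable_bounds()].
#'
#' The network exhibits a *bifurcation* when more than one attractor exists.
#'
#' @param network a `qn_network`.
#' @param state_space_cap refuse to enumerate state spaces larger than this
#'   (default `1e6`).
#' @return a list of class `qn_attractor_set`: `attractors` (list of
#'   `qn_attractor`), `bifurcation` (logical), `n_states`.
#' @examples
#' qn_attractors(qn_motif("mutual_activation"))
#' @export
qn_attractors <- function(network, state_space_cap = 1e6) {
  n_states <- qn_state_space_size(network)
  if (n_states > state_space_cap)
    stop(sprintf(paste0(
      "state space has %s states, above the cap of %s; ",
      "use qn_stable_bounds() for large networks"),
      format(n_states, big.mark = ","), format(state_space_cap, big.mark = ",")))
  radices <- state_radices(network)
  mins <- vapply(network$nodes, `[[`, 0L, "min")
  nms <- names(network$nodes)
  N <- as.integer(n_states)

  succ <- integer(N)
  for (i in seq_len(N)) {
    s <- index_to_state2(i - 1, radices, mins, nms)
    succ[i] <- as.integer(state_to_index(step_bare(network, s), radices, mins)) + 1L
  }

  # attractor id per state: 0 = unvisited, -run while on current path
  aid <- integer(N)
  attractors <- list()
  witnesses <- integer()
  for (start in seq_len(N)) {
    if (aid[start] != 0L) next
    path <- integer()
    cur <- start
    while (aid[cur] == 0L) {
      aid[cur] <- -1L
      path[length(path) + 1L] <- cur
      cur <- succ[cur]
    }
    if (aid[cur] == -1L) {
      # new cycle: cur is on the current path
      pos <- match(cur, path)
      cyc <- path[pos:length(path)]
      id <- length(attractors) + 1L
      attractors[[id]] <- cyc
      witnesses[id] <- start
      final <- id
    } else {
      final <- aid[cur]
    }
    aid[path] <- final
  }

  out <- vector("list", length(attractors))
  for (k in seq_along(attractors)) {
    states <- lapply(attractors[[k]] - 1, index_to_state2,
                     radices = radices, mins = mins, nms = nms)
    out[[k]] <- qn_attractor(states,
                             witness = index_to_state2(witnesses[k] - 1,
                                                       radices, mins, nms))
  }
  structure(list(attractors = out, bifurcation = length(out) > 1,
                 n_states = N),
            class = "qn_attractor_set")
}

#' @export
print.qn_attractor_set <- function(x, ...) {
  sizes <- vapply(x$attractors, function(a) length(a$states), 0L)
  cat(sprintf("%d attractor(s) over %d states (%d fixed point(s), %d loop(s))%s\n",
              length(x$attractors), x$n_states, sum(sizes == 1), sum(sizes > 1),
              if (x$bifurcation) " - bifurcation" else ""))
  for (a in x$attractors) print(a)
  invisible(x)
}

#' Test whether a state is a fixed point
#'
#' A state is a fixed point iff for every node the target value is equal to
#' the current level, or points beyond a range endpoint the node already sits
#' at. Checked directly from the target functions, without simulation.
#'
#' @param network a `qn_network`.
#' @param state a valid state.
#' @return logical.
#' @export
qn_is_fixed_point <- function(network, state) {
  state <- check_state(network, state)
  for (nd in network$nodes) {
    v <- state[[nd$name]]
    t <- node_target_bare(network, nd, state)
    cmp <- sign(t[1] - v * t[2])
    if (cmp > 0 && v < nd$max) return(FALSE)
    if (cmp < 0 && v > nd$min) return(FALSE)
  }
  TRUE
}
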