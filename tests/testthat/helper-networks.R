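# Small fixture networks built in code, plus an independent naive evaluator
# used as an oracle against the package's exact-arithmetic path.

two_node_mutual <- function() qn_motif("mutual_activation")

# In -> A -> B cascade, all ranges 0-2, default functions
cascade3 <- function() qn_motif("linear_cascade", cascade_length = 2)

# single self-inhibiting node, range 0-1
self_inhibitor <- function() {
  qn_network(nodes = data.frame(name = "A", min = 0, max = 1),
             edges = data.frame(source = "A", target = "A", sign = "inhibiting"))
}

# Independent oracle for the default target function on equal-range nodes:
# plain floating-point mean of activators minus mean of inhibitors, written
# without any package internals. Empty-set conventions mirror the documented
# ones: a node with no regulators holds its level; empty pos with non-empty
# neg counts as full activation; empty neg counts as zero inhibition.
naive_default_target <- function(pos_levels, neg_levels, current, max_level) {
  if (!length(pos_levels) && !length(neg_levels)) return(current)
  p <- if (length(pos_levels)) mean(pos_levels) else max_level
  n <- if (length(neg_levels)) mean(neg_levels) else 0
  p - n
}

# Independent one-step oracle for equal-range default-function networks.
naive_step <- function(net, state) {
  out <- state
  for (nm in names(net$nodes)) {
    nd <- net$nodes[[nm]]
    v <- state[[nm]]
    t <- naive_default_target(state[nd$pos], state[nd$neg], v, nd$max)
    w <- v + sign(t - v)
    out[[nm]] <- as.integer(min(nd$max, max(nd$min, w)))
  }
  out
}

expect_same_attractors <- function(aset, expected_states) {
  # expected_states: list of lists of named vectors (each inner list a cycle)
  canon <- function(states)
    paste(sort(vapply(states, function(s) paste(names(s), s, sep = "=", collapse = ","), "")),
          collapse = "|")
  got <- sort(vapply(aset$attractors, function(a) canon(a$states), ""))
  want <- sort(vapply(expected_states, canon, ""))
  expect_identical(got, want)
}
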