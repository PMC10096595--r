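# Qualitative-network data model.
#
# A qualitative network generalises a Boolean network: each node holds an
# integer activity level in a finite range [min, max] and, at every synchronous
# step, moves one level toward the value of its target function evaluated on
# the current levels of its regulators. Unless an explicit expression is given,
# the target function defaults to avg(activators) - avg(inhibitors), with the
# regulator levels first rescaled into the node's own range.

#' Create a qualitative network
#'
#' @param nodes a data.frame with columns `name`, `min`, `max` and optionally
#'   `kind` (free-text tag such as `"protein"`, `"receptor"`, `"gene"`,
#'   `"secreted"`, `"process"`, `"drug-action"`; metadata only, never used by
#'   the dynamics).
#' @param edges a data.frame with columns `source`, `target`, `sign`
#'   (`"activating"`/`"inhibiting"`, also accepted: `"+"`/`"-"`,
#'   `"Activator"`/`"Inhibitor"`). May have zero rows.
#' @param functions optional explicit target functions: a named character
#'   vector (names = node names) or a data.frame with columns `node`,
#'   `expression`. Nodes without an entry (or with the entry `"default"`) get
#'   the default target function.
#' @param behaviors optional character vector naming the designated behaviour
#'   (phenotype) nodes. Defaults to nodes whose `kind` is `"process"` or
#'   `"behavior"`.
#' @param name optional model name.
#' @param validate if `TRUE` (default), stop on any structural diagnostic; set
#'   to `FALSE` to build a possibly malformed network for inspection with
#'   [qn_validate()].
#'
#' @details Default target functions follow these conventions (each isolated in
#'   one place so it can be swapped): with activators `pos` and inhibitors
#'   `neg`, the target is `avg(pos) - avg(neg)`; if `pos` is empty but `neg` is
#'   not, `avg(pos)` is taken to be the node's maximum level (inhibition
#'   opposes full activation); if `neg` is empty, `avg(neg)` is 0; a node with
#'   no regulators and no explicit function holds its current level, so
#'   unregulated inputs keep whatever a background clamps them to.
#'
#' @return an object of class `qn_network`.
#' @examples
#' net <- qn_network(
#'   nodes = data.frame(name = c("A", "B"), min = 0, max = 1),
#'   edges = data.frame(source = c("A", "B"), target = c("B", "A"),
#'                      sign = "activating"))
#' net
#' @export
qn_network <- function(nodes, edges, functions = NULL, behaviors = NULL,
                       name = "qualitative network", validate = TRUE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "min", "max") %in% names(nodes)))
  if (is.null(nodes$kind)) nodes$kind <- "protein"
  if (is.null(edges) || !NROW(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    stopifnot(all(c("source", "target", "sign") %in% names(edges)))
    edges$sign <- normalize_sign(edges$sign)
  }
  fn_map <- normalize_functions(functions)

  node_list <- vector("list", nrow(nodes))
  names(node_list) <- nodes$name
  for (i in seq_len(nrow(nodes))) {
    nm <- nodes$name[i]
    node_list[[i]] <- list(
      name = nm,
      min = as.integer(nodes$min[i]),
      max = as.integer(nodes$max[i]),
      kind = as.character(nodes$kind[i]),
      pos = edges$source[edges$target == nm & edges$sign == "activating"],
      neg = edges$source[edges$target == nm & edges$sign == "inhibiting"],
      target_src = if (nm %in% names(fn_map)) fn_map[[nm]] else "default"
    )
  }
  if (is.null(behaviors))
    behaviors <- nodes$name[nodes$kind %in% c("process", "behavior")]

  net <- structure(
    list(name = name, nodes = node_list, edges = edges, behaviors = behaviors),
    class = "qn_network")

  diags <- qn_validate(net)
  if (validate && length(diags))
    stop("invalid qualitative network:\n  - ", paste(diags, collapse = "\n  - "),
         call. = FALSE)
  if (!length(diags)) net <- qn_compile(net)
  net
}

normalize_sign <- function(s) {
  out <- tolower(as.character(s))
  out[out %in% c("+", "activator", "activating", "activation", "1")] <- "activating"
  out[out %in% c("-", "inhibitor", "inhibiting", "inhibition")] <- "inhibiting"
  bad <- setdiff(unique(out), c("activating", "inhibiting"))
  if (length(bad)) stop("unknown edge sign(s): ", paste(bad, collapse = ", "))
  out
}

normalize_functions <- function(functions) {
  if (is.null(functions)) return(list())
  if (is.data.frame(functions)) {
    stopifnot(all(c("node", "expression") %in% names(functions)))
    fn <- as.list(as.character(functions$expression))
    names(fn) <- functions$node
    return(fn)
  }
  as.list(functions)
}

#' Validate a qualitative network
#'
#' Checks every structural invariant and returns diagnostics instead of
#' raising: dangling edges, duplicate node names, degenerate ranges
#' (`min >= max`), unparsable target expressions, `var()` references that do
#' not name an in-edge source, and behaviour nodes absent from the network.
#'
#' @param network a `qn_network` (possibly built with `validate = FALSE`).
#' @return a character vector of diagnostics; empty when the network is
#'   well-formed.
#' @export
qn_validate <- function(network) {
  stopifnot(inherits(network, "qn_network"))
  diags <- character()
  nms <- names(network$nodes)
  dup <- unique(nms[duplicated(nms)])
  if (length(dup))
    diags <- c(diags, paste0("duplicate node name: ", dup))
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    if (!e$source[i] %in% nms)
      diags <- c(diags, sprintf("dangling edge: source '%s' (-> %s) is not a node",
                                e$source[i], e$target[i]))
    if (!e$target[i] %in% nms)
      diags <- c(diags, sprintf("dangling edge: target '%s' (<- %s) is not a node",
                                e$target[i], e$source[i]))
  }
  for (nd in network$nodes) {
    if (nd$min >= nd$max)
      diags <- c(diags, sprintf("degenerate range for node '%s': [%d, %d]",
                                nd$name, nd$min, nd$max))
    if (!identical(nd$target_src, "default")) {
      ast <- tryCatch(qn_parse_target(nd$target_src), error = function(err) err)
      if (inherits(ast, "error")) {
        diags <- c(diags, sprintf("node '%s': %s", nd$name, conditionMessage(ast)))
      } else {
        bad <- setdiff(ast_vars(ast), c(nd$pos, nd$neg))
        if (length(bad))
          diags <- c(diags, sprintf(
            "node '%s': var(%s) does not name an in-edge source",
            nd$name, paste(bad, collapse = "), var(")))
      }
    }
  }
  bad_beh <- setdiff(network$behaviors, nms)
  if (length(bad_beh))
    diags <- c(diags, paste0("behaviour node not in network: ", bad_beh))
  diags
}

# Expand the default target function for one node. This is the single place
# that encodes the empty-set conventions described in ?qn_network.
default_target_ast <- function(node) {
  has_pos <- length(node$pos) > 0
  has_neg <- length(node$neg) > 0
  if (!has_pos && !has_neg) return(NULL)  # identity: hold current level
  pos_ast <- if (has_pos) ast_call("avg", lapply(node$pos, ast_var))
             else ast_const(node$max)
  if (!has_neg) return(pos_ast)
  neg_ast <- ast_call("avg", lapply(node$neg, ast_var))
  ast_call("-", list(pos_ast, neg_ast))
}

# Attach compiled target ASTs (and regulator metadata) to every node.
qn_compile <- function(network) {
  for (i in seq_along(network$nodes)) {
    nd <- network$nodes[[i]]
    if (identical(nd$target_src, "default")) {
      nd$ast <- default_target_ast(nd)
      nd$is_default <- TRUE
    } else {
      nd$ast <- qn_parse_target(nd$target_src, regulators = c(nd$pos, nd$neg))
      nd$is_default <- FALSE
    }
    nd$deps <- if (is.null(nd$ast)) character() else unique(ast_vars(nd$ast))
    nd$deps_repeat <- if (is.null(nd$ast)) FALSE else anyDuplicated(ast_vars(nd$ast)) > 0
    network$nodes[[i]] <- nd
  }
  network
}

#' Rescale a regulator level between node ranges
#'
#' When a node with range `[a, b]` regulates a node with range `[a', b']`, its
#' level `x` enters the regulated node's target function as
#' `(x - a) * (b' - a') / (b - a) + a'`. The map is monotone and carries
#' endpoints to endpoints; identical ranges give the identity.
#'
#' @param level integer level of the regulator.
#' @param source_range length-2 integer vector `c(a, b)`, `a < b`.
#' @param target_range length-2 integer vector `c(a', b')`, `a' < b'`.
#' @return the rescaled level as an exact `qn_rational`.
#' @examples
#' as.numeric(qn_scale(1, c(0, 2), c(0, 4)))  # 2
#' @export
qn_scale <- function(level, source_range, target_range) {
  a <- source_range[1]; b <- source_range[2]
  a2 <- target_range[1]; b2 <- target_range[2]
  stopifnot(a < b, a2 < b2)
  if (level < a || level > b)
    stop(sprintf("level %s outside source range [%s, %s]", level, a, b))
  structure(scale_bare(level, a, b, a2, b2), class = "qn_rational")
}

scale_bare <- function(level, a, b, a2, b2) {
  qr_add(qr_bare((level - a) * (b2 - a2), (b - a)), c(a2, 1))
}

check_state <- function(network, state) {
  nms <- names(network$nodes)
  if (is.null(names(state)) && length(state) == length(nms)) names(state) <- nms
  missing <- setdiff(nms, names(state))
  if (length(missing))
    stop("state is missing node(s): ", paste(missing, collapse = ", "))
  state <- state[nms]
  for (nd in network$nodes) {
    v <- state[[nd$name]]
    if (is.na(v) || v != round(v) || v < nd$min || v > nd$max)
      stop(sprintf("state level %s for node '%s' outside range [%d, %d]",
                   v, nd$name, nd$min, nd$max))
  }
  storage.mode(state) <- "integer"
  state
}

#' Evaluate a node's target function in a state
#'
#' Each regulator level is first rescaled into the node's own range with
#' [qn_scale()], then the target expression is evaluated in exact rational
#' arithmetic. The result may lie outside the node's range; clamping only
#' happens in the dynamics ([qn_step()]).
#'
#' @param network a `qn_network`.
#' @param node node name.
#' @param state a valid network state (named integer vector).
#' @return the target value as a `qn_rational`.
#' @export
qn_target_value <- function(network, node, state) {
  nd <- network$nodes[[node]]
  if (is.null(nd)) stop("unknown node: ", node)
  state <- check_state(network, state)
  structure(node_target_bare(network, nd, state), class = "qn_rational")
}

node_target_bare <- function(network, nd, state) {
  if (is.null(nd$ast)) return(c(state[[nd$name]], 1))
  env <- function(nm) {
    src <- network$nodes[[nm]]
    scale_bare(state[[nm]], src$min, src$max, nd$min, nd$max)
  }
  ast_eval(nd$ast, env)
}

#' @export
print.qn_network <- function(x, ...) {
  cat(sprintf("Qualitative network '%s': %d nodes, %d edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  rng <- vapply(x$nodes, function(n) sprintf("[%d,%d]", n$min, n$max), "")
  cat("  ranges: ", paste(unique(rng), collapse = " "), "\n", sep = "")
  if (length(x$behaviors))
    cat("  behaviour nodes: ", paste(x$behaviors, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.qn_network <- function(object, ...) {
  kinds <- table(vapply(object$nodes, `[[`, "", "kind"))
  expl <- sum(!vapply(object$nodes, function(n) identical(n$target_src, "default"), TRUE))
  structure(list(name = object$name, n_nodes = length(object$nodes),
                 n_edges = nrow(object$edges), kinds = kinds,
                 n_explicit = expl,
                 state_space = prod(vapply(object$nodes,
                                           function(n) n$max - n$min + 1, 0))),
            class = "summary.qn_network")
}

#' @export
print.summary.qn_network <- function(x, ...) {
  cat(sprintf("Qualitative network '%s'\n", x$name))
  cat(sprintf("  %d nodes (%d with explicit target functions), %d edges\n",
              x$n_nodes, x$n_explicit, x$n_edges))
  cat(sprintf("  state-space size: %s\n", format(x$state_space, big.mark = ",")))
  cat("  node kinds:\n")
  for (k in names(x$kinds)) cat(sprintf("    %-12s %d\n", k, x$kinds[[k]]))
  invisible(x)
}

#' Plot the interaction graph of a qualitative network
#'
#' Draws the signed interaction graph with igraph when available (activating
#' edges as arrows, inhibiting edges in red; node colours follow the `kind`
#' tag). Falls back to a text summary when igraph is not installed.
#'
#' @param x a `qn_network`.
#' @param ... passed to `igraph::plot.igraph`.
#' @export
plot.qn_network <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    print(x)
    return(invisible(x))
  }
  g <- igraph::graph_from_data_frame(
    x$edges[, c("source", "target")],
    vertices = data.frame(name = names(x$nodes),
                          kind = vapply(x$nodes, `[[`, "", "kind")))
  pal <- c(protein = "pink", complex = "pink", receptor = "lightblue",
           secreted = "grey80", gene = "cyan", process = "orange",
           behavior = "orange", `drug-action` = "yellow")
  kind <- igraph::V(g)$kind
  igraph::V(g)$color <- ifelse(kind %in% names(pal), pal[kind], "white")
  igraph::E(g)$color <- ifelse(x$edges$sign == "inhibiting", "red3", "grey30")
  igraph::plot.igraph(g, edge.arrow.size = 0.4, vertex.label.cex = 0.7, ...)
  invisible(x)
}
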