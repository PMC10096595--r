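# Mutations, drugs and genetic backgrounds as target-function overrides.
#
# A knockout replaces a node's target function by its minimum level, an
# activation/overexpression by its maximum, set_level by a given constant, and
# a drug by one or more node-level overrides (constant clamps or replacement
# expressions). Backgrounds are named sets of clamps applied before any
# perturbation; a perturbation targeting a background-clamped node overrides
# the clamp (last write wins) and says so loudly.

#' Perturbation constructors
#'
#' @param node node name.
#' @param level integer level for `qn_set_level`.
#' @return an object of class `qn_perturbation`.
#' @examples
#' qn_knockout("TNF")
#' qn_set_level("MITF", 3)
#' @export
qn_knockout <- function(node) {
  structure(list(kind = "knockout", node = node,
                 label = paste0("KO:", node)), class = "qn_perturbation")
}

#' @rdname qn_knockout
#' @export
qn_overexpress <- function(node) {
  structure(list(kind = "overexpress", node = node,
                 label = paste0("OE:", node)), class = "qn_perturbation")
}

#' @rdname qn_knockout
#' @export
qn_set_level <- function(node, level) {
  structure(list(kind = "set_level", node = node, level = as.integer(level),
                 label = paste0(node, "=", level)), class = "qn_perturbation")
}

#' Define a drug as a set of node-level target overrides
#'
#' @param name drug name.
#' @param overrides a named list: names are node names; each value is either an
#'   integer clamp level or a character replacement target expression.
#' @param class free-text pathway/class annotation (e.g. `"TGFB"`, `"MAPK"`);
#'   metadata used for reporting only.
#' @return an object of class `qn_drug` (also a `qn_perturbation`).
#' @examples
#' qn_drug("trametinib", list(MEK = 0, MAPK_LC = 0), class = "MAPK")
#' @export
qn_drug <- function(name, overrides, class = NA_character_) {
  stopifnot(is.list(overrides), !is.null(names(overrides)),
            all(nzchar(names(overrides))))
  structure(list(kind = "drug", name = name, overrides = overrides,
                 class = class, label = name),
            class = c("qn_drug", "qn_perturbation"))
}

#' @export
print.qn_perturbation <- function(x, ...) {
  if (x$kind == "drug") {
    ov <- vapply(seq_along(x$overrides), function(i) {
      paste0(names(x$overrides)[i], " := ", x$overrides[[i]])
    }, "")
    cat(sprintf("Drug '%s' (%s): %s\n", x$name,
                if (is.na(x$class)) "unclassified" else x$class,
                paste(ov, collapse = "; ")))
  } else {
    cat("Perturbation:", x$label, "\n")
  }
  invisible(x)
}

#' Define a genetic/transcriptional background
#'
#' A background is a named set of node clamps (e.g. a driver mutation present,
#' a tumour suppressor lost, a transcriptional state fixed) applied before any
#' perturbation or drug.
#'
#' @param name background name.
#' @param clamps named integer vector or named list, node -> level.
#' @return an object of class `qn_background`.
#' @examples
#' qn_background("healthy", c(BRAF_V600E = 0, PTEN = 2))
#' @export
qn_background <- function(name, clamps) {
  clamps <- unlist(clamps)
  if (length(clamps))
    stopifnot(!is.null(names(clamps)), all(nzchar(names(clamps))))
  else clamps <- stats::setNames(integer(), character())
  structure(list(name = name, clamps = clamps), class = "qn_background")
}

#' @export
print.qn_background <- function(x, ...) {
  cat(sprintf("Background '%s': %s\n", x$name,
              paste(names(x$clamps), x$clamps, sep = "=", collapse = ", ")))
  invisible(x)
}

override_node_target <- function(network, node, value, origin = "perturbation",
                                 mark_background = FALSE) {
  nd <- network$nodes[[node]]
  if (is.null(nd)) stop(origin, " targets unknown node: ", node)
  if (isTRUE(nd$bg_clamped) && !mark_background)
    message(sprintf("note: %s overrides the background clamp on node '%s'",
                    origin, node))
  if (is.character(value)) {
    nd$target_src <- value
    nd$ast <- qn_parse_target(value, regulators = c(nd$pos, nd$neg))
  } else {
    value <- as.integer(value)
    if (value < nd$min || value > nd$max)
      stop(sprintf("%s level %d for node '%s' outside range [%d, %d]",
                   origin, value, node, nd$min, nd$max))
    nd$target_src <- as.character(value)
    nd$ast <- ast_const(value)
  }
  nd$is_default <- FALSE
  nd$deps <- if (is.null(nd$ast)) character() else unique(ast_vars(nd$ast))
  nd$deps_repeat <- if (is.null(nd$ast)) FALSE else anyDuplicated(ast_vars(nd$ast)) > 0
  if (mark_background) nd$bg_clamped <- TRUE
  network$nodes[[node]] <- nd
  network
}

#' Apply perturbations and backgrounds to a network
#'
#' Returns a modified copy; the input network is untouched. `what` may be a
#' single `qn_perturbation`, `qn_drug` or `qn_background`, or a list of them,
#' applied in order (last write wins on the same node, so e.g. a knockout
#' followed by an overexpression of the same node leaves the overexpression).
#'
#' @param network a `qn_network`.
#' @param what perturbation(s)/background(s) to apply.
#' @return the perturbed `qn_network`.
#' @examples
#' net <- qn_motif("tnf_autocrine")
#' qn_apply(net, qn_knockout("TNF"))
#' @export
qn_apply <- function(network, what) {
  stopifnot(inherits(network, "qn_network"))
  if (inherits(what, "qn_perturbation") || inherits(what, "qn_background"))
    what <- list(what)
  for (p in what) {
    if (inherits(p, "qn_background")) {
      for (nm in names(p$clamps))
        network <- override_node_target(network, nm, p$clamps[[nm]],
                                        origin = sprintf("background '%s'", p$name),
                                        mark_background = TRUE)
    } else if (inherits(p, "qn_perturbation")) {
      network <- switch(p$kind,
        knockout = override_node_target(network, p$node,
                                        network$nodes[[p$node]]$min %||% stop("unknown node: ", p$node),
                                        origin = p$label),
        overexpress = override_node_target(network, p$node,
                                           network$nodes[[p$node]]$max %||% stop("unknown node: ", p$node),
                                           origin = p$label),
        set_level = override_node_target(network, p$node, p$level, origin = p$label),
        drug = {
          net2 <- network
          for (nm in names(p$overrides))
            net2 <- override_node_target(net2, nm, p$overrides[[nm]],
                                         origin = sprintf("drug '%s'", p$name))
          net2
        },
        stop("unknown perturbation kind: ", p$kind))
    } else {
      stop("qn_apply: expected qn_perturbation or qn_background objects")
    }
  }
  network
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an in silico perturbation screen
#'
#' For every background crossed with every perturbation (and, when `pairwise`,
#' every unordered pair of distinct perturbations), applies the background then
#' the perturbation(s), bounds the stable states with [qn_stable_bounds()] and
#' reports each readout with [qn_reported_level()]. A baseline (unperturbed)
#' row is included for every background. When both `Proliferation` and
#' `Apoptosis` (or the names given in `growth_nodes`) are among the readouts, a
#' `tumor_growth_score` column (proliferation minus apoptosis) is added.
#'
#' A failure in one cell is recorded in that row's `note` column and the
#' screen continues.
#'
#' @param network a `qn_network`.
#' @param backgrounds list of `qn_background` (or a single one).
#' @param perturbations list of `qn_perturbation`/`qn_drug` (may be empty for
#'   baselines only).
#' @param readouts character vector of node names to report.
#' @param pairwise also screen unordered pairs of distinct perturbations.
#' @param growth_nodes length-2 character vector naming the proliferation and
#'   apoptosis readouts used for the growth score.
#' @return a data.frame of class `qn_screen` with columns `background`,
#'   `perturbation_1`, `perturbation_2`, `proven_unique`, one column per
#'   readout, `tumor_growth_score` (when applicable) and `note`.
#' @export
qn_screen <- function(network, backgrounds, perturbations = list(),
                      readouts, pairwise = FALSE,
                      growth_nodes = c("Proliferation", "Apoptosis")) {
  if (inherits(backgrounds, "qn_background")) backgrounds <- list(backgrounds)
  if (inherits(perturbations, "qn_perturbation")) perturbations <- list(perturbations)
  if (!length(backgrounds)) stop("at least one background is required")
  miss <- setdiff(readouts, names(network$nodes))
  if (length(miss)) stop("readout(s) not in network: ", paste(miss, collapse = ", "))

  combos <- list()
  for (p in perturbations) combos[[length(combos) + 1L]] <- list(p)
  if (pairwise && length(perturbations) >= 2) {
    idx <- utils::combn(length(perturbations), 2)
    for (j in seq_len(ncol(idx))) {
      pr <- perturbations[idx[, j]]
      # canonical order by label so duplicated unordered pairs collapse
      pr <- pr[order(vapply(pr, `[[`, "", "label"))]
      combos[[length(combos) + 1L]] <- pr
    }
  }

  rows <- list()
  with_growth <- all(growth_nodes %in% readouts)
  for (bg in backgrounds) {
    base_net <- qn_apply(network, bg)
    for (cell in c(list(list()), combos)) {
      labels <- vapply(cell, `[[`, "", "label")
      row <- list(background = bg$name,
                  perturbation_1 = if (length(labels) >= 1) labels[1] else NA_character_,
                  perturbation_2 = if (length(labels) >= 2) labels[2] else NA_character_)
      res <- tryCatch({
        net <- if (length(cell)) qn_apply(base_net, cell) else base_net
        b <- qn_stable_bounds(net)
        lv <- qn_reported_level(b, readouts)
        list(levels = lv, unique = attr(b, "proven_unique"), note = NA_character_)
      }, error = function(e) {
        list(levels = stats::setNames(rep(NA_real_, length(readouts)), readouts),
             unique = NA, note = conditionMessage(e))
      })
      row$proven_unique <- res$unique
      for (rd in readouts) row[[rd]] <- unname(res$levels[[rd]])
      if (with_growth)
        row$tumor_growth_score <- res$levels[[growth_nodes[1]]] - res$levels[[growth_nodes[2]]]
      row$note <- res$note
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  structure(out, readouts = readouts, growth_nodes = growth_nodes,
            class = c("qn_screen", "data.frame"))
}

#' Tumour growth score of a screen row
#'
#' The growth score is the reported proliferation level minus the reported
#' apoptosis level.
#'
#' @param row a one-row data.frame (or list) containing the two readouts.
#' @param growth_nodes names of the proliferation and apoptosis readouts.
#' @return numeric score.
#' @export
qn_growth_score <- function(row, growth_nodes = c("Proliferation", "Apoptosis")) {
  if (!all(growth_nodes %in% names(row)))
    stop("row lacks readout(s): ",
         paste(setdiff(growth_nodes, names(row)), collapse = ", "))
  unname(unlist(row[growth_nodes[1]]) - unlist(row[growth_nodes[2]]))
}

#' @export
print.qn_screen <- function(x, n = 10, ...) {
  cat(sprintf("In silico screen: %d rows (%d backgrounds)\n",
              nrow(x), length(unique(x$background))))
  print(utils::head(as.data.frame(x), n), row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("  ... %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Heatmap of one readout across a screen
#'
#' @param x a `qn_screen`.
#' @param readout which readout column to draw (default: the first one).
#' @param ... passed to [graphics::image()].
#' @export
plot.qn_screen <- function(x, readout = attr(x, "readouts")[1], ...) {
  lab <- ifelse(is.na(x$perturbation_1), "baseline",
                ifelse(is.na(x$perturbation_2), x$perturbation_1,
                       paste(x$perturbation_1, x$perturbation_2, sep = "+")))
  bgs <- unique(x$background)
  labs <- unique(lab)
  m <- matrix(NA_real_, length(labs), length(bgs), dimnames = list(labs, bgs))
  for (i in seq_len(nrow(x))) m[lab[i], x$background[i]] <- x[[readout]][i]
  op <- graphics::par(mar = c(8, 10, 2, 1)); on.exit(graphics::par(op))
  graphics::image(seq_along(bgs), seq_along(labs), t(m), axes = FALSE,
                  xlab = "", ylab = "", main = readout,
                  col = grDevices::hcl.colors(25, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1, seq_along(bgs), bgs, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_along(labs), labs, las = 2, cex.axis = 0.6)
  invisible(m)
}

#' Select optimal drug combinations from a pairwise screen
#'
#' Filters the pair rows of a pairwise screen to those whose residency readout
#' does not exceed the per-background baseline residency in any background of
#' the screen (i.e. combinations that do not enhance Langerhans-cell
#' residency), then ranks the surviving pairs by ascending tumour growth
#' score. The attribute `optimal` holds the admissible pairs attaining the
#' minimum score.
#'
#' @param screen a pairwise `qn_screen` containing a `tumor_growth_score`
#'   column.
#' @param residency_node name of the residency readout.
#' @param max_score optional admissibility threshold on the growth score
#'   (default `Inf`: the filter is purely the residency criterion).
#' @return a ranked data.frame of admissible pairs with columns
#'   `perturbation_1`, `perturbation_2`, `tumor_growth_score` (worst across
#'   backgrounds) and `residency_ok`; attribute `optimal` is the subset with
#'   minimal score.
#' @export
qn_optimal_pairs <- function(screen, residency_node, max_score = Inf) {
  stopifnot(inherits(screen, "qn_screen"))
  if (!residency_node %in% names(screen))
    stop("residency readout '", residency_node, "' not in screen")
  if (!"tumor_growth_score" %in% names(screen))
    stop("screen lacks a tumor_growth_score column")
  base <- screen[is.na(screen$perturbation_1), ]
  baseline_res <- stats::setNames(base[[residency_node]], base$background)
  pairs <- screen[!is.na(screen$perturbation_2), ]
  if (!nrow(pairs)) stop("screen contains no pair rows; run qn_screen(pairwise = TRUE)")
  key <- paste(pairs$perturbation_1, pairs$perturbation_2, sep = " + ")
  agg <- lapply(split(pairs, key), function(d) {
    data.frame(perturbation_1 = d$perturbation_1[1],
               perturbation_2 = d$perturbation_2[1],
               tumor_growth_score = max(d$tumor_growth_score),
               residency_ok = all(!is.na(d[[residency_node]]) &
                                    d[[residency_node]] <= baseline_res[d$background]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[out$residency_ok & out$tumor_growth_score <= max_score, , drop = FALSE]
  out <- out[order(out$tumor_growth_score, out$perturbation_1, out$perturbation_2), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "optimal") <-
    out[!is.na(out$tumor_growth_score) &
          out$tumor_growth_score == suppressWarnings(min(out$tumor_growth_score)), ,
        drop = FALSE]
  out
}
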