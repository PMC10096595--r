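# Scoring model predictions against experiment tables.
#
# An experiment record fixes a background, applies perturbations, and states
# one or more expected measurements for readout nodes. Expectations come in
# three dialects, because literature readouts differ in precision:
#   level     - an absolute reported level (exact match)
#   range     - an interval [lo, hi] that must contain the reported level
#   direction - "increase" / "decrease" / "unchanged" relative to the
#               background-only baseline, with strict inequalities (ties count
#               as unchanged)

#' Construct an experiment record
#'
#' @param id record identifier (used in error messages and reports).
#' @param background a `qn_background` or a background name resolved at
#'   scoring time.
#' @param perturbations list of `qn_perturbation`/`qn_drug` (possibly empty).
#' @param measurements a list of measurements, each a list with fields `node`,
#'   `kind` (`"level"`, `"range"`, `"direction"`) and `value` (a level, a
#'   length-2 numeric `c(lo, hi)`, or one of the three direction strings).
#' @return an object of class `qn_experiment`.
#' @examples
#' qn_experiment("ex1", qn_background("healthy", c(In = 0)),
#'               list(qn_knockout("A")),
#'               list(list(node = "B", kind = "direction", value = "decrease")))
#' @export
qn_experiment <- function(id, background, perturbations = list(), measurements) {
  stopifnot(length(measurements) >= 1)
  for (m in measurements) {
    stopifnot(all(c("node", "kind", "value") %in% names(m)))
    if (!m$kind %in% c("level", "range", "direction"))
      stop("record '", id, "': unknown expectation kind '", m$kind, "'")
    if (m$kind == "direction" &&
        !m$value %in% c("increase", "decrease", "unchanged"))
      stop("record '", id, "': unknown direction '", m$value, "'")
    if (m$kind == "range" && length(m$value) != 2)
      stop("record '", id, "': range expectation needs c(lo, hi)")
  }
  if (inherits(perturbations, "qn_perturbation")) perturbations <- list(perturbations)
  structure(list(id = id, background = background,
                 perturbations = perturbations, measurements = measurements),
            class = "qn_experiment")
}

resolve_background <- function(record, backgrounds) {
  bg <- record$background
  if (inherits(bg, "qn_background")) return(bg)
  if (is.character(bg)) {
    if (is.null(backgrounds) || is.null(backgrounds[[bg]]))
      stop("record '", record$id, "': unknown background '", bg, "'")
    return(backgrounds[[bg]])
  }
  stop("record '", record$id, "': invalid background")
}

# reported levels of `nodes` under background+perturbations; method "auto"
# uses exhaustive enumeration for small state spaces (exact limits) and
# interval bounds otherwise.
predict_levels <- function(network, background, perturbations, nodes,
                           method = c("auto", "bounds", "enumerate"),
                           enum_cap = 1e4) {
  method <- match.arg(method)
  net <- qn_apply(network, background)
  if (length(perturbations)) net <- qn_apply(net, perturbations)
  use_enum <- switch(method,
    enumerate = TRUE,
    bounds = FALSE,
    auto = qn_state_space_size(net) <= enum_cap)
  res <- if (use_enum) qn_attractors(net, state_space_cap = max(enum_cap, 1e6))
         else qn_stable_bounds(net)
  qn_reported_level(res, nodes)
}

#' Reproduce one experiment in the model
#'
#' Applies the record's background and perturbations, analyses the stable
#' states and returns the reported level of every measured readout, together
#' with the background-only baseline needed for directional expectations.
#'
#' @param network a `qn_network`.
#' @param record a `qn_experiment`.
#' @param backgrounds optional named list of `qn_background`s used to resolve
#'   records that reference backgrounds by name.
#' @param method `"auto"` (default; exhaustive enumeration when the state
#'   space is at most `1e4` states, interval bounds otherwise), `"bounds"`, or
#'   `"enumerate"`.
#' @return a list with `predicted` and `baseline` (named numeric vectors).
#' @export
qn_run_experiment <- function(network, record, backgrounds = NULL,
                              method = "auto") {
  stopifnot(inherits(record, "qn_experiment"))
  bg <- resolve_background(record, backgrounds)
  nodes <- unique(vapply(record$measurements, `[[`, "", "node"))
  miss <- setdiff(nodes, names(network$nodes))
  if (length(miss))
    stop("record '", record$id, "': readout node(s) not in network: ",
         paste(miss, collapse = ", "))
  predicted <- predict_levels(network, bg, record$perturbations, nodes, method)
  needs_base <- any(vapply(record$measurements, `[[`, "", "kind") == "direction")
  baseline <- if (needs_base) predict_levels(network, bg, list(), nodes, method)
              else stats::setNames(rep(NA_real_, length(nodes)), nodes)
  list(predicted = predicted, baseline = baseline)
}

measurement_pass <- function(kind, value, predicted, baseline) {
  switch(kind,
    level = isTRUE(predicted == as.numeric(value)),
    range = isTRUE(predicted >= value[1] && predicted <= value[2]),
    direction = switch(value,
      increase = isTRUE(predicted > baseline),
      decrease = isTRUE(predicted < baseline),
      unchanged = isTRUE(predicted == baseline)))
}

#' Score a set of experiments against the model
#'
#' Runs every record with [qn_run_experiment()] and scores each measurement
#' individually (one experiment may contribute several measurements). Scoring
#' is deterministic and independent of record order.
#'
#' @inheritParams qn_run_experiment
#' @param records non-empty list of `qn_experiment`s.
#' @return an object of class `qn_validation`: a per-measurement data.frame
#'   (`id`, `node`, `kind`, `expected`, `predicted`, `baseline`, `pass`,
#'   `note`) with attributes `n_pass`, `n_total`, `percent`.
#' @export
qn_score_experiments <- function(network, records, backgrounds = NULL,
                                 method = "auto") {
  if (inherits(records, "qn_experiment")) records <- list(records)
  if (!length(records))
    stop("empty experiment list: nothing to score")
  rows <- list()
  for (rec in records) {
    res <- tryCatch(qn_run_experiment(network, rec, backgrounds, method),
                    error = function(e) e)
    for (m in rec$measurements) {
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          id = rec$id, node = m$node, kind = m$kind,
          expected = format_expectation(m), predicted = NA_real_,
          baseline = NA_real_, pass = FALSE,
          note = conditionMessage(res), stringsAsFactors = FALSE)
        next
      }
      p <- res$predicted[[m$node]]
      b <- res$baseline[[m$node]]
      rows[[length(rows) + 1L]] <- data.frame(
        id = rec$id, node = m$node, kind = m$kind,
        expected = format_expectation(m), predicted = p, baseline = b,
        pass = measurement_pass(m$kind, m$value, p, b),
        note = NA_character_, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(tab,
            n_pass = sum(tab$pass), n_total = nrow(tab),
            percent = 100 * sum(tab$pass) / nrow(tab),
            class = c("qn_validation", "data.frame"))
}

format_expectation <- function(m) {
  switch(m$kind,
    level = as.character(m$value),
    range = paste0("[", m$value[1], ", ", m$value[2], "]"),
    direction = as.character(m$value))
}

#' @export
print.qn_validation <- function(x, ...) {
  cat(sprintf("Model validation: %d/%d measurements correct (%.1f%%)\n",
              attr(x, "n_pass"), attr(x, "n_total"), attr(x, "percent")))
  fails <- x[!x$pass, , drop = FALSE]
  if (nrow(fails)) {
    cat("Failing measurements:\n")
    print(as.data.frame(fails), row.names = FALSE)
  }
  invisible(x)
}
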