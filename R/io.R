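# Model, drug, background and experiment interchange.
#
# Two formats: BMA-style model JSON (Model.Variables with
# Id/Name/RangeFrom/RangeTo/Formula and Model.Relationships with
# FromVariable/ToVariable/Type Activator|Inhibitor), so models can be opened
# in the BioModelAnalyzer web tool; and plain CSV tables (the authoring
# format). All readers validate and reject malformed input rather than
# coercing. Layout blocks of BMA JSON are preserved opaquely on round-trip and
# never interpreted.

#' Read a BMA-style model JSON document
#'
#' @param path path to a JSON file (or a JSON string).
#' @param name optional model name override.
#' @return a validated `qn_network`. An empty `Formula` expands to the default
#'   target function. `var(<id>)` references by numeric variable id are
#'   rewritten to the variable's name.
#' @export
qn_read_bma <- function(path, name = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  model <- if (!is.null(doc$Model)) doc$Model else doc
  if (is.null(model$Variables))
    stop("qn_format_error: missing $.Model.Variables")
  vars <- model$Variables
  get_field <- function(v, field, i) {
    if (is.null(v[[field]]))
      stop(sprintf("qn_format_error: missing $.Model.Variables[%d].%s", i, field))
    v[[field]]
  }
  nodes <- do.call(rbind, lapply(seq_along(vars), function(i) {
    v <- vars[[i]]
    data.frame(id = as.character(get_field(v, "Id", i)),
               name = get_field(v, "Name", i),
               min = as.integer(get_field(v, "RangeFrom", i)),
               max = as.integer(get_field(v, "RangeTo", i)),
               formula = if (is.null(v$Formula)) "" else as.character(v$Formula),
               kind = if (is.null(v$Kind)) "protein" else as.character(v$Kind),
               stringsAsFactors = FALSE)
  }))
  rels <- model$Relationships
  edges <- if (length(rels)) do.call(rbind, lapply(seq_along(rels), function(i) {
    r <- rels[[i]]
    for (f in c("FromVariable", "ToVariable", "Type"))
      if (is.null(r[[f]]))
        stop(sprintf("qn_format_error: missing $.Model.Relationships[%d].%s", i, f))
    ty <- as.character(r$Type)
    if (!ty %in% c("Activator", "Inhibitor"))
      stop(sprintf("qn_format_error: unknown Relationship Type '%s' at $.Model.Relationships[%d]",
                   ty, i))
    data.frame(source = as.character(r$FromVariable),
               target = as.character(r$ToVariable),
               sign = if (ty == "Activator") "activating" else "inhibiting",
               stringsAsFactors = FALSE)
  })) else NULL
  # edge endpoints are variable ids; map to names
  id2name <- stats::setNames(nodes$name, nodes$id)
  if (!is.null(edges)) {
    bad <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(bad))
      stop("qn_format_error: relationship references unknown variable id(s): ",
           paste(bad, collapse = ", "))
    edges$source <- unname(id2name[edges$source])
    edges$target <- unname(id2name[edges$target])
  }
  fml <- nodes$formula
  fml <- vapply(fml, rewrite_var_ids, "", id2name = id2name)
  keep <- nzchar(fml) & fml != "default"
  functions <- if (any(keep)) stats::setNames(fml[keep], nodes$name[keep]) else NULL
  net <- qn_network(nodes[, c("name", "min", "max", "kind")], edges, functions,
                    name = name %||% (model$Name %||% "BMA model"))
  attr(net, "bma_ids") <- stats::setNames(nodes$id, nodes$name)
  attr(net, "bma_layout") <- doc$Layout
  net
}

# rewrite var(3) to var(Name) using the id map; formulas already written with
# names pass through byte-identically (round-trip stability)
rewrite_var_ids <- function(formula, id2name) {
  if (!nzchar(formula)) return(formula)
  e <- tryCatch(str2lang(formula), error = function(err) NULL)
  if (is.null(e) || !is.language(e)) return(formula)
  changed <- FALSE
  walk <- function(x) {
    if (is.call(x)) {
      if (identical(as.character(x[[1]]), "var") && length(x) == 2 &&
          is.numeric(x[[2]])) {
        id <- as.character(x[[2]])
        if (!is.null(id2name[[id]])) {
          x[[2]] <- as.symbol(id2name[[id]])
          changed <<- TRUE
        }
        return(x)
      }
      for (i in seq_along(x)[-1]) x[[i]] <- walk(x[[i]])
    }
    x
  }
  out <- walk(e)
  if (changed) paste(deparse(out), collapse = " ") else formula
}

#' Write a network as BMA-style model JSON
#'
#' Emits a canonical key order so diffs are meaningful; a Layout block read by
#' [qn_read_bma()] from the same file is carried through opaquely.
#'
#' @param network a `qn_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
qn_write_bma <- function(network, path) {
  ids <- attr(network, "bma_ids")
  if (is.null(ids))
    ids <- stats::setNames(as.character(seq_along(network$nodes)),
                           names(network$nodes))
  vars <- lapply(names(network$nodes), function(nm) {
    nd <- network$nodes[[nm]]
    list(Id = as.integer(ids[[nm]]), Name = nm,
         RangeFrom = nd$min, RangeTo = nd$max,
         Formula = if (identical(nd$target_src, "default")) "" else nd$target_src,
         Kind = nd$kind)
  })
  rels <- lapply(seq_len(nrow(network$edges)), function(i) {
    list(Id = i,
         FromVariable = as.integer(ids[[network$edges$source[i]]]),
         ToVariable = as.integer(ids[[network$edges$target[i]]]),
         Type = if (network$edges$sign[i] == "activating") "Activator" else "Inhibitor")
  })
  doc <- list(Model = list(Name = network$name, Variables = vars,
                           Relationships = rels))
  layout <- attr(network, "bma_layout")
  if (!is.null(layout)) doc$Layout <- layout
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a model from node/edge/function CSV tables
#'
#' CSV dialects (UTF-8, header row): `nodes_csv` has columns
#' `name,min,max,kind`; `edges_csv` has `source,target,sign`; the optional
#' `functions_csv` has `node,expression`. Nodes absent from `functions_csv`
#' get the default target function.
#'
#' @param nodes_csv,edges_csv,functions_csv file paths (`functions_csv` and
#'   `edges_csv` may be `NULL`).
#' @param name model name.
#' @return a validated `qn_network`.
#' @export
qn_read_model_tables <- function(nodes_csv, edges_csv = NULL,
                                 functions_csv = NULL, name = "model") {
  nodes <- utils::read.csv(nodes_csv, stringsAsFactors = FALSE)
  need <- setdiff(c("name", "min", "max"), names(nodes))
  if (length(need))
    stop("qn_format_error: nodes table lacks column(s): ", paste(need, collapse = ", "))
  if (any(is.na(suppressWarnings(as.integer(nodes$min)))) ||
      any(is.na(suppressWarnings(as.integer(nodes$max)))))
    stop("qn_format_error: non-integer node range in nodes table")
  edges <- if (!is.null(edges_csv)) utils::read.csv(edges_csv, stringsAsFactors = FALSE)
           else NULL
  functions <- NULL
  if (!is.null(functions_csv)) {
    fn <- utils::read.csv(functions_csv, stringsAsFactors = FALSE)
    if (!all(c("node", "expression") %in% names(fn)))
      stop("qn_format_error: functions table needs columns node,expression")
    unknown <- setdiff(fn$node, nodes$name)
    if (length(unknown))
      stop("qn_format_error: functions table names unknown node(s): ",
           paste(unknown, collapse = ", "))
    functions <- fn
  }
  qn_network(nodes, edges, functions, name = name)
}

#' Write a network as node/edge/function CSV tables
#'
#' @param network a `qn_network`.
#' @param dir output directory (created if missing); writes `nodes.csv`,
#'   `edges.csv` and `functions.csv`.
#' @return `dir`, invisibly.
#' @export
qn_write_model_tables <- function(network, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nodes <- data.frame(name = names(network$nodes),
                      min = vapply(network$nodes, `[[`, 0L, "min"),
                      max = vapply(network$nodes, `[[`, 0L, "max"),
                      kind = vapply(network$nodes, `[[`, "", "kind"),
                      stringsAsFactors = FALSE)
  utils::write.csv(nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  utils::write.csv(network$edges, file.path(dir, "edges.csv"), row.names = FALSE)
  expl <- !vapply(network$nodes, function(n) identical(n$target_src, "default"), TRUE)
  fns <- data.frame(node = names(network$nodes)[expl],
                    expression = vapply(network$nodes[expl], `[[`, "", "target_src"),
                    stringsAsFactors = FALSE)
  utils::write.csv(fns, file.path(dir, "functions.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read drug definitions from CSV
#'
#' Columns: `drug,class,node,override` with one row per node override; the
#' `override` column holds either an integer clamp level or a replacement
#' target expression.
#'
#' @param path CSV path.
#' @param network optional `qn_network` to cross-check override nodes against.
#' @return a named list of `qn_drug`s (in first-appearance order).
#' @export
qn_read_drugs <- function(path, network = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("drug", "node", "override"), names(tab))
  if (length(need))
    stop("qn_format_error: drugs table lacks column(s): ", paste(need, collapse = ", "))
  if (!is.null(network)) {
    bad <- which(!tab$node %in% names(network$nodes))
    if (length(bad))
      stop("qn_format_error: drugs table row(s) ", paste(bad, collapse = ", "),
           " target unknown node(s): ",
           paste(unique(tab$node[bad]), collapse = ", "))
  }
  out <- list()
  for (nm in unique(tab$drug)) {
    d <- tab[tab$drug == nm, , drop = FALSE]
    ov <- lapply(d$override, function(x) {
      n <- suppressWarnings(as.integer(x))
      if (!is.na(n) && as.character(n) == trimws(x)) n else as.character(x)
    })
    names(ov) <- d$node
    cls <- if ("class" %in% names(d)) d$class[1] else NA_character_
    out[[nm]] <- qn_drug(nm, ov, class = cls)
  }
  out
}

#' Read backgrounds from CSV
#'
#' Columns: `background,node,level`, one row per clamp.
#'
#' @param path CSV path.
#' @param network optional network for cross-checking clamp nodes and levels.
#' @return a named list of `qn_background`s.
#' @export
qn_read_backgrounds <- function(path, network = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("background", "node", "level"), names(tab))
  if (length(need))
    stop("qn_format_error: backgrounds table lacks column(s): ",
         paste(need, collapse = ", "))
  lv <- suppressWarnings(as.integer(tab$level))
  if (any(is.na(lv)))
    stop("qn_format_error: non-integer clamp level in backgrounds table row(s) ",
         paste(which(is.na(lv)), collapse = ", "))
  if (!is.null(network)) {
    for (i in seq_len(nrow(tab))) {
      nd <- network$nodes[[tab$node[i]]]
      if (is.null(nd))
        stop("qn_format_error: backgrounds table row ", i,
             " clamps unknown node '", tab$node[i], "'")
      if (lv[i] < nd$min || lv[i] > nd$max)
        stop("qn_format_error: backgrounds table row ", i, " clamps '",
             tab$node[i], "' to ", lv[i], ", outside [", nd$min, ", ", nd$max, "]")
    }
  }
  out <- list()
  for (nm in unique(tab$background)) {
    d <- tab[tab$background == nm, , drop = FALSE]
    out[[nm]] <- qn_background(nm, stats::setNames(as.integer(d$level), d$node))
  }
  out
}

# parse one perturbation token: "KO:X", "OE:X", "X=2", "drug:Name"
parse_perturbation_token <- function(tok, drugs) {
  tok <- trimws(tok)
  if (grepl("^KO:", tok)) return(qn_knockout(sub("^KO:", "", tok)))
  if (grepl("^OE:", tok)) return(qn_overexpress(sub("^OE:", "", tok)))
  if (grepl("^drug:", tok)) {
    nm <- sub("^drug:", "", tok)
    if (is.null(drugs[[nm]]))
      stop("qn_format_error: unknown drug '", nm, "' (no matching drugs table entry)")
    return(drugs[[nm]])
  }
  if (grepl("=", tok, fixed = TRUE)) {
    parts <- strsplit(tok, "=", fixed = TRUE)[[1]]
    return(qn_set_level(trimws(parts[1]), as.integer(parts[2])))
  }
  stop("qn_format_error: cannot parse perturbation token '", tok, "'")
}

#' Read experiment records from CSV
#'
#' Columns: `id,background,perturbations,readout,expectation_kind,`
#' `expectation_value`. One row per measurement; rows sharing an `id` form one
#' experiment. `perturbations` is a `;`-separated list of tokens — `KO:Node`,
#' `OE:Node`, `Node=level`, `drug:Name` — or empty for the baseline.
#' `expectation_value` is a level, a range `lo..hi`, or
#' increase/decrease/unchanged.
#'
#' @param path CSV path.
#' @param backgrounds named list of `qn_background`s the records refer to.
#' @param drugs named list of `qn_drug`s for `drug:` tokens.
#' @return a list of `qn_experiment`s.
#' @export
qn_read_experiments <- function(path, backgrounds, drugs = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- setdiff(c("id", "background", "readout", "expectation_kind",
                    "expectation_value"), names(tab))
  if (length(need))
    stop("qn_format_error: experiments table lacks column(s): ",
         paste(need, collapse = ", "))
  if (!nrow(tab)) stop("qn_format_error: experiments table is empty")
  bad_bg <- setdiff(unique(tab$background), names(backgrounds))
  if (length(bad_bg))
    stop("qn_format_error: experiments table references undefined background(s): ",
         paste(bad_bg, collapse = ", "))
  records <- list()
  for (id in unique(tab$id)) {
    d <- tab[tab$id == id, , drop = FALSE]
    if (length(unique(d$background)) != 1)
      stop("qn_format_error: record '", id, "' mixes backgrounds")
    ptxt <- if ("perturbations" %in% names(d)) trimws(d$perturbations[1]) else ""
    perts <- if (nzchar(ptxt))
      lapply(strsplit(ptxt, ";", fixed = TRUE)[[1]],
             parse_perturbation_token, drugs = drugs)
      else list()
    meas <- lapply(seq_len(nrow(d)), function(i) {
      kind <- d$expectation_kind[i]
      val <- trimws(d$expectation_value[i])
      value <- switch(kind,
        level = as.numeric(val),
        range = {
          parts <- as.numeric(strsplit(val, "..", fixed = TRUE)[[1]])
          if (length(parts) != 2 || anyNA(parts))
            stop("qn_format_error: record '", id, "': bad range '", val, "'")
          parts
        },
        direction = val,
        stop("qn_format_error: record '", id, "': unknown expectation kind '",
             kind, "'"))
      list(node = d$readout[i], kind = kind, value = value)
    })
    records[[length(records) + 1L]] <-
      qn_experiment(id, backgrounds[[d$background[1]]], perts, meas)
  }
  records
}

#' Write screen results to CSV and/or JSON
#'
#' @param screen a `qn_screen`.
#' @param csv,json output paths (either may be `NULL`).
#' @return invisibly, the screen.
#' @export
qn_write_screen <- function(screen, csv = NULL, json = NULL) {
  if (!is.null(csv))
    utils::write.csv(as.data.frame(screen), csv, row.names = FALSE, na = "")
  if (!is.null(json))
    jsonlite::write_json(as.data.frame(screen), json, dataframe = "rows",
                         na = "null", auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(screen)
}

#' Write a validation report to JSON and/or text
#'
#' @param report a `qn_validation`.
#' @param json,txt output paths (either may be `NULL`).
#' @return invisibly, the report.
#' @export
qn_write_validation <- function(report, json = NULL, txt = NULL) {
  if (!is.null(json))
    jsonlite::write_json(
      list(n_pass = attr(report, "n_pass"), n_total = attr(report, "n_total"),
           percent = attr(report, "percent"),
           measurements = as.data.frame(report)),
      json, dataframe = "rows", na = "null", auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  if (!is.null(txt)) {
    con <- file(txt, "w"); on.exit(close(con))
    sink(con); print(report); sink()
  }
  invisible(report)
}
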