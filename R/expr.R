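# Target-function expression language.
#
# Grammar (a restriction of R expression syntax, parsed with base R and then
# validated node by node):
#   expr := integer constant
#         | var(NAME)
#         | expr + expr | expr - expr | -expr
#         | const * expr | expr * const | expr / const
#         | avg(expr, ...) | min(expr, ...) | max(expr, ...)
#         | ceil(expr) | floor(expr)
# Multiplication must involve a constant factor and division a non-zero constant
# denominator, so that interval evaluation of any expression stays sound and
# exact for the stability analysis.

QN_AST_OPS <- c("+", "-", "*", "/", "avg", "min", "max", "ceil", "floor")

ast_const <- function(num, den = 1) list(op = "const", v = qr_bare(num, den))
ast_var <- function(name) list(op = "var", name = name)
ast_call <- function(op, args) list(op = op, args = args)

ast_is_const <- function(ast) identical(ast$op, "const")

# fold an all-constant call into a constant node
ast_fold <- function(op, args) {
  if (!all(vapply(args, ast_is_const, TRUE))) return(ast_call(op, args))
  vs <- lapply(args, `[[`, "v")
  v <- switch(op,
    "+" = qr_add(vs[[1]], vs[[2]]),
    "-" = if (length(vs) == 1) qr_bare(-vs[[1]][1], vs[[1]][2]) else qr_sub(vs[[1]], vs[[2]]),
    "*" = qr_mul(vs[[1]], vs[[2]]),
    "/" = qr_div(vs[[1]], vs[[2]]),
    "avg" = qr_mean(vs),
    "min" = qr_min(vs),
    "max" = qr_max(vs),
    "ceil" = qr_ceil(vs[[1]]),
    "floor" = qr_floor(vs[[1]])
  )
  list(op = "const", v = v)
}

lang_to_ast <- function(e) {
  if (is.numeric(e)) {
    if (length(e) != 1 || is.na(e) || e != round(e))
      stop("qn_parse_error: only integer constants are allowed, got ", deparse(e))
    return(ast_const(e))
  }
  if (is.symbol(e))
    stop("qn_parse_error: bare name '", as.character(e),
         "' is not allowed; regulator references must be written var(",
         as.character(e), ")")
  if (!is.call(e)) stop("qn_parse_error: unsupported construct ", deparse(e))
  op <- as.character(e[[1]])
  args_lang <- as.list(e)[-1]
  if (op == "(") return(lang_to_ast(args_lang[[1]]))
  if (op == "var") {
    if (length(args_lang) != 1)
      stop("qn_parse_error: var() takes exactly one regulator name")
    a <- args_lang[[1]]
    nm <- if (is.symbol(a)) as.character(a)
          else if (is.character(a)) a
          else stop("qn_parse_error: var() argument must be a name, got ", deparse(a))
    return(ast_var(nm))
  }
  if (!op %in% QN_AST_OPS)
    stop("qn_parse_error: unsupported operator or function '", op, "' in ", deparse(e))
  args <- lapply(args_lang, lang_to_ast)
  if (op %in% c("ceil", "floor") && length(args) != 1)
    stop("qn_parse_error: ", op, "() takes exactly one argument")
  if (op %in% c("avg", "min", "max") && length(args) < 1)
    stop("qn_parse_error: ", op, "() needs at least one argument")
  if (op == "-" && length(args) == 1)
    return(ast_fold("-", list(ast_const(0), args[[1]])))
  if (op %in% c("+", "-", "*", "/") && length(args) != 2)
    stop("qn_parse_error: '", op, "' is binary")
  if (op == "*" && !ast_is_const(args[[1]]) && !ast_is_const(args[[2]]))
    stop("qn_parse_error: multiplication must involve a constant factor: ", deparse(e))
  if (op == "/") {
    if (!ast_is_const(args[[2]]))
      stop("qn_parse_error: division denominator must be a constant: ", deparse(e))
    if (args[[2]]$v[1] == 0)
      stop("qn_parse_error: division by zero constant")
  }
  ast_fold(op, args)
}

#' Parse a target-function expression
#'
#' Parses the expression language used for node target functions: integer
#' constants, `var(Name)` regulator references, `+`, `-`, constant
#' multiplication, constant division, n-ary `avg`, `min`, `max`, and unary
#' `ceil`/`floor`. When `regulators` is supplied, every `var()` reference must
#' name one of them.
#'
#' @param text expression string, e.g. `"min(var(RAF), var(MEK)) + 1"`.
#' @param regulators optional character vector of admissible regulator names
#'   (the sources of the node's incoming edges).
#' @return an abstract syntax tree of class `qn_target`.
#' @examples
#' qn_parse_target("min(var(RAF), var(MEK)) + 1", regulators = c("RAF", "MEK"))
#' @export
qn_parse_target <- function(text, regulators = NULL) {
  stopifnot(is.character(text), length(text) == 1)
  e <- tryCatch(str2lang(text), error = function(err)
    stop("qn_parse_error: invalid syntax in \"", text, "\": ",
         conditionMessage(err), call. = FALSE))
  ast <- lang_to_ast(e)
  if (!is.null(regulators)) {
    bad <- setdiff(ast_vars(ast), regulators)
    if (length(bad))
      stop("qn_parse_error: unresolved regulator reference(s) ",
           paste0("var(", bad, ")", collapse = ", "),
           " in \"", text, "\"", call. = FALSE)
  }
  structure(ast, class = "qn_target")
}

# all var names referenced, with repeats
ast_vars <- function(ast) {
  if (ast$op == "var") return(ast$name)
  if (ast$op == "const") return(character())
  unlist(lapply(ast$args, ast_vars))
}

#' Deparse a target-function AST back to its canonical text form
#'
#' The output re-parses to an identical AST (`qn_parse_target` o
#' `qn_deparse_target` is the identity on ASTs).
#'
#' @param ast a `qn_target` AST.
#' @return a single character string.
#' @export
qn_deparse_target <- function(ast) {
  dep <- function(a, parent_prec = 0) {
    if (a$op == "const") {
      v <- a$v
      if (v[2] == 1) return(if (v[1] < 0) paste0("(", v[1], ")") else format(v[1]))
      return(paste0("(", v[1], "/", v[2], ")"))
    }
    if (a$op == "var") {
      nm <- a$name
      if (!grepl("^[A-Za-z.][A-Za-z0-9._]*$", nm)) nm <- paste0("`", nm, "`")
      return(paste0("var(", nm, ")"))
    }
    if (a$op %in% c("avg", "min", "max", "ceil", "floor"))
      return(paste0(a$op, "(", paste(vapply(a$args, dep, ""), collapse = ", "), ")"))
    prec <- if (a$op %in% c("+", "-")) 1 else 2
    s <- paste(dep(a$args[[1]], prec),
               a$op,
               dep(a$args[[2]], prec + 1))  # left-assoc; right side binds tighter
    if (prec < parent_prec) paste0("(", s, ")") else s
  }
  dep(ast)
}

# Exact evaluation. env: function(name) -> bare rational c(num, den)
ast_eval <- function(ast, env) {
  op <- ast$op
  if (op == "const") return(ast$v)
  if (op == "var") return(env(ast$name))
  vs <- lapply(ast$args, ast_eval, env = env)
  switch(op,
    "+" = qr_add(vs[[1]], vs[[2]]),
    "-" = qr_sub(vs[[1]], vs[[2]]),
    "*" = qr_mul(vs[[1]], vs[[2]]),
    "/" = qr_div(vs[[1]], vs[[2]]),
    "avg" = qr_mean(vs),
    "min" = qr_min(vs),
    "max" = qr_max(vs),
    "ceil" = qr_ceil(vs[[1]]),
    "floor" = qr_floor(vs[[1]])
  )
}

# Sound interval evaluation. env: function(name) -> list(lo=, hi=) of bare
# rationals (already scaled). Every operator in the grammar is monotone in each
# argument (subtraction is anti-monotone in its second argument; constant
# multiplication flips with the sign of the constant), so componentwise
# propagation is sound; it is exact whenever no regulator appears twice.
ast_eval_interval <- function(ast, env) {
  op <- ast$op
  if (op == "const") return(list(lo = ast$v, hi = ast$v))
  if (op == "var") return(env(ast$name))
  vs <- lapply(ast$args, ast_eval_interval, env = env)
  los <- lapply(vs, `[[`, "lo")
  his <- lapply(vs, `[[`, "hi")
  switch(op,
    "+" = list(lo = qr_add(los[[1]], los[[2]]), hi = qr_add(his[[1]], his[[2]])),
    "-" = list(lo = qr_sub(los[[1]], his[[2]]), hi = qr_sub(his[[1]], los[[2]])),
    "*" = {
      # one side is a constant interval (enforced by the grammar)
      if (ast_is_const(ast$args[[1]])) { c0 <- vs[[1]]$lo; x <- vs[[2]] }
      else { c0 <- vs[[2]]$lo; x <- vs[[1]] }
      if (c0[1] >= 0) list(lo = qr_mul(c0, x$lo), hi = qr_mul(c0, x$hi))
      else list(lo = qr_mul(c0, x$hi), hi = qr_mul(c0, x$lo))
    },
    "/" = {
      c0 <- vs[[2]]$lo
      if (c0[1] >= 0) list(lo = qr_div(los[[1]], c0), hi = qr_div(his[[1]], c0))
      else list(lo = qr_div(his[[1]], c0), hi = qr_div(los[[1]], c0))
    },
    "avg" = list(lo = qr_mean(los), hi = qr_mean(his)),
    "min" = list(lo = qr_min(los), hi = qr_min(his)),
    "max" = list(lo = qr_max(los), hi = qr_max(his)),
    "ceil" = list(lo = qr_ceil(los[[1]]), hi = qr_ceil(his[[1]])),
    "floor" = list(lo = qr_floor(los[[1]]), hi = qr_floor(his[[1]]))
  )
}

#' @export
print.qn_target <- function(x, ...) {
  cat("<target function> ", qn_deparse_target(x), "\n", sep = "")
  invisible(x)
}
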