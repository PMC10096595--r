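# Exact rational arithmetic on length-2 numeric vectors c(num, den), den > 0.
# All magnitudes in qualitative networks are tiny (levels <= 7, denominators are
# products of regulator counts and constant divisors), so doubles hold every
# intermediate integer exactly.

qr_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

#' Construct an exact rational number
#'
#' Rationals are stored as a length-2 numeric vector `c(numerator, denominator)`
#' in lowest terms with a positive denominator. They are used throughout the
#' package so that fixed points and interval bounds are decided by exact
#' comparison, never by floating-point tolerance.
#'
#' @param num integer numerator.
#' @param den integer denominator (non-zero).
#' @return a length-2 numeric vector of class `qn_rational`.
#' @examples
#' qn_rational(1, 3)
#' as.numeric(qn_rational(3, 2))
#' @export
qn_rational <- function(num, den = 1) {
  if (den == 0) stop("rational with zero denominator")
  if (den < 0) { num <- -num; den <- -den }
  g <- qr_gcd(num, den)
  if (g > 1) { num <- num / g; den <- den / g }
  structure(c(num, den), class = "qn_rational")
}

qr_bare <- function(num, den) {
  # internal fast path: no class attribute
  if (den < 0) { num <- -num; den <- -den }
  g <- qr_gcd(num, den)
  if (g > 1) c(num / g, den / g) else c(num, den)
}

qr_add <- function(a, b) qr_bare(a[1] * b[2] + b[1] * a[2], a[2] * b[2])
qr_sub <- function(a, b) qr_bare(a[1] * b[2] - b[1] * a[2], a[2] * b[2])
qr_mul <- function(a, b) qr_bare(a[1] * b[1], a[2] * b[2])
qr_div <- function(a, b) {
  if (b[1] == 0) stop("rational division by zero")
  qr_bare(a[1] * b[2], a[2] * b[1])
}
# sign of a - b
qr_cmp <- function(a, b) sign(a[1] * b[2] - b[1] * a[2])
qr_floor <- function(a) c(floor(a[1] / a[2]), 1)
qr_ceil <- function(a) c(ceiling(a[1] / a[2]), 1)

qr_mean <- function(xs) {
  acc <- c(0, 1)
  for (x in xs) acc <- qr_add(acc, x)
  qr_div(acc, c(length(xs), 1))
}

qr_min <- function(xs) {
  m <- xs[[1]]
  for (x in xs[-1]) if (qr_cmp(x, m) < 0) m <- x
  m
}

qr_max <- function(xs) {
  m <- xs[[1]]
  for (x in xs[-1]) if (qr_cmp(x, m) > 0) m <- x
  m
}

qr_num <- function(a) a[1] / a[2]

#' @export
as.numeric.qn_rational <- function(x, ...) x[1] / x[2]

#' @export
as.double.qn_rational <- function(x, ...) x[1] / x[2]

#' @export
format.qn_rational <- function(x, ...) {
  if (x[2] == 1) format(x[1]) else paste0(x[1], "/", x[2])
}

#' @export
print.qn_rational <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
Ops.qn_rational <- function(e1, e2) {
  to_q <- function(e) {
    if (inherits(e, "qn_rational")) unclass(e)
    else if (is.numeric(e) && length(e) == 1 && e == round(e)) c(e, 1)
    else stop("qn_rational arithmetic needs integer or qn_rational operands")
  }
  if (nargs() == 1) {
    if (.Generic == "-") return(structure(qr_bare(-e1[1], e1[2]), class = "qn_rational"))
    if (.Generic == "+") return(e1)
    stop("unsupported unary operator for qn_rational: ", .Generic)
  }
  a <- to_q(e1); b <- to_q(e2)
  switch(.Generic,
    "+" = structure(qr_add(a, b), class = "qn_rational"),
    "-" = structure(qr_sub(a, b), class = "qn_rational"),
    "*" = structure(qr_mul(a, b), class = "qn_rational"),
    "/" = structure(qr_div(a, b), class = "qn_rational"),
    "==" = qr_cmp(a, b) == 0,
    "!=" = qr_cmp(a, b) != 0,
    "<"  = qr_cmp(a, b) < 0,
    ">"  = qr_cmp(a, b) > 0,
    "<=" = qr_cmp(a, b) <= 0,
    ">=" = qr_cmp(a, b) >= 0,
    stop("unsupported operator for qn_rational: ", .Generic)
  )
}
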