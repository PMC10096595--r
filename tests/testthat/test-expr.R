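# Target-function expression language: parsing, evaluation, round-trips.

test_that("default target expansion follows the avg(pos) - avg(neg) rule", {
  net <- qn_network(
    nodes = data.frame(name = c("A", "B", "C", "X"), min = 0, max = 2),
    edges = data.frame(source = c("A", "B", "C"), target = "X",
                       sign = c("activating", "activating", "inhibiting")))
  # activators at {2, 0}, inhibitor at {1}: avg = 1 minus avg = 1 -> 0
  v <- qn_target_value(net, "X", c(A = 2, B = 0, C = 1, X = 0))
  expect_true(v == 0)
  # exactness: denominator divides |pos| * |neg|
  v2 <- qn_target_value(net, "X", c(A = 2, B = 1, C = 0, X = 0))
  expect_identical(unclass(v2)[2], 2)  # 3/2 exactly, not 1.4999...
  expect_equal(as.numeric(v2), 1.5)
})

test_that("explicit expressions parse and evaluate exactly", {
  ast <- qn_parse_target("min(var(RAF), var(MEK)) + 1")
  net <- qn_network(
    nodes = data.frame(name = c("RAF", "MEK", "OUT"), min = 0, max = 2),
    edges = data.frame(source = c("RAF", "MEK"), target = "OUT",
                       sign = "activating"),
    functions = c(OUT = "min(var(RAF), var(MEK)) + 1"))
  expect_true(qn_target_value(net, "OUT", c(RAF = 1, MEK = 2, OUT = 0)) == 2)

  cnet <- qn_network(nodes = data.frame(name = "K", min = 0, max = 2),
                     edges = NULL, functions = c(K = "2"))
  expect_true(qn_target_value(cnet, "K", c(K = 0)) == 2)
  expect_true(qn_target_value(cnet, "K", c(K = 2)) == 2)
})

test_that("regulators are rescaled into the regulated node's range", {
  net <- qn_network(
    nodes = data.frame(name = c("A", "X"), min = 0, max = c(2, 4)),
    edges = data.frame(source = "A", target = "X", sign = "activating"))
  expect_true(qn_target_value(net, "X", c(A = 1, X = 0)) == 2)
  expect_true(qn_target_value(net, "X", c(A = 2, X = 0)) == 4)
})

test_that("parse errors are specific", {
  expect_error(qn_parse_target("min(var(A), "), "qn_parse_error")
  expect_error(qn_parse_target("var(A) / var(B)"), "denominator")
  expect_error(qn_parse_target("var(A) * var(B)"), "constant factor")
  expect_error(qn_parse_target("A + 1"), "var\\(A\\)")
  expect_error(qn_parse_target("log(var(A))"), "unsupported")
  expect_error(qn_parse_target("var(A) / 0"), "zero")
  expect_error(qn_parse_target("var(B)", regulators = "A"), "unresolved")
  expect_error(qn_parse_target("1.5"), "integer constants")
})

test_that("parse-unparse-reparse is the identity on ASTs", {
  exprs <- c("2",
             "var(A)",
             "avg(var(A), var(B)) - avg(var(C))",
             "min(2, 2 * var(TNF))",
             "var(RTK) + (2 - var(PTEN)) / 2",
             "2 * floor(var(ERK) / 2)",
             "max(var(p53), 2 - var(NFkB) - var(AKT))",
             "ceil(avg(var(A), var(B), var(C)))",
             "-var(A) + 3",
             "min(var(E2F), avg(var(NFkB), var(AKT)))")
  for (e in exprs) {
    ast <- qn_parse_target(e)
    txt <- qn_deparse_target(ast)
    expect_identical(unclass(qn_parse_target(txt)), unclass(ast), label = e)
  }
})

test_that("rational arithmetic is exact and comparable", {
  third <- qn_rational(1, 3)
  expect_true(third + third + third == 1)
  expect_true(qn_rational(1, 2) > qn_rational(1, 3))
  expect_true(qn_rational(2, 4) == qn_rational(1, 2))
  expect_equal(as.numeric(qn_rational(7, 2)), 3.5)
  expect_error(qn_rational(1, 0), "zero denominator")
})
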