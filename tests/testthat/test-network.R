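# Network construction, validation diagnostics, and level rescaling.

test_that("scaling maps endpoints to endpoints and is monotone", {
  expect_equal(as.numeric(qn_scale(1, c(0, 2), c(0, 4))), 2)
  expect_equal(as.numeric(qn_scale(2, c(0, 2), c(0, 4))), 4)
  expect_equal(as.numeric(qn_scale(0, c(0, 2), c(0, 4))), 0)
  # identity on identical ranges
  for (v in 0:3) expect_equal(as.numeric(qn_scale(v, c(0, 3), c(0, 3))), v)
  # monotone, endpoints hit, for a few range pairs
  for (rng in list(list(c(0, 2), c(0, 7)), list(c(0, 3), c(0, 2)),
                   list(c(1, 4), c(0, 2)))) {
    vals <- vapply(rng[[1]][1]:rng[[1]][2],
                   function(v) as.numeric(qn_scale(v, rng[[1]], rng[[2]])), 0)
    expect_true(all(diff(vals) > 0))
    expect_equal(vals[1], rng[[2]][1])
    expect_equal(vals[length(vals)], rng[[2]][2])
  }
  expect_error(qn_scale(3, c(0, 2), c(0, 4)), "outside source range")
})

test_that("validation returns one diagnostic per violation", {
  ok <- two_node_mutual()
  expect_length(qn_validate(ok), 0)

  bad <- qn_network(
    nodes = data.frame(name = c("A", "A", "B", "C"),
                       min = c(0, 0, 0, 1), max = c(1, 1, 1, 1)),
    edges = data.frame(source = c("A", "X"), target = c("Z", "B"),
                       sign = "activating"),
    functions = c(B = "var(Q) + 1"),
    validate = FALSE)
  d <- qn_validate(bad)
  expect_true(any(grepl("duplicate node name: A", d)))
  expect_true(any(grepl("dangling edge: target 'Z'", d)))
  expect_true(any(grepl("dangling edge: source 'X'", d)))
  expect_true(any(grepl("degenerate range for node 'C'", d)))
  expect_true(any(grepl("var\\(Q\\) does not name an in-edge source", d)))

  expect_error(qn_network(nodes = data.frame(name = "A", min = 0, max = 0),
                          edges = NULL),
               "degenerate range")
})

test_that("states are checked against node ranges", {
  net <- two_node_mutual()
  expect_error(qn_step(net, c(A = 2, B = 0)), "outside range")
  expect_error(qn_step(net, c(A = 0)), "missing node")
  # unnamed full-length states are accepted in node order
  expect_identical(qn_step(net, c(0, 0)), c(A = 0L, B = 0L))
})

test_that("node kind tags never affect dynamics", {
  base <- data.frame(name = c("A", "B"), min = 0, max = 1)
  e <- data.frame(source = c("A", "B"), target = c("B", "A"), sign = "activating")
  n1 <- qn_network(cbind(base, kind = "protein"), e)
  n2 <- qn_network(cbind(base, kind = c("gene", "receptor")), e)
  for (a in 0:1) for (b in 0:1)
    expect_identical(qn_step(n1, c(A = a, B = b)), qn_step(n2, c(A = a, B = b)))
})

test_that("edge sign spellings are normalised", {
  n <- qn_network(
    nodes = data.frame(name = c("A", "B"), min = 0, max = 1),
    edges = data.frame(source = "A", target = "B",
                       sign = "Inhibitor"))
  expect_identical(n$edges$sign, "inhibiting")
  expect_error(qn_network(
    nodes = data.frame(name = c("A", "B"), min = 0, max = 1),
    edges = data.frame(source = "A", target = "B", sign = "sideways")),
    "unknown edge sign")
})
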