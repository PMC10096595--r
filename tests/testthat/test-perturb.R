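# Perturbations, backgrounds, screens, growth score and combination selection.

test_that("knockout, activation and set_level clamp the stable level", {
  net <- cascade3()
  b <- qn_stable_bounds(qn_apply(net, list(qn_set_level("In", 2),
                                           qn_knockout("N1"))))
  expect_equal(b$lo[b$node == "N1"], 0)
  expect_equal(b$hi[b$node == "N1"], 0)
  expect_equal(b$lo[b$node == "N2"], 0)  # knockout propagates

  b2 <- qn_stable_bounds(qn_apply(net, qn_overexpress("In")))
  expect_equal(b2$lo[b2$node == "In"], 2)

  expect_error(qn_apply(net, qn_set_level("In", 7)), "outside range")
  expect_error(qn_apply(net, qn_knockout("Nope")), "unknown node")
  # original untouched
  net2 <- qn_apply(net, qn_knockout("In"))
  expect_identical(net$nodes$In$target_src, "default")
  expect_identical(net2$nodes$In$target_src, "0")
})

test_that("disjoint perturbations commute; same-node is last-write-wins", {
  net <- cascade3()
  p1 <- qn_set_level("In", 1); p2 <- qn_knockout("N2")
  a <- qn_apply(net, list(p1, p2))
  b <- qn_apply(net, list(p2, p1))
  expect_identical(lapply(a$nodes, `[[`, "target_src"),
                   lapply(b$nodes, `[[`, "target_src"))
  c1 <- qn_apply(net, list(qn_knockout("In"), qn_overexpress("In")))
  expect_identical(c1$nodes$In$target_src, "2")
})

test_that("perturbing a background-clamped node overrides the clamp loudly", {
  net <- cascade3()
  bg <- qn_background("bg", c(In = 0))
  withbg <- qn_apply(net, bg)
  expect_message(out <- qn_apply(withbg, qn_set_level("In", 2)),
                 "overrides the background clamp")
  expect_identical(out$nodes$In$target_src, "2")
})

test_that("screens cover background x perturbation with baselines", {
  net <- cascade3()
  bgs <- list(qn_background("lo", c(In = 0)), qn_background("hi", c(In = 2)))
  sc <- qn_screen(net, bgs, list(), readouts = "N2")
  expect_equal(nrow(sc), 2)            # baselines only
  expect_true(all(is.na(sc$perturbation_1)))
  expect_equal(sc$N2[sc$background == "hi"], 2)
  expect_equal(sc$N2[sc$background == "lo"], 0)

  perts <- list(qn_knockout("N1"), qn_overexpress("N1"), qn_knockout("N2"))
  sc2 <- qn_screen(net, bgs, perts, readouts = "N2", pairwise = TRUE)
  # per background: 1 baseline + 3 singles + choose(3,2) pairs
  expect_equal(nrow(sc2), 2 * (1 + 3 + 3))
  expect_equal(sum(!is.na(sc2$perturbation_2)), 2 * 3)
  # clamped node's reported level equals its clamp regardless of the pairing
  ko_rows <- sc2[!is.na(sc2$perturbation_1) &
                   (sc2$perturbation_1 == "KO:N2" |
                      !is.na(sc2$perturbation_2) & sc2$perturbation_2 == "KO:N2"), ]
  expect_true(all(ko_rows$N2 == 0))
})

test_that("screen output is order-invariant and failures stay in-cell", {
  net <- cascade3()
  bgs <- list(qn_background("lo", c(In = 0)), qn_background("hi", c(In = 2)))
  perts <- list(qn_knockout("N1"), qn_overexpress("N2"))
  sc_a <- qn_screen(net, bgs, perts, readouts = "N2")
  sc_b <- qn_screen(net, rev(bgs), rev(perts), readouts = "N2")
  key <- function(d) {
    k <- paste(d$background, d$perturbation_1, d$perturbation_2)
    d[order(k), c("background", "perturbation_1", "N2")]
  }
  expect_equal(key(as.data.frame(sc_a)), key(as.data.frame(sc_b)),
               ignore_attr = TRUE)
})

test_that("growth score is proliferation minus apoptosis, exact on midpoints", {
  expect_equal(qn_growth_score(list(Proliferation = 2, Apoptosis = 1)), 1)
  expect_equal(qn_growth_score(list(Proliferation = 1, Apoptosis = 1)), 0)
  expect_equal(qn_growth_score(list(Proliferation = 1.5, Apoptosis = 0.5)), 1)
  expect_error(qn_growth_score(list(Proliferation = 1)), "lacks readout")
})

test_that("optimal-pair selection filters on residency and ranks by score", {
  # toy two-node 'tumour' with a residency reporter
  net <- qn_network(
    nodes = data.frame(name = c("Proliferation", "Apoptosis", "Res"),
                       min = 0, max = 2,
                       kind = c("process", "process", "process")),
    edges = NULL,
    functions = c(Proliferation = "2", Apoptosis = "0", Res = "1"))
  drugs <- list(
    qn_drug("good1", list(Proliferation = 0)),
    qn_drug("good2", list(Apoptosis = 2)),
    qn_drug("bad", list(Proliferation = 0, Res = 2)))  # raises residency
  sc <- qn_screen(net, qn_background("bg", c()), drugs,
                  readouts = c("Proliferation", "Apoptosis", "Res"),
                  pairwise = TRUE)
  ranked <- qn_optimal_pairs(sc, "Res")
  # pairs containing 'bad' are excluded
  expect_false(any(ranked$perturbation_1 == "bad" | ranked$perturbation_2 == "bad"))
  expect_equal(nrow(ranked), 1)
  expect_equal(ranked$tumor_growth_score, -2)
  expect_identical(sort(c(ranked$perturbation_1, ranked$perturbation_2)),
                   c("good1", "good2"))
  opt <- attr(ranked, "optimal")
  expect_equal(nrow(opt), 1)
})
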