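# Interval-refinement bounds on stable states and midpoint reporting.

test_that("a clamped cascade refines to a proven unique fixed point", {
  net <- qn_apply(cascade3(), qn_set_level("In", 2))
  b <- qn_stable_bounds(net)
  expect_true(attr(b, "proven_unique"))
  expect_true(all(b$lo == 2 & b$hi == 2))
  # enumeration agrees
  aset <- qn_attractors(net)
  expect_length(aset$attractors, 1)
  expect_identical(unname(aset$attractors[[1]]$states[[1]]), c(2L, 2L, 2L))
})

test_that("bistable motifs are reported as not proven unique", {
  b <- qn_stable_bounds(two_node_mutual())
  expect_false(attr(b, "proven_unique"))
  expect_true(all(b$lo == 0 & b$hi == 1))

  # clamped node is a singleton regardless of in-edges
  net <- qn_apply(two_node_mutual(), qn_set_level("A", 1))
  b2 <- qn_stable_bounds(net)
  expect_identical(b2$lo[b2$node == "A"], b2$hi[b2$node == "A"])
  expect_equal(b2$lo[b2$node == "A"], 1)
})

test_that("reported levels are fixed values or midpoints", {
  net <- qn_apply(cascade3(), qn_set_level("In", 2))
  expect_equal(unname(qn_reported_level(qn_stable_bounds(net), "N2")), 2)
  b <- qn_stable_bounds(two_node_mutual())
  expect_equal(unname(qn_reported_level(b, c("A", "B"))), c(0.5, 0.5))
  # midpoint of [0, 2] is 1
  idn <- qn_network(nodes = data.frame(name = "U", min = 0, max = 2), edges = NULL)
  expect_equal(unname(qn_reported_level(qn_stable_bounds(idn), "U")), 1)
  expect_error(qn_reported_level(b, "Zz"), "unknown node")
  # from attractor sets: limits across all attractor states
  aset <- qn_attractors(two_node_mutual())
  expect_equal(unname(qn_reported_level(aset, "A")), 0.5)
})

test_that("every enumerated attractor state lies inside the bounds box", {
  # property-based containment + uniqueness agreement on random networks
  for (seed in 101:140) {
    rn <- qn_random_network(n_nodes = 5, edge_density = 0.35, max_range = 2,
                            seed = seed)
    aset <- qn_attractors(rn)
    b <- qn_stable_bounds(rn)
    lims <- stats::setNames(asplit(cbind(b$lo, b$hi), 1), b$node)
    for (a in aset$attractors) for (st in a$states)
      for (nm in names(st)) {
        expect_gte(st[[nm]], lims[[nm]][1])
        expect_lte(st[[nm]], lims[[nm]][2])
      }
    if (attr(b, "proven_unique")) {
      expect_length(aset$attractors, 1)
      expect_length(aset$attractors[[1]]$states, 1)
      expect_equal(unname(qn_reported_level(b, b$node)),
                   unname(as.numeric(aset$attractors[[1]]$states[[1]][b$node])))
    }
  }
})

test_that("refinement is monotone in clamping and bounded in sweeps", {
  rn <- qn_random_network(6, 0.3, max_range = 2, seed = 201)
  b_free <- qn_stable_bounds(rn)
  b_clamped <- qn_stable_bounds(qn_apply(rn, qn_set_level(names(rn$nodes)[1], 0)))
  # a sweep cap equal to the theoretical bound must suffice (no error, same result)
  cap <- sum(vapply(rn$nodes, function(n) n$max - n$min + 1, 0)) + 1
  b_capped <- qn_stable_bounds(rn, max_sweeps = cap)
  expect_identical(as.data.frame(b_free), as.data.frame(b_capped))
  expect_true(all(b_clamped$hi - b_clamped$lo <= b_free$hi - b_free$lo |
                    b_clamped$node == names(rn$nodes)[1]))
})

test_that("corner simulation exhibits both states of a bistable loop", {
  tnf <- qn_motif("tnf_autocrine")
  b <- qn_stable_bounds(tnf)
  expect_false(attr(b, "proven_unique"))
  corners <- qn_corner_attractors(tnf, b)
  expect_length(corners, 2)
  expect_true(all(vapply(corners, function(a) length(a$states), 0) == 1))
  tnf_levels <- sort(vapply(corners, function(a) a$states[[1]][["TNF"]], 0L))
  expect_identical(tnf_levels, c(0L, 2L))
})
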