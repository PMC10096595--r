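# Experiment scoring: expectation dialects, aggregation, determinism.

test_that("the three expectation dialects score as defined", {
  net <- cascade3()
  bg <- qn_background("on", c(In = 2))
  rec <- function(kind, value, pert = list(qn_knockout("N1")))
    qn_experiment("r", bg, pert,
                  list(list(node = "N2", kind = kind, value = value)))

  # knockout of N1 drives N2 to 0; baseline (In = 2) has N2 = 2
  r1 <- qn_score_experiments(net, rec("level", 0))
  expect_true(all(r1$pass))
  r2 <- qn_score_experiments(net, rec("range", c(0, 1)))
  expect_true(all(r2$pass))
  r3 <- qn_score_experiments(net, rec("direction", "decrease"))
  expect_true(all(r3$pass))
  r4 <- qn_score_experiments(net, rec("direction", "increase"))
  expect_false(any(r4$pass))
  # empty perturbation list: prediction equals baseline, ties are "unchanged"
  r5 <- qn_score_experiments(net, rec("direction", "unchanged", pert = list()))
  expect_true(all(r5$pass))
  # range containment holds for midpoints
  half <- qn_score_experiments(
    two_node_mutual(),
    qn_experiment("m", qn_background("free", c()), list(),
                  list(list(node = "A", kind = "range", value = c(0, 1)))))
  expect_equal(half$predicted, 0.5)
  expect_true(all(half$pass))
})

test_that("scoring aggregates measurement-level counts and percent", {
  net <- cascade3()
  bg <- qn_background("on", c(In = 2))
  recs <- list(
    qn_experiment("a", bg, list(),
                  list(list(node = "N1", kind = "level", value = 2),
                       list(node = "N2", kind = "level", value = 2))),
    qn_experiment("b", bg, list(qn_knockout("N1")),
                  list(list(node = "N2", kind = "level", value = 1))))  # wrong
  rep <- qn_score_experiments(net, recs)
  expect_equal(attr(rep, "n_total"), 3)
  expect_equal(attr(rep, "n_pass"), 2)
  expect_equal(attr(rep, "percent"), 200 / 3)
  expect_identical(rep$id[!rep$pass], "b")

  expect_error(qn_score_experiments(net, list()), "empty experiment list")
  # scoring is order-independent
  rep2 <- qn_score_experiments(net, rev(recs))
  expect_equal(attr(rep2, "n_pass"), attr(rep, "n_pass"))
})

test_that("record errors are attributed to the record id, run continues", {
  net <- cascade3()
  recs <- list(
    qn_experiment("bad", qn_background("bg", c(Nonexistent = 1)), list(),
                  list(list(node = "N1", kind = "level", value = 0))),
    qn_experiment("good", qn_background("bg", c(In = 0)), list(),
                  list(list(node = "N1", kind = "level", value = 0))))
  rep <- qn_score_experiments(net, recs)
  expect_false(rep$pass[rep$id == "bad"])
  expect_match(rep$note[rep$id == "bad"], "unknown node")
  expect_true(rep$pass[rep$id == "good"])
})

test_that("oracle-labelled synthetic experiment sets validate at 100%", {
  for (seed in c(7, 8)) {
    net <- qn_random_network(4, 0.4, max_range = 2, seed = seed)
    recs <- qn_synthetic_experiments(net, 12, seed = seed + 100)
    rep <- qn_score_experiments(net, recs)
    expect_equal(attr(rep, "percent"), 100)
  }
})

test_that("a corrupted fraction fails at exactly the corrupted measurements", {
  net <- qn_motif("tnf_autocrine")
  recs <- qn_synthetic_experiments(net, 10, seed = 42, corrupt_fraction = 0.2)
  corrupted <- attr(recs, "corrupted")
  expect_length(corrupted, 2)
  rep <- qn_score_experiments(net, recs)
  expect_identical(sort(rep$id[!rep$pass]), corrupted)
  expect_equal(attr(rep, "n_pass"), 8)
})

test_that("generators are deterministic in the seed", {
  n1 <- qn_random_network(5, 0.3, 2, seed = 99)
  n2 <- qn_random_network(5, 0.3, 2, seed = 99)
  expect_identical(n1$edges, n2$edges)
  expect_identical(attr(n1, "provenance")$n_edges, nrow(n1$edges))
  r1 <- qn_synthetic_experiments(qn_motif("mutual_activation"), 6, seed = 5)
  r2 <- qn_synthetic_experiments(qn_motif("mutual_activation"), 6, seed = 5)
  expect_identical(r1, r2)
})
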