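# Synchronous step, trajectory simulation, exhaustive attractor enumeration.

test_that("step moves each node one level toward its target, clamped", {
  net <- two_node_mutual()
  expect_identical(qn_step(net, c(A = 0, B = 0)), c(A = 0L, B = 0L))
  expect_identical(qn_step(net, c(A = 1, B = 0)), c(A = 0L, B = 1L))
  expect_identical(qn_step(net, c(A = 1, B = 1)), c(A = 1L, B = 1L))

  # node at max with target above max stays at max
  k <- qn_network(nodes = data.frame(name = "K", min = 0, max = 2),
                  edges = NULL, functions = c(K = "5"))
  expect_identical(qn_step(k, c(K = 2)), c(K = 2L))
  expect_identical(qn_step(k, c(K = 0)), c(K = 1L))  # one level per step

  # agreement with an independently written naive oracle on equal-range
  # default-function networks
  for (seed in 1:5) {
    rn <- qn_random_network(4, 0.4, max_range = 1, seed = seed)
    radix <- expand.grid(rep(list(0:1), 4))
    for (r in seq_len(nrow(radix))) {
      st <- stats::setNames(as.integer(radix[r, ]), names(rn$nodes))
      expect_identical(qn_step(rn, st), naive_step(rn, st))
    }
  }
})

test_that("simulation detects fixed points and loops", {
  net <- two_node_mutual()
  sim <- qn_simulate(net, c(A = 0, B = 0))
  expect_true(sim$converged)
  expect_length(sim$trajectory, 1)
  expect_length(sim$attractor$states, 1)

  sim2 <- qn_simulate(net, c(A = 1, B = 0))
  expect_length(sim2$attractor$states, 2)

  # self-inhibiting node: target 1 - v, strict comparison gives a 2-cycle
  sim3 <- qn_simulate(self_inhibitor(), c(A = 0))
  expect_length(sim3$attractor$states, 2)

  # budget exhaustion is reported, not hidden
  sim4 <- qn_simulate(qn_motif("linear_cascade", cascade_length = 4),
                      c(In = 2, N1 = 0, N2 = 0, N3 = 0, N4 = 0), max_steps = 1)
  expect_false(sim4$converged)
  expect_null(sim4$attractor)
})

test_that("exhaustive enumeration finds every attractor", {
  aset <- qn_attractors(two_node_mutual())
  expect_same_attractors(aset, list(
    list(c(A = 0L, B = 0L)),
    list(c(A = 1L, B = 1L)),
    list(c(A = 1L, B = 0L), c(A = 0L, B = 1L))))
  expect_true(aset$bifurcation)

  # identity target: every level is a fixed point
  idn <- qn_network(nodes = data.frame(name = "U", min = 0, max = 2),
                    edges = NULL)
  aset2 <- qn_attractors(idn)
  expect_length(aset2$attractors, 3)
  expect_true(all(vapply(aset2$attractors, function(a) length(a$states), 0) == 1))

  expect_error(qn_attractors(qn_melanoma_lc()$network), "cap")
})

test_that("attractor cycles are consistent and witnesses reach them", {
  for (seed in 6:10) {
    rn <- qn_random_network(4, 0.5, max_range = 2, seed = seed)
    aset <- qn_attractors(rn)
    expect_gte(length(aset$attractors), 1)
    for (a in aset$attractors) {
      k <- length(a$states)
      for (i in seq_len(k))  # stepping moves along the cycle
        expect_identical(qn_step(rn, a$states[[i]]), a$states[[i %% k + 1]])
      expect_length(unique(vapply(a$states, paste, "", collapse = ",")), k)
      sim <- qn_simulate(rn, a$witness)
      expect_true(sim$converged)
      got <- sort(vapply(sim$attractor$states, paste, "", collapse = ","))
      expect_identical(got, sort(vapply(a$states, paste, "", collapse = ",")))
    }
  }
})

test_that("dynamics are deterministic and movement is bounded by one level", {
  rn <- qn_random_network(5, 0.4, max_range = 2, seed = 11)
  st <- stats::setNames(c(0L, 2L, 1L, 0L, 2L), names(rn$nodes))
  s1 <- qn_simulate(rn, st)
  s2 <- qn_simulate(rn, st)
  expect_identical(s1$trajectory, s2$trajectory)
  cur <- st
  for (i in 1:10) {
    nxt <- qn_step(rn, cur)
    expect_true(all(abs(nxt - cur) <= 1))
    cur <- nxt
  }
})

test_that("fixed-point predicate agrees with simulation", {
  for (seed in 12:14) {
    rn <- qn_random_network(4, 0.4, max_range = 2, seed = seed)
    aset <- qn_attractors(rn)
    for (a in aset$attractors) {
      if (length(a$states) == 1)
        expect_true(qn_is_fixed_point(rn, a$states[[1]]))
      else
        for (st in a$states) expect_false(qn_is_fixed_point(rn, st))
    }
  }
})
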