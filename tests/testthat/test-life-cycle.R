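test_that("decomposition recovers the vital rates of the reference matrix", {
  M <- stage_matrix(rbind(c(0.60268, 0), c(0.00732, 0.98)))
  v <- decompose_matrix(M)
  expect_equal(v$s_max, c(0.61, 0.98))
  expect_equal(v$g, 0.012)
})

test_that("decompose/rebuild round trip is the identity on random conformant cycles", {
  for (v in random_life_cycles(100, n = 2, H = 200, seed = 11)) {
    v2 <- decompose_matrix(rebuild_matrix(v))
    expect_equal(v2$s_max, v$s_max, tolerance = 1e-12)
    expect_equal(v2$g, v$g, tolerance = 1e-12)
  }
  # and for a larger stage count
  v <- vital_rates(c(0.5, 0.7, 0.9, 0.95), c(0.9, 0.5, 0.4))
  v2 <- decompose_matrix(rebuild_matrix(v))
  expect_equal(v2$s_max, v$s_max)
  expect_equal(v2$g, v$g)
})

test_that("conformance enforcement zeroes and reports illegal entries", {
  ok <- rbind(c(0.5, 0), c(0.2, 0.9))
  expect_equal(nrow(conformance_report(stage_matrix(ok))), 0)
  expect_equal(unclass(as_stage_matrix(ok, "drop"))[1:2, 1:2], ok)

  retro <- rbind(c(0.5, 0.05), c(0.2, 0.9))
  expect_error(stage_matrix(retro), class = "agflow_conformance_error")
  dropped <- as_stage_matrix(retro, policy = "drop")
  expect_equal(dropped[1, 2], 0)
  rep <- conformance_report(dropped)
  expect_equal(rep$value, 0.05)
  expect_equal(rep$column, 2L)

  fec <- rbind(c(0.5, 0, 12), c(0.2, 0.8, 0), c(0, 0.1, 0.95))
  dropped <- as_stage_matrix(fec, policy = "drop")
  expect_equal(dropped[1, 3], 0)
  expect_true(12 %in% conformance_report(dropped)$value)
  # dropped mass becomes mortality: survivals come from what remains
  expect_equal(decompose_matrix(dropped)$s_max, c(0.7, 0.9, 0.95))

  over <- rbind(c(0.9, 0), c(0.2, 0.9))
  expect_error(stage_matrix(over), class = "agflow_matrix_error")
})

test_that("fundamental matrix matches the scalar closed form and the Neumann series", {
  M <- rebuild_matrix(ref_vital)
  F_ <- fundamental_matrix(M)
  expect_equal(F_[1, 1], 1 / (1 - 0.61 * (1 - 0.012)), tolerance = 1e-12)

  expect_equal(fundamental_matrix(stage_matrix(matrix(0, 2, 2))), diag(2))

  U <- unclass(rebuild_matrix(vital3))
  S <- diag(3); P <- diag(3)
  for (i in 1:2000) { P <- P %*% U; S <- S + P }
  expect_equal(fundamental_matrix(rebuild_matrix(vital3)), S, tolerance = 1e-10)

  immortal <- vital_rates(c(1, 1), 0.5)
  expect_error(fundamental_matrix(rebuild_matrix(immortal)),
               class = "agflow_matrix_error")
})

test_that("typical life history rounds expected ages up and enforces the horizon", {
  expect_equal(ref_history$a, 3L)

  ladder <- vital_rates(c(1, 1, 0.9), c(1, 1))
  F_ <- fundamental_matrix(rebuild_matrix(ladder))
  expect_equal(typical_life_history(F_, 10)$a, c(1L, 2L))

  # hand summation on a fixed 3-stage cycle
  F3 <- fundamental_matrix(rebuild_matrix(vital3))
  expected <- ceiling(c(F3[1, 1], F3[1, 1] + F3[2, 1]) - 1e-9)
  expect_equal(typical_life_history(F3, 20)$a, as.integer(expected))

  slow <- vital_rates(c(0.99, 0.9), 0.001)
  expect_error(
    typical_life_history(fundamental_matrix(rebuild_matrix(slow)), 60),
    class = "agflow_species_excluded"
  )
})

test_that("life-history probabilities follow the geometric growth process", {
  expect_equal(life_history_probability(life_history(5, 60), g = 0.012),
               0.988^4 * 0.012)
  expect_equal(life_history_probability(life_history(c(1, 2), 60), g = c(1, 1)), 1)
  # geometric normalisation over an infinite horizon
  g <- 0.3
  p <- vapply(1:400, function(a1) life_history_probability(life_history(a1, 400), g),
              numeric(1))
  expect_equal(sum(p), 1 - (1 - g)^400, tolerance = 1e-12)
})

test_that("enumeration yields every feasible history with consistent probabilities", {
  e <- enumerate_life_histories(g = 0.25, n = 2, H = 3)
  expect_equal(unlist(e$a), 1:3)
  expect_equal(e$probability, c(0.25, 0.75 * 0.25, 0.75^2 * 0.25))

  e3 <- enumerate_life_histories(g = c(0.4, 0.3), n = 3, H = 4)
  expect_equal(nrow(e3), choose(4, 2))
  expect_true(all(e3$probability > 0 & e3$probability <= 1))
  manual <- vapply(seq_len(nrow(e3)), function(i) {
    life_history_probability(life_history(e3$a[[i]], 4), c(0.4, 0.3))
  }, numeric(1))
  expect_equal(e3$probability, manual)

  e60 <- enumerate_life_histories(g = 0.012, n = 2, H = 60)
  expect_equal(sum(e60$probability), 1 - 0.988^60, tolerance = 1e-12)

  expect_error(enumerate_life_histories(g = rep(0.5, 10), n = 11, H = 60, cap = 1e4),
               class = "agflow_cap_error")
})

test_that("life-history validation enforces ordering and the horizon", {
  expect_error(life_history(c(3, 3), 60), class = "agflow_history_error")
  expect_error(life_history(c(2, 1), 60), class = "agflow_history_error")
  expect_error(life_history(61, 60), class = "agflow_history_error")
  expect_error(life_history(c(1, 1), 60), class = "agflow_history_error")
})
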