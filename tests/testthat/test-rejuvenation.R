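test_that("organ scores count correct cells over the scored set", {
  pat <- target_pattern(matrix(1L, 6, 6), n_types = 3L)
  cells <- matrix(FALSE, 6, 6); cells[3:4, 3:4] <- TRUE
  organ <- dilate_boundary(organ_mask("o", cells), pat)

  types <- matrix(1L, 6, 6)
  expect_equal(organ_score(types, organ, pat), 1.0)

  types[3, 3:4] <- 2L  # 2 of 4 organ cells wrong
  expect_equal(organ_score(types, organ, pat), 0.5)

  # organ fully correct, 4 of the 12 boundary cells wrong: 12/16
  types <- matrix(1L, 6, 6)
  types[2, 2:5] <- 3L
  expect_equal(organ_score(types, organ, pat, include_boundary = TRUE), 0.75)

  no_b <- organ_mask("o", cells)
  expect_error(organ_score(types, no_b, pat, include_boundary = TRUE),
               "boundary")
})

test_that("treatment planning uses a strict threshold and the refractory", {
  pol <- intervention_policy(threshold = 0.6, refractory = 25)
  never <- c(LeftEye = -Inf, Mouth = -Inf)
  expect_equal(plan_interventions(c(LeftEye = 0.5, Mouth = 0.9), pol, never, 100),
               "LeftEye")
  # boundary case exactly at the threshold: no treatment (r_o < r_th is strict)
  expect_length(plan_interventions(c(LeftEye = 0.6, Mouth = 0.6), pol, never, 100), 0)
  recent <- c(LeftEye = 90, Mouth = -Inf)
  expect_length(plan_interventions(c(LeftEye = 0.2, Mouth = 0.9), pol, recent, 100), 0)
  expect_equal(plan_interventions(c(LeftEye = 0.2, Mouth = 0.9), pol, recent, 115),
               "LeftEye")
})

test_that("resets write the declared payload and never touch other cells", {
  pat <- make_toy_face()
  arch <- toy_arch(width = 8, height = 8, n_types = 3, n_hidden = 1)
  g <- random_genome(arch, seed = 13)
  tis <- make_tissue(g)
  tis$states <- matrix(stream_rnorm(rng_stream(7), 4 * 64), 4, 64)
  tis$memory <- matrix(stream_rnorm(rng_stream(8), arch$hidden_dim * 64),
                       arch$hidden_dim, 64)
  organ <- pat$organs$LeftEye
  idx <- which(as.vector(organ$cells))

  polA <- intervention_policy(mode = "organ_full_reset", payload = "initial_state")
  outA <- apply_intervention(tis, organ, pat, g, polA)
  expect_identical(outA$tissue$states[, idx], g$structural[, idx])
  expect_true(all(outA$tissue$memory[, idx] == 0))
  expect_identical(outA$tissue$states[, -idx], tis$states[, -idx])
  expect_identical(outA$tissue$memory[, -idx], tis$memory[, -idx])
  expect_equal(outA$event$n_cells_reset, 4L)

  # wrong-cells mode: already-correct organ cells are spared
  tis2 <- tis
  enc <- c(-1, -1, 1, 0)  # expresses type 3, the organ type
  tis2$states[, idx[1:2]] <- enc
  tis2$states[, idx[3:4]] <- c(1, -1, -1, 0)  # expresses type 1: wrong
  polB <- intervention_policy(mode = "wrong_cells_reset", payload = "target_state")
  outB <- apply_intervention(tis2, organ, pat, g, polB)
  expect_identical(outB$tissue$states[, idx[1:2]], tis2$states[, idx[1:2]])
  expect_equal(outB$event$n_cells_reset, 2L)
  reset_cols <- outB$tissue$states[, idx[3:4]]
  expect_true(all(reset_cols[3, ] == 1 & reset_cols[1, ] == -1 &
                    reset_cols[2, ] == -1 & reset_cols[4, ] == 0))
  # target-state payload expresses the target type by construction
  expect_equal(ncaging:::expressed_types_vec(outB$tissue$states, 3)[idx],
               rep(3L, 4))

  # boundary-augmented wrong-cells reset touches wrong boundary cells only
  tis3 <- tis
  polC <- intervention_policy(mode = "wrong_cells_reset",
                              include_boundary = TRUE,
                              payload = "target_state")
  outC <- apply_intervention(tis3, organ, pat, g, polC)
  scored <- c(idx, which(as.vector(organ$boundary_cells)))
  wrong <- scored[ncaging:::expressed_types_vec(tis3$states, 3)[scored] !=
                    as.vector(pat$types)[scored]]
  expect_setequal(outC$event$cells, wrong)
})

test_that("rejuvenation runs obey the threshold and refractory contracts", {
  pat <- make_toy_face()
  arch <- toy_arch(width = 8, height = 8, n_types = 3, n_hidden = 1)
  g <- zero_genome(arch)  # all states zero: every organ scores 0 forever
  cfg <- nca_config(arch, t_D = 5, t_A = 120, xi_c = 0)

  off <- intervention_policy(threshold = 0, refractory = 25)
  tr0 <- run_with_rejuvenation(g, cfg, off, pat$organs, pat, seed = 1)
  expect_equal(nrow(tr0$events), 0L)

  pol <- intervention_policy(threshold = 0.6, mode = "organ_full_reset",
                             payload = "initial_state", refractory = 25)
  tr <- run_with_rejuvenation(g, cfg, pol, pat$organs, pat, seed = 1)
  # initial-state payload leaves the zero genome broken, so each organ is
  # re-treated at exactly the refractory cadence
  for (nm in names(pat$organs)) {
    times <- tr$events$time[tr$events$organ == nm]
    expect_equal(times, seq(1L, 120L, by = 25L))
  }

  # post-hoc audit: every event satisfies the strict threshold + refractory
  for (i in seq_len(nrow(tr$events))) {
    ev <- tr$events[i, ]
    expect_lt(tr$scores[ev$time + 1L, ev$organ], pol$threshold)
    prior <- tr$events$time[tr$events$organ == ev$organ & tr$events$time < ev$time]
    if (length(prior)) expect_gte(ev$time - max(prior), pol$refractory)
  }
})

test_that("monitoring can be deferred past development", {
  pat <- make_toy_face()
  arch <- toy_arch(width = 8, height = 8, n_types = 3, n_hidden = 1)
  g <- zero_genome(arch)
  cfg <- nca_config(arch, t_D = 5, t_A = 60, xi_c = 0)
  pol <- intervention_policy(threshold = 0.6, refractory = 25, start = 30)
  tr <- run_with_rejuvenation(g, cfg, pol, pat$organs, pat, seed = 1)
  expect_true(all(tr$events$time >= 30))
})
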