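test_that("neighborhood perception respects fixed boundaries and closures", {
  arch <- toy_arch(width = 4, height = 4, n_types = 3, n_hidden = 1)
  g <- random_genome(arch, seed = 2)
  tis <- make_tissue(g)

  interior <- 2L + (2L - 1L) * 4L  # cell (2,2)
  nh <- neighborhood_states(tis, interior)
  expect_equal(dim(nh), c(4L, 9L))
  expect_equal(nh[, 1], tis$states[, interior])
  expect_false(any(colSums(abs(nh)) == 0))  # no zero vectors in the interior

  corner <- 1L  # cell (1,1): 5 of 8 Moore slots off-grid
  nhc <- neighborhood_states(tis, corner)
  expect_equal(sum(colSums(abs(nhc)) == 0), 5L)

  gj <- gap_junction_state(arch)
  gj$open[interior, ] <- FALSE
  iso <- neighborhood_states(tis, interior, gj)
  expect_equal(sum(colSums(abs(iso)) == 0), 8L)
  expect_equal(iso[, 1], tis$states[, interior])
})

test_that("a zero-weight controller proposes the zero action", {
  arch <- toy_arch()
  g <- zero_genome(arch)
  nh <- matrix(rnorm(3 * 9), 3, 9)
  out <- cell_action(nh, numeric(arch$hidden_dim), g$params)
  expect_equal(out$action, rep(0, 3))
})

test_that("actions are invariant to neighbor ordering (mean pooling)", {
  arch <- toy_arch(n_types = 3)
  g <- random_genome(arch, seed = 5)
  nh <- matrix(rnorm(4 * 9), 4, 9)
  mem <- rnorm(arch$hidden_dim)
  base <- cell_action(nh, mem, g$params)
  for (i in 1:5) {
    perm <- cbind(nh[, 1], nh[, 1 + sample(8)])
    out <- cell_action(perm, mem, g$params)
    expect_equal(out$action, base$action, tolerance = 1e-12)
    expect_equal(out$memory, base$memory, tolerance = 1e-12)
  }
})

test_that("proposed actions are clipped to l_a and states to l_c", {
  expect_equal(ncaging:::clip(c(1.7, -0.2, 0.4, -3.0), c(-1, 1)),
               c(1.0, -0.2, 0.4, -1.0))
  expect_equal(ncaging:::clip(2.9 + 0.5, c(-3, 3)), 3.0)
})

test_that("engine step agrees with the single-cell perception-action cycle", {
  arch <- toy_arch(width = 3, height = 3, n_types = 3, n_hidden = 1)
  g <- random_genome(arch, seed = 11)
  tis <- make_tissue(g)
  tis$states <- matrix(stream_rnorm(rng_stream(4), 4 * 9), 4, 9)
  tis$memory <- matrix(stream_rnorm(rng_stream(5), arch$hidden_dim * 9),
                       arch$hidden_dim, 9)
  stepped <- nca_step(tis, g, xi_c = 0, p_d = 1, streams = nca_streams(1))
  for (i in seq_len(9)) {
    nh <- neighborhood_states(tis, i)
    ref <- cell_action(nh, tis$memory[, i], g$params)
    expect_equal(stepped$states[, i],
                 ncaging:::clip(tis$states[, i] + ref$action, c(-3, 3)),
                 tolerance = 1e-12)
    expect_equal(stepped$memory[, i], ref$memory, tolerance = 1e-12)
  }
})

test_that("zero noise and zero controller is a fixed point; noise matches xi_c", {
  arch <- toy_arch(width = 4, height = 4)
  g <- zero_genome(arch)
  cfg <- nca_config(arch, t_D = 5, t_A = 35, xi_c = 0)
  traj <- simulate_nca(g, cfg, seed = 1, steps = 35)
  expect_true(all(apply(traj$types, 2, function(col) length(unique(col)) == 1L)))

  # with P_D = 0 and zero initial states the per-component increments are
  # pure N(0, xi_c^2) draws; check the empirical sd over ~1.2e5 draws
  arch2 <- toy_arch(width = 50, height = 50, n_types = 2, n_hidden = 1)
  g2 <- zero_genome(arch2)
  cfg2 <- nca_config(arch2, t_D = 1, t_A = 16, xi_c = 0.125)
  sch <- aging_schedules(competency = schedule("constant", 0))
  tr <- simulate_nca(g2, cfg2, schedules = sch, seed = 9, steps = 16,
                     record_states = TRUE)
  flat <- t(matrix(tr$states, nrow = prod(dim(tr$states)[1:2])))  # time x comp
  incr <- diff(flat)
  # exclude clipped cells (|state| near bound) — none expected this early
  expect_lt(max(abs(tr$final$states)), 3)
  expect_lt(abs(sd(incr) - 0.125) / 0.125, 0.01)
})

test_that("type expression takes the argmax with lowest-index tie-break", {
  arch <- toy_arch(width = 1, height = 3, n_types = 3, n_hidden = 1)
  g <- zero_genome(arch)
  tis <- make_tissue(g)
  tis$states[, 1] <- c(0.2, -1.0, 0.9, 0)
  tis$states[, 2] <- c(1.0, 1.0, 0.0, 0)
  tis$states[, 3] <- c(-3, -3, -3, 0)
  expect_equal(as.vector(express_types(tis)), c(3L, 1L, 1L))
})

test_that("trajectories are bitwise deterministic under a fixed seed", {
  arch <- toy_arch()
  g <- random_genome(arch, seed = 3)
  cfg <- nca_config(arch, t_D = 10, t_A = 60)
  sch <- aging_schedules(noise = schedule("linear", 0, 0.5),
                         competency = schedule("sin4", 1, 0),
                         gap_junction = schedule("linear", 1, 0.5),
                         mutation_sigma = 0.005)
  a <- simulate_nca(g, cfg, schedules = sch, seed = 123, steps = 60)
  b <- simulate_nca(g, cfg, schedules = sch, seed = 123, steps = 60)
  expect_identical(a$types, b$types)
  expect_identical(a$final, b$final)
  c2 <- simulate_nca(g, cfg, schedules = sch, seed = 124, steps = 60)
  expect_false(identical(a$types, c2$types))
})

test_that("state and action bounds hold under fuzzed configurations", {
  for (i in 1:25) {
    fuzz <- rng_stream(1000 + i)
    w <- 2L + (abs(stream_sample(fuzz, 1:4, 1)))
    h <- 2L + (abs(stream_sample(fuzz, 1:4, 1)))
    nt <- stream_sample(fuzz, 2:4, 1)
    arch <- toy_arch(width = w, height = h, n_types = nt, n_hidden = 1)
    g <- random_genome(arch, seed = i, scale = 2)
    xi <- abs(stream_rnorm(fuzz, 1))
    cfg <- nca_config(arch, t_D = 3, t_A = 15, xi_c = xi)
    sch <- aging_schedules(
      noise = schedule("linear", 0, abs(stream_rnorm(fuzz, 1)) * 2),
      competency = schedule("sin4", 1, 0),
      gap_junction = schedule("linear", 1, stream_runif(fuzz, 1)),
      mutation_sigma = abs(stream_rnorm(fuzz, 1)) * 0.05)
    tr <- simulate_nca(g, cfg, schedules = sch, seed = i, steps = 15,
                       record_states = TRUE)
    expect_true(all(abs(tr$states) <= 3))
    expect_true(all(tr$types >= 1L & tr$types <= nt))
  }
})

test_that("full gap-junction closure reduces cells to isolated dynamics", {
  arch <- toy_arch(width = 3, height = 3, n_types = 3, n_hidden = 1)
  g <- random_genome(arch, seed = 21)
  cfg <- nca_config(arch, t_D = 5, t_A = 30, xi_c = 0)
  sch <- aging_schedules(gap_junction = schedule("constant", 0))
  traj <- simulate_nca(g, cfg, schedules = sch, seed = 1, steps = 30)

  arch1 <- toy_arch(width = 1, height = 1, n_types = 3, n_hidden = 1)
  cfg1 <- nca_config(arch1, t_D = 5, t_A = 30, xi_c = 0)
  for (i in seq_len(9)) {
    g1 <- zero_genome(arch1)
    g1$structural[, 1] <- g$structural[, i]
    g1$functional <- g$functional
    g1$params <- g$params
    t1 <- simulate_nca(g1, cfg1, seed = 1, steps = 30)
    expect_equal(t1$types[, 1], traj$types[, i])
  }
})
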