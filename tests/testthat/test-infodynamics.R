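test_that("AIS matches closed-form cases", {
  expect_equal(local_ais(rep(1L, 50), k = 1)$mean, 0)
  # deterministic alternation with an exactly uniform marginal (odd length
  # gives 25/25 next-symbol counts): p(next | past) = 1, p(next) = 1/2
  alt <- rep_len(c(0L, 1L), 51)
  expect_equal(local_ais(alt, k = 1)$mean, 1)
  iid <- as.integer(stream_runif(rng_stream(3), 1e4) < 0.5)
  expect_lt(local_ais(iid, k = 1)$mean, 0.01)
  expect_error(local_ais(c(1L, 2L), k = 5), "too short")
})

test_that("TE matches closed-form cases", {
  # lag-1 copy with a de Bruijn source: (dest past, source) pairs cycle the
  # four combinations with exact frequencies (length 4m + 1 and the matching
  # initial destination symbol), next = source exactly -> 1 bit
  src <- rep_len(c(0L, 0L, 1L, 1L), 65)
  dst <- c(1L, src[-65])
  expect_equal(local_te(src, dst, k = 1)$mean, 1)

  expect_equal(local_te(rep(2L, 40), rep(c(0L, 1L), 20), k = 1)$mean, 0)

  s <- rng_stream(4)
  a <- as.integer(stream_runif(s, 1e4) < 0.5)
  b <- as.integer(stream_runif(s, 1e4) < 0.5)
  expect_lt(local_te(a, b, k = 1)$mean, 0.01)
  expect_error(local_te(a, b[-1], k = 1), "equal length")
})

test_that("plug-in estimators agree exactly with brute-force histogram oracles", {
  s <- rng_stream(9)
  for (i in 1:40) {
    len <- 4L + (i %% 7L)
    k <- 1L + (i %% 2L)
    x <- as.integer(stream_runif(s, len) < 0.5)
    if (length(unique(x)) == 1L) x[1] <- 1L - x[1]
    expect_equal(local_ais(x, k)$mean, brute_ais(x, k), tolerance = 1e-12)
    y <- as.integer(stream_runif(s, len) < 0.5)
    expect_equal(local_te(y, x, k)$mean, brute_te(y, x, k), tolerance = 1e-12)
  }
})

test_that("plug-in means respect information-theoretic bounds", {
  s <- rng_stream(14)
  saw_negative_local <- FALSE
  for (i in 1:20) {
    x <- as.integer(floor(stream_runif(s, 60) * 3))
    a <- local_ais(x, k = 2)
    expect_gte(a$mean, -1e-12)
    # mean AIS bounded by the plug-in entropy of the next-state marginal
    nxt <- x[3:60]
    p <- table(nxt) / length(nxt)
    expect_lte(a$mean, -sum(p * log2(p)) + 1e-12)
    y <- as.integer(floor(stream_runif(s, 60) * 3))
    te <- local_te(y, x, k = 2)
    expect_gte(te$mean, -1e-12)
    if (any(a$local < 0) || any(te$local < 0)) saw_negative_local <- TRUE
  }
  expect_true(saw_negative_local)  # locals can be negative, means cannot
})

test_that("spatial entropy matches closed forms and is position-invariant", {
  expect_equal(spatial_entropy(matrix(2L, 5, 5)), 0)
  g3 <- c(rep(1L, 27), rep(2L, 27), rep(3L, 27))
  expect_equal(spatial_entropy(g3), log2(3))
  g <- c(rep(1L, 8), rep(2L, 4), rep(3L, 4))
  expect_equal(spatial_entropy(g), 1.5)
  s <- rng_stream(5)
  grid <- as.integer(floor(stream_runif(s, 36) * 3)) + 1L
  expect_equal(spatial_entropy(grid), spatial_entropy(sample(grid)))
})

test_that("symbolization exposes types and binned states", {
  arch <- toy_arch(width = 3, height = 3, n_types = 3)
  g <- zero_genome(arch)
  cfg <- nca_config(arch, t_D = 5, t_A = 20, xi_c = 0)
  tr <- simulate_nca(g, cfg, seed = 1, steps = 20, record_states = TRUE)
  sym <- symbolize(tr)
  expect_equal(attr(sym, "alphabet"), 3L)
  expect_true(all(apply(sym, 2, function(col) length(unique(col)) == 1L)))

  tr2 <- simulate_nca(g, cfg, seed = 1, steps = 20)
  expect_error(symbolize(tr2, mode = "binned"), "record_states")
  binned <- symbolize(tr, mode = "binned", bins = 4)
  expect_length(binned, arch$n_state)
  expect_true(all(vapply(binned, function(b) all(b %in% 0:3), NA)))
  # binning arithmetic: states at 0 fall in bin 2 of [-3, 3] with 4 bins
  expect_true(all(binned[[1]] == 2L))
})

test_that("information maps localize activity and match grid shape", {
  # static trajectory -> AIS map all zeros
  rows <- rep(list(rep(1L, 9)), 12)
  tr <- fake_traj(rows, 3, 3, 2)
  maps <- info_maps(tr, k = 1)
  expect_equal(dim(maps$ais), c(3L, 3L))
  expect_true(all(maps$ais == 0))

  # one deterministically toggling cell carries 1 bit of AIS, others none
  # (odd series length so the plug-in marginal is exactly uniform)
  rows <- lapply(1:13, function(t) {
    r <- rep(1L, 9); r[5] <- 1L + (t %% 2L); r
  })
  tr <- fake_traj(rows, 3, 3, 2)
  maps <- info_maps(tr, k = 1)
  expect_equal(as.vector(maps$ais)[5], 1)
  expect_true(all(as.vector(maps$ais)[-5] == 0))
  expect_error(info_maps(tr, k = 1, window = 0:1), "window too small")
})

test_that("windowed info series tracks a developing organism", {
  arch <- toy_arch()
  g <- random_genome(arch, seed = 2)
  cfg <- nca_config(arch, t_D = 10, t_A = 80)
  tr <- simulate_nca(g, cfg, seed = 8, steps = 80)
  info <- info_series(tr, k = 1, window = 30, stride = 15)
  expect_true(all(c("ais", "te", "se") %in% names(info)))
  expect_true(all(info$ais >= 0 & info$te >= 0))
  expect_true(all(info$se >= 0 & info$se <= log2(2)))
})
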