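# Shared helpers: tiny genomes, hand-built trajectories, and independent
# brute-force oracles used to cross-check the streaming implementations.

toy_arch <- function(width = 4L, height = 4L, n_types = 2L, n_hidden = 1L,
                     sensor_dim = 2L, hidden_dim = 2L) {
  nca_architecture(width = width, height = height, n_types = n_types,
                   n_hidden = n_hidden, sensor_dim = sensor_dim,
                   hidden_dim = hidden_dim)
}

random_genome <- function(arch, seed = 1, scale = 0.5) {
  decode_genome(scale * stream_rnorm(rng_stream(seed), genome_length(arch)), arch)
}

zero_genome <- function(arch) decode_genome(numeric(genome_length(arch)), arch)

# trajectory object built directly from a list of flattened type rows
fake_traj <- function(rows, width, height, n_types, t_D = length(rows) - 1L) {
  types <- do.call(rbind, rows)
  structure(list(types = types, width = width, height = height,
                 n_types = n_types, t_D = t_D, steps = nrow(types) - 1L),
            class = "nca_trajectory")
}

# independent recount of the fitness counters by explicit loops over the
# logged grids (oracle for nca_fitness)
recount_fitness <- function(types, target_vec, t_D, r_T, r_S) {
  n_j <- length(target_vec)
  n_G <- 0L
  for (i in seq_len(n_j)) if (types[t_D + 1L, i] == target_vec[i]) n_G <- n_G + 1L
  n_T <- 0L
  for (t in 1:t_D) {
    ok <- TRUE
    for (i in seq_len(n_j)) if (types[t + 1L, i] != target_vec[i]) { ok <- FALSE; break }
    if (ok) n_T <- n_T + 1L
  }
  n_S <- 0L
  if (t_D >= 2L) for (t in 1:(t_D - 1L)) {
    same <- TRUE
    for (i in seq_len(n_j)) if (types[t + 1L, i] != types[t + 2L, i]) { same <- FALSE; break }
    if (same) n_S <- n_S + 1L
  }
  list(n_G = n_G, n_T = n_T, n_S = n_S,
       r = (2 * n_G - n_j) + r_T * n_T - r_S * n_S)
}

# Brute-force plug-in AIS: tabulate every (past-configuration, next) pair by
# explicit enumeration over all alphabet configurations and evaluate the
# weighted-average mutual information directly from the histograms.
brute_ais <- function(x, k) {
  n <- length(x)
  syms <- sort(unique(x))
  pasts <- expand.grid(rep(list(syms), k))
  m <- n - k
  total <- 0
  for (pi in seq_len(nrow(pasts))) {
    past <- as.numeric(pasts[pi, k:1])  # oldest first
    for (nx in syms) {
      cnt <- 0L; cnt_p <- 0L; cnt_n <- 0L
      for (t in (k + 1):n) {
        is_p <- all(x[(t - k):(t - 1)] == past)
        if (is_p) cnt_p <- cnt_p + 1L
        if (x[t] == nx) cnt_n <- cnt_n + 1L
        if (is_p && x[t] == nx) cnt <- cnt + 1L
      }
      if (cnt > 0) {
        total <- total + (cnt / m) * log2((cnt / m) / ((cnt_p / m) * (cnt_n / m)))
      }
    }
  }
  total
}

# Brute-force plug-in TE by full histogram enumeration.
brute_te <- function(src, dst, k) {
  n <- length(dst)
  syms_d <- sort(unique(dst)); syms_s <- sort(unique(src))
  pasts <- expand.grid(rep(list(syms_d), k))
  m <- n - k
  total <- 0
  for (pi in seq_len(nrow(pasts))) {
    past <- as.numeric(pasts[pi, k:1])
    for (z in syms_s) for (nx in syms_d) {
      c_pzn <- 0L; c_pz <- 0L; c_pn <- 0L; c_p <- 0L
      for (t in (k + 1):n) {
        is_p <- all(dst[(t - k):(t - 1)] == past)
        if (!is_p) next
        c_p <- c_p + 1L
        if (src[t - 1] == z) c_pz <- c_pz + 1L
        if (dst[t] == nx) c_pn <- c_pn + 1L
        if (src[t - 1] == z && dst[t] == nx) c_pzn <- c_pzn + 1L
      }
      if (c_pzn > 0) {
        total <- total + (c_pzn / m) * log2((c_pzn / c_pz) / (c_pn / c_p))
      }
    }
  }
  total
}

all_binary_seqs <- function(len) {
  m <- as.matrix(expand.grid(rep(list(0:1), len)))
  lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
}
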