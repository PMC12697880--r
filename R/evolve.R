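#' Evolve an automaton to grow a target pattern
#'
#' Runs CMA-ES over the flat genome (structural initial states plus
#' functional controller parameters), selecting on the phenotype: each
#' candidate genome is deployed for `t_D` developmental steps under the
#' training noise level (`config$xi_c`), its trajectory is scored with
#' [nca_fitness()], and the candidate's fitness is the mean over
#' `config$repetitions` independent rollouts. Each rollout draws from a fresh
#' stream derived from `(seed, generation, candidate, repetition)`, so runs
#' are fully reproducible and ranking noise is controlled.
#'
#' The search starts from the zero genome with initial step size
#' `config$sigma0` and stops early once the best candidate of a generation
#' attains the solved pattern term `N_j` on every repetition. If the best
#' score stagnates for `stall` consecutive generations the strategy restarts
#' from scratch (fresh mean and step size, new derived sampling stream) —
#' the usual remedy for premature covariance collapse on noisy objectives —
#' while the total generation budget `config$generations` is never exceeded.
#'
#' @param target a [target_pattern()] whose grid matches `config$arch`.
#' @param config an [nca_config()]; `population`, `generations`,
#'   `repetitions`, `sigma0`, `r_T`, `r_S`, `t_D` and `xi_c` control the
#'   evolutionary run.
#' @param seed master seed.
#' @param stall generations without best-score improvement before a restart.
#' @return a list with `genome` (best-ever `nca_genome`), `history` (one row
#'   per generation: `gen`, `best_r`, `mean_r`, `best_pattern`, `sigma`),
#'   `solved` (logical), and `best_r`.
#' @export
evolve_nca <- function(target, config, seed = 1L, stall = 40L) {
  a <- config$arch
  if (a$width != target$width || a$height != target$height ||
      a$n_types != target$n_types) {
    stop("target pattern does not match the configured architecture")
  }
  dim <- genome_length(a)
  dev_cfg <- config
  n_j <- a$n_cells

  eval_candidate <- function(x, gen, cand) {
    genome <- decode_genome(x, a, l_c = config$l_c)
    rs <- numeric(config$repetitions)
    pats <- numeric(config$repetitions)
    for (rep in seq_len(config$repetitions)) {
      traj <- simulate_nca(genome, dev_cfg, seed = derive_seed(seed, "eval", gen, cand, rep),
                           steps = config$t_D)
      fb <- nca_fitness(traj, target, r_T = config$r_T, r_S = config$r_S,
                        t_D = config$t_D)
      rs[rep] <- fb$r
      pats[rep] <- fb$pattern_term
    }
    structure(-mean(rs), pattern = mean(pats))
  }

  if (config$generations == 0L) {
    genome <- decode_genome(numeric(dim), a, l_c = config$l_c)
    return(list(genome = genome,
                history = data.frame(gen = integer(), best_r = numeric(),
                                     mean_r = numeric(), best_pattern = numeric(),
                                     sigma = numeric()),
                solved = FALSE, best_r = NA_real_))
  }

  total_hist <- list()
  best_overall <- list(x = numeric(dim), value = Inf)
  gens_used <- 0L
  restart <- 0L
  solved <- FALSE
  while (gens_used < config$generations && !solved) {
    restart <- restart + 1L
    offset <- gens_used
    gen_best_pattern <- numeric(0)
    records <- numeric(0)  # best-ever fitness (to minimize) per generation
    fn_tracked <- local({
      cur_best <- -Inf
      function(x, gen, cand) {
        v <- eval_candidate(x, offset + gen, cand)
        p <- attr(v, "pattern")
        if (length(gen_best_pattern) < gen) gen_best_pattern[gen] <<- -Inf
        if (p > gen_best_pattern[gen]) gen_best_pattern[gen] <<- p
        as.numeric(v)
      }
    })
    stop_fn <- function(gen, best_fit, best) {
      records[gen] <<- best$value
      if (gen_best_pattern[gen] >= n_j) return(TRUE)
      # restart on stagnation: best-ever score barely moved over `stall` gens
      gen > stall && (records[gen - stall] - records[gen]) < 0.5
    }
    stream <- rng_stream(derive_seed(seed, "cmaes", restart))
    res <- cma_es_min(fn_tracked, numeric(dim), config$sigma0,
                      lambda = config$population,
                      max_gen = config$generations - gens_used,
                      stream = stream, stop_fn = stop_fn)
    h <- res$history
    if (nrow(h)) {
      h$gen <- h$gen + offset
      h$best_pattern <- gen_best_pattern[seq_len(nrow(h))]
      total_hist[[restart]] <- h
      gens_used <- gens_used + nrow(h)
    } else {
      break
    }
    if (res$best$value < best_overall$value) best_overall <- res$best
    solved <- any(gen_best_pattern >= n_j)
  }
  hist <- do.call(rbind, total_hist)
  history <- data.frame(gen = hist$gen, best_r = -hist$best,
                        mean_r = -hist$mean,
                        best_pattern = hist$best_pattern,
                        sigma = hist$sigma)
  genome <- decode_genome(best_overall$x, a, l_c = config$l_c)
  list(genome = genome, history = history, solved = solved,
       best_r = -best_overall$value)
}
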