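#' Run configuration
#'
#' Bundles the system parameters of a morphogenesis/aging run. The defaults
#' reproduce the reference system: a 16 x 16 grid with `N_G = 3` cell types
#' and `N_H = 1` hidden channel (`N_C = 4` state channels), state-update
#' noise `xi_c = 0.125`, actions clipped to `l_a = [-1, 1]`, states clipped
#' to `l_c = [-3, 3]`, and `t_D = 35` developmental steps.
#'
#' @param arch an [nca_architecture()].
#' @param t_D developmental horizon (steps scored by the evolutionary
#'   fitness).
#' @param t_A lifespan (total steps of a deployment run), `t_A >= t_D`.
#' @param xi_c baseline state-update noise amplitude.
#' @param l_a action bounds.
#' @param l_c state bounds.
#' @param r_T premature-completion bonus weight in the fitness score.
#' @param r_S stagnation penalty weight in the fitness score.
#' @param population CMA-ES population size.
#' @param generations maximum CMA-ES generations.
#' @param repetitions noisy-fitness evaluation repetitions per candidate.
#' @param sigma0 initial CMA-ES step size.
#' @return an object of class `nca_config`.
#' @export
nca_config <- function(arch = nca_architecture(), t_D = 35L, t_A = t_D,
                       xi_c = 0.125, l_a = c(-1, 1), l_c = c(-3, 3),
                       r_T = 0.1, r_S = 0.1, population = 24L,
                       generations = 200L, repetitions = 3L, sigma0 = 0.5) {
  t_D <- as.integer(t_D); t_A <- as.integer(t_A)
  if (t_D < 1L || t_A < t_D) stop("need t_A >= t_D >= 1")
  if (population < 1L || generations < 0L || repetitions < 1L) {
    stop("population and repetitions must be positive, generations non-negative")
  }
  cfg <- list(arch = arch, t_D = t_D, t_A = t_A, xi_c = xi_c,
              l_a = l_a, l_c = l_c, r_T = r_T, r_S = r_S,
              population = as.integer(population),
              generations = as.integer(generations),
              repetitions = as.integer(repetitions), sigma0 = sigma0)
  class(cfg) <- "nca_config"
  cfg
}

#' @export
print.nca_config <- function(x, ...) {
  cat(sprintf(paste0("NCA run configuration: t_D = %d, t_A = %d, xi_c = %g, ",
                     "l_a = [%g, %g], l_c = [%g, %g]\n"),
              x$t_D, x$t_A, x$xi_c, x$l_a[1], x$l_a[2], x$l_c[1], x$l_c[2]))
  print(x$arch)
  invisible(x)
}

clip <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

# Moore-neighborhood index table: row i holds the flattened (column-major)
# indices of cell i's 8 neighbors in a fixed order; 0 marks out-of-grid slots
# (fixed boundary: those slots are perceived as the zero state vector).
neighbor_index <- function(width, height) {
  n <- width * height
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  r <- rep(seq_len(height), times = width)
  cc <- rep(seq_len(width), each = height)
  nb <- matrix(0L, n, 8L)
  for (v in 1:8) {
    rr <- r + offs[v, 1]; c2 <- cc + offs[v, 2]
    ok <- rr >= 1L & rr <= height & c2 >= 1L & c2 <= width
    nb[ok, v] <- rr[ok] + (c2[ok] - 1L) * height
  }
  nb
}

#' Named random-number streams for a simulation run
#'
#' @param seed master seed; substream seeds are derived from it by label.
#' @return a list of [rng_stream()]s: `noise`, `gate`, `gj`, `mutation`.
#' @export
nca_streams <- function(seed) {
  list(noise = rng_stream(derive_seed(seed, "noise")),
       gate = rng_stream(derive_seed(seed, "gate")),
       gj = rng_stream(derive_seed(seed, "gj")),
       mutation = rng_stream(derive_seed(seed, "mutation")))
}

#' Initialize a tissue from a genome
#'
#' The tissue is the dynamical object stepped by the automaton: the grid of
#' continuous cell states (initialized from the structural genes) plus each
#' cell's controller recurrent memory (initialized to zero) and the step
#' index.
#'
#' @param genome an `nca_genome` (see [decode_genome()]).
#' @return an object of class `nca_tissue` with fields `states`
#'   (`n_state x n_cells`), `memory` (`hidden_dim x n_cells`), `time`, and
#'   the architecture.
#' @export
make_tissue <- function(genome) {
  a <- genome$architecture
  t <- list(states = genome$structural,
            memory = matrix(0, a$hidden_dim, a$n_cells),
            time = 0L, arch = a)
  class(t) <- "nca_tissue"
  t
}

#' @export
print.nca_tissue <- function(x, ...) {
  cat(sprintf("NCA tissue: %d x %d grid at step %d\n",
              x$arch$height, x$arch$width, x$time))
  invisible(x)
}

#' Perceived neighborhood of one cell
#'
#' Returns the state vectors a cell perceives: its own state first, then its
#' 8 Moore neighbors in a fixed order. Out-of-grid neighbors (fixed boundary
#' conditions) and neighbors whose incoming gap junction has been closed
#' contribute the zero vector.
#'
#' @param tissue an [make_tissue()] object.
#' @param cell_index flattened (column-major) cell index.
#' @param gj optional [gap_junction_state()].
#' @return an `n_state x 9` matrix (self in column 1).
#' @export
neighborhood_states <- function(tissue, cell_index, gj = NULL) {
  a <- tissue$arch
  stopifnot(cell_index >= 1L, cell_index <= a$n_cells)
  nb <- neighbor_index(a$width, a$height)[cell_index, ]
  out <- matrix(0, a$n_state, 9L)
  out[, 1] <- tissue$states[, cell_index]
  for (v in 1:8) {
    if (nb[v] > 0L && (is.null(gj) || gj$open[cell_index, v])) {
      out[, v + 1L] <- tissue$states[, nb[v]]
    }
  }
  out
}

#' One perception-action cycle of a single cell
#'
#' Embeds each perceived neighbor state separately through the tanh sensor
#' layer, mean-pools the embeddings into a context vector (so the action is
#' invariant to any permutation of the neighbor columns), advances the gated
#' recurrent memory one step, and returns the proposed action clipped to
#' `l_a`.
#'
#' @param neigh `n_state x (N+1)` matrix of perceived states (self first),
#'   e.g. from [neighborhood_states()].
#' @param memory the cell's recurrent memory vector.
#' @param params decoded controller weights (`genome$params`).
#' @param l_a action bounds.
#' @return a list with `action` (length `n_state`, within `l_a`) and the
#'   advanced `memory`.
#' @export
cell_action <- function(neigh, memory, params, l_a = c(-1, 1)) {
  if (!all(is.finite(unlist(params, use.names = FALSE)))) {
    stop("controller parameters must be finite")
  }
  e <- tanh(params$W_e %*% neigh + params$b_e)
  ctx <- rowMeans(e)
  f <- stats::plogis(params$W_f %*% ctx + params$U_f %*% memory + params$b_f)
  cand <- tanh(params$W_c %*% ctx + params$U_c %*% (f * memory) + params$b_c)
  mem2 <- (1 - f) * memory + f * cand
  act <- clip(tanh(params$W_o %*% mem2 + params$b_o), l_a)
  list(action = as.vector(act), memory = as.vector(mem2))
}

# vectorized engine step over the whole grid; mutates nothing, returns
# list(states, memory). `open` is the n_cells x 8 logical open-link matrix.
engine_step <- function(states, memory, params, nb, open, xi_c, p_d,
                        l_a, l_c, streams) {
  n <- ncol(states)
  e <- tanh(params$W_e %*% states + params$b_e)
  e0 <- tanh(params$b_e)                      # embedding of the zero state
  acc <- e + 8 * e0                           # self + 8 blocked placeholders
  for (v in 1:8) {
    j <- which(open[, v])
    if (length(j)) acc[, j] <- acc[, j] - e0 + e[, nb[j, v], drop = FALSE]
  }
  ctx <- acc / 9
  f <- stats::plogis(params$W_f %*% ctx + params$U_f %*% memory + params$b_f)
  cand <- tanh(params$W_c %*% ctx + params$U_c %*% (f * memory) + params$b_c)
  memory <- (1 - f) * memory + f * cand
  act <- clip(tanh(params$W_o %*% memory + params$b_o), l_a)
  # competency gate: the proposed action is applied only with probability
  # P_D; the gate and noise draws come from dedicated streams in a fixed
  # order (cells in column-major grid order)
  u <- stream_runif(streams$gate, n)
  if (p_d < 1) act[, u > p_d] <- 0
  z <- stream_rnorm(streams$noise, length(states))
  states <- clip(states + act + xi_c * z, l_c)
  list(states = states, memory = memory)
}

#' Advance a tissue by one step
#'
#' All cells perceive the time-`t` states, propose actions, and update
#' synchronously: `c(t+1) = clip(c(t) + a(t) + xi, l_c)` where each action
#' survives the competency gate with probability `p_d` (otherwise it is
#' zeroed) and `xi` is i.i.d. zero-mean Gaussian noise of standard deviation
#' `xi_c` per component. Noise is applied regardless of the gate.
#'
#' @param tissue an [make_tissue()] object.
#' @param genome the `nca_genome` supplying controller parameters.
#' @param xi_c noise amplitude for this step.
#' @param p_d competency (probability a proposed action is applied).
#' @param gj optional [gap_junction_state()].
#' @param streams named streams from [nca_streams()].
#' @param l_a,l_c action and state bounds.
#' @return the advanced tissue.
#' @export
nca_step <- function(tissue, genome, xi_c = 0.125, p_d = 1, gj = NULL,
                     streams = nca_streams(0), l_a = c(-1, 1), l_c = c(-3, 3)) {
  a <- tissue$arch
  nb <- neighbor_index(a$width, a$height)
  open <- if (is.null(gj)) nb > 0L else gj$open
  st <- engine_step(tissue$states, tissue$memory, genome$params, nb, open,
                    xi_c, p_d, l_a, l_c, streams)
  tissue$states <- st$states
  tissue$memory <- st$memory
  tissue$time <- tissue$time + 1L
  tissue
}

expressed_types_vec <- function(states, n_types) {
  g <- states[seq_len(n_types), , drop = FALSE]
  max.col(t(g), ties.method = "first")
}

#' Expressed cell types of a tissue
#'
#' A cell's type is the 1-based index of the maximum component of its
#' indicator channels (the first `n_types` state channels); ties break to the
#' lowest index.
#'
#' @param tissue an [make_tissue()] object.
#' @return an integer `height x width` type grid.
#' @export
express_types <- function(tissue) {
  a <- tissue$arch
  matrix(expressed_types_vec(tissue$states, a$n_types), a$height, a$width)
}

# shared simulation loop; policy/organs/target enable rejuvenation monitoring
sim_loop <- function(genome, config, schedules = NULL, seed = 1L,
                     steps = config$t_A, record_states = FALSE,
                     policy = NULL, organs = NULL, target = NULL) {
  a <- genome$architecture
  if (!identical(unclass(a)[c("width", "height", "n_state")],
                 unclass(config$arch)[c("width", "height", "n_state")])) {
    stop("genome architecture does not match the run configuration")
  }
  if (is.null(schedules)) schedules <- aging_schedules()
  streams <- nca_streams(seed)
  nb <- neighbor_index(a$width, a$height)
  gj <- gap_junction_state(a)
  use_gj <- !is.null(schedules$gap_junction)
  functional <- genome$functional
  params <- genome$params

  states <- genome$structural
  memory <- matrix(0, a$hidden_dim, a$n_cells)
  types <- matrix(NA_integer_, steps + 1L, a$n_cells)
  types[1L, ] <- expressed_types_vec(states, a$n_types)
  states_log <- if (record_states) array(NA_real_, c(a$n_state, a$n_cells, steps + 1L))
  if (record_states) states_log[, , 1L] <- states

  monitor <- !is.null(policy)
  if (monitor) {
    stopifnot(!is.null(organs), !is.null(target))
    scores <- matrix(NA_real_, steps + 1L, length(organs),
                     dimnames = list(NULL, names(organs)))
    last_event <- stats::setNames(rep(-Inf, length(organs)), names(organs))
    events <- list()
  }

  for (t in seq_len(steps)) {
    tk <- t - 1L  # schedules are evaluated at the pre-update time
    if (schedules$mutation_sigma > 0) {
      functional <- mutate_genome_step(functional, schedules$mutation_sigma,
                                       streams$mutation)
      params <- decode_controller(functional, a)
    }
    if (use_gj) {
      p_gj <- eval_schedule(schedules$gap_junction, tk, config$t_A, default = 1)
      gj <- update_gap_junctions(gj, p_gj, streams$gj)
    }
    xi_c <- eval_schedule(schedules$noise, tk, config$t_A, default = config$xi_c)
    p_d <- eval_schedule(schedules$competency, tk, config$t_A, default = 1)
    st <- engine_step(states, memory, params, nb, gj$open, xi_c, p_d,
                      config$l_a, config$l_c, streams)
    states <- st$states
    memory <- st$memory
    tv <- expressed_types_vec(states, a$n_types)
    types[t + 1L, ] <- tv

    if (monitor) {
      for (nm in names(organs)) {
        scores[t + 1L, nm] <- organ_score(tv, organs[[nm]], target,
                                          include_boundary = policy_boundary(policy, nm))
      }
      if (t >= policy$start) {
        treat <- plan_interventions(scores[t + 1L, ], policy, last_event, t)
        for (nm in treat) {
          res <- apply_reset(states, memory, organs[[nm]], target, genome,
                             policy, nm)
          states <- res$states
          memory <- res$memory
          last_event[nm] <- t
          events[[length(events) + 1L]] <- data.frame(
            time = t, organ = nm, n_cells_reset = res$n_cells,
            mode = policy$mode, payload = policy$payload,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (record_states) states_log[, , t + 1L] <- states
  }

  traj <- list(types = types, width = a$width, height = a$height,
               n_types = a$n_types, t_D = config$t_D, steps = steps,
               seed = seed, gj_open = gj$open,
               states = if (record_states) states_log,
               final = list(states = states, memory = memory))
  class(traj) <- "nca_trajectory"
  if (monitor) {
    ev <- if (length(events)) do.call(rbind, events) else
      data.frame(time = integer(), organ = character(),
                 n_cells_reset = integer(), mode = character(),
                 payload = character(), stringsAsFactors = FALSE)
    traj$scores <- scores
    traj$events <- ev
  }
  traj
}

#' Deploy a genome for a full lifespan
#'
#' Initializes the tissue from the structural genes with zeroed recurrent
#' memories and advances it for `steps` time steps, applying any perturbation
#' schedules (including per-step genome diffusion with controller re-decoding
#' when `mutation_sigma > 0`). The expressed type grid is recorded at every
#' step; full state snapshots are recorded when `record_states = TRUE`.
#' Trajectories are bitwise reproducible under a fixed seed and
#' configuration.
#'
#' @param genome an `nca_genome`.
#' @param config an [nca_config()]; its grid must match the genome.
#' @param schedules an [aging_schedules()] (or `NULL` for baseline
#'   conditions).
#' @param seed master seed for the run's random streams.
#' @param steps number of steps to simulate (default `config$t_A`).
#' @param record_states record full continuous states at every step.
#' @return an object of class `nca_trajectory` with the per-step type grids
#'   (`types`, one row per time `0..steps`), the final tissue, and the final
#'   gap-junction state.
#' @export
simulate_nca <- function(genome, config, schedules = NULL, seed = 1L,
                         steps = config$t_A, record_states = FALSE) {
  sim_loop(genome, config, schedules = schedules, seed = seed, steps = steps,
           record_states = record_states)
}

#' @export
print.nca_trajectory <- function(x, ...) {
  cat(sprintf("NCA trajectory: %d x %d grid, %d steps%s\n",
              x$height, x$width, x$steps,
              if (!is.null(x$events)) sprintf(", %d intervention events",
                                              nrow(x$events)) else ""))
  invisible(x)
}

#' Type grid of a trajectory at one time step
#'
#' @param trajectory an `nca_trajectory`.
#' @param t time step in `0..steps`.
#' @return an integer `height x width` type grid.
#' @export
type_grid <- function(trajectory, t) {
  stopifnot(t >= 0L, t <= trajectory$steps)
  matrix(trajectory$types[t + 1L, ], trajectory$height, trajectory$width)
}
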