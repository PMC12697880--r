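#' Canonical scaled-down study conditions
#'
#' The reference system (16 x 16 smiley, `t_D = 35`) is too large to evolve
#' routinely, so the package defines two fixed toy organisms used by its
#' scaled-down experiments; all tunables below are study conditions, chosen
#' once and documented in the methods vignette:
#'
#' * `stripe` — the 4 x 4 two-type stripe ([make_stripe()]), the standard
#'   evolution smoke task: population 24, at most 200 generations, 3
#'   evaluation repetitions, `t_D = 20`, training noise 0.125, sensor/
#'   recurrent dimensions 2/2.
#' * `face` — the 8 x 8 mini-smiley ([make_toy_face()]) with eye and mouth
#'   organs, the organism for aging, perturbation and rejuvenation
#'   experiments: same cell architecture, population 24, at most 300
#'   generations, `t_D = 35` (the reference developmental horizon), lifespan `t_A = 1000` (matching the reference
#'   perturbation experiments; `20 t_D = 700` marks the end-of-life point of
#'   the unperturbed aging comparison).
#'
#' @param which `"stripe"` or `"face"`.
#' @return a list with `pattern` (a [target_pattern()]) and `config`
#'   (an [nca_config()]).
#' @export
toy_study_conditions <- function(which = c("stripe", "face")) {
  which <- match.arg(which)
  if (which == "stripe") {
    pattern <- make_stripe()
    arch <- nca_architecture(width = 4L, height = 4L, n_types = 2L,
                             n_hidden = 1L, sensor_dim = 2L, hidden_dim = 2L)
    config <- nca_config(arch, t_D = 20L, t_A = 400L, xi_c = 0.125,
                         population = 24L, generations = 200L,
                         repetitions = 3L)
  } else {
    pattern <- make_toy_face()
    arch <- nca_architecture(width = 8L, height = 8L, n_types = 3L,
                             n_hidden = 1L, sensor_dim = 2L, hidden_dim = 2L)
    config <- nca_config(arch, t_D = 35L, t_A = 1000L, xi_c = 0.125,
                         population = 24L, generations = 300L,
                         repetitions = 3L)
  }
  list(pattern = pattern, config = config)
}

#' The four lifetime perturbation mechanisms at their reference settings
#'
#' Misdifferentiation noise rising linearly from 0 to 1 over the lifespan,
#' competency falling from 1 to 0 along the quartic-sine schedule,
#' gap-junction open fraction falling linearly from 1 to 0, and genetic
#' damage with per-step standard deviation `sigma_x = 0.01`.
#'
#' @return a named list of [aging_schedules()], one per mechanism.
#' @export
reference_mechanisms <- function() {
  list(noise = aging_schedules(noise = schedule("linear", 0, 1)),
       competency = aging_schedules(competency = schedule("sin4", 1, 0)),
       gap_junction = aging_schedules(gap_junction = schedule("linear", 1, 0)),
       mutation = aging_schedules(mutation_sigma = 0.01))
}
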