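#' Time-dependent perturbation schedules
#'
#' Aging-acceleration experiments modulate simulation parameters over the
#' lifespan `t_A` through simple schedule specifications:
#' * `constant` — always `from`;
#' * `linear` — linear interpolation from `from` at `t = 0` to `to` at
#'   `t = t_A`;
#' * `sin4` — `from + (to - from) * (1 - sin((pi/2) (1 - t/t_A))^4)`, the
#'   quartic-sine form used for the competency schedule: with `from = 1`,
#'   `to = 0` it evaluates to `sin^4((pi/2)(1 - t/t_A))`, i.e. 1 at birth and
#'   0 at the end of life.
#'
#' @param kind one of `"constant"`, `"linear"`, `"sin4"`.
#' @param from value at `t = 0`.
#' @param to value at `t = t_A` (ignored for `constant`).
#' @return an object of class `nca_schedule`.
#' @export
schedule <- function(kind = c("constant", "linear", "sin4"), from, to = from) {
  kind <- match.arg(kind)
  s <- list(kind = kind, from = from, to = to)
  class(s) <- "nca_schedule"
  s
}

#' Evaluate a schedule at a time step
#'
#' @param spec an [schedule()] object (or `NULL`, returning `default`).
#' @param t time step, `0 <= t <= t_A`.
#' @param t_A lifespan over which the schedule is stretched.
#' @param default value returned when `spec` is `NULL`.
#' @return the schedule value at `t`.
#' @examples
#' eval_schedule(schedule("linear", 1, 0), t = 500, t_A = 1000) # 0.5
#' eval_schedule(schedule("sin4", 1, 0), t = 500, t_A = 1000)   # sin^4(pi/4) = 0.25
#' @export
eval_schedule <- function(spec, t, t_A, default = NA_real_) {
  if (is.null(spec)) return(default)
  if (is.numeric(spec) && length(spec) == 1L) return(as.numeric(spec))
  if (!inherits(spec, "nca_schedule")) stop("unknown schedule specification")
  frac <- if (t_A > 0) t / t_A else 0
  switch(spec$kind,
         constant = spec$from,
         linear = spec$from + (spec$to - spec$from) * frac,
         sin4 = spec$from + (spec$to - spec$from) *
           (1 - sin((pi / 2) * (1 - frac))^4),
         stop(sprintf("unknown schedule kind '%s'", spec$kind)))
}

#' Parse a schedule from a compact string
#'
#' Accepts the CLI syntax `kind:from:to`, e.g. `"linear:0:1"` or
#' `"constant:0.125"`.
#'
#' @param text schedule string.
#' @return an [schedule()] object.
#' @export
parse_schedule <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (!(length(parts) %in% c(2L, 3L))) stop(sprintf("malformed schedule '%s'", text))
  vals <- suppressWarnings(as.numeric(parts[-1]))
  if (anyNA(vals)) stop(sprintf("malformed schedule '%s'", text))
  schedule(parts[1], vals[1], if (length(vals) == 2L) vals[2] else vals[1])
}

#' Bundle of lifetime perturbation mechanisms
#'
#' Collects the four aging-acceleration mechanisms applied over a lifespan:
#' the misdifferentiation noise schedule for the state-update noise
#' amplitude, the competency schedule for the probability that a proposed
#' cell action is actually applied, the gap-junction schedule for the
#' fraction of intercellular links kept open, and the per-step standard
#' deviation of the functional-genome random walk (genetic damage).
#'
#' With no schedules attached a run uses the baseline conditions: constant
#' noise (the run configuration's `xi_c`), full competency, all gap junctions
#' open, no mutation.
#'
#' @param noise schedule for the noise amplitude `xi_c(t)` (or `NULL`).
#' @param competency schedule for `P_D(t)` in `[0, 1]` (or `NULL`).
#' @param gap_junction schedule for `P_GJ(t)` in `[0, 1]` (or `NULL`).
#' @param mutation_sigma per-step mutation standard deviation `sigma_x >= 0`
#'   (0 disables genetic damage).
#' @return an object of class `aging_schedules`.
#' @export
aging_schedules <- function(noise = NULL, competency = NULL,
                            gap_junction = NULL, mutation_sigma = 0) {
  stopifnot(mutation_sigma >= 0)
  s <- list(noise = noise, competency = competency,
            gap_junction = gap_junction, mutation_sigma = mutation_sigma)
  class(s) <- "aging_schedules"
  s
}

#' Gap-junction connectivity state
#'
#' Tracks, for every cell, which of its incoming neighbor links are
#' permanently blocked. Links are directed: closing cell i's link from a
#' neighbor only blocks what i perceives. Closure is monotone: once closed, a
#' link never reopens. Out-of-grid slots of edge cells are not links.
#'
#' @param arch an [nca_architecture()] (supplies grid dimensions).
#' @return an object of class `gap_junction_state` with fields `open`
#'   (`n_cells x 8` logical, `TRUE` for open in-grid links, `FALSE` both for
#'   closed links and non-existent out-of-grid slots) and `n_links` (per-cell
#'   in-grid link count).
#' @export
gap_junction_state <- function(arch) {
  nb <- neighbor_index(arch$width, arch$height)
  open <- nb > 0L
  g <- list(open = open, n_links = rowSums(open))
  class(g) <- "gap_junction_state"
  g
}

#' Close gap junctions down to a target open fraction
#'
#' For each cell, while the fraction of its still-open links exceeds
#' `p_target`, one uniformly chosen open link is permanently blocked. After
#' the call every cell's open fraction is at most `p_target` (up to the 1/N
#' quantization of discrete links). `p_target = 1` never closes anything;
#' `p_target = 0` isolates every cell completely.
#'
#' @param gj a [gap_junction_state()].
#' @param p_target target open fraction `P_GJ(t)` in `[0, 1]`.
#' @param stream an [rng_stream()] used to pick which links close.
#' @return the updated `gap_junction_state`.
#' @export
update_gap_junctions <- function(gj, p_target, stream) {
  stopifnot(p_target >= 0, p_target <= 1)
  n_open <- rowSums(gj$open)
  allowed <- floor(p_target * gj$n_links + 1e-9)
  need <- which(n_open > allowed & n_open > 0L)
  if (length(need)) {
    for (i in need) {
      open_slots <- which(gj$open[i, ])
      k <- n_open[i] - allowed[i]
      close <- if (length(open_slots) == 1L) open_slots else
        stream_sample(stream, open_slots, k)
      gj$open[i, close] <- FALSE
    }
  }
  gj
}

#' One step of diffusive genetic damage
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation `sigma` to
#' every functional gene (the shared controller parameters); structural genes
#' are never mutated during life. Applied at every time step this is a random
#' walk whose per-parameter variance grows as `t * sigma^2`.
#'
#' @param functional numeric vector of functional genes.
#' @param sigma per-step standard deviation `sigma_x >= 0`.
#' @param stream an [rng_stream()].
#' @return the mutated functional gene vector.
#' @export
mutate_genome_step <- function(functional, sigma, stream) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(functional)
  functional + sigma * stream_rnorm(stream, length(functional))
}
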