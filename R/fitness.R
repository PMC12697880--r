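#' Morphogenesis fitness score
#'
#' Scores a developmental trajectory against a target pattern:
#' \deqn{r = (2 n_G - N_j) + r_T n_T - r_S n_S}
#' where `n_G` counts cells expressing their target type at the end of the
#' scored window (`t_D`), `n_T` counts steps `1..t_D` at which the target
#' pattern is realized entirely, and `n_S` counts pairs of successive steps
#' `(t, t+1)` with `1 <= t <= t_D - 1` during which no cell changed its
#' expressed type. A pattern term of `N_j` (all cells correct, so
#' `r = N_j` at `r_T = r_S = 0`) marks the task as solved.
#'
#' When scoring whole lifespans rather than development, pass the lifespan
#' end as `t_D`: the stagnation term then accumulates over the entire scored
#' window.
#'
#' @param trajectory an `nca_trajectory` (from [simulate_nca()]).
#' @param target a [target_pattern()].
#' @param r_T premature-completion bonus weight.
#' @param r_S stagnation penalty weight.
#' @param t_D end of the scored window; the trajectory must cover it.
#' @return an object of class `fitness_breakdown` with counters `n_G`,
#'   `n_T`, `n_S`, the weights, the pattern term `2 n_G - N_j`, and the
#'   total score `r`.
#' @export
nca_fitness <- function(trajectory, target, r_T = 0.1, r_S = 0.1,
                        t_D = trajectory$t_D) {
  if (trajectory$steps < t_D) {
    stop(sprintf("trajectory covers %d steps but t_D = %d", trajectory$steps, t_D))
  }
  tv <- as.vector(target$types)
  n_j <- length(tv)
  rows <- trajectory$types[seq_len(t_D + 1L), , drop = FALSE]
  n_G <- sum(rows[t_D + 1L, ] == tv)
  full <- vapply(seq_len(t_D) + 1L, function(i) all(rows[i, ] == tv), NA)
  n_T <- sum(full)
  n_S <- 0L
  if (t_D >= 2L) {
    static <- vapply(2L:(t_D), function(i) all(rows[i, ] == rows[i + 1L, ]), NA)
    n_S <- sum(static)
  }
  pattern <- 2L * n_G - n_j
  fb <- list(n_G = n_G, n_T = n_T, n_S = n_S, N_j = n_j,
             r_T = r_T, r_S = r_S, pattern_term = pattern,
             r = pattern + r_T * n_T - r_S * n_S)
  class(fb) <- "fitness_breakdown"
  fb
}

#' @export
print.fitness_breakdown <- function(x, ...) {
  cat(sprintf("fitness r = %.3f (pattern term %d; n_G = %d/%d, n_T = %d, n_S = %d)\n",
              x$r, x$pattern_term, x$n_G, x$N_j, x$n_T, x$n_S))
  invisible(x)
}

#' Pattern-match term at a single time step
#'
#' The term `2 n_G(t) - N_j` of the fitness score evaluated against the type
#' grid recorded at time `t`; used to track morphological integrity over a
#' lifespan.
#'
#' @param trajectory an `nca_trajectory`.
#' @param target a [target_pattern()].
#' @param t time step in `0..steps`.
#' @return a number in `[-N_j, N_j]`.
#' @export
pattern_term <- function(trajectory, target, t) {
  tv <- as.vector(target$types)
  2L * sum(trajectory$types[t + 1L, ] == tv) - length(tv)
}
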