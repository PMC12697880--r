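#' Rejuvenation intervention policy
#'
#' Configures organ-level monitoring and threshold-triggered resets. An organ
#' is treated at step `t` when its score drops strictly below `threshold`
#' (the printed rule is `r_o < r_th`) and at least `refractory` steps have
#' passed since the organ's last intervention, allowing unperturbed
#' development in between. Two intervention modes exist: resetting the whole
#' organ (`organ_full_reset`) or only its wrongly expressed cells
#' (`wrong_cells_reset`), each optionally augmented with the organ's boundary
#' ring for both scoring and resetting. The reset payload is either the
#' cell's primordial initial state from the structural genes
#' (`initial_state`) or an indicator encoding of the target type
#' (`target_state`: +1 on the target channel, -1 on the other indicator
#' channels, hidden channels 0). Reset cells also have their recurrent
#' working memory erased.
#'
#' @param threshold score threshold `r_th` in `(0, 1]` (default 0.6).
#' @param mode `"organ_full_reset"` or `"wrong_cells_reset"`.
#' @param include_boundary logical: augment scoring and resets with the
#'   boundary ring. Either a single flag or a named logical vector per organ
#'   (organs missing from the vector default to `FALSE`, e.g. to omit the
#'   mouth's boundary while using the eyes').
#' @param payload `"initial_state"` or `"target_state"`.
#' @param refractory minimum steps between interventions on the same organ
#'   (default 25).
#' @param start first step at which monitoring may trigger interventions
#'   (default 0; set to the developmental horizon to leave development
#'   untouched).
#' @return an object of class `intervention_policy`.
#' @export
intervention_policy <- function(threshold = 0.6,
                                mode = c("organ_full_reset", "wrong_cells_reset"),
                                include_boundary = FALSE,
                                payload = c("initial_state", "target_state"),
                                refractory = 25L, start = 0L) {
  mode <- match.arg(mode)
  payload <- match.arg(payload)
  if (!(threshold > 0 && threshold <= 1) && threshold != 0) {
    stop("threshold must be in (0, 1] (or 0 to disable)")
  }
  if (refractory < 1L) stop("refractory must be >= 1")
  p <- list(threshold = threshold, mode = mode,
            include_boundary = include_boundary, payload = payload,
            refractory = as.integer(refractory), start = as.integer(start))
  class(p) <- "intervention_policy"
  p
}

policy_boundary <- function(policy, organ_name) {
  ib <- policy$include_boundary
  if (length(ib) == 1L && is.null(names(ib))) return(isTRUE(ib))
  isTRUE(ib[[organ_name]])
}

#' Organ score
#'
#' The fraction of correctly expressed target cells over an organ's scored
#' cell set: the organ cells, plus its boundary ring when
#' `include_boundary = TRUE`.
#'
#' @param types integer type grid (matrix) or flattened type vector.
#' @param organ an [organ_mask()].
#' @param target the [target_pattern()].
#' @param include_boundary include the boundary ring in the scored set.
#' @return a fraction in `[0, 1]`.
#' @export
organ_score <- function(types, organ, target, include_boundary = FALSE) {
  tv <- as.vector(types)
  tgt <- as.vector(target$types)
  idx <- mask_index(organ$cells)
  if (include_boundary) {
    if (is.null(organ$boundary_cells)) {
      stop(sprintf("organ '%s' has no boundary ring; run dilate_boundary() first",
                   organ$name))
    }
    idx <- c(idx, mask_index(organ$boundary_cells))
  }
  if (!length(idx)) stop("empty scored cell set")
  mean(tv[idx] == tgt[idx])
}

#' Select organs due for intervention
#'
#' An organ is selected iff its score is strictly below the policy threshold
#' and its refractory period has elapsed; organs are independent.
#'
#' @param scores named numeric vector of current organ scores.
#' @param policy an [intervention_policy()].
#' @param last_event_times named numeric vector of each organ's last
#'   intervention time (`-Inf` if never treated).
#' @param t current time step.
#' @return character vector of organ names to treat.
#' @export
plan_interventions <- function(scores, policy, last_event_times, t) {
  due <- scores < policy$threshold &
    (t - last_event_times[names(scores)]) >= policy$refractory
  names(scores)[which(due)]
}

# core reset applied to raw state/memory matrices (shared by the public
# apply_intervention and the simulation loop)
apply_reset <- function(states, memory, organ, target, genome, policy,
                        organ_name = organ$name) {
  n_types <- target$n_types
  tgt <- as.vector(target$types)
  cells <- mask_index(organ$cells)
  if (policy_boundary(policy, organ_name)) {
    cells <- c(cells, mask_index(organ$boundary_cells))
  }
  if (policy$mode == "wrong_cells_reset") {
    expressed <- expressed_types_vec(states, n_types)
    cells <- cells[expressed[cells] != tgt[cells]]
  }
  if (length(cells)) {
    if (policy$payload == "initial_state") {
      states[, cells] <- genome$structural[, cells]
    } else {
      enc <- matrix(0, nrow(states), length(cells))
      enc[seq_len(n_types), ] <- -1
      enc[cbind(tgt[cells], seq_along(cells))] <- 1
      states[, cells] <- enc
    }
    memory[, cells] <- 0
  }
  list(states = states, memory = memory, n_cells = length(cells),
       cells = cells)
}

#' Apply one rejuvenation intervention to a tissue
#'
#' Replaces the selected cells' continuous states with the policy payload and
#' erases their recurrent memories; all other cells are untouched.
#'
#' @param tissue an [make_tissue()] object.
#' @param organ an [organ_mask()].
#' @param target the [target_pattern()].
#' @param genome the `nca_genome` (supplies primordial initial states).
#' @param policy an [intervention_policy()].
#' @return a list with the modified `tissue` and an `event` record
#'   (time, organ, cells reset, mode, payload).
#' @export
apply_intervention <- function(tissue, organ, target, genome, policy) {
  res <- apply_reset(tissue$states, tissue$memory, organ, target, genome, policy)
  tissue$states <- res$states
  tissue$memory <- res$memory
  list(tissue = tissue,
       event = list(time = tissue$time, organ = organ$name,
                    cells = res$cells, n_cells_reset = res$n_cells,
                    mode = policy$mode, payload = policy$payload))
}

#' Deploy a genome with organ monitoring and rejuvenation interventions
#'
#' Runs [simulate_nca()] with per-step organ scoring: after every state
#' update the expressed types are scored per organ, and any organ due under
#' the policy is treated before the next dynamics step. The returned
#' trajectory carries the per-step score log (`$scores`) and the intervention
#' event log (`$events`).
#'
#' @param genome an `nca_genome`.
#' @param config an [nca_config()].
#' @param policy an [intervention_policy()].
#' @param organs named list of [organ_mask()]s (e.g. `pattern$organs`).
#' @param target the [target_pattern()].
#' @param schedules optional [aging_schedules()].
#' @param seed master seed.
#' @param steps steps to simulate (default `config$t_A`).
#' @return an `nca_trajectory` with `scores` and `events`.
#' @export
run_with_rejuvenation <- function(genome, config, policy, organs, target,
                                  schedules = NULL, seed = 1L,
                                  steps = config$t_A) {
  for (nm in names(organs)) {
    if (policy_boundary(policy, nm) && is.null(organs[[nm]]$boundary_cells)) {
      organs[[nm]] <- dilate_boundary(organs[[nm]], target)
    }
  }
  sim_loop(genome, config, schedules = schedules, seed = seed, steps = steps,
           policy = policy, organs = organs, target = target)
}
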