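#' Growth-model parameters
#'
#' Bundles the parameters of the agent-based branch growth model. Branch tips
#' extend in fixed-length steps; at each step a tip proposes up to
#' `n_candidate_dirs` headings (previous heading plus Gaussian noise) and takes
#' the first one whose new segment stays inside the field and clears the
#' avoidance tests. With `repulsion = TRUE` a candidate segment is rejected when
#' it passes within `avoid_radius` of any segment — or the soma — of a
#' *different* cell (the tiled regime); with `self_avoidance = TRUE` the same
#' test is applied against
#' the cell's own segments, excluding segments incident to the tip's node, its
#' parent or its grandparent so that a branch never collides with its own
#' recent history or a freshly spawned sibling. A tip whose candidates are all
#' rejected stalls permanently. After a successful extension the tip branches
#' with probability `branch_prob`, splitting into two tips whose headings
#' diverge by `divergence_angle`.
#'
#' All length-like quantities are in pixel units of the rendered field;
#' angles are in radians.
#'
#' @param n_cells number of astrocytes in the culture.
#' @param field_size numeric length-2, (width, height) of the field in pixels.
#' @param soma_min_spacing minimum distance between any two somata, pixels.
#' @param primaries_per_cell number of primary branches seeded at each soma.
#' @param step_length tip extension per accepted step, pixels.
#' @param angle_noise_sd s.d. of the Gaussian heading noise, radians.
#' @param branch_prob probability per tip per accepted step of splitting.
#' @param divergence_angle angular separation of the two tips after a split,
#'   radians.
#' @param avoid_radius rejection distance for the avoidance tests, pixels.
#' @param n_candidate_dirs number of candidate headings proposed per step.
#' @param n_steps number of growth steps.
#' @param repulsion logical; reject candidates near other cells' branches
#'   (TRUE = tiled regime, FALSE = neutral regime).
#' @param self_avoidance logical; reject candidates near non-adjacent segments
#'   of the same cell.
#' @return an object of class `growth_params` (a validated list).
#' @seealso [growth_preset()], [generate_culture()]
#' @export
growth_params <- function(n_cells = 9,
                          field_size = c(900, 900),
                          soma_min_spacing = 200,
                          primaries_per_cell = 5,
                          step_length = 3,
                          angle_noise_sd = 0.4,
                          branch_prob = 0.35,
                          divergence_angle = 1.2,
                          avoid_radius = 4,
                          n_candidate_dirs = 8,
                          n_steps = 200,
                          repulsion = TRUE,
                          self_avoidance = TRUE) {
  p <- list(n_cells = as.integer(n_cells),
            field_size = as.numeric(field_size),
            soma_min_spacing = as.numeric(soma_min_spacing),
            primaries_per_cell = as.integer(primaries_per_cell),
            step_length = as.numeric(step_length),
            angle_noise_sd = as.numeric(angle_noise_sd),
            branch_prob = as.numeric(branch_prob),
            divergence_angle = as.numeric(divergence_angle),
            avoid_radius = as.numeric(avoid_radius),
            n_candidate_dirs = as.integer(n_candidate_dirs),
            n_steps = as.integer(n_steps),
            repulsion = isTRUE(repulsion),
            self_avoidance = isTRUE(self_avoidance))
  validate_growth_params(p)
  class(p) <- "growth_params"
  p
}

validate_growth_params <- function(p) {
  stopifnot(p$n_cells >= 1,
            length(p$field_size) == 2, all(p$field_size > 0),
            p$soma_min_spacing > 0,
            p$primaries_per_cell >= 1,
            p$step_length > 0,
            p$angle_noise_sd >= 0,
            p$branch_prob >= 0, p$branch_prob <= 1,
            p$divergence_angle >= 0,
            p$avoid_radius >= 0,
            p$n_candidate_dirs >= 1,
            p$n_steps >= 0)
  invisible(p)
}

#' Named growth-parameter presets
#'
#' Two calibrated regimes. `"tiled-DIV15"` is the repulsive (contact-avoiding)
#' regime grown long enough to emulate a mature, densely branched culture:
#' deep multi-order branching (maximum topological order above 20) with
#' essentially exclusive territories. `"neutral"` is identical except that
#' repulsion against other cells is switched off, so branches cross freely
#' into neighbouring territories.
#'
#' @param name `"tiled-DIV15"` or `"neutral"`.
#' @param ... overrides passed on to [growth_params()] (e.g. `n_steps` for an
#'   earlier developmental snapshot).
#' @return a `growth_params` object.
#' @export
growth_preset <- function(name = c("tiled-DIV15", "neutral"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "tiled-DIV15" = list(repulsion = TRUE),
    "neutral"     = list(repulsion = FALSE, n_steps = 60))
  args <- utils::modifyList(base, list(...))
  do.call(growth_params, args)
}

#' Excitotoxic-retraction parameters
#'
#' Parameters for the perturbation that emulates glutamate excitotoxicity:
#' over `n_rounds` rounds each terminal branch is removed independently with
#' probability `terminal_prune_prob`; with `exploration = TRUE` surviving tips
#' subsequently extend short segments *without* any avoidance test, emulating
#' exploratory processes that cross into neighbouring territories.
#'
#' @param terminal_prune_prob per-round removal probability of each terminal
#'   branch, in `[0, 1]`.
#' @param n_rounds number of pruning rounds (>= 0).
#' @param exploration logical; grow short neutral segments from surviving tips
#'   after pruning.
#' @param exploration_steps number of neutral steps per surviving tip.
#' @return an object of class `retraction_params`.
#' @export
retraction_params <- function(terminal_prune_prob = 0.5, n_rounds = 2,
                              exploration = TRUE, exploration_steps = 4) {
  stopifnot(terminal_prune_prob >= 0, terminal_prune_prob <= 1,
            n_rounds >= 0, exploration_steps >= 0)
  structure(list(terminal_prune_prob = as.numeric(terminal_prune_prob),
                 n_rounds = as.integer(n_rounds),
                 exploration = isTRUE(exploration),
                 exploration_steps = as.integer(exploration_steps)),
            class = "retraction_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Growth parameters\n")
  cat(sprintf("  %d cells on a %g x %g field (soma spacing >= %g)\n",
              x$n_cells, x$field_size[1], x$field_size[2], x$soma_min_spacing))
  cat(sprintf("  %d primaries, step %g px, noise sd %g rad, branch prob %g\n",
              x$primaries_per_cell, x$step_length, x$angle_noise_sd,
              x$branch_prob))
  cat(sprintf("  avoid radius %g px, %d candidates, %d steps, repulsion %s, self-avoidance %s\n",
              x$avoid_radius, x$n_candidate_dirs, x$n_steps,
              if (x$repulsion) "on" else "off",
              if (x$self_avoidance) "on" else "off"))
  invisible(x)
}
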