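#' Per-reaction rates of the intracellular model
#'
#' Evaluates every reaction rate law of the signaling network at a given cell
#' state. Environment slots of the state vector (`vegf_ext`, `dll4_nb`, ...)
#' carry the local extracellular VEGF-A available to the cell and the Dll4
#' presented by its neighbors, so the caller controls the cell's context.
#'
#' @param model An [ec_model()].
#' @param state Named (or model-ordered) numeric vector over all model
#'   species, amounts `>= 0`.
#' @param dll4_nb Trans-ligand amount; overwrites the `dll4_nb` slot.
#' @param vegf_local Extracellular VEGF-A available; overwrites `vegf_ext`.
#' @param params Parameter vector (defaults to the model's packaged values).
#' @return Named numeric vector of reaction rates (particles/h), one entry per
#'   reaction.
#' @examples
#' m <- ec_model()
#' r <- reaction_rates(m, dll4_nb = 5, vegf_local = 0)
#' r[["trans_bind"]]  # kt * notch1 * dll4_nb
#' @export
reaction_rates <- function(model, state = NULL, dll4_nb = 0, vegf_local = 0,
                           params = NULL) {
  cm <- model_compile(model)
  x <- prep_state(model, state)
  if (dll4_nb < 0 || vegf_local < 0) {
    stop("dll4_nb and vegf_local must be >= 0", call. = FALSE)
  }
  x["dll4_nb"] <- dll4_nb
  x["vegf_ext"] <- vegf_local
  p <- prep_params(model, params)
  r <- cpp_reaction_rates(cm, unname(x), unname(p))
  stats::setNames(r, cm$reaction_names)
}

#' One forward-Euler step of a cell's signaling state
#'
#' Advances the intracellular ODE system by `dt` hours using forward Euler
#' with two numerical guards: reaction fluxes are clipped within each step so
#' that consumption never drives a species below zero, and the step is split
#' into finer internal sub-steps whenever any variable would change by more
#' than 25% at once. Environment slots are treated like ordinary species, so
#' their change reports the exchange with the surroundings (e.g. VEGF-A bound
#' from the local pool).
#'
#' @inheritParams reaction_rates
#' @param dt Step length in hours, `>= 0`. `dt = 0` returns the state
#'   unchanged.
#' @param max_halvings Maximum number of times the internal step may be
#'   halved before the remaining error is accepted.
#' @return The updated named state vector.
#' @examples
#' m <- ec_model()
#' x <- euler_step(m, dt = 0.1, vegf_local = 100)
#' @export
euler_step <- function(model, state = NULL, dt = 0.1, dll4_nb = 0,
                       vegf_local = 0, params = NULL, max_halvings = 12) {
  cm <- model_compile(model)
  x <- prep_state(model, state)
  x["dll4_nb"] <- dll4_nb
  x["vegf_ext"] <- vegf_local
  if (!is.finite(dt) || dt < 0) stop("dt must be finite and >= 0", call. = FALSE)
  p <- prep_params(model, params)
  out <- cpp_cell_step(cm, unname(x), unname(p), dt, max_halvings)
  stats::setNames(out, model$species)
}

#' Simulate a single uncoupled cell
#'
#' Integrates one cell's signaling over time with a fixed extracellular
#' context: VEGF-A clamped at `vegf_local` (a non-depleting bath) and a fixed
#' trans-ligand amount `dll4_nb`. Useful for steady-state and convergence
#' studies of the ODE core without lattice coupling.
#'
#' @inheritParams euler_step
#' @param t_end Total simulated time (h).
#' @param record_every Record the state every this many steps.
#' @return A list with `time` (vector) and `state` (matrix, one row per record
#'   point, one column per species).
#' @export
simulate_cell <- function(model, state = NULL, t_end = 100, dt = 0.1,
                          dll4_nb = 0, vegf_local = 0, params = NULL,
                          record_every = 10L, max_halvings = 12) {
  cm <- model_compile(model)
  x <- prep_state(model, state)
  p <- prep_params(model, params)
  n_steps <- round(t_end / dt)
  keep <- seq(0, n_steps, by = record_every)
  out <- matrix(NA_real_, length(keep), length(model$species),
                dimnames = list(NULL, model$species))
  out[1, ] <- x
  row <- 2L
  for (s in seq_len(n_steps)) {
    x["dll4_nb"] <- dll4_nb
    x["vegf_ext"] <- vegf_local
    x <- stats::setNames(
      cpp_cell_step(cm, unname(x), unname(p), dt, max_halvings),
      model$species)
    x[model$env_species] <- 0
    if (s %in% keep) {
      out[row, ] <- x
      row <- row + 1L
    }
  }
  list(time = keep * dt, state = out)
}

#' Simulate a static lattice of coupled cells
#'
#' Integrates a fixed arrangement of cells (no movement, no proliferation)
#' whose Dll4-Notch1 systems are coupled through the neighbor-sharing rule:
#' each cell receives every neighbor's Dll4 divided by that neighbor's own
#' contact count, and trans binding consumes the presenting neighbor's ligand.
#' All cells sit in a VEGF-A bath clamped at `vegf_bath`. This is the
#' canonical setting for lateral-inhibition patterning experiments (two-cell
#' and 1-D ring fixtures, see [make_fixture()]).
#'
#' @param fixture A cell fixture as returned by [make_fixture()] (kinds
#'   `two_cell` and `ring_n`), or a list with elements `model`, `states`
#'   (cells x species matrix), `params` (cells x parameters matrix) and
#'   `neighbors` (list of integer neighbor indices, 1-based).
#' @param t_end,dt Simulated time and step (h).
#' @param vegf_bath Clamped extracellular VEGF-A per cell.
#' @param record_every Record every this many steps.
#' @param max_halvings Internal sub-stepping limit per cell step.
#' @return List with `time`, `traj` (one state matrix per cell) and `final`
#'   (cells x species matrix).
#' @export
simulate_cells <- function(fixture, t_end = 200, dt = 0.1, vegf_bath = 50,
                           record_every = 10L, max_halvings = 12) {
  m <- fixture$model
  cm <- model_compile(m)
  nb0 <- lapply(fixture$neighbors, function(v) as.integer(v) - 1L)
  res <- cpp_simulate_static(cm, fixture$states, fixture$params, nb0,
                             vegf_bath, dt, as.integer(round(t_end / dt)),
                             as.integer(record_every), max_halvings)
  colnames(res$final) <- m$species
  res$traj <- lapply(res$traj, function(tr) {
    colnames(tr) <- m$species
    tr
  })
  res
}

prep_state <- function(model, state) {
  full <- model_initial_state(model)
  if (is.null(state)) return(full)
  if (!is.null(names(state))) {
    bad <- setdiff(names(state), model$species)
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    full[names(state)] <- state
  } else {
    if (length(state) != length(model$species)) {
      stop(sprintf("state length %d does not match the model's %d variables",
                   length(state), length(model$species)), call. = FALSE)
    }
    full[] <- state
  }
  if (any(!is.finite(full)) || any(full < 0)) {
    stop("state must be finite and >= 0", call. = FALSE)
  }
  full
}

prep_params <- function(model, params) {
  p <- model$params
  if (is.null(params)) return(p)
  if (!is.null(names(params))) {
    bad <- setdiff(names(params), names(p))
    if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    p[names(params)] <- params
  } else {
    if (length(params) != length(p)) stop("parameter length mismatch",
                                          call. = FALSE)
    p[] <- params
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("parameters must be finite and >= 0", call. = FALSE)
  }
  p
}
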