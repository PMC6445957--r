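#' Cell-to-cell parameter sampling configuration
#'
#' Selected intracellular parameters are not identical across cells but drawn
#' per cell from log-normal distributions, inducing cellular heterogeneity.
#' Three parameter groups can be sampled: the maximal transcription rates
#' (`"tc"`), the translation rates (`"tl"`) and the NICD degradation rate
#' (`"nicd_deg"`); `"all"` selects all three, `"none"` disables sampling. The
#' distributions are parameterized by their actual mean (the model's parameter
#' value) and standard deviation `sd_frac * mean`, so `sd_frac` is the SD/mean
#' ratio reported for heterogeneity sweeps; `sd_frac = 0` degenerates to the
#' mean.
#'
#' @param group One of `"tc"`, `"tl"`, `"nicd_deg"`, `"all"`, `"none"`, or a
#'   character vector combining the first three.
#' @param sd_frac SD/mean ratio of the log-normal laws, `>= 0`.
#' @return A list of class `sampling_config`.
#' @export
sampling_config <- function(group = "all", sd_frac = 0.5) {
  valid <- c("tc", "tl", "nicd_deg", "all", "none")
  if (!all(group %in% valid)) {
    stop("group must be among ", paste(valid, collapse = ", "), call. = FALSE)
  }
  if (sd_frac < 0) stop("sd_frac must be >= 0", call. = FALSE)
  structure(list(group = group, sd_frac = sd_frac), class = "sampling_config")
}

param_groups <- function() {
  list(
    tc = c("vmax_tc_notch1", "vmax_tc_dll4", "vmax_tc_vegfr1",
           "vmax_tc_svegfr1", "vmax_tc_vegfr2"),
    tl = c("k_tl_notch1", "k_tl_dll4", "k_tl_mvegfr1", "k_tl_svegfr1",
           "k_tl_vegfr2"),
    nicd_deg = "k_nicd_degradation"
  )
}

sampled_param_names <- function(sampling) {
  g <- sampling$group
  if (identical(g, "none") || sampling$sd_frac == 0) return(character(0))
  if ("all" %in% g) g <- c("tc", "tl", "nicd_deg")
  unique(unlist(param_groups()[g]))
}

# per-parameter SD vector aligned to the model's parameter order
param_sd_vector <- function(model, sampling) {
  sd <- stats::setNames(numeric(length(model$params)), names(model$params))
  nm <- sampled_param_names(sampling)
  sd[nm] <- sampling$sd_frac * model$params[nm]
  sd
}

# initial amounts of seeded cells are sampled with the same SD/mean ratio
# whenever any parameter group is sampled; environment slots stay zero
initial_sd_vector <- function(model, sampling) {
  x0 <- model_initial_state(model)
  if (length(sampled_param_names(sampling)) == 0) return(0 * x0)
  sampling$sd_frac * x0
}

#' Sample per-cell signaling parameters
#'
#' Draws one parameter vector per cell. Sampled parameters follow log-normal
#' laws moment-matched so the distribution's mean equals the model's parameter
#' value and its standard deviation equals `sd_frac` times that value
#' (`meanlog = log(mu) - sigma2/2`, `sdlog^2 = sigma2 = log(1 + (sd/mu)^2)`).
#' Non-selected parameters are identical across cells.
#'
#' @param model An [ec_model()].
#' @param sampling A [sampling_config()].
#' @param n Number of cells.
#' @return An `n` x `length(model$params)` matrix, one row per cell.
#' @examples
#' m <- ec_model()
#' p <- sample_agent_params(m, sampling_config("tc", 0.5), n = 3)
#' @export
sample_agent_params <- function(model, sampling = sampling_config(), n = 1) {
  mu <- model$params
  sd <- param_sd_vector(model, sampling)
  out <- matrix(rep(mu, each = n), nrow = n,
                dimnames = list(NULL, names(mu)))
  for (j in which(sd > 0 & mu > 0)) {
    s2 <- log(1 + (sd[j] / mu[j])^2)
    out[, j] <- stats::rlnorm(n, meanlog = log(mu[j]) - s2 / 2,
                              sdlog = sqrt(s2))
  }
  out
}

#' Simulation configuration
#'
#' Collects everything a run needs: grid geometry, time stepping, the
#' intracellular model and its per-cell sampling, extracellular transport
#' parameters, agent behavior, the seeding scenario and the RNG seed. Defaults
#' are the packaged calibration: a 200 x 200 lattice (7 um/site, i.e. a
#' 1.4 x 1.4 mm sub-area of a culture well) simulated for 199 h at dt = 0.1 h,
#' seeded with two cell aggregates that represent embryoid bodies.
#'
#' @param grid `c(nr, nc)` lattice dimensions.
#' @param dx_um Lattice spacing in micrometers per site.
#' @param dt Scheduler time step (h).
#' @param t_end Total simulated time (h).
#' @param output_times Times (h) at which full snapshots are recorded; the
#'   initial state is always included.
#' @param seed Integer RNG seed; every stochastic element of the run (per-cell
#'   parameters, the asynchronous update order, movement) derives from it.
#' @param scenario `"wild_type"`, or `"vegfr1_ko"` which zeroes the maximal
#'   transcription rates of both VEGFR1 splice isoforms in every cell.
#' @param aggregates `"two"` (filled discs at 1/4 and 3/4 of the grid width),
#'   `"single"` (one central disc), `"none"`, or a list of
#'   `list(row, col, radius)` entries.
#' @param aggregate_radius Disc radius in sites for the named layouts.
#' @param model The intracellular [ec_model()]; its parameter values act as
#'   the per-cell sampling means.
#' @param param_overrides Named numeric vector of model-parameter overrides
#'   applied on top of `model` (useful for sweeps).
#' @param medium List: `vegf_reference` (particles/site in the bulk medium)
#'   and `k_in` (1/h medium-exchange rate).
#' @param field_params List of transport constants: `D_vegf`, `D_sv`, `D_svb`
#'   (sites^2/h) and `kdeg_vegf`, `kdeg_sv`, `kdeg_svb` (1/h).
#' @param behavior A [behavior_params()].
#' @param sampling A [sampling_config()].
#' @param max_substeps Diffusion sub-step cap per scheduler step.
#' @param max_halvings Signaling sub-step cap (halvings) per scheduler step.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid = c(200, 200), dx_um = 7, dt = 0.1, t_end = 199,
                       output_times = c(60, 90, 120, 199), seed = 1,
                       scenario = c("wild_type", "vegfr1_ko"),
                       aggregates = "two", aggregate_radius = 5,
                       model = ec_model(), param_overrides = NULL,
                       medium = list(vegf_reference = 10000, k_in = 0.05),
                       field_params = list(D_vegf = 20, D_sv = 10, D_svb = 10,
                                           kdeg_vegf = 0.01, kdeg_sv = 0.05,
                                           kdeg_svb = 0.2),
                       behavior = behavior_params(),
                       sampling = sampling_config(),
                       max_substeps = 64, max_halvings = 12) {
  scenario <- match.arg(scenario)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (t_end < 0) stop("t_end must be >= 0", call. = FALSE)
  if (length(output_times) && max(output_times) > t_end) {
    stop("total time must cover the largest output time", call. = FALSE)
  }
  if (is.character(aggregates) &&
      !aggregates %in% c("two", "single", "none")) {
    stop("unknown aggregate layout '", aggregates, "'", call. = FALSE)
  }
  if (!is.null(param_overrides)) {
    model <- ec_model(params = replace(model$params,
                                       names(param_overrides),
                                       param_overrides),
                      initial = model$initial)
  }
  if (scenario == "vegfr1_ko") {
    model <- ec_model(params = replace(model$params,
                                       c("vmax_tc_vegfr1", "vmax_tc_svegfr1"),
                                       c(0, 0)),
                      initial = model$initial)
  }
  structure(list(grid = grid, dx_um = dx_um, dt = dt, t_end = t_end,
                 output_times = sort(unique(output_times)), seed = seed,
                 scenario = scenario, aggregates = aggregates,
                 aggregate_radius = aggregate_radius, model = model,
                 medium = medium, field_params = field_params,
                 behavior = behavior, sampling = sampling,
                 max_substeps = max_substeps, max_halvings = max_halvings),
            class = "sim_config")
}

aggregate_sites <- function(config) {
  nr <- config$grid[1]; nc <- config$grid[2]
  agg <- config$aggregates
  if (is.character(agg)) {
    rad <- config$aggregate_radius
    centers <- switch(agg,
      two = list(c(round(nr / 2), round(nc / 4)),
                 c(round(nr / 2), round(3 * nc / 4))),
      single = list(c(round(nr / 2), round(nc / 2))),
      none = list(),
      stop("unknown aggregate layout '", agg, "'", call. = FALSE))
    agg <- lapply(centers, function(ct) list(row = ct[1], col = ct[2],
                                             radius = rad))
  }
  sites <- matrix(integer(0), 0, 2)
  for (a in agg) {
    rs <- max(1, a$row - a$radius):min(nr, a$row + a$radius)
    cs <- max(1, a$col - a$radius):min(nc, a$col + a$radius)
    for (r in rs) for (cc in cs) {
      if ((r - a$row)^2 + (cc - a$col)^2 <= a$radius^2) {
        sites <- rbind(sites, c(r, cc))
      }
    }
  }
  unique(sites)
}

#' Run a full simulation
#'
#' Executes the scheduler loop: at every time step all extracellular fields
#' are updated (diffusion, sVEGFR1-VEGF binding, degradation, medium
#' replenishment, in that fixed order), then all agents are visited in a fresh
#' uniformly random permutation. Each agent performs its signaling Euler step
#' against the world as already modified by earlier agents in the permutation
#' (asynchronous updates), updates filopodia, exchanges VEGF-A and sVEGFR1
#' with the fields, re-evaluates its phenotype and, if a tip cell, attempts a
#' chemotactic move with stalk-cell proliferation filling the vacated site.
#'
#' Runs are bit-reproducible: identical `(config, seed)` give identical
#' records.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_record`: list with `series` (per-step
#'   data frame of time, agent count, tip count and relative vessel area),
#'   `snapshots` (list of full state snapshots at the configured output
#'   times), `final_fields`, and the `config`.
#' @examples
#' \donttest{
#' cfg <- sim_config(grid = c(60, 60), t_end = 30, output_times = 30, seed = 1)
#' rec <- run_simulation(cfg)
#' tail(rec$series)
#' }
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  model <- config$model
  cm <- model_compile(model)
  sites <- aggregate_sites(config)
  fp <- config$field_params
  cfg <- list(
    nr = as.integer(config$grid[1]), nc = as.integer(config$grid[2]),
    dt = config$dt, t_end = config$t_end,
    output_times = as.numeric(config$output_times),
    max_substeps = as.integer(config$max_substeps),
    max_halvings = as.integer(config$max_halvings),
    D_vegf = fp$D_vegf, D_sv = fp$D_sv, D_svb = fp$D_svb,
    kdeg_vegf = fp$kdeg_vegf, kdeg_sv = fp$kdeg_sv, kdeg_svb = fp$kdeg_svb,
    vegf_ref = config$medium$vegf_reference, k_in = config$medium$k_in,
    k_on_sv = unname(model$params["k_on_svegfr1"]),
    k_off_sv = unname(model$params["k_off_svegfr1"]),
    behavior = unclass(config$behavior),
    param_mu = unname(model$params),
    param_sd = unname(param_sd_vector(model, config$sampling)),
    initial_state = unname(model_initial_state(model)),
    initial_sd = unname(initial_sd_vector(model, config$sampling)),
    seed_sites = matrix(as.integer(sites - 1L), ncol = 2)
  )
  set.seed(config$seed)
  raw <- cpp_run(cm, cfg)
  n_sites <- raw$n_sites
  series <- data.frame(time = raw$series$time,
                       n_agents = raw$series$n_agents,
                       n_tips = raw$series$n_tips)
  series$arel_ec <- 100 * series$n_agents / n_sites
  snapshots <- lapply(raw$snapshots, function(s) {
    colnames(s$state) <- model$species
    agents <- data.frame(id = s$id, row = s$row + 1L, col = s$col + 1L,
                         tip = s$tip == 1L)
    list(time = s$time, occupancy = s$occupancy, vegf = s$vegf,
         agents = agents, state = s$state)
  })
  structure(list(series = series, snapshots = snapshots,
                 final_fields = raw$final_fields, n_sites = n_sites,
                 timing = raw$timing, move_stats = raw$move_stats,
                 config = config),
            class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  cat(sprintf(
    "<sim_record> %s, %g h on %dx%d sites (seed %s)\n",
    x$config$scenario, x$config$t_end, x$config$grid[1], x$config$grid[2],
    format(x$config$seed)))
  cat(sprintf("  final: %d agents (ArelEC %.1f%%), %d tip cells\n",
              as.integer(last$n_agents), last$arel_ec,
              as.integer(last$n_tips)))
  cat(sprintf("  %d snapshots at t = %s h\n", length(x$snapshots),
              paste(vapply(x$snapshots, `[[`, 0, "time"), collapse = ", ")))
  invisible(x)
}

#' Occupancy mask of a snapshot
#'
#' @param record A `sim_record`.
#' @param time Snapshot time (h); defaults to the last snapshot.
#' @return Logical occupancy matrix.
#' @export
occupancy_mask <- function(record, time = NULL) {
  stopifnot(inherits(record, "sim_record"))
  times <- vapply(record$snapshots, `[[`, 0, "time")
  i <- if (is.null(time)) length(times) else which.min(abs(times - time))
  record$snapshots[[i]]$occupancy > 0
}
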