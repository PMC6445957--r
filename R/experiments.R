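#' Single-parameter sensitivity sweep
#'
#' Re-runs the simulation over a grid of values of one intracellular
#' parameter, with several stochastic replicates per value, and records the
#' relative vessel area and branch points per millimeter at the evaluation
#' time. Values are interpreted as multiplicative scalings of the calibrated
#' parameter value when `relative = TRUE` (the conventional way sensitivity is
#' reported here), or as absolute values otherwise.
#'
#' @param param Name of the model parameter to vary. A character vector scales
#'   several parameters together (e.g. both VEGFR1 splice-isoform transcription
#'   rates, which jointly constitute "VEGFR1 transcription").
#' @param values Numeric grid (fractions of the calibrated value, or absolute
#'   values). The conventional wide grid is 51 values from 0.01 to 1.99.
#' @param config Base [sim_config()]; its seed acts as the seed base, and
#'   replicate `r` of value `i` runs with seed
#'   `seed + 1000 * (i - 1) + r - 1`.
#' @param replicates Stochastic replicates per value.
#' @param eval_time Evaluation time (h) for the reported metrics.
#' @param relative Interpret `values` as fractions of the calibrated value.
#' @return A data frame of class `sweep_result` with one row per (value,
#'   replicate): columns `param`, `value`, `scaling`, `replicate`, `seed`,
#'   `arel_ec`, `branch_points_per_mm`, `max_tip_count`, `first_tip_time`.
#' @export
run_sweep <- function(param, values, config, replicates = 20,
                      eval_time = 192, relative = TRUE) {
  stopifnot(inherits(config, "sim_config"), length(values) >= 1,
            replicates >= 1)
  base <- config$model$params
  if (!all(param %in% names(base))) {
    stop("unknown parameter(s) '", paste(setdiff(param, names(base)),
                                         collapse = ", "), "'", call. = FALSE)
  }
  rows <- list()
  for (i in seq_along(values)) {
    val <- if (relative) values[i] * base[param] else rep(values[i],
                                                          length(param))
    for (r in seq_len(replicates)) {
      seed <- config$seed + 1000L * (i - 1L) + (r - 1L)
      cfg <- config
      cfg$seed <- seed
      cfg$t_end <- max(eval_time, config$t_end)
      cfg$output_times <- eval_time
      cfg$model <- ec_model(params = replace(base, param, val),
                            initial = config$model$initial)
      if (cfg$scenario == "vegfr1_ko") {
        cfg$model <- ec_model(
          params = replace(cfg$model$params,
                           c("vmax_tc_vegfr1", "vmax_tc_svegfr1"), c(0, 0)),
          initial = cfg$model$initial)
      }
      rec <- run_simulation(cfg)
      ba <- branch_analysis(occupancy_mask(rec, eval_time),
                            dx_um = cfg$dx_um)
      tm <- tip_metrics(rec)
      rows[[length(rows) + 1L]] <- data.frame(
        param = paste(param, collapse = "+"), value = unname(val[1]),
        scaling = if (relative) values[i] else NA_real_,
        replicate = r, seed = seed,
        arel_ec = arel_ec_at(rec, eval_time),
        branch_points_per_mm = ba$branch_points_per_mm,
        max_tip_count = tm$max_tip_count,
        first_tip_time = tm$first_tip_time)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Summarize a sweep by parameter value
#'
#' @param sweep A [run_sweep()] result.
#' @return Data frame with per-value mean and SD of `arel_ec` and
#'   `branch_points_per_mm`.
#' @export
summarize_sweep <- function(sweep) {
  agg <- function(col, f) {
    stats::aggregate(sweep[[col]], by = list(value = sweep$value,
                                             scaling = sweep$scaling), f)$x
  }
  vals <- unique(sweep[, c("value", "scaling")])
  vals <- vals[order(vals$value), ]
  data.frame(
    value = vals$value, scaling = vals$scaling,
    arel_mean = agg("arel_ec", mean), arel_sd = agg("arel_ec", stats::sd),
    bp_mm_mean = agg("branch_points_per_mm",
                     function(v) mean(v, na.rm = TRUE)),
    sprouting = agg("first_tip_time", function(v) mean(v < 192) >= 0.5)
  )
}

#' Paired wild-type / VEGFR1-knockout comparison
#'
#' Runs the wild-type and VEGFR1-knockout scenarios with paired seeds and
#' summarizes the relative vessel area and branch points per millimeter over
#' replicates. Replicate `r` of both scenarios uses seed `seed + r - 1`, so
#' the comparison is paired.
#'
#' @param config Base [sim_config()] (its `scenario` is ignored).
#' @param replicates Runs per scenario.
#' @param keep_first_record Keep the full `sim_record` of the first replicate
#'   of each scenario (for snapshot figures).
#' @return List of class `scenario_result`: `results` (one row per run),
#'   `summary` (mean and SD per scenario) and optionally `records`.
#' @export
run_scenarios <- function(config, replicates = 20, keep_first_record = FALSE) {
  stopifnot(inherits(config, "sim_config"), replicates >= 1)
  rows <- list()
  records <- list()
  for (scen in c("wild_type", "vegfr1_ko")) {
    for (r in seq_len(replicates)) {
      cfg <- sim_config(
        grid = config$grid, dx_um = config$dx_um, dt = config$dt,
        t_end = config$t_end, output_times = config$output_times,
        seed = config$seed + r - 1L, scenario = scen,
        aggregates = config$aggregates,
        aggregate_radius = config$aggregate_radius,
        model = config$model, medium = config$medium,
        field_params = config$field_params, behavior = config$behavior,
        sampling = config$sampling, max_substeps = config$max_substeps,
        max_halvings = config$max_halvings)
      rec <- run_simulation(cfg)
      nm <- network_metrics(rec)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(scenario = scen, replicate = r, seed = cfg$seed), nm)
      if (keep_first_record && r == 1L) records[[scen]] <- rec
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$scenario),
    function(d) data.frame(
      scenario = d$scenario[1], n = nrow(d),
      arel_mean = mean(d$arel_ec), arel_sd = stats::sd(d$arel_ec),
      bp_mm_mean = mean(d$branch_points_per_mm, na.rm = TRUE),
      bp_mm_sd = stats::sd(d$branch_points_per_mm))))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary,
                 records = if (keep_first_record) records),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Cell-to-cell heterogeneity sweep
#'
#' Varies the width (SD/mean ratio) of the log-normal distributions from which
#' per-cell parameters are drawn, for each selected parameter group, and
#' records the relative vessel area, the maximal number of concurrent tip
#' cells and the time of the first tip cell. The conventional grid is the
#' doubling sequence 0.01, 0.02, ..., 2.56.
#'
#' @param config Base [sim_config()].
#' @param groups Parameter groups to sweep (`"tc"`, `"tl"`, `"nicd_deg"`,
#'   `"all"`).
#' @param sd_grid SD/mean ratios.
#' @param replicates Replicates per (group, ratio).
#' @return Data frame with one row per run: `group`, `sd_frac`, `replicate`,
#'   `seed`, `arel_ec`, `max_tip_count`, `first_tip_time`.
#' @export
run_heterogeneity <- function(config,
                              groups = c("tc", "tl", "nicd_deg", "all"),
                              sd_grid = 0.01 * 2^(0:8), replicates = 20) {
  stopifnot(inherits(config, "sim_config"))
  rows <- list()
  for (g in groups) {
    for (i in seq_along(sd_grid)) {
      for (r in seq_len(replicates)) {
        cfg <- config
        cfg$sampling <- sampling_config(g, sd_grid[i])
        cfg$seed <- config$seed + 10000L * match(g, groups) +
          100L * (i - 1L) + (r - 1L)
        rec <- run_simulation(cfg)
        tm <- tip_metrics(rec)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, sd_frac = sd_grid[i], replicate = r, seed = cfg$seed,
          arel_ec = rec$series$arel_ec[nrow(rec$series)],
          max_tip_count = tm$max_tip_count,
          first_tip_time = tm$first_tip_time)
      }
    }
  }
  do.call(rbind, rows)
}

#' Sprouting criterion for sweep rows
#'
#' A condition is said to sprout when at least one tip cell appears before
#' `before` hours in at least half of its replicates.
#'
#' @param first_tip_times Vector of per-replicate first-tip times (h).
#' @param before Cutoff time (h).
#' @return Logical.
#' @export
sprouted <- function(first_tip_times, before = 192) {
  mean(first_tip_times < before) >= 0.5
}
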