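#' Write a field or mask as a CSV matrix
#'
#' @param x An [field()], a `sim_record` snapshot matrix, or any numeric
#'   matrix.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(x, path) {
  if (inherits(x, "ec_field")) x <- x$grid
  utils::write.table(x, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a CSV matrix written by [write_field_csv()]
#'
#' @param path Source file.
#' @return A numeric matrix.
#' @export
read_field_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Write a binary mask (or scaled field) as a grayscale PNG
#'
#' @param x Logical/numeric matrix; values are rescaled to `[0, 1]`.
#' @param path Destination `.png`.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(x, path) {
  if (inherits(x, "ec_field")) x <- x$grid
  m <- x * 1.0
  rng <- range(m)
  if (rng[2] > rng[1]) m <- (m - rng[1]) / (rng[2] - rng[1])
  png::writePNG(m, path)
  invisible(path)
}

#' Read a grayscale PNG as a binary mask
#'
#' @param path Source `.png`.
#' @param threshold Pixels strictly above this intensity are occupied.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path, threshold = 0.5) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > threshold
}

#' Write agent snapshots of a run as CSV
#'
#' One row per agent and snapshot: id, coordinates, phenotype and the key
#' intracellular state variables.
#'
#' @param record A `sim_record`.
#' @param path Destination `.csv`.
#' @param vars State variables to include.
#' @return `path`, invisibly.
#' @export
write_agents_csv <- function(record, path,
                             vars = c("vegfr1_mRNA", "vegfr2_mRNA",
                                      "dll4_mRNA", "nicd", "vegfr2_active",
                                      "filopodia")) {
  stopifnot(inherits(record, "sim_record"))
  rows <- lapply(record$snapshots, function(s) {
    cbind(data.frame(time = s$time), s$agents,
          as.data.frame(s$state[, vars, drop = FALSE]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a provenance manifest for a run
#'
#' Records the package version, seed, scenario and the full numeric
#' configuration as JSON so any run can be reproduced exactly.
#'
#' @param config A [sim_config()].
#' @param path Destination `.json`.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  manifest <- list(
    package = "angiosprout",
    version = as.character(utils::packageVersion("angiosprout")),
    seed = config$seed,
    scenario = config$scenario,
    grid = config$grid, dx_um = config$dx_um,
    dt = config$dt, t_end = config$t_end,
    output_times = config$output_times,
    aggregates = config$aggregates,
    aggregate_radius = config$aggregate_radius,
    medium = config$medium,
    field_params = config$field_params,
    behavior = unclass(config$behavior),
    sampling = unclass(config$sampling),
    model_params = as.list(config$model$params),
    model_initial = as.list(config$model$initial)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
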