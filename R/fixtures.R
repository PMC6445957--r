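#' Deterministic test fixtures
#'
#' Generates the small, fully specified objects used to probe the simulator:
#'
#' * `two_cell` — two coupled signaling cells (mutual neighbors), each with
#'   the packaged initial state multiplied by a small seeded log-normal
#'   perturbation, for lateral-inhibition fate-divergence experiments;
#' * `ring_n` — `n` cells on a 1-D ring (each touching its two neighbors;
#'   `ring_n` with `n = 2` equals `two_cell`), for alternating-pattern
#'   experiments;
#' * `vessel_mask` — a binary comb-shaped vessel mask built stroke by stroke
#'   with a known number of junctions and known skeleton length, for
#'   validating the branch analysis.
#'
#' @param kind `"two_cell"`, `"ring_n"` or `"vessel_mask"`.
#' @param n Ring size (`ring_n` only), `>= 2`.
#' @param perturb Multiplicative perturbation SD applied to each cell's
#'   initial state (cell fixtures only).
#' @param n_junctions Number of junctions in the comb (`vessel_mask` only).
#' @param arm Length in pixels of each comb tooth (`vessel_mask` only).
#' @param spacing Pixels between teeth along the backbone (`vessel_mask`).
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @param model The [ec_model()] the cells carry.
#' @param sampling A [sampling_config()] for per-cell parameters (defaults to
#'   no sampling, so cells differ only by the initial perturbation).
#' @return For cell fixtures: a list with `model`, `states` (cells x species),
#'   `params` (cells x parameters) and `neighbors` (1-based index list),
#'   ready for [simulate_cells()]. For `vessel_mask`: a list with `mask`,
#'   `n_junctions` and `length_sites` (the exact skeleton edge length of the
#'   constructed strokes).
#' @export
make_fixture <- function(kind = c("two_cell", "ring_n", "vessel_mask"),
                         n = 4, perturb = 0.01, n_junctions = 3, arm = 6,
                         spacing = 8, seed = 1, model = ec_model(),
                         sampling = sampling_config("none", 0)) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "vessel_mask") {
    return(comb_mask(n_junctions, arm, spacing))
  }
  ncell <- if (kind == "two_cell") 2L else as.integer(n)
  if (ncell < 2) stop("ring fixtures need n >= 2", call. = FALSE)
  x0 <- model_initial_state(model)
  states <- matrix(rep(x0, each = ncell), nrow = ncell,
                   dimnames = list(NULL, model$species))
  pert <- matrix(stats::rlnorm(ncell * length(x0), 0, perturb),
                 nrow = ncell)
  states <- states * pert
  states[, model$env_species] <- 0
  params <- sample_agent_params(model, sampling, n = ncell)
  neighbors <- if (ncell == 2) {
    list(2L, 1L)
  } else {
    lapply(seq_len(ncell), function(i) {
      c(if (i == 1) ncell else i - 1L, if (i == ncell) 1L else i + 1L)
    })
  }
  list(model = model, states = states, params = params,
       neighbors = neighbors, kind = kind)
}

# Comb: horizontal backbone with vertical teeth. Each tooth creates exactly
# one T-junction on the backbone. All strokes are 1 px wide, so the exact
# skeleton length is the number of drawn edges (all orthogonal).
comb_mask <- function(n_junctions, arm, spacing) {
  stopifnot(n_junctions >= 0, arm >= 2, spacing >= 3)
  width <- (n_junctions + 1) * spacing + 1
  height <- arm + 7
  m <- matrix(0L, height, width)
  backbone_row <- height - 3
  m[backbone_row, 2:(width - 1)] <- 1L
  tooth_cols <- if (n_junctions > 0) 1 + spacing * seq_len(n_junctions) + 1
                else integer(0)
  for (cc in tooth_cols) {
    m[(backbone_row - arm):(backbone_row - 1), cc] <- 1L
  }
  backbone_len <- (width - 2) - 1      # edges along the backbone
  length_sites <- backbone_len + n_junctions * arm
  list(mask = m, n_junctions = as.integer(n_junctions),
       length_sites = length_sites, kind = "vessel_mask")
}
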