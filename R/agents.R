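#' Behavioral parameters of endothelial-cell agents
#'
#' Thresholds and rates governing filopodia dynamics, tip-cell selection and
#' chemotactic movement. Numeric defaults belong to the packaged calibration.
#'
#' @param A_star Tip criterion threshold on filopodia length (sites), `> 0`.
#' @param D_star Tip criterion threshold on dll4 mRNA (particles), `> 0`.
#' @param filo_ext,filo_ret Filopodia extension/retraction rates (sites/h).
#' @param v2a_set Active-VEGFR2 setpoint (particles): filopodia extend while
#'   `vegfr2_active` exceeds this value and retract otherwise.
#' @param filo_max Maximum filopodia length (sites).
#' @param p_dev Probability of deviating 45 degrees clockwise (and, equally,
#'   counter-clockwise) from the gradient direction when moving; in
#'   `[0, 0.5]`.
#' @param move_rate Movement attempt rate of tip cells (attempts/h).
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(A_star = 1, D_star = 200, filo_ext = 2,
                            filo_ret = 2, v2a_set = 200, filo_max = 3,
                            p_dev = 0.2, move_rate = 1.3) {
  if (A_star <= 0 || D_star <= 0) stop("A_star and D_star must be > 0",
                                       call. = FALSE)
  if (p_dev < 0 || p_dev > 0.5) stop("p_dev must be in [0, 0.5]",
                                     call. = FALSE)
  if (min(filo_ext, filo_ret, v2a_set, filo_max, move_rate) < 0) {
    stop("rates and bounds must be >= 0", call. = FALSE)
  }
  structure(list(A_star = A_star, D_star = D_star, filo_ext = filo_ext,
                 filo_ret = filo_ret, v2a_set = v2a_set, filo_max = filo_max,
                 p_dev = p_dev, move_rate = move_rate),
            class = "behavior_params")
}

#' Tip-cell criterion
#'
#' A cell adopts the motile tip phenotype when all three criteria hold
#' strictly: `vegfr2_mRNA > vegfr1_mRNA`, `filopodia > A_star` and
#' `dll4_mRNA > D_star`. Boundary equality is non-tip.
#'
#' @param vegfr2_mRNA,vegfr1_mRNA,filopodia,dll4_mRNA Agent state values, or a
#'   named state vector passed as `vegfr2_mRNA` with the rest missing.
#' @param behavior A [behavior_params()] object.
#' @return Logical.
#' @export
is_tip <- function(vegfr2_mRNA, vegfr1_mRNA = NULL, filopodia = NULL,
                   dll4_mRNA = NULL, behavior = behavior_params()) {
  if (!is.null(names(vegfr2_mRNA)) && is.null(vegfr1_mRNA)) {
    st <- vegfr2_mRNA
    vegfr2_mRNA <- st[["vegfr2_mRNA"]]
    vegfr1_mRNA <- st[["vegfr1_mRNA"]]
    filopodia <- st[["filopodia"]]
    dll4_mRNA <- st[["dll4_mRNA"]]
  }
  (vegfr2_mRNA > vegfr1_mRNA) & (filopodia > behavior$A_star) &
    (dll4_mRNA > behavior$D_star)
}

#' Filopodia protrusion rule
#'
#' Filopodia extend at `filo_ext` sites/h while the cell's active VEGFR2
#' exceeds the setpoint and retract at `filo_ret` sites/h otherwise; length is
#' clipped to `[0, filo_max]`.
#'
#' @param filopodia Current length (sites, `>= 0`).
#' @param vegfr2_active Active VEGFR2 amount (particles).
#' @param behavior A [behavior_params()] object.
#' @param dt Time step (h).
#' @return Updated filopodia length.
#' @export
update_filopodia <- function(filopodia, vegfr2_active, behavior, dt) {
  d <- ifelse(vegfr2_active > behavior$v2a_set,
              behavior$filo_ext, -behavior$filo_ret)
  pmin(pmax(filopodia + d * dt, 0), behavior$filo_max)
}

#' Direction of the local VEGF-A gradient
#'
#' Scores each of the 8 lattice directions (clockwise from north) by the sum
#' of VEGF-A along the ray of `radius` sites leaving the cell, and returns the
#' direction of steepest increase. Ties between equal maxima are broken
#' uniformly at random; a locally uniform field gives no direction.
#'
#' @param vegf VEGF-A matrix (or an [field()] object).
#' @param row,col Agent coordinates (1-based).
#' @param radius Sensing radius in sites (`1 + filopodia length`).
#' @return Integer direction 1..8 (N, NE, E, SE, S, SW, W, NW), or `NA` when
#'   the field is locally uniform.
#' @export
gradient_direction <- function(vegf, row, col, radius = 1) {
  if (inherits(vegf, "ec_field")) vegf <- vegf$grid
  d <- cpp_gradient_direction(vegf, as.integer(row) - 1L,
                              as.integer(col) - 1L, as.integer(radius))
  if (d < 0) NA_integer_ else d + 1L
}

#' Apply the clockwise/counter-clockwise movement deviation
#'
#' A moving tip targets the gradient direction with probability
#' `1 - 2 * p_dev` and each of its 45-degree neighbors with probability
#' `p_dev`.
#'
#' @param direction Intended direction 1..8.
#' @param p_dev Deviation probability, in `[0, 0.5]`.
#' @return Sampled direction 1..8.
#' @export
deviate_direction <- function(direction, p_dev = 0.2) {
  stopifnot(direction %in% 1:8, p_dev >= 0, p_dev <= 0.5)
  cpp_deviate_direction(as.integer(direction) - 1L, p_dev) + 1L
}

#' Trans-ligand presented to a cell by its neighbors
#'
#' Sums Dll4 over the occupied Moore neighborhood of a site, dividing each
#' neighbor's surface ligand by that neighbor's own occupied-contact count (a
#' cell's ligand is shared among all its contacts).
#'
#' @param dll4 Matrix of per-site Dll4 amounts (0 on empty sites).
#' @param occupied Logical matrix of site occupancy.
#' @param row,col Coordinates of the receiving cell (1-based).
#' @return Trans-ligand amount available to the cell.
#' @export
neighbor_dll4 <- function(dll4, occupied, row, col) {
  stopifnot(is.matrix(dll4), all(dim(dll4) == dim(occupied)))
  cpp_neighbor_dll4(dll4, occupied, as.integer(row) - 1L,
                    as.integer(col) - 1L)
}

#' Unit offsets of the 8 lattice directions
#'
#' Clockwise from north; deviations of one step correspond to 45 degrees.
#'
#' @return An 8 x 2 integer matrix of (row, col) offsets.
#' @export
direction_offsets <- function() {
  matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L, 0L, -1L,
           -1L, -1L),
         ncol = 2, byrow = TRUE,
         dimnames = list(c("N", "NE", "E", "SE", "S", "SW", "W", "NW"),
                         c("row", "col")))
}
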