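#' Extracellular lattice field
#'
#' A 2-D lattice of particle counts per site with transport and decay
#' properties. Three such fields live in every simulation: `vegf` (VEGF-A),
#' `svegfr1` (exported soluble VEGFR1) and `svegfr1b` (the inert
#' sVEGFR1-VEGF-A complex).
#'
#' @param grid Numeric matrix of particle counts (all entries finite, `>= 0`),
#'   or a vector `c(nr, nc)` to create a zero-initialised field.
#' @param D Diffusion coefficient in lattice sites^2 per hour.
#' @param k_deg First-order degradation rate (1/h).
#' @param name Field name.
#' @param boundary Dirichlet boundary value: the outer lattice ring is held at
#'   this value during diffusion (the boundary abuts bulk culture medium).
#' @return An object of class `ec_field`.
#' @export
field <- function(grid, D = 0, k_deg = 0, name = "field", boundary = 0) {
  if (is.numeric(grid) && is.null(dim(grid)) && length(grid) == 2) {
    grid <- matrix(0, grid[1], grid[2])
  }
  if (!is.matrix(grid) || !is.numeric(grid)) {
    stop("grid must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(grid)) || any(grid < 0)) {
    stop("field entries must be finite and >= 0", call. = FALSE)
  }
  if (D < 0 || k_deg < 0) stop("D and k_deg must be >= 0", call. = FALSE)
  structure(list(grid = grid, D = D, k_deg = k_deg, name = name,
                 boundary = boundary),
            class = "ec_field")
}

#' @export
print.ec_field <- function(x, ...) {
  cat(sprintf("<ec_field> '%s' %dx%d, D=%g sites^2/h, k_deg=%g/h, total=%g\n",
              x$name, nrow(x$grid), ncol(x$grid), x$D, x$k_deg, sum(x$grid)))
  invisible(x)
}

#' Diffuse a field for one time step
#'
#' Explicit 5-point-stencil diffusion under Dirichlet boundary conditions: the
#' outermost lattice ring is held at the field's boundary value. The stability
#' number lambda = D dt / dx^2 is split into internal sub-steps so that each
#' sub-step satisfies lambda <= 0.25; if more than `max_substeps` would be
#' required the update fails rather than integrate an unstable stencil.
#'
#' @param f An [field()] object.
#' @param dt Time step (h).
#' @param max_substeps Cap on internal sub-steps.
#' @return The diffused field.
#' @export
diffuse <- function(f, dt, max_substeps = 1024L) {
  stopifnot(inherits(f, "ec_field"), dt >= 0)
  f$grid <- cpp_diffuse(f$grid, f$D, dt, 1.0, f$boundary,
                        as.integer(max_substeps))
  f
}

#' First-order degradation of a field
#'
#' Sitewise Euler update `x -> x * (1 - k_deg * dt)`, floored at zero.
#'
#' @inheritParams diffuse
#' @return The degraded field.
#' @export
degrade <- function(f, dt) {
  stopifnot(inherits(f, "ec_field"), dt >= 0)
  f$grid <- cpp_degrade(f$grid, f$k_deg, dt)
  f
}

#' Medium replenishment of VEGF-A
#'
#' Sitewise influx `k_in * (vegf_reference - local) * dt`, modeling exchange
#' with the bulk culture medium whose average VEGF-A level is maintained at a
#' constant reference (medium renewal). The law is signed: sites above the
#' reference lose VEGF-A to the medium.
#'
#' @inheritParams diffuse
#' @param medium List with `vegf_reference` (particles/site) and `k_in` (1/h),
#'   see [sim_config()].
#' @return The replenished field.
#' @export
replenish_vegf <- function(f, medium, dt) {
  stopifnot(inherits(f, "ec_field"), dt >= 0)
  if (medium$vegf_reference < 0 || medium$k_in < 0) {
    stop("medium parameters must be >= 0", call. = FALSE)
  }
  f$grid <- cpp_replenish(f$grid, medium$vegf_reference, medium$k_in, dt)
  f
}

#' Extracellular sVEGFR1 / VEGF-A binding kinetics
#'
#' Sitewise mass-action association of diffusible sVEGFR1 with VEGF-A into the
#' inert complex sVEGFR1b, and its dissociation (which releases VEGF-A back in
#' active form): `d(svb) = (k_on * vegf * sv - k_off * svb) * dt`. The update
#' is conservative — `vegf + svb` and `sv + svb` are unchanged sitewise — and
#' clipped so no site goes negative.
#'
#' @param vegf,sv,svb The three [field()]s.
#' @param k_on Association rate (1/(particles/site)/h).
#' @param k_off Dissociation rate (1/h).
#' @param dt Time step (h).
#' @return List of the three updated fields.
#' @export
svegfr1_vegf_kinetics <- function(vegf, sv, svb, k_on, k_off, dt) {
  stopifnot(inherits(vegf, "ec_field"), inherits(sv, "ec_field"),
            inherits(svb, "ec_field"), dt >= 0, k_on >= 0, k_off >= 0)
  res <- cpp_svegfr1_kinetics(vegf$grid, sv$grid, svb$grid, k_on, k_off, dt)
  vegf$grid <- res$vegf
  sv$grid <- res$svegfr1
  svb$grid <- res$svegfr1b
  list(vegf = vegf, svegfr1 = sv, svegfr1b = svb)
}
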