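#' Relative vessel area
#'
#' Percentage of lattice sites occupied by endothelial cells.
#'
#' @param mask Occupancy mask: logical or numeric matrix (non-zero =
#'   occupied), or a `sim_record` (uses the last snapshot).
#' @return Percentage in `[0, 100]`.
#' @examples
#' arel_ec(matrix(c(1, 0, 0, 0), 2, 2))  # 25
#' @export
arel_ec <- function(mask) {
  if (inherits(mask, "sim_record")) mask <- occupancy_mask(mask)
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  100 * sum(mask != 0) / length(mask)
}

#' Skeleton-based branch analysis of a vessel mask
#'
#' Quantifies the architecture of a binary vessel network the way wet-lab
#' images are analyzed: the mask is smoothed by one binary closing with a
#' 3 x 3 structuring element (to ensure connectivity of adjacent agents),
#' thinned to a 1-pixel-wide skeleton, and the skeleton is searched for
#' junctions. Junction pixels (skeleton pixels with more than 2 skeleton
#' neighbors) are merged into 8-connected clusters, each counted as one branch
#' point. Total vessel length is the sum of skeleton edge lengths (1 site per
#' orthogonal step, sqrt(2) per diagonal step) scaled by the lattice spacing.
#'
#' @param mask Logical/numeric occupancy matrix, or a `sim_record`.
#' @param dx_um Lattice spacing (micrometers per site) used for the mm
#'   calibration; taken from the record's configuration when a `sim_record` is
#'   given.
#' @param smooth Apply the 3 x 3 closing before skeletonization.
#' @return List of class `branch_metrics`: `branch_points`,
#'   `total_length_mm`, `branch_points_per_mm` (`NA` when the length is zero),
#'   `n_skeleton_px`, `skeleton` (0/1 matrix) and `empty` (flag for an empty
#'   mask, for which all metrics are zero).
#' @examples
#' m <- matrix(0L, 9, 9); m[5, 2:8] <- 1L; m[2:8, 5] <- 1L  # a plus sign
#' branch_analysis(m, smooth = FALSE)$branch_points          # 1 junction
#' @export
branch_analysis <- function(mask, dx_um = 10, smooth = TRUE) {
  if (inherits(mask, "sim_record")) {
    dx_um <- mask$config$dx_um
    mask <- occupancy_mask(mask)
  }
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  empty <- sum(m) == 0L
  if (empty) {
    res <- list(branch_points = 0L, length_sites = 0,
                n_skeleton_px = 0L, skeleton = m)
    warning("empty mask: all branch metrics are zero", call. = FALSE)
  } else {
    res <- cpp_branch_analysis(m, smooth)
  }
  total_mm <- res$length_sites * dx_um / 1000
  structure(list(
    branch_points = res$branch_points,
    total_length_mm = total_mm,
    branch_points_per_mm = if (total_mm > 0) res$branch_points / total_mm
                           else NA_real_,
    n_skeleton_px = res$n_skeleton_px,
    skeleton = res$skeleton,
    empty = empty
  ), class = "branch_metrics")
}

#' @export
print.branch_metrics <- function(x, ...) {
  cat(sprintf(
    "<branch_metrics> %d branch points, %.3f mm vessel length (%.2f /mm)\n",
    x$branch_points, x$total_length_mm,
    ifelse(is.na(x$branch_points_per_mm), NA, x$branch_points_per_mm)))
  invisible(x)
}

#' Tip-cell timing metrics of a run
#'
#' @param record A `sim_record`.
#' @param sentinel Value (h) reported as `first_tip_time` when no tip cell
#'   ever appears during the run; default 1000 h.
#' @return List with `max_tip_count` (maximum number of concurrent tip cells)
#'   and `first_tip_time` (h).
#' @export
tip_metrics <- function(record, sentinel = 1000) {
  stopifnot(inherits(record, "sim_record"))
  s <- record$series
  max_tips <- max(s$n_tips)
  first <- if (max_tips > 0) min(s$time[s$n_tips > 0]) else sentinel
  list(max_tip_count = max_tips, first_tip_time = first)
}

#' All network metrics of a run
#'
#' Convenience wrapper computing the relative vessel area, the skeleton-based
#' branch metrics and the tip-cell timing for one simulation record.
#'
#' @param record A `sim_record`.
#' @param time Snapshot time for the spatial metrics (default: last snapshot).
#' @return A one-row data frame with columns `arel_ec`, `branch_points`,
#'   `total_branch_length_mm`, `branch_points_per_mm`, `max_tip_count`,
#'   `first_tip_time`.
#' @export
network_metrics <- function(record, time = NULL) {
  mask <- occupancy_mask(record, time)
  ba <- branch_analysis(mask, dx_um = record$config$dx_um)
  tm <- tip_metrics(record)
  data.frame(arel_ec = arel_ec(mask), branch_points = ba$branch_points,
             total_branch_length_mm = ba$total_length_mm,
             branch_points_per_mm = ba$branch_points_per_mm,
             max_tip_count = tm$max_tip_count,
             first_tip_time = tm$first_tip_time)
}

#' Relative vessel area at a given time from the per-step series
#'
#' @param record A `sim_record`.
#' @param time Time (h); the closest recorded step is used.
#' @return Percentage of sites occupied at that time.
#' @export
arel_ec_at <- function(record, time) {
  s <- record$series
  s$arel_ec[which.min(abs(s$time - time))]
}
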