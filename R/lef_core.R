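# Local electric field (LEF) computation from point charges.
#
# The field at a probe p from charges q_i at r_i is the bare Coulomb sum
#   F = k_C * sum_i q_i (p - r_i) / |p - r_i|^3,   k_C = 14.3996 V*A/e,
# giving fields in V/A when positions are in A and charges in e.
# Projections on the axis frame give F_z (reaction axis, Fe->O) and F_y
# (selectivity axis).

#' Electric field at a point from selected source charges
#'
#' @param atoms Atom tibble for one frame.
#' @param point Probe position, 3-vector A.
#' @param sources Selection of source atoms (default `"all"`); excluded
#'   atoms contribute nothing.
#' @return Field 3-vector in V/A (lab frame).
#' @examples
#' a <- tibble::tibble(index = 0L, name = "Q", group = "Q",
#'                     x = 0, y = 0, z = -10, charge = 1)
#' field_at_point(a, c(0, 0, 0)) # ~ (0, 0, 0.1440)
#' @export
field_at_point <- function(atoms, point, sources = "all") {
  point <- vec3(point)
  src <- atoms[sel_rows(atoms, sources), , drop = FALSE]
  if (!nrow(src)) {
    return(c(0, 0, 0))
  }
  pos <- as.matrix(src[, c("x", "y", "z")])
  d <- cbind(point[1] - pos[, 1], point[2] - pos[, 2], point[3] - pos[, 3])
  r <- sqrt(rowSums(d^2))
  if (any(r < 1e-6)) {
    bad <- src[which(r < 1e-6)[1L], ]
    stop(sprintf("singularity error: source atom %s (index %d, group %s) coincides with the probe point",
                 bad$name, bad$index, bad$group), call. = FALSE)
  }
  unname(colSums(d * (K_COULOMB * src$charge / r^3)))
}

probe_point <- function(axis, probe = c("midpoint", "fe", "o", "average3")) {
  probe <- match.arg(probe)
  switch(probe,
    midpoint = list((axis$fe_pos + axis$o_pos) / 2),
    fe = list(axis$fe_pos),
    o = list(axis$o_pos),
    average3 = list(axis$fe_pos, (axis$fe_pos + axis$o_pos) / 2, axis$o_pos)
  )
}

#' Field on the reaction-axis frame, with group decomposition
#'
#' Evaluates the Coulomb field at a probe on the Fe-O axis and projects
#' it on the axis frame: `f_z` is the signed component along Fe->O and
#' `f_y` along the lateral selectivity axis. With `probe = "average3"`
#' the fields at Fe, the midpoint and O are averaged. When `decompose`
#' names source subsets, one row per subset is returned in addition to
#' the `"total"` row; by superposition the subset rows of a partition sum
#' to the total.
#'
#' @param atoms Atom tibble for one frame.
#' @param axis An [build_axis_frame()] result for the same frame.
#' @param sources Source selection (default: everything except the probed
#'   Fe/O atoms).
#' @param probe `"midpoint"` (default), `"fe"`, `"o"` or `"average3"`.
#' @param decompose Optional named character vector of selections whose
#'   contributions are reported separately.
#' @return Tibble with columns `source`, `fx`, `fy`, `fz` (lab frame,
#'   V/A), `f_y`, `f_z` (axis projections, V/A).
#' @export
field_on_axis <- function(atoms, axis,
                          sources = "not (group FE or group O1)",
                          probe = "midpoint", decompose = NULL) {
  stopifnot(inherits(axis, "axis_frame"))
  pts <- probe_point(axis, probe)
  sel_list <- c(list(total = sources), as.list(decompose))
  rows <- purrr::imap(sel_list, function(s, nm) {
    f <- Reduce(`+`, lapply(pts, function(p) field_at_point(atoms, p, s))) /
      length(pts)
    tibble(
      source = nm,
      fx = f[1], fy = f[2], fz = f[3],
      f_y = sum(f * axis$y_hat), f_z = sum(f * axis$z_hat)
    )
  })
  dplyr::bind_rows(rows)
}

#' Field time series over a trajectory
#'
#' One [field_on_axis()] evaluation per sampled frame, with the axis
#' frame rebuilt per frame so projections track the instantaneous Fe->O
#' direction.
#'
#' @param traj Long trajectory tibble.
#' @param sources Source selection.
#' @param fe,o,lateral_ref Selections passed to [build_axis_frame()].
#' @param probe Probe choice, see [field_on_axis()].
#' @param decompose Optional named selections for group decomposition.
#' @param stride Sampling interval in ps; must be at least the trajectory
#'   frame spacing. Frames at times `t0, t0 + stride, ...` are kept.
#' @return Tibble with one row per sampled frame and source: `frame`,
#'   `time`, `source`, `fx`, `fy`, `fz`, `f_y`, `f_z`.
#' @export
field_series <- function(traj, sources = "not (group FE or group O1)",
                         fe = "group FE", o = "group O1",
                         lateral_ref = "group TLN",
                         probe = "midpoint", decompose = NULL,
                         stride = NULL) {
  if (!nrow(traj)) {
    return(tibble(frame = integer(), time = double(), source = character(),
                  fx = double(), fy = double(), fz = double(),
                  f_y = double(), f_z = double()))
  }
  info <- dplyr::distinct(traj, .data$frame, .data$time) %>% dplyr::arrange(.data$time)
  if (!is.null(stride) && nrow(info) > 1L) {
    spacing <- min(diff(info$time))
    if (stride < spacing - 1e-9) {
      stop(sprintf("stride %.3g ps is below the trajectory frame spacing %.3g ps",
                   stride, spacing), call. = FALSE)
    }
    keep_t <- info$time[1L] + stride * (0:floor((max(info$time) - info$time[1L]) / stride))
    info <- info[vapply(info$time, function(t) any(abs(t - keep_t) < 1e-9), TRUE), ]
  }
  purrr::pmap(info, function(frame, time) {
    at <- traj[traj$frame == frame, , drop = FALSE]
    ax <- build_axis_frame(at, fe = fe, o = o, lateral_ref = lateral_ref)
    field_on_axis(at, ax, sources = sources, probe = probe,
                  decompose = decompose) %>%
      dplyr::mutate(frame = frame, time = time, .before = 1L)
  }) %>%
    dplyr::bind_rows()
}

#' Plot a field time series
#'
#' Axis-projected components `f_z` (reaction axis) and `f_y` (selectivity
#' axis) against time, one panel per source group.
#'
#' @param fs Output of [field_series()].
#' @return A ggplot object.
#' @export
plot_field_series <- function(fs) {
  long <- tidyr::pivot_longer(fs, c("f_y", "f_z"),
                              names_to = "component", values_to = "field")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$field,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$source)) +
    ggplot2::labs(x = "time (ps)", y = "local electric field (V/Å)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
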