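# Group dipole moments and field-dipole stabilization energies.
#
# A group's dipole from its point charges is
#   mu = k_D * sum_i q_i (r_i - origin),   k_D = 4.80320 D / (e*A).
# For a neutral group mu is origin-independent; for a charged group it is
# not, so a warning flag travels with the record. The interaction of a
# field component F_a (V/A) with a dipole component mu_a (D) is
#   dE_a = k_E * F_a * mu_a,   k_E = 4.8009 kcal/mol per (D * V/A),
# on the Gaussian sign convention in which a negative dE is stabilizing.

#' Group dipole moment from point charges
#'
#' @param atoms Atom tibble for one frame.
#' @param sel Selection naming the group's atoms.
#' @param origin `"geometric_center"` (default), `"charge_center"`
#'   (centroid weighted by |q|), or an explicit 3-vector in A.
#' @param axis Optional [build_axis_frame()] result; when given, the
#'   projections `mu_y`, `mu_z` on the selectivity and reaction axes are
#'   included.
#' @param label Group label for the output row (default: the selection).
#' @return One-row tibble: `group`, `mu_x`, `mu_y_lab`, `mu_z_lab`, `mu`
#'   (magnitude, Debye), `mu_y`, `mu_z` (axis projections, if `axis`
#'   given), `net_charge` (e), `origin_x/y/z` (A), `origin_dependent`
#'   (TRUE when the group carries net charge, in which case the dipole
#'   depends on the recorded origin).
#' @export
group_dipole <- function(atoms, sel, origin = "geometric_center",
                         axis = NULL, label = NULL) {
  rows <- sel_rows(atoms, sel)
  if (!length(rows)) stop("selection error: empty selection for group_dipole", call. = FALSE)
  sub <- atoms[rows, , drop = FALSE]
  pos <- as.matrix(sub[, c("x", "y", "z")])
  org <- if (is.numeric(origin)) {
    vec3(origin)
  } else {
    switch(match.arg(origin, c("geometric_center", "charge_center")),
      geometric_center = colMeans(pos),
      charge_center = {
        w <- abs(sub$charge)
        if (sum(w) == 0) colMeans(pos) else colSums(pos * w) / sum(w)
      }
    )
  }
  mu <- K_DEBYE * colSums(sub$charge * sweep(pos, 2L, org))
  net <- sum(sub$charge)
  dependent <- abs(net) > 1e-9
  if (dependent) {
    warning(sprintf("group %s carries net charge %+.4f e: its dipole depends on the chosen origin",
                    label %||% (if (is.character(sel)) sel else "<indices>"), net),
            call. = FALSE)
  }
  out <- tibble(
    group = label %||% (if (is.character(sel)) sel else "selection"),
    mu_x = mu[1], mu_y_lab = mu[2], mu_z_lab = mu[3],
    mu = norm3(mu),
    net_charge = net,
    origin_x = org[1], origin_y = org[2], origin_z = org[3],
    origin_dependent = dependent
  )
  if (!is.null(axis)) {
    stopifnot(inherits(axis, "axis_frame"))
    out$mu_y <- sum(mu * axis$y_hat)
    out$mu_z <- sum(mu * axis$z_hat)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Field-dipole stabilization energy
#'
#' Per-axis energies `dE_a = k_E * F_a * mu_a` with
#' `k_E = 4.8009 kcal/mol per (D * V/A)`; on the Gaussian convention used
#' for all reported vectors a negative `dE` stabilizes the state. When
#' full 3-vectors are supplied, the total `dE = k_E * |F| |mu| cos(theta)`
#' and the field-dipole angle `theta` are also reported, and the y/z
#' components are taken from the vectors (projected on `axis` if given,
#' else read as lab-frame y/z).
#'
#' Components may be given directly (`f_z = -0.29, mu_z = 8.67`) to
#' reproduce tabulated stabilization energies from printed field and
#' dipole components.
#'
#' @param f Field 3-vector, V/A (optional).
#' @param mu Dipole 3-vector, Debye (optional).
#' @param f_y,f_z Field components on the selectivity / reaction axis, V/A.
#' @param mu_y,mu_z Dipole components, Debye.
#' @param axis Optional [build_axis_frame()] result used to project `f`
#'   and `mu`.
#' @return One-row tibble: `de_z`, `de_y`, `de_total` (kcal/mol; NA when
#'   the corresponding inputs are absent), `theta_deg` (angle between F
#'   and mu; NA unless both full vectors with nonzero magnitude are
#'   given), plus the components used.
#' @examples
#' stabilization_energy(f_z = -0.29, mu_z = 8.67)$de_z # -12.07
#' @export
stabilization_energy <- function(f = NULL, mu = NULL,
                                 f_y = NULL, f_z = NULL,
                                 mu_y = NULL, mu_z = NULL,
                                 axis = NULL) {
  de_total <- NA_real_
  theta <- NA_real_
  if (!is.null(f) && !is.null(mu)) {
    f <- vec3(f)
    mu <- vec3(mu)
    de_total <- K_FIELD_DIPOLE * sum(f * mu)
    nf <- norm3(f)
    nm <- norm3(mu)
    if (nf > 0 && nm > 0) {
      theta <- acos(pmin(1, pmax(-1, sum(f * mu) / (nf * nm)))) * 180 / pi
    }
    if (!is.null(axis)) {
      stopifnot(inherits(axis, "axis_frame"))
      f_y <- f_y %||% sum(f * axis$y_hat)
      f_z <- f_z %||% sum(f * axis$z_hat)
      mu_y <- mu_y %||% sum(mu * axis$y_hat)
      mu_z <- mu_z %||% sum(mu * axis$z_hat)
    } else {
      f_y <- f_y %||% f[2]
      f_z <- f_z %||% f[3]
      mu_y <- mu_y %||% mu[2]
      mu_z <- mu_z %||% mu[3]
    }
  }
  comp <- function(fa, ma) {
    if (is.null(fa) || is.null(ma)) NA_real_ else K_FIELD_DIPOLE * fa * ma
  }
  stopifnot(all(vapply(list(f_y, f_z, mu_y, mu_z),
                       function(v) is.null(v) || (is.finite(v) && length(v) == 1L),
                       TRUE)))
  tibble(
    de_z = comp(f_z, mu_z),
    de_y = comp(f_y, mu_y),
    de_total = de_total,
    theta_deg = theta,
    f_y = f_y %||% NA_real_, f_z = f_z %||% NA_real_,
    mu_y = mu_y %||% NA_real_, mu_z = mu_z %||% NA_real_
  )
}

#' Per-state stabilization table
#'
#' Assembles the standard report — one row per state with the dipole
#' magnitude, axis field and dipole components, and the per-axis
#' field-dipole energies — from a tibble of per-state components.
#'
#' @param states Tibble with columns `state`, `mu` (total dipole
#'   magnitude, D), `f_z`, `mu_z`, `f_y`, `mu_y`.
#' @return Tibble with columns `state`, `mu`, `f_z`, `mu_z`, `de_z`,
#'   `f_y`, `mu_y`, `de_y` (energies kcal/mol).
#' @export
table1_report <- function(states) {
  need <- c("state", "mu", "f_z", "mu_z", "f_y", "mu_y")
  missing_cols <- setdiff(need, names(states))
  if (length(missing_cols)) {
    stop(sprintf("states table is missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  states %>%
    dplyr::rowwise() %>%
    dplyr::mutate(
      de_z = stabilization_energy(f_z = .data$f_z, mu_z = .data$mu_z)$de_z,
      de_y = stabilization_energy(f_y = .data$f_y, mu_y = .data$mu_y)$de_y
    ) %>%
    dplyr::ungroup() %>%
    dplyr::select(dplyr::all_of(c("state", "mu", "f_z", "mu_z", "de_z",
                                  "f_y", "mu_y", "de_y")))
}
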