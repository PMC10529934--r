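# Synthetic cage-system generators.
#
# These emulate the geometry and statistics of a caged iron-oxo oxidant:
# a central Fe-O axis, a ring of charged peripheral substituents, a
# neutral polar cage shell, a thin solvent shell, plus distance series
# with two-population structure and steered-work traces with a known
# free-energy profile. Every generator carries an analytic ground truth
# so downstream estimators can be tested against closed forms.

#' Specification of a synthetic caged oxidant system
#'
#' Defaults describe the reference study conditions: four +1 e peripheral
#' charges (the tetra-methylpyridinium periphery) on an 8 A ring, a
#' neutral polar cage shell at 12 A, a thin solvent shell of small dipolar
#' molecules, a 1.65 A Fe=O bond, and 0.15 A Gaussian positional jitter
#' per frame.
#'
#' @param n_periphery Number of charged peripheral sites.
#' @param periphery_charge Charge per peripheral site, e.
#' @param periphery_radius Ring radius of the periphery, A.
#' @param n_cage_dipoles Number of neutral +/- polar pairs on the cage shell.
#' @param shell_radius Cage shell radius, A.
#' @param n_solvent Number of two-site dipolar solvent molecules.
#' @param solvent_shell Length-2 `(r_min, r_max)` solvent shell bounds, A.
#' @param feo_length Fe=O bond length, A.
#' @param positional_sigma Isotropic Gaussian jitter per atom per frame, A.
#' @param n_frames Number of trajectory frames (frame 0 is jitter-free).
#' @param stride Time between frames, ps.
#' @param seed Integer seed; generation is bit-reproducible for fixed seed.
#' @return A `cage_spec` list.
#' @export
cage_spec <- function(n_periphery = 4, periphery_charge = 1, periphery_radius = 8,
                      n_cage_dipoles = 12, shell_radius = 12,
                      n_solvent = 30, solvent_shell = c(13, 16),
                      feo_length = 1.65, positional_sigma = 0.15,
                      n_frames = 50, stride = 10, seed = 1) {
  stopifnot(
    n_periphery >= 1, periphery_radius > 0, shell_radius > 0,
    length(solvent_shell) == 2L, solvent_shell[1] < solvent_shell[2],
    solvent_shell[1] > 0, feo_length > 0, positional_sigma >= 0,
    n_frames >= 1, stride > 0
  )
  structure(as.list(environment()), class = "cage_spec")
}

rand_unit_vec <- function(n = 1L) {
  v <- matrix(rnorm(3L * n), ncol = 3L)
  v / sqrt(rowSums(v^2))
}

# Coulomb field of point charges at a probe, inline closed form used for
# ground truth (same physics as lef_core, but evaluated here on the
# jitter-free construction geometry).
coulomb_field <- function(pos, q, point) {
  d <- sweep(-pos, 2L, -point) # point - pos, rowwise
  r <- sqrt(rowSums(d^2))
  colSums(d * (K_COULOMB * q / r^3))
}

#' Generate a synthetic caged oxidant system with analytic ground truth
#'
#' Builds the jitter-free reference geometry, a jittered trajectory
#' (frame 0 is the reference geometry itself), and a ground-truth record
#' holding the analytic Coulomb field at the Fe-O midpoint and the group
#' dipole moments of the reference geometry. Peripheral charges are placed
#' with exact n-fold symmetry in the Fe-O midplane, so their field at the
#' midpoint cancels analytically; counter-ions neutralizing the periphery
#' sit far outside the solvent shell.
#'
#' @param spec A [cage_spec()].
#' @return List with elements `atoms` (reference-geometry atom tibble),
#'   `trajectory` (long tibble), `ground_truth` (list with
#'   `expected_field_at_origin` V/A, `expected_group_dipoles` Debye,
#'   `source_selection`), and `spec`.
#' @export
gen_cage_system <- function(spec = cage_spec()) {
  stopifnot(inherits(spec, "cage_spec"))
  with_local_seed(spec$seed, {
    rows <- list()

    add <- function(name, group, pos, charge, radius = 1.5) {
      tibble(name = name, group = group,
             x = pos[1], y = pos[2], z = pos[3],
             charge = charge, radius = radius)
    }

    # Fe-O axis centered on the origin
    half <- spec$feo_length / 2
    rows[[length(rows) + 1L]] <- add("FE", "FE", c(0, 0, -half), 1.0)
    rows[[length(rows) + 1L]] <- add("O1", "O1", c(0, 0, half), -1.0)

    # Charged periphery: exact n-fold ring in the z = 0 midplane
    ang <- 2 * pi * (seq_len(spec$n_periphery) - 1L) / spec$n_periphery
    for (k in seq_len(spec$n_periphery)) {
      rows[[length(rows) + 1L]] <- add(
        sprintf("P%d", k), "HM1",
        spec$periphery_radius * c(cos(ang[k]), sin(ang[k]), 0),
        spec$periphery_charge
      )
    }

    # Substrate ring (lateral reference): neutral hexagon offset along +y,
    # plus the two prochiral hydrogens pointing back toward the oxo atom.
    ring_c <- c(0, 3.5, 0.6)
    hex <- 2 * pi * (0:5) / 6
    for (k in 1:6) {
      rows[[length(rows) + 1L]] <- add(
        sprintf("C%d", k), "TLN",
        ring_c + 1.4 * c(cos(hex[k]), 0, sin(hex[k])),
        0.10 * (-1)^k
      )
    }
    rows[[length(rows) + 1L]] <- add("HR", "TLN", c(0.3, 2.2, 0.8), 0)
    rows[[length(rows) + 1L]] <- add("HS", "TLN", c(-0.3, 2.6, 1.4), 0)

    placed <- function() {
      tb <- dplyr::bind_rows(rows)
      as.matrix(tb[, c("x", "y", "z")])
    }

    # Rejection placement keeping everything >= 0.8 A apart
    place_apart <- function(propose, min_sep = 0.8, max_try = 100L) {
      cur <- placed()
      for (i in seq_len(max_try)) {
        p <- propose()
        d <- sqrt(colSums((t(cur) - p)^2))
        if (all(d >= min_sep)) return(p)
      }
      stop("placement failed: could not keep atoms 0.8 A apart after 100 attempts",
           call. = FALSE)
    }

    # Neutral polar pairs on the cage shell
    for (k in seq_len(spec$n_cage_dipoles)) {
      u <- as.numeric(rand_unit_vec())
      t0 <- as.numeric(rand_unit_vec())
      t0 <- t0 - sum(t0 * u) * u
      t0 <- t0 / norm3(t0)
      cen <- place_apart(function() spec$shell_radius * as.numeric(rand_unit_vec()))
      # pair straddles the placed center along the tangent
      rows[[length(rows) + 1L]] <- add(sprintf("CP%d", k), "CAGE", cen + 0.5 * t0, 0.2)
      rows[[length(rows) + 1L]] <- add(sprintf("CM%d", k), "CAGE", cen - 0.5 * t0, -0.2)
    }

    # Thin shell of two-site dipolar solvent molecules
    rs <- spec$solvent_shell
    for (k in seq_len(spec$n_solvent)) {
      cen <- place_apart(function() {
        r <- (rs[1]^3 + runif(1) * (rs[2]^3 - rs[1]^3))^(1 / 3)
        r * as.numeric(rand_unit_vec())
      })
      u <- as.numeric(rand_unit_vec())
      rows[[length(rows) + 1L]] <- add(sprintf("SP%d", k), "SOLV", cen + 0.5 * u, 0.1)
      rows[[length(rows) + 1L]] <- add(sprintf("SM%d", k), "SOLV", cen - 0.5 * u, -0.1)
    }

    # Counter-ions neutralize the periphery, far outside the solvent shell
    q_tot <- sum(dplyr::bind_rows(rows)$charge)
    if (abs(q_tot) > 1e-12) {
      n_cl <- max(1L, as.integer(ceiling(abs(q_tot))))
      far <- 3 * rs[2]
      ang_cl <- 2 * pi * (seq_len(n_cl) - 1L) / n_cl + pi / max(1L, n_cl)
      for (k in seq_len(n_cl)) {
        rows[[length(rows) + 1L]] <- add(
          sprintf("CL%d", k), "CL",
          far * c(cos(ang_cl[k]), sin(ang_cl[k]), 0),
          -q_tot / n_cl, radius = 1.8
        )
      }
    }

    atoms <- dplyr::bind_rows(rows)
    atoms <- dplyr::mutate(atoms, index = dplyr::row_number() - 1L,
                           .before = 1L)

    # Trajectory: frame 0 jitter-free, later frames iid Gaussian jitter
    n_at <- nrow(atoms)
    frames <- lapply(seq_len(spec$n_frames) - 1L, function(f) {
      jit <- if (f == 0L || spec$positional_sigma == 0) {
        matrix(0, n_at, 3L)
      } else {
        matrix(rnorm(3L * n_at, sd = spec$positional_sigma), n_at, 3L)
      }
      tibble(
        frame = f, time = f * spec$stride,
        index = atoms$index, name = atoms$name, group = atoms$group,
        x = atoms$x + jit[, 1L], y = atoms$y + jit[, 2L], z = atoms$z + jit[, 3L],
        charge = atoms$charge
      )
    })
    trajectory <- dplyr::bind_rows(frames)

    src_sel <- "not (group FE or group O1)"
    src <- atoms[sel_rows(atoms, src_sel), , drop = FALSE]
    gt_field <- coulomb_field(as.matrix(src[, c("x", "y", "z")]), src$charge,
                              c(0, 0, 0))
    gt_dip <- lapply(
      setNames(nm = setdiff(unique(atoms$group), c("FE", "O1"))),
      function(g) {
        sub <- atoms[atoms$group == g, , drop = FALSE]
        cen <- colMeans(sub[, c("x", "y", "z")])
        K_DEBYE * colSums(sub$charge * sweep(as.matrix(sub[, c("x", "y", "z")]),
                                             2L, cen))
      }
    )

    list(
      atoms = atoms,
      trajectory = trajectory,
      ground_truth = list(
        expected_field_at_origin = unname(gt_field),
        expected_group_dipoles = lapply(gt_dip, unname),
        source_selection = src_sel,
        probe_point = c(0, 0, 0)
      ),
      spec = spec
    )
  })
}

#' Generate paired pro-R / pro-S distance time series
#'
#' Each series is a two-component Gaussian mixture over a near and a far
#' approach distance; the pro-R series puts weight `p_near` on the near
#' component and the pro-S series puts the same weight on the far one,
#' mimicking the two-population structure of abstraction-distance plots.
#'
#' @param n Number of samples per series.
#' @param p_near Mixture weight of the near component in the pro-R series.
#' @param mu_near,mu_far Component means, A (`mu_near < mu_far`).
#' @param sigma Component standard deviation, A (> 0).
#' @param seed Integer seed.
#' @return Tibble with columns `step`, `pro_r`, `pro_s` (A).
#' @export
gen_distance_series <- function(n, p_near = 0.7, mu_near = 2.6, mu_far = 3.4,
                                sigma = 0.2, seed = 1) {
  if (sigma <= 0) stop("parameter error: sigma must be > 0", call. = FALSE)
  stopifnot(p_near >= 0, p_near <= 1, mu_near < mu_far, n >= 1)
  with_local_seed(seed, {
    near_r <- runif(n) < p_near
    near_s <- runif(n) < p_near
    tibble(
      step = seq_len(n) - 1L,
      pro_r = ifelse(near_r, rnorm(n, mu_near, sigma), rnorm(n, mu_far, sigma)),
      pro_s = ifelse(near_s, rnorm(n, mu_far, sigma), rnorm(n, mu_near, sigma))
    )
  })
}

#' Free-energy profile constructors for work-trace generation
#'
#' `pmf_linear()` gives `slope * (s - s0)`; `pmf_harmonic()` gives
#' `0.5 * k * (s - center)^2` shifted to zero at the first breakpoint by
#' the caller. Any function of the coordinate (kcal/mol) is accepted
#' wherever a `pmf` argument appears.
#'
#' @param slope Slope in kcal/mol/A.
#' @param s0 Coordinate where the linear profile is zero, A.
#' @param k Force constant, kcal/mol/A^2.
#' @param center Minimum position, A.
#' @return A function of the reaction coordinate.
#' @export
pmf_linear <- function(slope = 1, s0 = 0) {
  force(slope); force(s0)
  function(s) slope * (s - s0)
}

#' @rdname pmf_linear
#' @export
pmf_harmonic <- function(k = 0.1, center = 3) {
  force(k); force(center)
  function(s) 0.5 * k * (s - center)^2
}

#' Generate staged steered-work traces with exact Jarzynski recovery
#'
#' Emulates adaptive steered MD pulling over staged reaction-coordinate
#' windows. Per-stage work increments are Gaussian with mean equal to the
#' stage free-energy difference plus the dissipation offset
#' `beta * sigma_w^2 / 2` and standard deviation `sigma_w`, so stagewise
#' Jarzynski averaging recovers the input profile exactly in expectation
#' (Gaussian-work closed form: `dG = <W> - beta * var(W) / 2`).
#'
#' @param pmf Function of the coordinate giving the free-energy profile,
#'   kcal/mol (see [pmf_linear()]).
#' @param n_traj Number of trajectories per stage.
#' @param sigma_w Work noise per stage, kcal/mol (>= 0).
#' @param stages Strictly increasing reaction-coordinate breakpoints, A;
#'   default 3 to 23 A in 10 stages.
#' @param temperature Temperature, K.
#' @param seed Integer seed.
#' @return Long tibble of work traces: `traj_id`, `stage` (0 at the start
#'   point), `coordinate` (A), `cumulative_work` (kcal/mol).
#' @export
gen_work_traces <- function(pmf, n_traj = 20, sigma_w = 1,
                            stages = seq(3, 23, length.out = 11),
                            temperature = 300, seed = 1) {
  if (is.unsorted(stages, strictly = TRUE)) {
    stop("parameter error: stage breakpoints must be strictly increasing",
         call. = FALSE)
  }
  stopifnot(is.function(pmf), sigma_w >= 0, temperature > 0, n_traj >= 1)
  g <- pmf(stages)
  stopifnot(all(is.finite(g)))
  dg <- diff(g)
  beta <- 1 / (R_GAS_KCAL * temperature)
  n_stage <- length(dg)
  with_local_seed(seed, {
    incr <- matrix(
      rnorm(n_traj * n_stage,
            mean = rep(dg + beta * sigma_w^2 / 2, each = n_traj),
            sd = sigma_w),
      nrow = n_traj, ncol = n_stage
    )
    cum <- if (n_stage == 1L) {
      cbind(0, incr)
    } else {
      cbind(0, t(apply(incr, 1L, cumsum)))
    }
    tidyr::expand_grid(traj_id = seq_len(n_traj), stage = 0:n_stage) %>%
      dplyr::mutate(
        coordinate = stages[.data$stage + 1L],
        cumulative_work = cum[cbind(.data$traj_id, .data$stage + 1L)]
      )
  })
}

#' Generate a contact-distance series with prescribed occupancy
#'
#' Samples are drawn below the cutoff (around `d_in`) with probability
#' `occupancy` and above it (around `d_out`) otherwise, using truncated
#' normals so the below-cutoff fraction converges exactly to `occupancy`.
#'
#' @param n Number of samples.
#' @param occupancy Target fraction of samples below `cutoff`, in `[0, 1]`.
#' @param d_in,d_out Typical in-contact / out-of-contact distances, A.
#' @param cutoff Contact cutoff, A (`d_in < cutoff < d_out`).
#' @param seed Integer seed.
#' @return Tibble with columns `step`, `distance` (A).
#' @export
gen_contact_series <- function(n, occupancy = 0.88, d_in = 4, d_out = 6,
                               cutoff = 5, seed = 1) {
  if (occupancy < 0 || occupancy > 1) {
    stop("parameter error: occupancy must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(d_in < cutoff, cutoff < d_out, n >= 1)
  s <- min(cutoff - d_in, d_out - cutoff) / 2
  with_local_seed(seed, {
    below <- runif(n) < occupancy
    u <- runif(n)
    d <- numeric(n)
    # inverse-CDF truncated normals: strictly below / at-or-above cutoff
    p_in <- pnorm(cutoff, d_in, s)
    p_out <- pnorm(cutoff, d_out, s)
    d[below] <- qnorm(u[below] * p_in, d_in, s)
    d[!below] <- qnorm(p_out + u[!below] * (1 - p_out), d_out, s)
    tibble(step = seq_len(n) - 1L, distance = d)
  })
}
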