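# Trajectory selectivity analytics: distance populations, contact
# occupancy, representative-frame selection, and Boltzmann
# barrier-difference selectivity ratios.

#' Per-frame distance between two single-atom selections
#'
#' @param traj Long trajectory tibble.
#' @param sel_a,sel_b Selections resolving to exactly one atom each.
#' @return Tibble with columns `frame`, `time`, `distance` (A), in frame
#'   order.
#' @export
distance_series <- function(traj, sel_a, sel_b) {
  if (!nrow(traj)) {
    return(tibble(frame = integer(), time = double(), distance = double()))
  }
  f0 <- traj_frame(traj, min(traj$frame))
  ia <- resolve_selection(f0, sel_a)
  ib <- resolve_selection(f0, sel_b)
  if (length(ia) != 1L || length(ib) != 1L) {
    stop(sprintf("ambiguity error: selections must resolve to exactly one atom (got %d and %d)",
                 length(ia), length(ib)), call. = FALSE)
  }
  a <- traj[traj$index == ia, , drop = FALSE] %>% dplyr::arrange(.data$frame)
  b <- traj[traj$index == ib, , drop = FALSE] %>% dplyr::arrange(.data$frame)
  tibble(
    frame = a$frame, time = a$time,
    distance = sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  )
}

#' Population histogram of a distance series
#'
#' Empirical normalized histogram (density integrates to one). For an
#' unbiased equilibrium trajectory this is the Boltzmann population of
#' the distance coordinate. The mode is the center of the
#' highest-density bin, ties broken toward smaller distance (the
#' closer-approach population is the chemically relevant one).
#'
#' @param series Numeric vector of distances (A), or a tibble with a
#'   `distance` column.
#' @param bin_width Bin width, A (> 0); default 0.1 A.
#' @return A `population_hist` tibble with columns `bin_low`, `bin_high`,
#'   `bin_mid`, `count`, `density`, and attributes `n_samples`,
#'   `bin_width`, `mode`.
#' @export
population_hist <- function(series, bin_width = 0.1) {
  x <- if (is.data.frame(series)) series$distance else as.numeric(series)
  if (!length(x)) stop("empty series: cannot histogram", call. = FALSE)
  stopifnot(bin_width > 0, all(is.finite(x)))
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (max(edges) < hi - 1e-12) edges <- c(edges, max(edges) + bin_width)
  cts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                  nbins = length(edges) - 1L)
  dens <- cts / (sum(cts) * bin_width)
  out <- tibble(
    bin_low = edges[-length(edges)],
    bin_high = edges[-1L],
    bin_mid = (edges[-length(edges)] + edges[-1L]) / 2,
    count = cts,
    density = dens
  )
  mode_bin <- which(dens == max(dens))[1L] # ties toward smaller distance
  structure(out, class = c("population_hist", class(out)),
            n_samples = length(x), bin_width = bin_width,
            mode = out$bin_mid[mode_bin])
}

#' Mode of a population histogram
#' @param hist A [population_hist()] result.
#' @return Mode bin center, A.
#' @export
hist_mode <- function(hist) attr(hist, "mode")

#' Most populated frame of a trajectory
#'
#' Returns the earliest frame whose distance falls in the mode bin of
#' the population histogram — the representative snapshot of the
#' dominant population, typically used to seed reaction-path
#' calculations.
#'
#' @param series Distance series tibble aligned to the trajectory
#'   (columns `frame`, `distance`, as from [distance_series()]).
#' @param hist Histogram of that series, from [population_hist()]; built
#'   automatically when omitted.
#' @return 0-based frame id.
#' @export
most_populated_frame <- function(series, hist = NULL) {
  stopifnot(is.data.frame(series), all(c("frame", "distance") %in% names(series)))
  if (!nrow(series)) stop("empty series", call. = FALSE)
  if (is.null(hist)) hist <- population_hist(series)
  m <- hist_mode(hist)
  bw <- attr(hist, "bin_width")
  row <- hist[abs(hist$bin_mid - m) < bw / 2, , drop = FALSE]
  lo <- row$bin_low[1L]
  hi <- row$bin_high[1L]
  in_bin <- series$distance >= lo &
    (series$distance < hi | (hi >= max(hist$bin_high) & series$distance <= hi))
  if (!any(in_bin)) stop("alignment error: no frame falls in the mode bin", call. = FALSE)
  min(series$frame[in_bin])
}

#' Contact occupancy of a distance series
#'
#' Fraction of samples strictly below the cutoff (a sample exactly at the
#' cutoff is out of contact).
#'
#' @param series Numeric distances (A) or a tibble with a `distance`
#'   column.
#' @param cutoff Contact cutoff, A.
#' @return One-row tibble: `cutoff`, `n`, `n_below`, `occupancy`,
#'   `se` (binomial standard error).
#' @export
contact_occupancy <- function(series, cutoff = 5) {
  x <- if (is.data.frame(series)) series$distance else as.numeric(series)
  if (!length(x)) stop("empty series", call. = FALSE)
  p <- mean(x < cutoff)
  tibble(cutoff = cutoff, n = length(x), n_below = sum(x < cutoff),
         occupancy = p, se = sqrt(p * (1 - p) / length(x)))
}

#' Enantiomer ratio from the pro-R / pro-S barrier difference
#'
#' Boltzmann ratio of the two transition-state populations,
#' `ratio = exp(ddE / (R T))` with `ddE = |barrier_s - barrier_r|` in
#' kcal/mol and `R = 1.98720425e-3 kcal/(mol K)`. The major product is
#' the one with the lower abstraction barrier.
#'
#' @param barrier_r Pro-R hydrogen-abstraction barrier, kcal/mol.
#' @param barrier_s Pro-S barrier, kcal/mol.
#' @param temperature Temperature, K (> 0); default 298.15 K.
#' @return One-row tibble: `dd_barrier` (kcal/mol), `temperature`,
#'   `ratio` (>= 1, major : minor), `major` (`"R"`, `"S"` or `"tie"`),
#'   `percent_major`.
#' @examples
#' enantiomer_ratio(4.8, 7.81) # ~161 : 1 in favour of R
#' @export
enantiomer_ratio <- function(barrier_r, barrier_s, temperature = 298.15) {
  stopifnot(temperature > 0, is.finite(barrier_r), is.finite(barrier_s))
  dd <- barrier_s - barrier_r
  ratio <- exp(abs(dd) / (R_GAS_KCAL * temperature))
  major <- if (dd > 0) "R" else if (dd < 0) "S" else "tie"
  tibble(
    dd_barrier = abs(dd), temperature = temperature,
    ratio = ratio, major = major,
    percent_major = 100 * ratio / (1 + ratio)
  )
}

#' Boltzmann fraction of reaction on the lower of two spin surfaces
#'
#' Two-state Boltzmann partition over the barrier difference:
#' `1 / (1 + exp(-ddE / (R T)))`, the fraction proceeding over the lower
#' barrier (`barrier_a` vs `barrier_b`, kcal/mol).
#'
#' @param barrier_a,barrier_b Barriers on the two surfaces, kcal/mol.
#' @param temperature Temperature, K (> 0).
#' @return Fraction in `[0.5, 1)` proceeding on the lower-barrier surface.
#' @export
spin_state_preference <- function(barrier_a, barrier_b, temperature = 298.15) {
  stopifnot(temperature > 0)
  dd <- abs(barrier_a - barrier_b)
  1 / (1 + exp(-dd / (R_GAS_KCAL * temperature)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.population_hist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$density)) +
    ggplot2::geom_col(width = attr(object, "bin_width"), fill = "steelblue",
                      colour = NA) +
    ggplot2::geom_vline(xintercept = attr(object, "mode"), linetype = 2) +
    ggplot2::labs(x = "distance (Å)", y = "population density (1/Å)") +
    ggplot2::theme_minimal()
}
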