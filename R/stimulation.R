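#' Stochastic stimulation schedule
#'
#' Generates the on/off stimulation paradigm: after an initial burn-in with
#' no stimulation, stimulus epochs alternate with off intervals; stimulus
#' durations and interstimulus intervals are drawn i.i.d. from exponential
#' distributions with means `T_on` and `T_off`, and the stimulus identity is
#' drawn uniformly (or with the given probabilities).  `phases` allows the
#' means to switch mid-run (e.g. learning phase `T_on = 1 s`, `T_off = 2 s`,
#' recall phase `T_on = 0.2 s`, `T_off = 20 s`).
#'
#' @param total_T total simulated time (s).
#' @param n_patterns number of stimulus patterns.
#' @param T_on,T_off mean stimulus duration and mean interstimulus
#'   interval (s).
#' @param burn_in initial unstimulated period (s), at least 50 s in the
#'   reference paradigm.
#' @param phases `NULL` or a data.frame with columns `t_start`, `T_on`,
#'   `T_off`; the row with the largest `t_start` not exceeding the current
#'   time provides the means (overrides `T_on`/`T_off`).
#' @param prob stimulus probabilities (default uniform).
#' @return data.frame with columns `pattern` (1-based), `t_start`, `t_end`;
#'   zero rows if `total_T <= burn_in`.
#' @export
schedule_stimuli <- function(total_T, n_patterns, T_on = 1, T_off = 2,
                             burn_in = 50, phases = NULL, prob = NULL) {
  stopifnot(total_T > 0, n_patterns >= 1, T_on > 0, T_off > 0, burn_in >= 0)
  if (is.null(prob)) prob <- rep(1 / n_patterns, n_patterns)
  pat <- integer(0); t0 <- numeric(0); t1 <- numeric(0)
  t <- burn_in
  while (t < total_T) {
    if (!is.null(phases)) {
      row <- max(which(phases$t_start <= t))
      T_on_c <- phases$T_on[row]; T_off_c <- phases$T_off[row]
    } else { T_on_c <- T_on; T_off_c <- T_off }
    start <- t + stats::rexp(1, 1 / T_off_c)
    if (start >= total_T) break
    end <- min(start + stats::rexp(1, 1 / T_on_c), total_T)
    pat <- c(pat, sample.int(n_patterns, 1, prob = prob))
    t0 <- c(t0, start); t1 <- c(t1, end)
    t <- end
  }
  data.frame(pattern = pat, t_start = t0, t_end = t1)
}

#' Instantaneous input rate under a stimulation pattern
#'
#' Rate of each input unit: `background + zeta * increment` while the
#' unit's pattern is active, `background` otherwise.
#'
#' @param zeta per-unit activation values in `[0, 1]`.
#' @param active logical: is the pattern currently active?
#' @param background background rate in Hz (paradigm value 10).
#' @param increment rate increment at `zeta = 1` (paradigm value 35).
#' @return per-unit rates in Hz.
#' @export
pattern_rate <- function(zeta, active, background = 10, increment = 35) {
  if (any(zeta < 0 | zeta > 1)) stop("'zeta' must lie in [0, 1]")
  rate <- rep_len(background, length(zeta))
  if (active) rate + zeta * increment else rate
}

#' Overlapping geometric shape patterns on the input grid
#'
#' Rasterises `n_patterns` binary masks of simple geometric shapes (disc,
#' square, triangle, cross) on the input grid.  Shapes are sized and
#' positioned, with seeded jitter, such that every pair of masks shares at
#' least one unit (the downstream protocols only rely on this overlap
#' structure).
#'
#' @param grid input grid dimensions, e.g. `c(64, 64)`.
#' @param n_patterns number of patterns (1-4).
#' @param seed RNG seed.
#' @return matrix (`prod(grid)` x `n_patterns`) of 0/1 activations; unit id
#'   `(y - 1) * nx + x` maps to row `id`.
#' @export
make_shape_patterns <- function(grid = c(64, 64), n_patterns = 4, seed = 1) {
  stopifnot(n_patterns >= 1, n_patterns <= 4)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  nx <- grid[1]; ny <- grid[2]
  xs <- rep(seq_len(nx), times = ny)
  ys <- rep(seq_len(ny), each = nx)
  s <- min(nx, ny)
  ## shape centres sit in different quadrant directions so each pattern has
  ## a distinct core, displaced little enough that neighbours still overlap
  ang <- c(45, 135, 225, 315)[seq_len(n_patterns)] * pi / 180
  off <- 0.18 * s
  jit <- function() stats::runif(2, -s / 25, s / 25)
  masks <- matrix(0, nx * ny, n_patterns)
  shapes <- c("disc", "square", "triangle", "cross")
  for (k in seq_len(n_patterns)) {
    j <- jit()
    cx <- (nx + 1) / 2 + off * cos(ang[k]) + j[1]
    cy <- (ny + 1) / 2 + off * sin(ang[k]) + j[2]
    m <- switch(shapes[k],
      disc = (xs - cx)^2 + (ys - cy)^2 <= (0.24 * s)^2,
      square = abs(xs - cx) <= 0.20 * s & abs(ys - cy) <= 0.20 * s,
      triangle = {
        h <- 0.46 * s
        (ys >= cy - h / 2) & (ys <= cy + h / 2) &
          (abs(xs - cx) <= (cy + h / 2 - ys) * 0.5)
      },
      cross = (abs(xs - cx) <= 0.07 * s & abs(ys - cy) <= 0.36 * s) |
              (abs(ys - cy) <= 0.07 * s & abs(xs - cx) <= 0.36 * s))
    ## a small shared central blob guarantees pairwise overlap (the shapes
    ## all cover part of the middle of the field), while the displaced
    ## bodies give each pattern a distinct core
    central <- (xs - (nx + 1) / 2)^2 + (ys - (ny + 1) / 2)^2 <= (0.05 * s)^2
    masks[, k] <- as.numeric(m | central)
  }
  for (a in seq_len(n_patterns)) for (b in seq_len(n_patterns)) {
    if (a < b && sum(masks[, a] * masks[, b]) == 0)
      stop("generated masks do not overlap; choose another seed")
  }
  masks
}

#' Graded Gaussian activation profiles over a 1-D input index
#'
#' Builds `n_profiles` activation profiles `zeta(i) = exp(-(i - c)^2 /
#' (2 sigma^2))` over the presynaptic index, with distinct random centres
#' and peak value 1 (the receptive-field development stimulus: fixed width,
#' shifting centre).
#'
#' @param n_inputs number of input units.
#' @param sigma profile standard deviation in index units (reference
#'   value 50).
#' @param n_profiles number of distinct centres (reference value 10).
#' @param seed RNG seed.
#' @return matrix (`n_inputs` x `n_profiles`) of activations in `[0, 1]`.
#' @export
make_gaussian_profile_stimuli <- function(n_inputs = 1000, sigma = 50,
                                          n_profiles = 10, seed = 1) {
  stopifnot(sigma > 0, n_profiles >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  centres <- stats::runif(n_profiles, 1, n_inputs)
  idx <- seq_len(n_inputs)
  vapply(centres, function(cc) exp(-(idx - cc)^2 / (2 * sigma^2)),
         numeric(n_inputs))
}
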