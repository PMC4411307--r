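#' Stimulus-evoked firing rates
#'
#' For every neuron and stimulus, the number of spikes emitted during that
#' stimulus' on-epochs inside the analysis window divided by the total
#' on-time of the stimulus in the window.
#'
#' @param raster data.frame with columns `time` (s) and `id` (0-based
#'   neuron index).
#' @param schedule data.frame with columns `pattern`, `t_start`, `t_end`
#'   (as from [schedule_stimuli()]).
#' @param window length-2 numeric analysis window (s).
#' @param n_neurons number of neurons (rows of the result).
#' @return matrix (`n_neurons` x `n_patterns`) of evoked rates in Hz;
#'   columns for stimuli with zero on-time in the window are `NA` (flagged
#'   with a warning).
#' @export
evoked_rates <- function(raster, schedule, window, n_neurons) {
  stopifnot(length(window) == 2, window[2] > window[1])
  n_pat <- max(schedule$pattern)
  sch <- schedule
  sch$t_start <- pmax(sch$t_start, window[1])
  sch$t_end <- pmin(sch$t_end, window[2])
  sch <- sch[sch$t_end > sch$t_start, , drop = FALSE]
  counts <- matrix(0, n_neurons, n_pat)
  on_time <- numeric(n_pat)
  for (r in seq_len(nrow(sch))) {
    mu <- sch$pattern[r]
    on_time[mu] <- on_time[mu] + (sch$t_end[r] - sch$t_start[r])
    sel <- raster$time >= sch$t_start[r] & raster$time < sch$t_end[r]
    if (any(sel)) {
      tab <- tabulate(raster$id[sel] + 1L, nbins = n_neurons)
      counts[, mu] <- counts[, mu] + tab
    }
  }
  rates <- sweep(counts, 2, on_time, "/")
  if (any(on_time == 0)) {
    warning("stimuli with zero on-time in the window: ",
            paste(which(on_time == 0), collapse = ", "))
    rates[, on_time == 0] <- NA_real_
  }
  rates
}

#' Assign readout populations from evoked rates
#'
#' Neuron `i` is counted as coding for stimulus `mu` if its evoked rate
#' exceeds the threshold.  The default threshold rule is
#' `max(thr_abs, median_i + n_sd * mad_i)` per stimulus (robust location
#' and scale, so a large responsive subpopulation cannot inflate its own
#' threshold), which separates ~30 Hz assembly responses from ~1 Hz
#' background at any network scale.  Sets may overlap; the complement of
#' their union is the reserve pool.
#'
#' @param nu evoked-rate matrix from [evoked_rates()].
#' @param thr_abs absolute floor of the threshold in Hz.
#' @param n_sd number of robust standard deviations above the median.
#' @param threshold optional fixed threshold (overrides the rule).
#' @return object of class `readout_set`: list with `members` (list of
#'   0-based id vectors per stimulus), `reserve` (0-based ids in no set),
#'   and `threshold` (per-stimulus values used).
#' @export
assign_readouts <- function(nu, thr_abs = 10, n_sd = 2, threshold = NULL) {
  n_pat <- ncol(nu)
  thr <- if (!is.null(threshold)) rep_len(threshold, n_pat) else
    vapply(seq_len(n_pat), function(mu)
      max(thr_abs, stats::median(nu[, mu], na.rm = TRUE) +
            n_sd * stats::mad(nu[, mu], na.rm = TRUE)), numeric(1))
  members <- lapply(seq_len(n_pat), function(mu)
    which(!is.na(nu[, mu]) & nu[, mu] > thr[mu]) - 1L)
  all_m <- unique(unlist(members))
  structure(list(members = members,
                 reserve = setdiff(seq_len(nrow(nu)) - 1L, all_m),
                 threshold = thr),
            class = "readout_set")
}

#' Population activity of a neuron set
#'
#' Mean firing rate of the set in time bins: spike count of members per bin
#' divided by `|M| * bin` (Hz).
#'
#' @param raster spike data.frame (`time`, `id`).
#' @param members 0-based member ids (non-empty).
#' @param bin bin width in seconds (reference resolution 50 ms).
#' @param t_range length-2 time range; defaults to the raster's span.
#' @return data.frame with `t` (bin centre) and `rate` (Hz).
#' @export
population_activity <- function(raster, members, bin = 0.05,
                                t_range = NULL) {
  if (length(members) == 0) stop("empty member set")
  if (is.null(t_range)) t_range <- c(0, max(raster$time, 0))
  breaks <- seq(t_range[1], t_range[2], by = bin)
  if (breaks[length(breaks)] < t_range[2])
    breaks <- c(breaks, breaks[length(breaks)] + bin)
  tt <- raster$time[raster$id %in% members]
  tt <- tt[tt >= t_range[1] & tt < breaks[length(breaks)]]
  counts <- tabulate(findInterval(tt, breaks), nbins = length(breaks) - 1)
  data.frame(t = breaks[-length(breaks)] + bin / 2,
             rate = counts / (length(members) * bin))
}

#' Covariance matrix of stimulus-evoked responses
#'
#' `C[mu, nu] = mean_i[(nu_i^mu - mean^mu) * (nu_i^nu - mean^nu)]`, where
#' `mean^mu` is the mean evoked response of all neurons for stimulus `mu`.
#' The result is symmetric positive semi-definite (a Gram matrix of the
#' centred response vectors).
#'
#' @param nu evoked-rate matrix (neurons x stimuli), at least 2 stimuli.
#' @return covariance matrix (stimuli x stimuli).
#' @export
evoked_covariance <- function(nu) {
  stopifnot(ncol(nu) >= 2)
  centred <- sweep(nu, 2, colMeans(nu, na.rm = TRUE))
  crossprod(as.matrix(centred)) / nrow(nu)
}

#' Per-neuron rate and interspike-interval statistics
#'
#' Firing rate, ISI coefficient of variation (sd/mean of the ISIs) and ISI
#' collection per neuron within a window.  Neurons with fewer than 3 spikes
#' (< 2 ISIs) are excluded from the CV statistics and counted.
#'
#' @param raster spike data.frame (`time`, `id`).
#' @param window length-2 analysis window (s).
#' @param n_neurons number of neurons.
#' @return list with `rate` (Hz per neuron), `cv` (CV-ISI per neuron, `NA`
#'   where undefined), `n_excluded`, and `isi` (pooled ISIs).
#' @export
spike_stats <- function(raster, window, n_neurons) {
  stopifnot(window[2] > window[1])
  sel <- raster$time >= window[1] & raster$time < window[2]
  r <- raster[sel, , drop = FALSE]
  dur <- window[2] - window[1]
  rate <- tabulate(r$id + 1L, nbins = n_neurons) / dur
  cv <- rep(NA_real_, n_neurons)
  isis <- vector("list", n_neurons)
  sp <- split(r$time, factor(r$id, levels = 0:(n_neurons - 1)))
  for (i in seq_len(n_neurons)) {
    st <- sort(sp[[i]])
    if (length(st) >= 3) {
      isi <- diff(st)
      cv[i] <- stats::sd(isi) / mean(isi)
      isis[[i]] <- isi
    }
  }
  list(rate = rate, cv = cv, n_excluded = sum(is.na(cv)),
       isi = unlist(isis))
}

#' Peristimulus time histogram
#'
#' Trial-averaged, member-averaged firing rate aligned on event onsets.
#'
#' @param raster spike data.frame (`time`, `id`).
#' @param events event (stimulus onset) times in seconds.
#' @param members 0-based neuron ids to average over.
#' @param window length-2 window around each event (s), e.g. `c(-0.2, 0.5)`.
#' @param bin bin width (s).
#' @return data.frame with `t` (bin centre relative to onset) and `rate`
#'   (Hz).
#' @export
psth <- function(raster, events, members, window = c(-0.2, 0.5),
                 bin = 0.01) {
  stopifnot(length(events) >= 1, length(members) >= 1)
  breaks <- seq(window[1], window[2], by = bin)
  if (breaks[length(breaks)] < window[2])
    breaks <- c(breaks, breaks[length(breaks)] + bin)
  tt <- raster$time[raster$id %in% members]
  rel <- unlist(lapply(events, function(e) {
    x <- tt - e
    x[x >= window[1] & x < breaks[length(breaks)]]
  }))
  counts <- tabulate(findInterval(rel, breaks), nbins = length(breaks) - 1)
  data.frame(t = breaks[-length(breaks)] + bin / 2,
             rate = counts / (length(events) * length(members) * bin))
}
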