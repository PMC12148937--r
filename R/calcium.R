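#' Mechanical-deformation stimulus protocol
#'
#' Describes the poking protocol used for calcium imaging of enteric
#' neurons: each epoch starts with the electrode lowered 25 um into the
#' mucosa (t = 0, stimulus onset), lowered a further 25 um at 10 s, and
#' raised at 25 s; the 20 s post-stimulus window follows the release, and
#' each epoch's 20 s baseline precedes its onset (and therefore overlaps
#' the previous epoch's post-stimulus window). Defaults: 24 epochs at 45 s
#' period, 50 frames/s, first onset at 20 s, 40 s tail — a 1140 s (19 min)
#' recording.
#'
#' @param n_epochs number of stimulation epochs.
#' @param fps sampling rate, frames per second.
#' @param t_first_down_s electrode first-down time, epoch-relative (stimulus
#'   onset; 0 by definition).
#' @param t_second_down_s second 25 um lowering, epoch-relative seconds.
#' @param t_release_s electrode raise time, epoch-relative seconds (end of
#'   mechanical deformation).
#' @param post_window_s post-stimulus window length after release, seconds.
#' @param baseline_s baseline window length before each onset, seconds.
#' @param immediate_cutoff_s latency boundary between immediate and delayed
#'   responses, seconds.
#' @param epoch_starts_s absolute onset times; defaults to
#'   `first_onset_s + (0:(n_epochs-1)) * epoch_period_s`.
#' @param first_onset_s onset of the first epoch, seconds.
#' @param epoch_period_s time between consecutive onsets, seconds.
#' @param tail_s recording time after the last post-stimulus window.
#' @return object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(n_epochs = 24, fps = 50,
                              t_first_down_s = 0, t_second_down_s = 10,
                              t_release_s = 25, post_window_s = 20,
                              baseline_s = 20, immediate_cutoff_s = 0.5,
                              epoch_starts_s = NULL, first_onset_s = 20,
                              epoch_period_s = 45, tail_s = 40) {
  .assert_scalar_num(n_epochs, "n_epochs", lo = 1, integer = TRUE)
  .assert_scalar_num(fps, "fps", lo = 1e-9)
  if (!(t_second_down_s < t_release_s))
    stop("t_second_down_s must be earlier than t_release_s", call. = FALSE)
  if (any(c(post_window_s, baseline_s, immediate_cutoff_s) < 0))
    stop("window lengths must be non-negative", call. = FALSE)
  if (is.null(epoch_starts_s))
    epoch_starts_s <- first_onset_s + (seq_len(n_epochs) - 1) * epoch_period_s
  if (length(epoch_starts_s) != n_epochs || any(diff(epoch_starts_s) <= 0))
    stop("epoch_starts_s must be strictly increasing, one per epoch", call. = FALSE)
  duration_s <- max(epoch_starts_s) + t_release_s + post_window_s + tail_s
  structure(list(n_epochs = as.integer(n_epochs), fps = fps,
                 t_first_down_s = t_first_down_s,
                 t_second_down_s = t_second_down_s,
                 t_release_s = t_release_s, post_window_s = post_window_s,
                 baseline_s = baseline_s,
                 immediate_cutoff_s = immediate_cutoff_s,
                 epoch_starts_s = as.numeric(epoch_starts_s),
                 duration_s = duration_s),
            class = "stimulus_protocol")
}

#' Spike-detection parameters
#'
#' The detector (see [detect_spikes()]) thresholds a causally smoothed
#' dF/F trace at `z_threshold` times the baseline noise sigma (robust MAD
#' estimate on the raw dF/F), backtracks each detection to the first raw
#' threshold crossing to recover the transient onset, and merges onsets
#' closer than `min_separation_s`.
#'
#' @param z_threshold detection threshold in baseline-noise sigmas.
#' @param min_separation_s refractory merge window, seconds.
#' @param smooth_s causal boxcar length for the detection trace, seconds.
#' @param baseline_window_s running-percentile window for F0 in
#'   [compute_dff()], seconds.
#' @param baseline_percentile percentile used for F0.
#' @return object of class `spike_params`.
#' @export
spike_params <- function(z_threshold = 3.5, min_separation_s = 0.5,
                         smooth_s = 0.3, baseline_window_s = 30,
                         baseline_percentile = 10) {
  .assert_scalar_num(z_threshold, "z_threshold", lo = 1e-9)
  .assert_scalar_num(min_separation_s, "min_separation_s", lo = 0)
  .assert_scalar_num(smooth_s, "smooth_s", lo = 0)
  .assert_scalar_num(baseline_window_s, "baseline_window_s", lo = 1e-9)
  .assert_scalar_num(baseline_percentile, "baseline_percentile", lo = 0, hi = 100)
  structure(list(z_threshold = z_threshold,
                 min_separation_s = min_separation_s, smooth_s = smooth_s,
                 baseline_window_s = baseline_window_s,
                 baseline_percentile = baseline_percentile),
            class = "spike_params")
}

#' Compute dF/F from a raw fluorescence trace
#'
#' F0 is a running low percentile (default 10th over 30 s), evaluated on a
#' 1 s grid and linearly interpolated, which tracks slow baseline drift
#' while ignoring transients.
#'
#' @param f numeric raw fluorescence trace.
#' @param fps sampling rate.
#' @param params a [spike_params()] (only the baseline fields are used).
#' @return numeric dF/F trace of the same length.
#' @export
compute_dff <- function(f, fps, params = spike_params()) {
  stopifnot(is.numeric(f), length(f) > 1, all(is.finite(f)))
  n <- length(f)
  half <- round(params$baseline_window_s * fps / 2)
  stride <- max(1L, as.integer(round(fps)))          # one F0 knot per second
  knots <- unique(c(seq(1L, n, by = stride), n))
  f0k <- vapply(knots, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    unname(stats::quantile(f[lo:hi], params$baseline_percentile / 100,
                           names = FALSE))
  }, numeric(1))
  f0 <- stats::approx(knots, f0k, xout = seq_len(n), rule = 2)$y
  if (any(f0 <= 0)) stop("non-positive F0 baseline; trace not a raw fluorescence signal?",
                         call. = FALSE)
  (f - f0) / f0
}

#' Detect calcium transients on a dF/F trace
#'
#' A sample-wise threshold on raw dF/F cannot satisfy a low false-positive
#' budget at 50 frames/s (a 3.5-sigma white-noise upcrossing occurs about
#' every 1.5 min), so detection runs on a short causal boxcar average: the
#' smoothed trace must exceed `z_threshold * sigma`, with sigma the robust
#' (MAD) noise estimate of the raw dF/F. Each detection is then backtracked
#' over the smoothing window to the first raw sample above threshold, which
#' for fast-rising transients recovers the true onset sample. Onsets closer
#' than `min_separation_s` are merged (the earliest is kept).
#'
#' @param dff numeric dF/F trace.
#' @param fps sampling rate.
#' @param params a [spike_params()].
#' @param sigma optional known noise sigma; when missing it is estimated
#'   robustly from first differences (`mad(diff(dff))/sqrt(2)`), which is
#'   insensitive to the slow transients themselves.
#' @return numeric vector of spike onset times, seconds from trace start.
#' @export
detect_spikes <- function(dff, fps, params = spike_params(), sigma = NULL) {
  stopifnot(is.numeric(dff), length(dff) > 1)
  if (is.null(sigma)) sigma <- stats::mad(diff(dff)) / sqrt(2)
  if (sigma <= 0) return(numeric(0))
  w <- max(1L, as.integer(round(params$smooth_s * fps)))
  sm <- as.numeric(stats::filter(dff, rep(1 / w, w), sides = 1))
  sm[seq_len(w - 1)] <- cumsum(dff[seq_len(w - 1)]) / seq_len(w - 1)
  thr <- params$z_threshold * sigma
  above <- sm > thr
  rises <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(rises)) return(numeric(0))
  onsets <- vapply(rises, function(i) {
    back <- max(1L, i - w + 1L):i
    hit <- back[dff[back] > thr]
    if (length(hit)) hit[1] else i
  }, numeric(1))
  times <- sort(unique((onsets - 1) / fps))
  keep <- times[1]
  for (t in times[-1]) if (t - keep[length(keep)] >= params$min_separation_s)
    keep <- c(keep, t)
  keep
}

#' Epoch window table for a recorded trace
#'
#' Expresses each epoch's stimulus (`[0, t_release + post? )` — stimulus
#' window is `[0, t_release)`), post-stimulus (`[t_release,
#' t_release + post_window)`) and baseline (`[-baseline, 0)`) windows in
#' both seconds and half-open sample ranges. A sample can belong to several
#' windows (each epoch's baseline overlaps the previous post-stimulus
#' window); epochs whose windows extend beyond the trace are flagged
#' incomplete.
#'
#' @param n_samples trace length in samples.
#' @param protocol a [stimulus_protocol()].
#' @return data.frame, one row per epoch: onset_s, window bounds in seconds
#'   (`stim_from_s` ... `base_to_s`), sample ranges (1-based, half-open),
#'   and `complete`.
#' @export
segment_epochs <- function(n_samples, protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"), n_samples >= 1)
  on <- protocol$epoch_starts_s
  fps <- protocol$fps
  idx <- function(t) as.integer(floor(t * fps)) + 1L   # sample containing time t
  df <- data.frame(
    epoch = seq_along(on), onset_s = on,
    stim_from_s = on, stim_to_s = on + protocol$t_release_s,
    post_from_s = on + protocol$t_release_s,
    post_to_s = on + protocol$t_release_s + protocol$post_window_s,
    base_from_s = on - protocol$baseline_s, base_to_s = on)
  df$stim_from_i <- idx(df$stim_from_s); df$stim_to_i <- idx(df$stim_to_s)
  df$post_from_i <- idx(df$post_from_s); df$post_to_i <- idx(df$post_to_s)
  df$base_from_i <- pmax(1L, idx(pmax(df$base_from_s, 0))); df$base_to_i <- idx(df$base_to_s)
  df$complete <- df$base_from_s >= 0 & df$post_to_i - 1L <= n_samples
  df
}

#' Per-epoch spike count, first-spike latency and latency class
#'
#' Latency is measured from stimulus onset (the first electrode-down).
#' Classes follow the protocol taxonomy: immediate (`< immediate_cutoff`,
#' default 0.5 s), delayed (from the cutoff up to electrode release at
#' 25 s; a spike at exactly 0.5 s is delayed), poststimulus (within the
#' post window after release), `none` otherwise. Spike counts cover the
#' stimulus plus post-stimulus window.
#'
#' @param epoch_onset_s epoch onset, absolute seconds.
#' @param spikes numeric spike onset times, absolute seconds.
#' @param protocol a [stimulus_protocol()].
#' @return list: `n_spikes`, `first_latency_s` (NA if none),
#'   `latency_class`.
#' @export
epoch_latency <- function(epoch_onset_s, spikes, protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  rel <- spikes - epoch_onset_s
  win_end <- protocol$t_release_s + protocol$post_window_s
  in_win <- rel >= 0 & rel < win_end
  if (!any(in_win))
    return(list(n_spikes = 0L, first_latency_s = NA_real_,
                latency_class = "none"))
  first <- min(rel[in_win])
  cls <- if (first < protocol$immediate_cutoff_s) "immediate"
         else if (first < protocol$t_release_s) "delayed"
         else "poststimulus"
  list(n_spikes = sum(in_win), first_latency_s = first, latency_class = cls)
}

#' Categorize a cell from its spike times
#'
#' `spontaneous` if any spike falls on a pure-baseline sample — baseline
#' time not belonging to any epoch's stimulus or post-stimulus window
#' (baselines overlap the previous post window by design, so
#' stimulus-attributable activity is not counted as ongoing); otherwise
#' `quiescent_responding` if any spike falls in a stimulus or post window;
#' otherwise `nonresponding`.
#'
#' @param spikes numeric spike onset times, absolute seconds.
#' @param protocol a [stimulus_protocol()].
#' @return one of `"spontaneous"`, `"quiescent_responding"`,
#'   `"nonresponding"`.
#' @export
classify_cell <- function(spikes, protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (!length(spikes)) return("nonresponding")
  on <- protocol$epoch_starts_s
  win_end <- protocol$t_release_s + protocol$post_window_s
  in_stim_post <- vapply(spikes, function(t)
    any(t >= on & t < on + win_end), logical(1))
  in_baseline <- vapply(spikes, function(t)
    any(t >= on - protocol$baseline_s & t < on), logical(1))
  if (any(in_baseline & !in_stim_post)) "spontaneous"
  else if (any(in_stim_post)) "quiescent_responding"
  else "nonresponding"
}

#' Full epoch analysis of a set of ROI traces
#'
#' Runs dF/F conversion, spike detection, cell categorization and per-epoch
#' latency classification for every ROI column of a trace table.
#'
#' @param traces data.frame with column `time_s` and one column per ROI
#'   (raw fluorescence), e.g. from [gen_traces()] or [read_traces_csv()].
#' @param protocol a [stimulus_protocol()].
#' @param params a [spike_params()].
#' @param dff logical: are the trace columns already dF/F (skip baseline
#'   division)?
#' @return list: `categories` (named character per ROI), `epochs`
#'   (data.frame cell, epoch, n_spikes, first_latency_s, latency_class),
#'   `spikes` (named list of onset-time vectors).
#' @export
analyze_traces <- function(traces, protocol = stimulus_protocol(),
                           params = spike_params(), dff = FALSE) {
  stopifnot(is.data.frame(traces), "time_s" %in% names(traces))
  fps <- protocol$fps
  rois <- setdiff(names(traces), "time_s")
  spikes <- list(); categories <- character(0); rows <- list()
  for (r in rois) {
    x <- traces[[r]]
    dx <- if (dff) x else compute_dff(x, fps, params)
    sp <- detect_spikes(dx, fps, params)
    spikes[[r]] <- sp
    categories[r] <- classify_cell(sp, protocol)
    for (e in seq_len(protocol$n_epochs)) {
      el <- epoch_latency(protocol$epoch_starts_s[e], sp, protocol)
      rows[[length(rows) + 1L]] <-
        data.frame(cell = r, epoch = e, n_spikes = el$n_spikes,
                   first_latency_s = el$first_latency_s,
                   latency_class = el$latency_class)
    }
  }
  list(categories = categories,
       epochs = do.call(rbind, c(rows, make.row.names = FALSE)),
       spikes = spikes)
}

#' Compare an epoch metric between two cell groups
#'
#' Reduces per-epoch results to one value per cell and reports both a
#' two-tailed Student's t test and a Mann-Whitney U test on the per-cell
#' values.
#'
#' @param a,b epoch-result data.frames (as `epochs` from
#'   [analyze_traces()]) for the two groups.
#' @param metric `"spikes_per_epoch"` (mean spikes over epochs),
#'   `"latency"` (mean first-spike latency over responding epochs) or
#'   `"n_responding_epochs"`.
#' @param primary which test to flag as primary.
#' @return list: `metric`, per-cell values `values_a`/`values_b`,
#'   `t` and `mwu` (statistic + p), `primary`.
#' @export
compare_groups <- function(a, b,
                           metric = c("spikes_per_epoch", "latency",
                                      "n_responding_epochs"),
                           primary = c("t", "mwu")) {
  metric <- match.arg(metric); primary <- match.arg(primary)
  per_cell <- function(df) {
    if (!nrow(df)) stop("empty group", call. = FALSE)
    sp <- split(df, df$cell)
    vapply(sp, function(d) switch(metric,
      spikes_per_epoch = mean(d$n_spikes),
      latency = if (all(is.na(d$first_latency_s))) NA_real_
                else mean(d$first_latency_s, na.rm = TRUE),
      n_responding_epochs = sum(d$latency_class != "none")), numeric(1))
  }
  va <- per_cell(a); vb <- per_cell(b)
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (!length(va) || !length(vb)) stop("empty group after metric reduction", call. = FALSE)
  tt <- stats::t.test(va, vb, var.equal = FALSE)
  wt <- stats::wilcox.test(va, vb, exact = FALSE)
  list(metric = metric, values_a = va, values_b = vb,
       t = list(statistic = unname(tt$statistic), p_value = tt$p.value),
       mwu = list(statistic = unname(wt$statistic), p_value = wt$p.value),
       primary = primary)
}
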