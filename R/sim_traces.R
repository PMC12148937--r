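#' Configuration for the synthetic calcium-trace generator
#'
#' Emulates GCaMP6f fluorescence recordings under the mechanical-deformation
#' protocol: a baseline fluorescence level with Gaussian noise, on which
#' calcium transients (instantaneous rise, exponential decay) are planted.
#' Cells are `nonresponding` (noise only), `quiescent` (one transient per
#' epoch at a planted latency from stimulus onset) or `spontaneous`
#' (homogeneous-Poisson transients throughout the recording, optionally with
#' stimulus-locked responses as well).
#'
#' @param n_cells number of ROIs.
#' @param category_of_cell character vector (length 1 or `n_cells`) with
#'   values `"nonresponding"`, `"quiescent"` or `"spontaneous"`.
#' @param planted_latency_s numeric vector of candidate latencies (seconds
#'   from epoch onset); one is drawn per epoch per responding cell. Must lie
#'   inside the stimulus + post-stimulus window of the protocol.
#' @param transient length-2 numeric: amplitude in units of `noise_sd`, and
#'   exponential decay constant in seconds.
#' @param noise_sd Gaussian noise standard deviation (fluorescence units).
#' @param spontaneous_rate_hz Poisson event rate for spontaneous cells.
#' @param protocol a [stimulus_protocol()].
#' @param seed integer seed.
#' @param baseline_f baseline fluorescence level.
#' @param spontaneous_responds should spontaneous cells also carry
#'   stimulus-locked responses (they did in the recordings this emulates)?
#' @return object of class `sim_trace_config`.
#' @export
sim_trace_config <- function(n_cells = 10,
                             category_of_cell = "quiescent",
                             planted_latency_s = 0.3,
                             transient = c(amplitude = 5, decay_s = 1),
                             noise_sd = 1, spontaneous_rate_hz = 0.1,
                             protocol = stimulus_protocol(), seed = 1L,
                             baseline_f = 100, spontaneous_responds = TRUE) {
  .assert_scalar_num(n_cells, "n_cells", lo = 1, integer = TRUE)
  stopifnot(inherits(protocol, "stimulus_protocol"))
  category_of_cell <- rep_len(category_of_cell, n_cells)
  ok <- category_of_cell %in% c("nonresponding", "quiescent", "spontaneous")
  if (!all(ok)) stop("unknown cell category: ",
                     paste(unique(category_of_cell[!ok]), collapse = ", "),
                     call. = FALSE)
  .assert_scalar_num(noise_sd, "noise_sd", lo = 1e-12)
  .assert_scalar_num(spontaneous_rate_hz, "spontaneous_rate_hz", lo = 0)
  .assert_scalar_num(seed, "seed", integer = TRUE)
  if (length(transient) != 2L || any(!is.finite(transient)) || any(transient <= 0))
    stop("transient must be positive (amplitude, decay_s)", call. = FALSE)
  win <- protocol$t_release_s + protocol$post_window_s
  if (any(category_of_cell == "quiescent") &&
      (any(!is.finite(planted_latency_s)) ||
       any(planted_latency_s < 0) || any(planted_latency_s >= win)))
    stop(sprintf("planted_latency_s must lie in [0, %g) s for quiescent cells", win),
         call. = FALSE)
  structure(list(n_cells = as.integer(n_cells),
                 category_of_cell = category_of_cell,
                 planted_latency_s = planted_latency_s,
                 transient = as.numeric(transient), noise_sd = noise_sd,
                 spontaneous_rate_hz = spontaneous_rate_hz,
                 protocol = protocol, seed = as.integer(seed),
                 baseline_f = baseline_f,
                 spontaneous_responds = isTRUE(spontaneous_responds)),
            class = "sim_trace_config")
}

#' Generate synthetic calcium traces with known event times
#'
#' @param config a [sim_trace_config()].
#' @return list with `traces` (data.frame, column `time_s` then one column
#'   per ROI), `truth` (data.frame: `cell`, `time_s`, `epoch` — NA for
#'   spontaneous events — and `type` = `"response"`/`"spontaneous"`),
#'   `category` (named character, ground-truth category per cell), and the
#'   `protocol`.
#' @export
gen_traces <- function(config) {
  stopifnot(inherits(config, "sim_trace_config"))
  set.seed(config$seed)
  pr <- config$protocol
  fps <- pr$fps
  n_t <- as.integer(round(pr$duration_s * fps))
  time_s <- (seq_len(n_t) - 1) / fps
  amp <- config$transient[1] * config$noise_sd
  tau <- config$transient[2]

  cells <- sprintf("roi%03d", seq_len(config$n_cells))
  category <- stats::setNames(config$category_of_cell, cells)
  traces <- matrix(0, nrow = n_t, ncol = config$n_cells,
                   dimnames = list(NULL, cells))
  truth <- list()

  kernel_at <- function(t0) {
    # transient sampled on the time grid: 0 before t0, amp*exp(-(t-t0)/tau) after
    dt <- time_s - t0
    ifelse(dt >= 0, amp * exp(-dt / tau), 0)
  }

  for (j in seq_len(config$n_cells)) {
    f <- config$baseline_f + stats::rnorm(n_t, 0, config$noise_sd)
    cat_j <- category[j]
    ev_t <- numeric(0); ev_e <- integer(0); ev_type <- character(0)
    if (cat_j %in% c("quiescent", "spontaneous") &&
        (cat_j == "quiescent" || config$spontaneous_responds)) {
      lat <- if (length(config$planted_latency_s) == 1L)
        rep(config$planted_latency_s, pr$n_epochs)
      else sample(config$planted_latency_s, pr$n_epochs, replace = TRUE)
      t0 <- pr$epoch_starts_s + lat
      ev_t <- c(ev_t, t0); ev_e <- c(ev_e, seq_len(pr$n_epochs))
      ev_type <- c(ev_type, rep("response", pr$n_epochs))
    }
    if (cat_j == "spontaneous" && config$spontaneous_rate_hz > 0) {
      n_sp <- stats::rpois(1, config$spontaneous_rate_hz * pr$duration_s)
      t_sp <- sort(stats::runif(n_sp, 0, pr$duration_s))
      ev_t <- c(ev_t, t_sp); ev_e <- c(ev_e, rep(NA_integer_, n_sp))
      ev_type <- c(ev_type, rep("spontaneous", n_sp))
    }
    for (t0 in ev_t) f <- f + kernel_at(t0)
    traces[, j] <- f
    if (length(ev_t))
      truth[[cells[j]]] <- data.frame(cell = cells[j], time_s = ev_t,
                                      epoch = ev_e, type = ev_type)
  }
  truth <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
           else data.frame(cell = character(0), time_s = numeric(0),
                           epoch = integer(0), type = character(0))
  list(traces = data.frame(time_s = time_s, traces, check.names = FALSE),
       truth = truth, category = category, protocol = pr)
}
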