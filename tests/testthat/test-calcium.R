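# dF/F, epoch segmentation, spike detection, latency taxonomy,
# cell categorization, group comparison

test_that("dF/F follows the closed form on constant and step traces", {
  fps <- 50
  expect_equal(compute_dff(rep(100, 1000), fps), rep(0, 1000))
  # doubling step at 40 s of a 60 s trace: shortly after the step the
  # running 10th percentile still sits at the pre-step level
  f <- c(rep(100, 40 * fps), rep(200, 20 * fps))
  dff <- compute_dff(f, fps)
  probe <- (41 * fps):(43 * fps)
  expect_true(all(abs(dff[probe] - 1) < 1e-9))
  expect_true(all(abs(dff[1:(35 * fps)]) < 1e-9))
})

test_that("planted transient amplitude survives dF/F within 5%", {
  tr <- gen_traces(sim_trace_config(n_cells = 1, category_of_cell = "quiescent",
                                    planted_latency_s = 2, noise_sd = 1e-6,
                                    transient = c(5e5, 1), seed = 2))
  f <- tr$traces[[2]]
  dff <- compute_dff(f, tr$protocol$fps)
  # amplitude 5e5 * 1e-6 * F0(=100): peak dF/F should be 0.005
  peak <- max(dff)
  expect_lt(abs(peak - 0.005) / 0.005, 0.05)
})

test_that("epoch windows land on the right samples and flag truncation", {
  pr <- stimulus_protocol()
  seg <- segment_epochs(round(pr$duration_s * pr$fps), pr)
  expect_equal(nrow(seg), 24L)
  expect_true(all(seg$complete))
  # second electrode-down at 10 s after onset is 500 samples after onset
  onset_i <- seg$stim_from_i[1]
  second_down_i <- as.integer(floor((seg$onset_s[1] + pr$t_second_down_s) * pr$fps)) + 1L
  expect_equal(second_down_i - onset_i, 500L)
  # all windows inside the trace
  expect_true(all(seg$post_to_i - 1 <= round(pr$duration_s * pr$fps)))
  # truncated recording: final epochs incomplete
  seg2 <- segment_epochs(round(500 * pr$fps), pr)
  expect_false(all(seg2$complete))
  expect_true(seg2$complete[1])
})

test_that("spike detection keeps false positives rare on pure noise", {
  fps <- 50
  n <- 19 * 60 * fps
  rate <- sapply(1:20, function(s) {
    set.seed(s)
    dff <- rnorm(n, 0, 0.02)
    length(detect_spikes(dff, fps, spike_params(z_threshold = 3.5))) / 19
  })
  expect_lt(mean(rate), 0.02)
})

test_that("spikes at 5 sigma are recalled and refractory merging applies", {
  fps <- 50
  set.seed(11)
  recalls <- sapply(1:5, function(s) {
    set.seed(s)
    dff <- rnorm(240 * fps, 0, 0.02)
    t0 <- seq(5, 235, by = 10)
    for (t in t0) {
      i <- round(t * fps):(240 * fps)
      dff[i] <- dff[i] + 5 * 0.02 * exp(-(i - round(t * fps)) / (1 * fps))
    }
    sp <- detect_spikes(dff, fps, spike_params())
    mean(sapply(t0, function(t) any(abs(sp - t) < 0.3)))
  })
  expect_gte(mean(recalls), 0.95)
  # two events 0.1 s apart collapse into one under min_separation 0.5
  dff <- rep(0, 20 * fps)
  for (t in c(5, 5.1)) {
    i <- round(t * fps):(20 * fps)
    dff[i] <- dff[i] + 0.5 * exp(-(i - round(t * fps)) / fps)
  }
  sp <- detect_spikes(dff + rnorm(length(dff), 0, 0.02), fps, spike_params())
  expect_equal(sum(sp > 4 & sp < 6), 1L)
})

test_that("latency classes follow the half-open window taxonomy", {
  pr <- stimulus_protocol()
  on <- pr$epoch_starts_s[1]
  expect_equal(epoch_latency(on, on + 0.3, pr)$latency_class, "immediate")
  expect_equal(epoch_latency(on, on + 12, pr)$latency_class, "delayed")
  expect_equal(epoch_latency(on, on + 30, pr)$latency_class, "poststimulus")
  expect_equal(epoch_latency(on, on + 46, pr)$latency_class, "none")
  # boundary: exactly 0.5 s is delayed; exactly 25 s is poststimulus
  expect_equal(epoch_latency(on, on + 0.5, pr)$latency_class, "delayed")
  expect_equal(epoch_latency(on, on + 25, pr)$latency_class, "poststimulus")
  el <- epoch_latency(on, on + c(0.3, 3, 80), pr)
  expect_equal(el$n_spikes, 2L)
  expect_equal(el$first_latency_s, 0.3)
})

test_that("cells are categorized by baseline vs stimulus-locked activity", {
  pr <- stimulus_protocol()
  expect_equal(classify_cell(numeric(0), pr), "nonresponding")
  expect_equal(classify_cell(pr$epoch_starts_s[3] + 0.3, pr),
               "quiescent_responding")
  # a spike in the pure baseline before the first epoch marks spontaneity
  expect_equal(classify_cell(c(5, pr$epoch_starts_s[3] + 0.3), pr),
               "spontaneous")
  # post-stimulus spikes overlap the next baseline but stay stimulus-locked
  expect_equal(classify_cell(pr$epoch_starts_s[3] + 30, pr),
               "quiescent_responding")
})

test_that("the full trace pipeline recovers planted categories and latencies", {
  tr <- gen_traces(sim_trace_config(
    n_cells = 6,
    category_of_cell = c("nonresponding", "quiescent", "quiescent",
                         "quiescent", "nonresponding", "quiescent"),
    planted_latency_s = c(0.3, 12, 30), transient = c(5, 1), seed = 31))
  an <- analyze_traces(tr$traces)
  expect_identical(unname(an$categories[c(1, 5)]), rep("nonresponding", 2))
  expect_identical(unname(an$categories[c(2, 3, 4, 6)]),
                   rep("quiescent_responding", 4))
  # per-epoch latency class vs planted truth
  truth <- tr$truth[tr$truth$type == "response", ]
  truth$planted <- truth$time_s - tr$protocol$epoch_starts_s[truth$epoch]
  truth$expected <- ifelse(truth$planted < 0.5, "immediate",
                    ifelse(truth$planted < 25, "delayed", "poststimulus"))
  got <- merge(truth, an$epochs, by = c("cell", "epoch"))
  expect_gte(mean(got$latency_class == got$expected), 0.95)
})

test_that("group comparisons report both tests and require data", {
  mk_epochs <- function(cells, lambda) {
    do.call(rbind, lapply(cells, function(cl) {
      n <- rpois(24, lambda)
      data.frame(cell = cl, epoch = 1:24, n_spikes = n,
                 first_latency_s = ifelse(n > 0, 1, NA),
                 latency_class = ifelse(n > 0, "delayed", "none"))
    }))
  }
  set.seed(41)
  a <- mk_epochs(paste0("a", 1:10), 2)
  cg <- compare_groups(a, a, "spikes_per_epoch")
  expect_equal(cg$t$p_value, 1, tolerance = 1e-9)
  expect_error(compare_groups(a[0, ], a, "spikes_per_epoch"), "empty")
  # power: one extra spike per epoch, 30 vs 30 cells
  power <- mean(replicate(100, {
    g1 <- mk_epochs(paste0("a", 1:30), 2)
    g2 <- mk_epochs(paste0("b", 1:30), 3)
    compare_groups(g1, g2, "spikes_per_epoch")$mwu$p_value < 0.05
  }))
  expect_gte(power, 0.8)
})
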