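test_that("passive simulator matches the RC closed form", {
  p <- membrane_params(input_resistance_Mohm = 400, capacitance_pF = 30)
  sw <- simulate_sweep(p, step_protocol(0, 200, 500), sweep_ms = 1000)
  expect_equal(sw$voltage_mV, rep(-70, length(sw$voltage_mV)),
               tolerance = 1e-8)   # zero injection, no noise: flat at E_L
  sw <- simulate_sweep(p, step_protocol(-20, 200, 500), sweep_ms = 1000)
  d <- mean(sw$voltage_mV[sw$time_ms > 600 & sw$time_ms <= 700]) -
    mean(sw$voltage_mV[sw$time_ms < 200])
  expect_rel_error(d, -8, 0.005)              # I * R = -8 mV within 0.5%
  tau <- membrane_time_constant(sw)
  expect_lt(abs(tau - 12), 0.1 + 1e-9)        # R*C within one sample
})

test_that("slow K conductance controls first-spike latency", {
  lat <- vapply(c(0, 1, 3), function(g) {
    cs <- simulate_cell_sweeps(membrane_params(kslow_conductance_nS = g))
    first_spike_latency(cs$suprathreshold)
  }, 0)
  expect_lt(lat[1], 100)        # no slow K: immediate firing
  expect_gt(lat[3], 400)        # strong slow K: late-spiking
  expect_true(all(diff(lat) > 0))  # latency monotone in the conductance
})

test_that("hump conductance produces a depolarizing hump, absent otherwise", {
  plain <- simulate_cell_sweeps(membrane_params())
  humped <- simulate_cell_sweeps(membrane_params(hump_conductance_nS = 0.15))
  expect_lt(abs(depolarizing_hump(plain$subthreshold)), 0.5)
  expect_gt(depolarizing_hump(humped$subthreshold), 0.5)
})

test_that("simulation is reproducible under a seed and guards instability", {
  p <- membrane_params(noise_sd_mV = 0.3, seed = 11)
  a <- simulate_sweep(p, step_protocol(-20, 200, 500), sweep_ms = 900)
  b <- simulate_sweep(p, step_protocol(-20, 200, 500), sweep_ms = 900)
  expect_identical(a$voltage_mV, b$voltage_mV)
  expect_error(
    simulate_sweep(membrane_params(hump_conductance_nS = 2000),
                   step_protocol(200, 200, 500)),
    "instability")
})

test_that("sampled feature tables honour the spec exactly", {
  spec <- table_preset_spec(seed = 5)
  tab <- sample_feature_table(spec)
  expect_equal(dim(tab), c(33L, 12L))
  expect_equal(as.vector(table(tab$morphology)[c("NGC", "eNGC", "SBC-like")]),
               c(11L, 12L, 10L))
  tab2 <- sample_feature_table(spec)
  expect_identical(tab$values, tab2$values)   # same seed, same table
  # degenerate SDs: every row equals its subtype mean
  ref <- l1in_reference()$intrinsic_by_subtype
  spec0 <- synthetic_dataset_spec(c(NGC = 3, eNGC = 2, "SBC-like" = 2),
                                  ref$mean, matrix(1e-12, 3, 12), seed = 1)
  tab0 <- sample_feature_table(spec0)
  expect_equal(tab0$values[1, ], ref$mean["NGC", ], tolerance = 1e-6)
  expect_error(
    sample_feature_table(synthetic_dataset_spec(
      c(NGC = 3, eNGC = 3, "SBC-like" = 3), ref$mean,
      matrix(1, 3, 12), correlation = -0.5)),
    "positive definite")
})

test_that("sample means of the preset approach the reference summaries", {
  # large-n check that the generator is centred on the reported means
  spec <- table_preset_spec(n_per_subtype = c(NGC = 400, eNGC = 400,
                                              "SBC-like" = 400), seed = 3)
  tab <- sample_feature_table(spec)
  ref <- l1in_reference()$intrinsic_by_subtype
  ngc <- tab$values[tab$morphology == "NGC", ]
  expect_lt(abs(mean(ngc[, "resting_vm_mV"]) - ref$mean["NGC", "resting_vm_mV"]),
            1.5)
  expect_lt(abs(mean(ngc[, "input_resistance_Mohm"]) -
                  ref$mean["NGC", "input_resistance_Mohm"]), 20)
})

test_that("opto dataset generator reproduces group sizes and degenerate SEMs", {
  d <- simulate_opto_dataset(seed = 1)
  expect_equal(nrow(d), 50L)            # 14 + 18 + 12 + 6 cells
  expect_equal(sort(unique(d$group)),
               sort(c("L2/3PyN", "L2/3IN", "L5/6PyN", "L5/6IN")))
  gs <- data.frame(
    group = "G", mean_amp_pA = 100, sem_amp_pA = 1e-12,
    mean_lat_ms = 4, sem_lat_ms = 1e-12, n = 5L)
  d0 <- simulate_opto_dataset(gs, seed = 2)
  expect_equal(d0$amplitude_pA, rep(100, 5), tolerance = 1e-6)
  gs$n <- 1L
  expect_error(simulate_opto_dataset(gs), "n >= 2")
})

test_that("pulse trains have perfect fidelity up to 20 Hz and lose it above", {
  for (f in c(1, 5, 20)) {
    tr <- simulate_pulse_train(f, n_pulses = 7, seed = 1)
    expect_equal(spike_fidelity(tr$spike_times_ms, tr$pulse_times_ms), 1)
  }
  fid <- vapply(c(40, 80), function(f) {
    tr <- simulate_pulse_train(f, n_pulses = 40, seed = 2)
    spike_fidelity(tr$spike_times_ms, tr$pulse_times_ms)
  }, 0)
  expect_true(all(fid < 1))
  expect_lte(fid[2], fid[1])   # non-increasing with frequency
})
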