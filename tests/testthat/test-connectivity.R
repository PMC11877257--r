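test_that("coupling coefficient recovers the planted gap-junction strength", {
  p <- simulate_pair("electrical", coupling = 0.05, stim = "step",
                     noise_sd_mV = 0, seed = 1)
  expect_equal(as.numeric(coupling_coefficient(p)), 0.05, tolerance = 0.02)
  # drive independence (noiseless): -50 vs -100 pA give the same ratio
  p50 <- simulate_pair("electrical", coupling = 0.05, stim = "step",
                       step_pA = -50, noise_sd_mV = 0)
  expect_equal(as.numeric(coupling_coefficient(p50)),
               as.numeric(coupling_coefficient(p)), tolerance = 0.001)
  # unconnected pair: coefficient ~ 0 within noise
  p0 <- simulate_pair("none", stim = "step", seed = 2)
  expect_lt(abs(coupling_coefficient(p0)), 0.005)
})

test_that("electrical detection flags coupled pairs with sub-ms latency", {
  pe <- simulate_pair("electrical", coupling = 0.05, seed = 3)
  de <- detect_electrical(pe)
  expect_true(de$electrical)
  expect_gte(de$latency_ms, 0)
  expect_lt(de$latency_ms, 1.5)
  p0 <- simulate_pair("none", seed = 4)
  expect_false(detect_electrical(p0)$electrical)
  # halving the coupling roughly halves the averaged spikelet
  ph <- simulate_pair("electrical", coupling = 0.025, seed = 3)
  expect_equal(detect_electrical(ph)$peak_mV / de$peak_mV, 0.5,
               tolerance = 0.15)
})

test_that("uIPSC detection recovers amplitude and synaptic latency", {
  pc <- simulate_pair("chemical", gaba_amp_pA = 180, chem_latency_ms = 2.6,
                      seed = 5)
  du <- detect_uipsc(pc)
  expect_true(du$chemical)
  expect_equal(du$amplitude_pA, 180, tolerance = 0.1 * 180)
  expect_equal(du$latency_ms, 2.6, tolerance = 0.2)
  expect_false(detect_uipsc(simulate_pair("none", seed = 6))$chemical)
  expect_error(simulate_pair("chemical", gaba_amp_pA = 0), "gaba_amp_pA")
})

test_that("dual-connected pairs trigger both detectors; latencies are ordered", {
  pb <- simulate_pair("both", coupling = 0.05, gaba_amp_pA = 180, seed = 7)
  de <- detect_electrical(pb)
  du <- detect_uipsc(pb)
  expect_true(de$electrical)
  expect_true(du$chemical)
  expect_lt(de$latency_ms, du$latency_ms)
})

test_that("connectivity map counts directed chemical and undirected electrical", {
  calls <- data.frame(
    cell_a = c("p1a", "p2a", "p3a", "p4a", "p5a", "p6a", "p7a"),
    cell_b = c("p1b", "p2b", "p3b", "p4b", "p5b", "p6b", "p7b"),
    electrical = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    chemical_ab = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    chemical_ba = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  groups <- c(p1a = "G2", p1b = "G3", p2a = "G2", p2b = "G3",
              p3a = "G2", p3b = "G3", p4a = "G2", p4b = "G3",
              p5a = "G2", p5b = "G3", p6a = "G2", p6b = "G3",
              p7a = "G2", p7b = "G3")
  m <- connectivity_map(calls, groups)
  fwd <- m$chemical[m$chemical$from == "G2" & m$chemical$to == "G3", ]
  expect_equal(fwd$tested, 7L)
  expect_equal(fwd$connected, 5L)
  expect_equal(fwd$proportion, 5 / 7)
  rev <- m$chemical[m$chemical$from == "G3" & m$chemical$to == "G2", ]
  expect_equal(rev$connected, 0L)       # direction respected
  # within-group electrical 3/6
  calls2 <- data.frame(cell_a = paste0("e", 1:6, "a"),
                       cell_b = paste0("e", 1:6, "b"),
                       electrical = rep(c(TRUE, FALSE), 3),
                       chemical_ab = FALSE, chemical_ba = FALSE)
  groups2 <- setNames(rep("G2", 12), c(paste0("e", 1:6, "a"),
                                       paste0("e", 1:6, "b")))
  m2 <- connectivity_map(calls2, groups2)
  expect_equal(m2$electrical$proportion, 0.5)
  expect_equal(m2$electrical$tested, 6L)
  empty <- connectivity_map(calls[0, ], groups)
  expect_equal(nrow(empty$electrical), 0L)
  expect_error(connectivity_map(calls, groups[-1]), "without group")
})

test_that("spike fidelity counts pulses followed by spikes", {
  pulses <- seq(0, 600, by = 100)
  expect_equal(spike_fidelity(pulses + 3, pulses), 1)
  expect_equal(spike_fidelity(pulses[c(1, 3, 5, 7)] + 3, pulses), 4 / 7)
  expect_equal(spike_fidelity(c(3, 3.5, 4), pulses), 1 / 7)  # capped per pulse
  expect_error(spike_fidelity(1, numeric(0)), "no pulses")
})

test_that("eIPSC quantification recovers amplitude and latency, flags silence", {
  tr <- simulate_eipsc_trace(372, latency_ms = 4, seed = 8)
  q <- eipsc_quantify(tr)
  expect_true(q$response)
  expect_equal(q$amplitude_pA, 372, tolerance = 0.05 * 372)
  expect_equal(q$latency_ms, 4, tolerance = 0.3)
  flat <- simulate_eipsc_trace(0, seed = 9)
  expect_false(eipsc_quantify(flat)$response)
  # amplitude invariant to a DC offset in the holding current
  tr2 <- tr; tr2$current_pA <- tr2$current_pA + 50
  expect_equal(eipsc_quantify(tr2)$amplitude_pA, q$amplitude_pA,
               tolerance = 1e-9)
})

test_that("pharmacological block comparisons behave like the paired t-test", {
  set.seed(13)
  before <- rnorm(10, 150, 30)
  expect_equal(block_comparison(before, before)$p_value, 1)
  blocked <- before * 0.05 + rnorm(10, 0, 2)
  res <- block_comparison(before, blocked)
  expect_lt(res$p_value, 0.05)
  expect_error(block_comparison(before, blocked[-1]), "equal lengths")
})
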