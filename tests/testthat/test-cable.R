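# Analytic oracles keep the solver honest: exponential charging of an
# isopotential patch, steady-state cosh attenuation of a sealed cylinder,
# and the fixed point at rest.

pp <- passive_params(R_m = 6800, C_m = 1, R_a = 150, E_leak = -86)

test_that("space constant follows sqrt(R_m d / 4 R_a) scaling", {
  expect_equal(space_constant(1.0, 6000, 150), 316.2278, tolerance = 1e-6)
  expect_equal(space_constant(4, 6000, 150) / space_constant(1, 6000, 150), 2)
  expect_error(space_constant(-1, 6000, 150), "positive")
})

test_that("rest is an exact fixed point of the solver", {
  m <- build_cable_model(cylinder_recon(100, n = 101), pp)
  res <- simulate_cable(m, list(), dt = 0.1, T = 1000,
                        probes = c(1, nrow(m$comp)))
  expect_lt(max(abs(res$V - pp$E_leak)), 1e-6)  # < 1 uV drift over 1 s
})

test_that("isopotential charging has tau = R_m * C_m within 1%", {
  m <- isopotential_model(pp)
  tau <- measure_tau(m, comp = 1, dt = 0.01)
  expect_equal(tau, pp$R_m * pp$C_m * 1e-3, tolerance = 0.01)
})

test_that("steady-state attenuation matches the sealed-end cosh profile", {
  L <- 300
  d <- 1
  m <- build_cable_model(cylinder_recon(L, d = d, n = 301), pp)
  nc <- nrow(m$comp)
  res <- simulate_cable(m, list(list(type = "current", comp = nc,
                                     amp_nA = 0.01, t_start = 0,
                                     t_end = 400)),
                        dt = 0.05, T = 400, probes = 2:nc)
  V <- res$V[nrow(res$V), ] - pp$E_leak
  x <- m$comp$x_um[2:nc]
  lam <- space_constant(d, pp$R_m, pp$R_a)
  s <- max(x) - x                    # distance from the injection end
  pred <- cosh((L - s) / lam) / cosh(L / lam)
  expect_lt(max(abs(V / V[length(V)] - pred) / pred), 0.02)
})

test_that("halving dt changes the peak EPSP by < 0.5%", {
  m <- build_cable_model(cylinder_recon(150, n = 151), pp)
  nc <- nrow(m$comp)
  syn <- list(list(type = "synapse", comp = nc, onsets = 5,
                   params = synapse_params(), kind = "AMPA+NMDA"))
  p1 <- max(simulate_cable(m, syn, dt = 0.05, T = 60, probes = nc)$V) -
    pp$E_leak
  p2 <- max(simulate_cable(m, syn, dt = 0.025, T = 60, probes = nc)$V) -
    pp$E_leak
  expect_lt(abs(p1 - p2) / p2, 0.005)
})

test_that("spine correction scales c_m and r_m but not their product", {
  sm <- spine_density_model(1, 35, 8)
  rec <- sample_morphology(species_preset("mouse"), seed = 14)
  m0 <- build_cable_model(rec, pp)
  m2 <- build_cable_model(rec, pp, spine_model = sm, F_spines = 2)
  dend <- m2$comp$seg_id > 0
  plateau <- m2$comp$x_um > 150
  expect_equal(m2$comp$c_m[dend & plateau],
               rep(2, sum(dend & plateau)), tolerance = 1e-3)
  expect_equal(m2$comp$c_m[1], 1)               # soma not corrected
  # tau identity: (R_m / F) * (C_m * F) invariant per compartment
  expect_equal(m2$comp$c_m * m2$comp$r_m, m0$comp$c_m * m0$comp$r_m,
               tolerance = 1e-12)
  # F = 1 leaves everything untouched
  m1 <- build_cable_model(rec, pp, spine_model = sm, F_spines = 1)
  expect_equal(m1$comp$c_m, m0$comp$c_m)
})

test_that("compartment lengths cover the dendrite and respect the cap", {
  rec <- sample_morphology(species_preset("human"), seed = 15)
  m <- build_cable_model(rec, pp)
  dend <- m$comp$seg_id > 0
  expect_equal(sum(m$comp$length_um[dend]),
               spnmorph:::total_dendritic_length(rec), tolerance = 1e-6)
  expect_true(all(m$comp$length_um[dend] <= 10 + 1e-9))
  expect_error(build_cable_model(
    spn_recon(within(rec$nodes, x[2] <- NaN))), "non-finite")
})

test_that("EPSP attenuates monotonically from tip to soma with growing latency", {
  for (sp in c("mouse", "human")) {
    preset <- species_preset(sp)
    rec <- sample_morphology(preset, seed = 11)
    m <- build_cable_model(rec, preset$passive,
                           spine_model = spine_density_model(1, 35, 8))
    syn <- synapse_params(g_ampa_nS = 0.5 * preset$syn_conductance_factor)
    att <- epsp_attenuation(m, syn = syn, T = 120)
    expect_equal(which.max(att$peak_mV), 1L)      # maximal at the synapse
    expect_true(all(diff(att$peak_mV) < 0))
    expect_true(all(diff(att$latency_ms) >= 0))
  }
})

test_that("distributed drive vanishes at low rate and grows with rate", {
  preset <- species_preset("mouse")
  rec <- sample_morphology(preset, seed = 11)
  m <- build_cable_model(rec, preset$passive,
                         spine_model = spine_density_model(1, 35, 8))
  lo <- distributed_drive(m, rate_hz = 0.5, seed = 2, T = 500)
  hi <- distributed_drive(m, rate_hz = 30, seed = 2, T = 500)
  expect_lt(lo$soma_mV, 2)
  expect_gt(hi$soma_mV, lo$soma_mV)
  expect_error(distributed_drive(m, rate_hz = 0), "positive")
})

test_that("clustered drive: local response dominates and NMDA sets the duration", {
  preset <- species_preset("mouse")
  rec <- sample_morphology(preset, seed = 11)
  m <- build_cable_model(rec, preset$passive,
                         spine_model = spine_density_model(1, 35, 8))
  on <- clustered_drive(m, T = 400)
  off <- clustered_drive(m, nmda_on = FALSE, T = 400)
  expect_gte(on$local_peak_mV, on$soma_peak_mV)
  expect_lt(off$plateau_ms, 0.5 * on$plateau_ms)
  expect_gt(on$local_peak_mV, 20)   # tens of millivolts locally
})

test_that("species rescaling transforms geometry as specified", {
  preset <- species_preset("mouse")
  rec <- sample_morphology(preset, seed = 16)
  # identity factors with unchanged soma
  id <- rescale_species(rec, 1, 1)
  expect_equal(id$nodes[c("x", "y", "z", "r")],
               rec$nodes[c("x", "y", "z", "r")])
  up <- rescale_species(rec, 1.7, 2, soma_radius = 8.7)
  segs0 <- partition_segments(rec)
  segs1 <- partition_segments(up)
  # mouse terminal diameter 0.6 -> 1.02
  expect_equal(unique(round(segs1$end_diam_um[segs1$is_terminal], 6)), 1.02)
  # terminal arc lengths doubled, internal segments untouched
  expect_equal(segs1$length_um[segs1$is_terminal],
               2 * segs0$length_um[segs0$is_terminal], tolerance = 1e-9)
  expect_equal(segs1$length_um[!segs1$is_terminal],
               segs0$length_um[!segs0$is_terminal], tolerance = 1e-9)
  expect_equal(up$nodes$r[up$nodes$type == 1L], 8.7)
  expect_error(rescale_species(rec, -1, 1), "positive")
})

test_that("terminal electrotonic lengths are similar across species presets", {
  pm <- species_preset("mouse")
  ph <- species_preset("human")
  com <- generate_cohort(pm, 8, seed = 5, spines = FALSE)
  coh <- generate_cohort(ph, 8, seed = 5, spines = FALSE)
  Lm <- mean(unlist(lapply(com, function(cl)
    electrotonic_summary(cl$recon, pm$passive)$L)))
  Lh <- mean(unlist(lapply(coh, function(cl)
    electrotonic_summary(cl$recon, ph$passive)$L)))
  lm_ <- mean(unlist(lapply(com, function(cl) {
    s <- partition_segments(cl$recon); s$length_um[s$is_terminal]
  })))
  lh_ <- mean(unlist(lapply(coh, function(cl) {
    s <- partition_segments(cl$recon); s$length_um[s$is_terminal]
  })))
  expect_gt(lh_ / lm_, 2)                  # physical lengths very different
  expect_lt(abs(Lh - Lm) / Lm, 0.25)       # electrotonic lengths similar
})

test_that("measured terminal tau is larger in the human preset", {
  pm <- species_preset("mouse")
  ph <- species_preset("human")
  mm <- build_cable_model(sample_morphology(pm, seed = 5), pm$passive)
  mh <- build_cable_model(sample_morphology(ph, seed = 5), ph$passive)
  tm <- spnmorph:::segment_comps(mm, spnmorph:::pick_terminal(mm))
  th <- spnmorph:::segment_comps(mh, spnmorph:::pick_terminal(mh))
  tau_m <- measure_tau(mm, comp = tm[length(tm)], T = 80)
  tau_h <- measure_tau(mh, comp = th[length(th)], T = 200)
  expect_gt(tau_h, tau_m)
})
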