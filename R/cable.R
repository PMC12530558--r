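# Passive branched-cable simulation with AMPA/NMDA synapses.
#
# Units: time ms, voltage mV, capacitance nF, conductance uS, current nA
# (1 nA into 1 nF gives 1 mV/ms). Specific constants keep their
# conventional units: C_m uF/cm^2, R_m Ohm cm^2, R_a Ohm cm; geometry um.

#' Passive membrane parameters
#'
#' @param C_m specific membrane capacitance before spine correction,
#'   uF/cm^2 (default 1).
#' @param R_m specific membrane resistivity, Ohm cm^2. Not an empirically
#'   printed value: a calibration constant of each species preset.
#' @param R_a cytoplasmic (axial) resistivity, Ohm cm (default 150).
#' @param E_leak leak reversal = resting potential, mV (default -86).
#' @param temperature degrees C (default 35; stored, passive dynamics do
#'   not use it).
#' @return List of class `passive_params`.
#' @export
passive_params <- function(C_m = 1, R_m = 6800, R_a = 150, E_leak = -86,
                           temperature = 35) {
  if (C_m <= 0 || R_m <= 0 || R_a <= 0) stop("passive constants must be > 0")
  if (E_leak < -100 || E_leak > 0)
    stop("E_leak outside physiological range [-100, 0] mV")
  structure(list(C_m = C_m, R_m = R_m, R_a = R_a, E_leak = E_leak,
                 temperature = temperature), class = "passive_params")
}

#' Steady-state space constant of a cylindrical cable
#'
#' `lambda = sqrt(R_m * d / (4 * R_a))` for diameter `d`.
#'
#' @param d diameter, um.
#' @param R_m membrane resistivity, Ohm cm^2.
#' @param R_a axial resistivity, Ohm cm.
#' @return Space constant in um.
#' @examples
#' space_constant(1.0, 6000, 150)  # 316.2 um
#' @export
space_constant <- function(d, R_m, R_a) {
  if (any(d <= 0) || R_m <= 0 || R_a <= 0) stop("inputs must be positive")
  1e4 * sqrt(R_m * (d * 1e-4) / (4 * R_a))
}

#' Glutamatergic synapse parameters
#'
#' Dual-exponential AMPA and NMDA conductances with a Jahr-Stevens
#' magnesium block on the NMDA component,
#' `B(V) = 1 / (1 + ([Mg]/K) * exp(-gamma * V))`.
#'
#' @param g_ampa_nS AMPA peak conductance (default 0.5 nS).
#' @param nmda_ratio NMDA:AMPA peak-conductance ratio (default 3).
#' @param tau_ampa rise/decay time constants, ms (default 0.2, 1.7).
#' @param tau_nmda rise/decay time constants, ms (default 2, 100).
#' @param E_syn reversal potential, mV (default 0).
#' @param mg_mM,mg_K_mM,mg_gamma magnesium block parameters
#'   (1 mM, 3.57 mM, 0.062 /mV).
#' @return List of class `synapse_params`.
#' @export
synapse_params <- function(g_ampa_nS = 0.5, nmda_ratio = 3,
                           tau_ampa = c(0.2, 1.7), tau_nmda = c(2, 100),
                           E_syn = 0, mg_mM = 1, mg_K_mM = 3.57,
                           mg_gamma = 0.062) {
  structure(list(g_ampa_nS = g_ampa_nS, nmda_ratio = nmda_ratio,
                 tau_ampa = tau_ampa, tau_nmda = tau_nmda, E_syn = E_syn,
                 mg_mM = mg_mM, mg_K_mM = mg_K_mM, mg_gamma = mg_gamma),
            class = "synapse_params")
}

#' Build a compartmental cable model from a reconstruction
#'
#' Discretises every dendritic segment into compartments no longer than
#' `min(0.1 * lambda_local, max_len_um)`; the soma sphere is one
#' isopotential compartment of area `4 pi r^2`. The spine membrane
#' correction multiplies dendritic `C_m` and divides dendritic `R_m` by
#' `F(x)` at each compartment's midpoint path distance (the soma is not
#' corrected). Optional channel-density profiles (functions of path
#' distance, keyed by mechanism name) are evaluated per compartment and
#' stored for active-model plug-ins; only the passive and synaptic
#' mechanisms are simulated here.
#'
#' @param recon a standardised [spn_recon].
#' @param passive a [passive_params].
#' @param spine_model optional [spine_density_model] for the F(x)
#'   correction.
#' @param F_spines plateau membrane factor used with `spine_model`
#'   (default 2).
#' @param channel_profiles optional named list of functions of path
#'   distance (um) returning conductance densities; stored, not solved.
#' @param max_len_um compartment length cap, um (default 10).
#' @return List of class `cable_model`: `comp` (compartment table),
#'   `passive`, `G` (conductance matrix, uS), `Cvec` (nF),
#'   `gleak` (uS), `soma_comp` (index 1), `channels`.
#' @export
build_cable_model <- function(recon, passive = passive_params(),
                              spine_model = NULL, F_spines = 2,
                              channel_profiles = NULL, max_len_um = 10) {
  nd <- recon$nodes
  if (!all(is.finite(as.matrix(nd[c("x", "y", "z", "r")]))))
    stop("non-finite geometry")
  soma_row <- which(nd$type == 1L)[1]
  soma_r <- nd$r[soma_row]
  segs <- partition_segments(recon)
  soma_rows <- which(nd$type == 1L)
  Fx <- if (is.null(spine_model)) function(x) rep.int(1, length(x))
    else function(x) spine_correction(x, spine_model, F_spines)

  comp <- list()
  # soma compartment
  soma_area <- 4 * pi * (soma_r * 1e-4)^2               # cm^2
  comp[[1]] <- data.frame(id = 1L, parent = NA_integer_, seg_id = 0L,
                          length_um = 2 * soma_r, diam_um = 2 * soma_r,
                          x_um = 0, area_cm2 = soma_area,
                          c_m = passive$C_m, r_m = passive$R_m,
                          r_axial_half = 0, is_terminal_tip = FALSE)
  next_id <- 1L
  last_comp_of_seg <- integer(NROW(segs))
  for (i in seq_len(NROW(segs))) {
    p <- segs$path[[i]]
    geo <- if (p[1] %in% soma_rows) p[-1] else p
    L <- segs$length_um[i]
    dbar <- segs$mean_diam_um[i]
    lam <- space_constant(max(dbar, 1e-3), passive$R_m, passive$R_a)
    h_max <- min(0.1 * lam, max_len_um)
    ncomp <- max(1L, ceiling(L / h_max))
    h <- L / ncomp
    s <- path_cumlen(nd, geo)
    dia <- 2 * nd$r[geo]
    parent_comp <- if (is.na(segs$parent_seg[i])) 1L
      else last_comp_of_seg[segs$parent_seg[i]]
    if (L < 1e-6) {
      # zero-length stub: no cable, daughters attach to the parent
      last_comp_of_seg[i] <- parent_comp
      next
    }
    for (k in seq_len(ncomp)) {
      mid <- (k - 0.5) * h
      dmid <- if (length(geo) > 1L)
        stats::approx(s, dia, xout = mid, rule = 2)$y else dia[1]
      x_mid <- segs$base_dist_um[i] + mid
      f <- Fx(x_mid)
      next_id <- next_id + 1L
      comp[[next_id]] <- data.frame(
        id = next_id, parent = parent_comp, seg_id = i,
        length_um = h, diam_um = dmid, x_um = x_mid,
        area_cm2 = pi * (dmid * 1e-4) * (h * 1e-4),
        c_m = passive$C_m * f, r_m = passive$R_m / f,
        r_axial_half = passive$R_a * (h / 2 * 1e-4) /
          (pi * (dmid / 2 * 1e-4)^2),
        is_terminal_tip = segs$is_terminal[i] && k == ncomp)
      parent_comp <- next_id
    }
    last_comp_of_seg[i] <- next_id
  }
  comp <- do.call(rbind, comp)
  n <- nrow(comp)
  gleak <- comp$area_cm2 / comp$r_m * 1e6                 # uS
  Cvec <- comp$c_m * comp$area_cm2 * 1e3                  # nF
  G <- matrix(0, n, n)
  for (i in 2:n) {
    p <- comp$parent[i]
    raxial <- comp$r_axial_half[i] + comp$r_axial_half[p] # Ohm
    g <- 1e6 / raxial                                     # uS
    G[i, p] <- G[i, p] - g
    G[p, i] <- G[p, i] - g
    G[i, i] <- G[i, i] + g
    G[p, p] <- G[p, p] + g
  }
  diag(G) <- diag(G) + gleak
  channels <- NULL
  if (!is.null(channel_profiles))
    channels <- lapply(channel_profiles, function(f) f(comp$x_um))
  structure(list(comp = comp, passive = passive, G = G, Cvec = Cvec,
                 gleak = gleak, soma_comp = 1L, segments = segs,
                 channels = channels),
            class = "cable_model")
}

#' Single-compartment (isopotential) cable model
#'
#' A membrane patch with no axial structure, useful as an analytic
#' reference: its step response charges exponentially with
#' `tau = R_m * C_m`.
#'
#' @param passive a [passive_params].
#' @param area_cm2 membrane area (default `1e-4` cm^2).
#' @return A [build_cable_model]-compatible `cable_model` with one
#'   compartment.
#' @export
isopotential_model <- function(passive = passive_params(),
                               area_cm2 = 1e-4) {
  comp <- data.frame(id = 1L, parent = NA_integer_, seg_id = 0L,
                     length_um = NA_real_, diam_um = NA_real_, x_um = 0,
                     area_cm2 = area_cm2, c_m = passive$C_m,
                     r_m = passive$R_m, r_axial_half = 0,
                     is_terminal_tip = FALSE)
  gleak <- area_cm2 / passive$R_m * 1e6
  structure(list(comp = comp, passive = passive,
                 G = matrix(gleak, 1, 1), Cvec = passive$C_m * area_cm2 * 1e3,
                 gleak = gleak, soma_comp = 1L,
                 segments = NULL, channels = NULL),
            class = "cable_model")
}

#' @export
print.cable_model <- function(x, ...) {
  cat("<cable_model> ", nrow(x$comp), " compartments (",
      sum(x$comp$seg_id > 0), " dendritic), E_leak ",
      x$passive$E_leak, " mV\n", sep = "")
  invisible(x)
}

# dual-exponential normalisation so the kernel peaks at 1
dualexp_norm <- function(tau_r, tau_d) {
  tp <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  1 / (exp(-tp / tau_d) - exp(-tp / tau_r))
}

#' Simulate a passive cable model
#'
#' Backward-Euler integration of the discretised cable equation. The
#' passive and axial terms are implicit (the system matrix is factorised
#' once); synaptic and injected currents enter explicitly at the previous
#' voltage. With zero stimulus the resting state `E_leak` is an exact
#' fixed point.
#'
#' @param model a [build_cable_model] model.
#' @param stimuli list of stimulus descriptors:
#'   `list(type = "current", comp, amp_nA, t_start, t_end)` or
#'   `list(type = "synapse", comp, onsets, params, kind)` with `params` a
#'   [synapse_params] and `kind` one of `"AMPA"`, `"NMDA"`,
#'   `"AMPA+NMDA"`.
#' @param dt time step, ms (default 0.025).
#' @param T total simulated time, ms.
#' @param probes compartment indices to record (default: soma).
#' @return List with `time` (ms) and `V` (matrix, time by probes, mV).
#' @export
simulate_cable <- function(model, stimuli = list(), dt = 0.025, T = 100,
                           probes = model$soma_comp) {
  if (dt <= 0) stop("dt must be positive")
  n <- nrow(model$comp)
  A <- diag(model$Cvec / dt, n) + model$G
  Ainv <- solve(A)
  E <- model$passive$E_leak
  leak_term <- model$gleak * E
  nt <- ceiling(T / dt) + 1L
  # preprocess stimuli
  cur <- Filter(function(s) s$type == "current", stimuli)
  syn <- Filter(function(s) s$type == "synapse", stimuli)
  syn_state <- lapply(syn, function(s) {
    onset_steps <- pmax(1L, as.integer(round(s$onsets / dt)) + 1L)
    p <- s$params
    list(comp = s$comp, onsets = onset_steps,
         kind = if (is.null(s$kind)) "AMPA+NMDA" else s$kind,
         p = p,
         norm_a = dualexp_norm(p$tau_ampa[1], p$tau_ampa[2]),
         norm_n = dualexp_norm(p$tau_nmda[1], p$tau_nmda[2]),
         dec_ar = exp(-dt / p$tau_ampa[1]), dec_ad = exp(-dt / p$tau_ampa[2]),
         dec_nr = exp(-dt / p$tau_nmda[1]), dec_nd = exp(-dt / p$tau_nmda[2]),
         a_r = 0, a_d = 0, n_r = 0, n_d = 0)
  })
  V <- rep.int(E, n)
  out <- matrix(NA_real_, nt, length(probes))
  out[1, ] <- V[probes]
  tvec <- (seq_len(nt) - 1L) * dt
  for (step in 2:nt) {
    t_now <- tvec[step - 1L]
    b <- model$Cvec / dt * V + leak_term
    for (s in cur)
      if (t_now >= s$t_start && t_now < s$t_end)
        b[s$comp] <- b[s$comp] + s$amp_nA
    if (length(syn_state)) {
      for (k in seq_along(syn_state)) {
        st <- syn_state[[k]]
        # advance dual-exp states, add impulses due this step
        imp <- sum(st$onsets == step - 1L)
        st$a_r <- st$a_r * st$dec_ar + imp
        st$a_d <- st$a_d * st$dec_ad + imp
        st$n_r <- st$n_r * st$dec_nr + imp
        st$n_d <- st$n_d * st$dec_nd + imp
        syn_state[[k]] <- st
        p <- st$p
        g_a <- if (st$kind %in% c("AMPA", "AMPA+NMDA"))
          p$g_ampa_nS * st$norm_a * (st$a_d - st$a_r) / 1e3 else 0  # uS
        g_n <- if (st$kind %in% c("NMDA", "AMPA+NMDA"))
          p$g_ampa_nS * p$nmda_ratio * st$norm_n * (st$n_d - st$n_r) / 1e3
          else 0
        vloc <- V[st$comp]
        block <- 1 / (1 + (p$mg_mM / p$mg_K_mM) * exp(-p$mg_gamma * vloc))
        b[st$comp] <- b[st$comp] +
          (g_a + g_n * block) * (p$E_syn - vloc)
      }
    }
    V <- drop(Ainv %*% b)
    if (!all(is.finite(V)))
      stop("solver instability: non-finite voltage at t = ", t_now, " ms")
    out[step, ] <- V[probes]
  }
  list(time = tvec, V = out)
}

#' Membrane time constant at a location
#'
#' Applies a brief (0.5 ms) small current pulse at the given compartment
#' and fits a single exponential to the local voltage decay.
#'
#' @param model a [build_cable_model] model.
#' @param comp compartment index (default: soma).
#' @param amp_nA pulse amplitude (default 0.02).
#' @param dt time step, ms.
#' @param T run length, ms (default `5 * R_m * C_m` in ms).
#' @return Fitted decay time constant, ms.
#' @export
measure_tau <- function(model, comp = model$soma_comp, amp_nA = 0.02,
                        dt = 0.025, T = NULL) {
  tau_nominal <- model$passive$R_m * model$passive$C_m * 1e-3
  if (is.null(T)) T <- 5 * tau_nominal + 5
  res <- simulate_cable(model,
                        list(list(type = "current", comp = comp,
                                  amp_nA = amp_nA, t_start = 1,
                                  t_end = 1.5)),
                        dt = dt, T = T, probes = comp)
  dv <- res$V[, 1] - model$passive$E_leak
  pk <- which.max(dv)
  if (dv[pk] <= 0) stop("no depolarisation measured")
  # fit the late tail: after a local pulse the early decay is dominated by
  # charge redistribution along the tree; the slowest (membrane) mode is
  # reached once the transient has fallen well below its peak
  sel <- which(res$time > res$time[pk] + 0.5 & dv > 0.005 * dv[pk] &
                 dv < 0.05 * dv[pk])
  if (length(sel) < 5) stop("decay too short to fit")
  fit <- stats::lm(log(dv[sel]) ~ res$time[sel])
  tau <- -1 / unname(stats::coef(fit)[2])
  if (tau <= 0) stop("non-monotone decay: model not passive?")
  tau
}

# compartments of one segment, ordered proximal -> distal
segment_comps <- function(model, seg_id) {
  which(model$comp$seg_id == seg_id)
}

# pick a terminal segment; longest by default
pick_terminal <- function(model, seg_id = NULL) {
  segs <- model$segments
  term <- which(segs$is_terminal)
  if (is.null(seg_id))
    seg_id <- term[which.max(segs$length_um[term])]
  if (!segs$is_terminal[seg_id]) stop("segment ", seg_id, " is not terminal")
  seg_id
}

#' EPSP attenuation along a terminal dendrite
#'
#' Stimulates an AMPA+NMDA synapse at the tip of a terminal segment and
#' reports the peak depolarisation and its latency at probes spaced along
#' the terminal and at the soma.
#'
#' @param model a [build_cable_model] model.
#' @param seg_id terminal segment id (default: longest terminal).
#' @param syn a [synapse_params].
#' @param n_probes probes along the terminal, tip to base (default 5).
#' @param dt,T solver settings.
#' @return Data frame: `probe` (1 = tip, then toward soma; last row is
#'   the soma), `x_um` (path distance), `peak_mV` (peak depolarisation
#'   above rest), `latency_ms`.
#' @export
epsp_attenuation <- function(model, seg_id = NULL, syn = synapse_params(),
                             n_probes = 5, dt = 0.025, T = 150) {
  seg_id <- pick_terminal(model, seg_id)
  comps <- segment_comps(model, seg_id)
  tip <- comps[length(comps)]
  idx <- unique(round(seq(length(comps), 1, length.out = n_probes)))
  probes <- c(comps[idx], model$soma_comp)
  res <- simulate_cable(model,
                        list(list(type = "synapse", comp = tip, onsets = 10,
                                  params = syn, kind = "AMPA+NMDA")),
                        dt = dt, T = T, probes = probes)
  dv <- sweep(res$V, 2, res$V[1, ])
  pk <- apply(dv, 2, which.max)
  data.frame(probe = seq_along(probes),
             comp = probes,
             x_um = model$comp$x_um[probes],
             peak_mV = dv[cbind(pk, seq_along(probes))],
             latency_ms = res$time[pk] - 10)
}

#' Distributed asynchronous synaptic drive
#'
#' Places `n_synapses` AMPA+NMDA synapses at uniform arc spacing along a
#' terminal segment, drives each with an independent Poisson onset train,
#' and reports the time-averaged depolarisation (over the last 80% of the
#' run) at the middle of the segment and at the soma.
#'
#' @param model a [build_cable_model] model.
#' @param seg_id terminal segment id (default: longest terminal).
#' @param n_synapses number of synapses (default 10).
#' @param rate_hz Poisson rate per synapse, Hz (5-30 in the standard
#'   protocol).
#' @param seed integer seed for the onset trains.
#' @param syn a [synapse_params].
#' @param dt time step, ms.
#' @param T run length, ms (default 2000).
#' @return List: `mid_mV` and `soma_mV` (mean depolarisation above rest),
#'   `rate_hz`, `n_synapses`.
#' @export
distributed_drive <- function(model, seg_id = NULL, n_synapses = 10,
                              rate_hz = 10, seed = 1,
                              syn = synapse_params(), dt = 0.05, T = 2000) {
  if (rate_hz <= 0) stop("rate must be positive")
  seg_id <- pick_terminal(model, seg_id)
  comps <- segment_comps(model, seg_id)
  if (!length(comps)) stop("terminal segment has no compartments")
  pos <- comps[unique(round(seq(1, length(comps),
                                length.out = n_synapses)))]
  pos <- rep_len(pos, n_synapses)
  set.seed(seed)
  stim <- lapply(seq_len(n_synapses), function(i) {
    nev <- stats::rpois(1, rate_hz * T / 1000)
    list(type = "synapse", comp = pos[i],
         onsets = sort(stats::runif(nev, 0, T)), params = syn,
         kind = "AMPA+NMDA")
  })
  mid <- comps[ceiling(length(comps) / 2)]
  res <- simulate_cable(model, stim, dt = dt, T = T,
                        probes = c(mid, model$soma_comp))
  sel <- res$time >= 0.2 * T
  E <- model$passive$E_leak
  list(mid_mV = mean(res$V[sel, 1]) - E,
       soma_mV = mean(res$V[sel, 2]) - E,
       rate_hz = rate_hz, n_synapses = n_synapses)
}

#' Clustered synchronous synaptic drive (NMDA plateau protocol)
#'
#' Places `n_synapses` AMPA+NMDA synapses in the middle of a terminal
#' segment and activates them in sequence at `isi` intervals. The
#' voltage-dependent NMDA conductance sustains a local plateau; with
#' `nmda_on = FALSE` the response collapses to the brief AMPA transient.
#'
#' @param model a [build_cable_model] model.
#' @param seg_id terminal segment id (default: longest terminal).
#' @param n_synapses number of clustered synapses (default 10).
#' @param isi inter-activation interval, ms (default 1).
#' @param nmda_on include the NMDA component (default `TRUE`).
#' @param syn a [synapse_params].
#' @param dt,T solver settings (default 0.025 ms, 500 ms).
#' @return List: `time`, `local_mV`, `soma_mV` (traces), `local_peak_mV`,
#'   `soma_peak_mV` (above rest), `plateau_ms` (time the local response
#'   stays above half its peak).
#' @export
clustered_drive <- function(model, seg_id = NULL, n_synapses = 10, isi = 1,
                            nmda_on = TRUE, syn = synapse_params(),
                            dt = 0.025, T = 500) {
  seg_id <- pick_terminal(model, seg_id)
  comps <- segment_comps(model, seg_id)
  mid <- comps[ceiling(length(comps) / 2)]
  t0 <- 10
  kind <- if (nmda_on) "AMPA+NMDA" else "AMPA"
  stim <- lapply(seq_len(n_synapses), function(i)
    list(type = "synapse", comp = mid, onsets = t0 + (i - 1) * isi,
         params = syn, kind = kind))
  res <- simulate_cable(model, stim, dt = dt, T = T,
                        probes = c(mid, model$soma_comp))
  E <- model$passive$E_leak
  local <- res$V[, 1] - E
  soma <- res$V[, 2] - E
  pk <- max(local)
  plateau <- sum(local > pk / 2) * dt
  list(time = res$time, local_mV = local, soma_mV = soma,
       local_peak_mV = pk, soma_peak_mV = max(soma), plateau_ms = plateau)
}

#' Rescale a reconstruction between species dimensions
#'
#' Multiplies all dendritic diameters by `diam_factor`, stretches every
#' terminal segment along its own arc about its base node by
#' `terminal_length_factor` (branch points stay fixed) and replaces the
#' soma radius. The standard cross-species swap is mouse-to-human
#' `(1.7, 2)` and human-to-mouse `(0.6, 0.5)`.
#'
#' @param recon a standardised [spn_recon].
#' @param diam_factor dendritic diameter factor (> 0).
#' @param terminal_length_factor terminal arc-length factor (> 0).
#' @param soma_radius new soma radius, um (default: keep).
#' @return The rescaled [spn_recon].
#' @export
rescale_species <- function(recon, diam_factor, terminal_length_factor,
                            soma_radius = NULL) {
  if (diam_factor <= 0 || terminal_length_factor <= 0)
    stop("factors must be positive")
  nd <- recon$nodes
  dend <- nd$type != 1L
  nd$r[dend] <- nd$r[dend] * diam_factor
  segs <- partition_segments(recon)
  soma_rows <- which(nd$type == 1L)
  for (i in which(segs$is_terminal)) {
    p <- segs$path[[i]]
    geo <- if (p[1] %in% soma_rows) p[-1] else p
    if (length(geo) < 2L) next
    base <- geo[1]
    rest <- geo[-1]
    nd$x[rest] <- nd$x[base] + (nd$x[rest] - nd$x[base]) *
      terminal_length_factor
    nd$y[rest] <- nd$y[base] + (nd$y[rest] - nd$y[base]) *
      terminal_length_factor
    nd$z[rest] <- nd$z[base] + (nd$z[rest] - nd$z[base]) *
      terminal_length_factor
  }
  if (!is.null(soma_radius)) nd$r[soma_rows] <- soma_radius
  structure(list(nodes = nd,
                 provenance = c(recon$provenance,
                                sprintf("rescaled: diam x%.2f, terminal x%.2f",
                                        diam_factor, terminal_length_factor))),
            class = "spn_recon")
}

#' Electrotonic summary of terminal segments
#'
#' For every terminal segment: physical length `l`, mean diameter, space
#' constant `lambda` and electrotonic length `L = l / lambda`.
#'
#' @param recon a standardised [spn_recon] (or a [cable_model]).
#' @param passive a [passive_params].
#' @return Data frame: `seg_id`, `length_um`, `diam_um`, `lambda_um`,
#'   `L`.
#' @export
electrotonic_summary <- function(recon, passive = passive_params()) {
  segs <- if (inherits(recon, "cable_model")) recon$segments
    else partition_segments(recon)
  term <- segs[segs$is_terminal, , drop = FALSE]
  lam <- space_constant(pmax(term$mean_diam_um, 1e-3), passive$R_m,
                        passive$R_a)
  data.frame(seg_id = term$seg_id, length_um = term$length_um,
             diam_um = term$mean_diam_um, lambda_um = lam,
             L = term$length_um / lam)
}
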