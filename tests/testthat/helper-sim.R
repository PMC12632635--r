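# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept at desk scale (a few runs, a few hundred trials).

# A session-2-like scanning schedule scaled for simulation tests:
# `n_blocks` alternating 0/90 state-blocks of `n_miniblocks` mini-blocks
# over `n_runs` runs.
sim_schedule <- function(seed, n_blocks = 8, n_miniblocks = 6,
                         n_runs = min(4, n_blocks),
                         config = task_config()) {
  gridshift:::make_schedule(rep(c(0, 90), n_blocks / 2), n_miniblocks,
                            config, seed = seed, n_runs = n_runs)
}

# Behavior + planted-modulation BOLD for one simulated subject.
sim_subject <- function(seed, regime = "cognitive", grid_phi = 10,
                        amplitude = 1, noise_sd = 1, n_blocks = 8,
                        n_miniblocks = 6, n_runs = min(4, n_blocks),
                        n_voxels = 1, agent = "transfer_learner", ...) {
  config <- task_config()
  seeds <- gridshift:::derive_seeds(seed, 3)
  sched <- sim_schedule(seeds[1], n_blocks, n_miniblocks, n_runs, config)
  beh <- simulate_agent(sched, agent, config, seed = seeds[2])
  sim <- bold_sim_config(n_voxels = n_voxels, regime = regime,
                         grid_phi = grid_phi, grid_amplitude = amplitude,
                         noise_sd = noise_sd, ...)
  bold <- simulate_bold(beh, sim, seed = seeds[3])
  list(behavior = beh, bold = bold, sim = sim, config = config)
}

# A tiny behavioral dataset with hand-set geometry: one color, targets on
# the x axis (current) and y axis (alternate), response at a chosen angle.
toy_trial <- function(resp_angle_deg, radius = 100) {
  list(response = radius * c(cos(resp_angle_deg * pi / 180),
                             sin(resp_angle_deg * pi / 180)),
       curr = c(100, 0), alt = c(0, 100))
}

# Smoothed Gaussian-null subject maps for permutation tests.
null_subject_maps <- function(n_subj, dims, fwhm = 3, seed = NULL) {
  gridshift:::with_seed(seed, {
    t(vapply(seq_len(n_subj),
             function(i) smooth_volume(rnorm(prod(dims)), dims, fwhm),
             numeric(prod(dims))))
  })
}
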