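# Shared fixtures. The heavy end-to-end study runs are computed once per
# test session and cached, so several test files can probe the same
# trained networks.

tiny_view <- function() view_params(width = 64, height = 16)

uniform_registry <- function() texture_registry(cycle = FALSE)

# short rendered sequence in a small box for module-level tests
test_frames <- function(n_steps = 600, seed = 3, box = c(8, 8)) {
  plan <- make_box(box[1], box[2])
  traj <- generate_trajectory(plan, motion_params(), n_steps = n_steps,
                              seed = seed)
  list(plan = plan, traj = traj,
       frames = render_frames(plan, traj, tiny_view()))
}

study_cache <- new.env(parent = emptyenv())

# the scaled open-field study: 20,000-step random walk in a 10 x 10 box,
# reduced architecture with ICA, place maps on a 0.5-unit grid
study_run_open <- function() {
  if (!is.null(study_cache$open)) return(study_cache$open)
  plan <- make_box(10, 10)
  view <- tiny_view()
  traj <- generate_trajectory(plan, motion_params(), n_steps = 20000,
                              seed = 42)
  frames <- render_frames(plan, traj, view)
  net <- train(reduced_architecture(), frames, batch_size = 5000,
               with_ica = TRUE, noise_sigma = 1e-4, seed = 42)
  maps <- sample_place(net, plan, view, spacing = 0.5, margin = 0.2)
  study_cache$open <- list(plan = plan, view = view, net = net, maps = maps)
  study_cache$open
}

# stereotyped corridor running along a 2-waypoint loop in a 12 x 2 box
study_run_corridor <- function() {
  if (!is.null(study_cache$corridor)) return(study_cache$corridor)
  plan <- make_box(12, 2)
  view <- tiny_view()
  pth <- make_path(rbind(c(1, 1), c(11, 1)), loop = TRUE)
  traj <- generate_trajectory(plan, motion_params(path_noise = 0.3),
                              n_steps = 10000, mode = "path", path = pth,
                              seed = 43)
  frames <- render_frames(plan, traj, view)
  net <- train(reduced_architecture(), frames, batch_size = 5000,
               with_ica = TRUE, noise_sigma = 1e-4, seed = 43)
  maps <- sample_place(net, plan, view, spacing = 0.5, margin = 0.2)
  study_cache$corridor <- list(plan = plan, view = view, net = net, maps = maps)
  study_cache$corridor
}
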