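# Shared fixtures: tiny seeded datasets generated in temp dirs at test time.

tiny_two_class_tree <- function(n_major = 12, n_minor = 12, seed = 7,
                                size = c(32L, 32L), noise_sd = 4) {
  dir <- tempfile("cyto_fix_")
  generate_dataset(two_class_specs(n_major, n_minor, noise_sd = noise_sd),
                   seed = seed, size = size, out_dir = dir)
}

tiny_run_config <- function(...) {
  cfg <- default_config()
  cfg$data$image_size <- c(32L, 32L)
  cfg$training$stage1_epochs <- 4L
  cfg$training$stage2_epochs <- 4L
  cfg$training$batch_size <- 16L
  utils::modifyList(cfg, list(...))
}
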