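# Run configuration: one structured list covering every module, strict
# validation (unknown keys and out-of-range values fail fast, naming the
# offending key), YAML round-trip.

#' Default run configuration
#'
#' The defaults describe the desk-scale profile: 32 x 32 greyscale inputs, a
#' three-stage backbone, a depth-2 transformer and a depth-3 supporter
#' stack.  `preproc_config()`'s 244 x 244 default applies to standalone
#' preprocessing; the training profile sets its own `data$image_size`.
#' @return a nested configuration list (class `cyto_config`)
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    out_dir = NULL,
    data = list(
      image_size = c(32L, 32L),
      normalize = TRUE,
      augment = list(rotation_max_deg = 20, hflip = TRUE, vflip = TRUE,
                     zoom = c(0.9, 1.1), shift = 0.1)),
    backbone = list(
      stages = list(
        list(type = "fused_mbconv", repeats = 1L, channels = 8L,
             stride = 2L, expansion = 2),
        list(type = "fused_mbconv", repeats = 1L, channels = 16L,
             stride = 2L, expansion = 2),
        list(type = "mbconv", repeats = 1L, channels = 16L, stride = 1L,
             expansion = 2)),
      supporter_insertion = FALSE),
    vit = list(P = 2L, d = 16L, heads = 2L, depth = 2L, ffn = 32L),
    supporter = list(depth = 3L, kernel = 3L, lstm_hidden = 8L,
                     attn_dim = 16L, seq_pool = 2L),
    rl = list(gamma = 0.9, alpha = 1e-3, eps_start = 1.0, eps_end = 0.05,
              eps_decay_frac = 0.5, beta = 1.2, w_min = 0.25, w_max = 4.0,
              replay_capacity = 2048L, batch_size = 32L, sync_period = 100L,
              hidden = 24L, minority = NULL,
              reward_minority_correct = 1.0, reward_minority_wrong = -1.0,
              reward_majority_correct = 0.1, reward_majority_wrong = 0.0),
    training = list(stage1_epochs = 60L, stage2_epochs = 20L,
                    batch_size = 16L, lr_stage1 = 1e-3, lr_stage2 = 1e-4,
                    augment_train = TRUE),
    evaluation = list(alpha = 0.05)),
    class = "cyto_config")
}

.cfg_check <- function(ok, key, msg) {
  if (!ok) stop("invalid config value at `", key, "`: ", msg, call. = FALSE)
}

#' Validate a configuration (strict)
#'
#' Unknown keys in any section are rejected; numeric constraints are checked
#' per module; error messages name the offending key (e.g. `rl.gamma`).
#' @param cfg configuration list
#' @return the validated config, invisibly
#' @export
validate_config <- function(cfg) {
  ref <- default_config()
  chk_keys <- function(x, refx, prefix) {
    extra <- setdiff(names(x), names(refx))
    if (length(extra))
      stop("unknown config key `", paste0(prefix, extra[1]), "`",
           call. = FALSE)
  }
  chk_keys(cfg, ref, "")
  for (sec in c("data", "vit", "supporter", "rl", "training", "evaluation"))
    chk_keys(cfg[[sec]], ref[[sec]], paste0(sec, "."))
  .cfg_check(length(cfg$data$image_size) == 2 && all(cfg$data$image_size >= 16),
             "data.image_size", "need two integers >= 16")
  .cfg_check(cfg$vit$d %% cfg$vit$heads == 0, "vit.heads",
             "d must be divisible by heads")
  .cfg_check(cfg$vit$P >= 1, "vit.P", "must be >= 1")
  rl <- cfg$rl
  .cfg_check(rl$gamma >= 0 && rl$gamma < 1, "rl.gamma", "must be in [0, 1)")
  .cfg_check(rl$alpha > 0, "rl.alpha", "must be > 0")
  .cfg_check(rl$eps_start >= 0 && rl$eps_start <= 1, "rl.eps_start",
             "must be in [0, 1]")
  .cfg_check(rl$eps_end >= 0 && rl$eps_end <= rl$eps_start, "rl.eps_end",
             "must be in [0, eps_start]")
  .cfg_check(rl$beta > 1, "rl.beta", "must be > 1")
  .cfg_check(rl$w_min > 0 && rl$w_min < 1 && rl$w_max > 1, "rl.w_min",
             "need 0 < w_min < 1 < w_max")
  .cfg_check(rl$replay_capacity >= rl$batch_size, "rl.replay_capacity",
             "must be >= rl.batch_size")
  .cfg_check(rl$reward_minority_correct > rl$reward_majority_correct &&
               rl$reward_majority_correct > 0 &&
               rl$reward_minority_wrong < 0, "rl.reward_minority_correct",
             "need minority_correct > majority_correct > 0 > minority_wrong")
  tr <- cfg$training
  .cfg_check(tr$stage1_epochs >= 1 && tr$stage2_epochs >= 0,
             "training.stage1_epochs", "epochs must be positive")
  .cfg_check(tr$batch_size >= 2, "training.batch_size", "must be >= 2")
  .cfg_check(cfg$evaluation$alpha > 0 && cfg$evaluation$alpha < 1,
             "evaluation.alpha", "must be in (0, 1)")
  invisible(cfg)
}

#' Load a YAML configuration, fill defaults, validate
#'
#' @param path YAML file; keys not present fall back to [default_config()]
#' @return validated `cyto_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user %||% list())
  if (!is.null(user$data$image_size))
    cfg$data$image_size <- as.integer(user$data$image_size)
  cfg <- structure(cfg, class = "cyto_config")
  validate_config(cfg)
  cfg
}

#' Write a configuration to YAML (round-trips through [load_config()])
#' @param cfg configuration list
#' @param path output file
#' @return `path`, invisibly
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
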