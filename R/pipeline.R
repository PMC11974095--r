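#' Default run configuration
#'
#' Flat key-value configuration for the end-to-end pipeline with every
#' default: copy number cap, action value range, trajectory length cap,
#' training hyperparameters, and stage seeds.
#' @return named list.
#' @export
default_config <- function() {
  list(c_max = 19L, vmax = 5L, max_len = 40L,
       iters = 2000L, batch_size = 32L, lr = 1e-3,
       epsilon_start = 0.5, epsilon_end = 0.1,
       embed_dim = 500L, n_conv = 10L,
       seed_simulator = 1L, seed_trainer = 1L, seed_bootstrap = 1L)
}

## Tiny stable config hash (polynomial rolling hash over the serialised
## key=value text); good enough for provenance strings, not cryptographic.
config_hash <- function(config) {
  txt <- paste(names(config),
               vapply(config, function(v) paste(format(v), collapse = ","),
                      character(1)),
               sep = "=", collapse = ";")
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2^32
  sprintf("%08x", h)
}

#' Run the full pipeline on an observation directory
#'
#' Stages: read and validate observations, initial per-cell calling,
#' policy training, final assignment, clone summary; writes `profiles.tsv`,
#' `scaling.tsv`, `clones.tsv`, a training log, and a manifest with the
#' configuration and its hash. Any stage failure halts with the stage name.
#'
#' @param input_dir directory of observation TSVs (see
#'   [read_observations()]).
#' @param out_dir output directory.
#' @param config configuration list (see [default_config()]); missing
#'   entries take defaults.
#' @return invisibly, the `evocn_calls` object.
#' @export
run_pipeline <- function(input_dir, out_dir, config = list()) {
  config <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  obs <- stage("io", validate_observations(input_dir))
  naive <- stage("call-naive", call_naive(obs, c_max = config$c_max))
  state <- stage("train", rl_train(
    obs, naive, iters = config$iters, batch_size = config$batch_size,
    lr = config$lr, epsilon_start = config$epsilon_start,
    epsilon_end = config$epsilon_end, max_len = config$max_len,
    seed = config$seed_trainer, embed_dim = config$embed_dim,
    n_conv = config$n_conv))
  calls <- stage("infer", assign_profiles(state))
  clones <- summarize_clones(calls)
  write_profiles(calls$profiles, obs$segments, obs$cell_ids,
                 file.path(out_dir, "profiles.tsv"))
  utils::write.table(data.frame(cell_id = obs$cell_ids,
                                scaling = signif(naive$scaling, 8)),
                     file.path(out_dir, "scaling.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(clones$table, file.path(out_dir, "clones.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(state$log, file.path(out_dir, "training_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(config, list(config_hash = config_hash(config),
                             n_cells = n_cells(obs),
                             n_segments = n_segments(obs$segments),
                             n_unique_profiles = calls$n_unique))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(calls)
}

#' Simulate, call, train, infer, and score one instance
#'
#' End-to-end driver on simulated ground truth; the workhorse behind the
#' simulation studies. Returns bin-weighted accuracy and L1 error of both
#' the initial caller and the trained pipeline, plus unique-profile counts.
#'
#' @param config an [sim_config()].
#' @param seed seed for the simulator; `seed + 1` seeds training.
#' @param iters,batch_size,embed_dim,n_conv,max_len training size knobs
#'   (reduced-budget defaults; see [rl_train()] for the full-scale ones).
#' @return list with `accuracy`, `l1_error`, `naive_accuracy`,
#'   `naive_l1_error`, `n_unique_pred`, `n_unique_true`, `calls`, `truth`,
#'   `segments`.
#' @export
run_sim_instance <- function(config, seed = 1L, iters = 200L,
                             batch_size = 8L, embed_dim = 192L,
                             n_conv = 6L, max_len = 40L) {
  sim <- simulate_dataset(config, seed = seed)
  naive <- call_naive(sim$obs, c_max = config$c_max)
  state <- rl_train(sim$obs, naive, iters = iters, batch_size = batch_size,
                    max_len = max_len, seed = seed + 1L,
                    embed_dim = embed_dim, n_conv = n_conv)
  calls <- assign_profiles(state)
  w <- sim$segments$n_bins
  list(accuracy = cn_accuracy(calls$profiles, sim$truth$profiles, w),
       l1_error = cn_l1_error(calls$profiles, sim$truth$profiles, w),
       naive_accuracy = cn_accuracy(naive$profiles, sim$truth$profiles, w),
       naive_l1_error = cn_l1_error(naive$profiles, sim$truth$profiles, w),
       n_unique_pred = calls$n_unique,
       n_unique_true = sim$truth$n_unique_profiles,
       calls = calls, truth = sim$truth, segments = sim$segments)
}
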