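# Shared fixtures, generated in code.

absent_pose <- function() person_pose(posture = "absent")

# one empty frame of a scene (noiseless unless the spec says otherwise)
render_empty_frame <- function(spec, seed = 1) {
  render_sequence(spec, action_script(0L, 1, list(absent_pose())),
                  seed = seed)
}

# precision / recall / IoU of a predicted label against ground truth
mask_scores <- function(pred, gt, label) {
  tp <- sum(pred == label & gt == label)
  c(precision = tp / max(sum(pred == label), 1),
    recall = tp / max(sum(gt == label), 1),
    iou = tp / max(sum(pred == label | gt == label), 1))
}

# The end-to-end benchmark is expensive (~2 min), so it is built once and
# memoised for every test that needs it.
.benchmark_env <- new.env(parent = emptyenv())

benchmark_run <- function() {
  if (!is.null(.benchmark_env$run)) return(.benchmark_env$run)
  cfg <- pipeline_config()
  spec <- demo_scene()          # noise 0.02 m, hole rate 0.05
  tr <- build_training_features(spec, demo_training_scripts(8, seed = 2),
                                cfg, seed = 100)
  model <- train_classifier(tr$features, tr$labels, seed = 1)
  sq <- render_sequence(spec, demo_day_script(), seed = 11)
  res <- suppressMessages(recognize_sequence(sq$frames, model, cfg))
  .benchmark_env$run <- list(config = cfg, spec = spec, model = model,
                             training = tr, truth = sq$truth, result = res)
  .benchmark_env$run
}
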