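# Pilot models shared between the learnability and end-to-end acceptance
# tests. Training happens at most once per test run and is fully seeded.

.pilot_cache <- new.env(parent = emptyenv())

pilot_localizer <- function() {
  if (!is.null(.pilot_cache$loc)) return(.pilot_cache$loc)
  ds <- make_dataset(40, 0, phantom_spec(), seed = 42)
  cfg <- localizer_config(depth = 3, base_filters = 8, input_size = 64,
                          epochs = 15, seed = 7)
  fit <- train_localizer(ds$images, cfg)
  .pilot_cache$loc <- list(fit = fit, images = ds$images)
  .pilot_cache$loc
}

pilot_convlstm <- function() {
  if (!is.null(.pilot_cache$cls)) return(.pilot_cache$cls)
  spec <- clip_phantom_spec(pulsation_amplitude = 0.4, noise_sd = 0.02)
  ds <- make_dataset(0, 80, spec, seed = 11)
  inputs <- clips_to_classifier_inputs(ds$clips)
  labels <- vapply(ds$clips, `[[`, "", "label")
  tr <- 1:60; te <- 61:80
  cfg <- classifier_config("convlstm", preset = "small", batch_size = 10,
                           epochs = 15, seed = 3)
  model <- build_classifier(cfg)
  fit <- train_classifier(model, inputs[tr], labels[tr], cfg)
  .pilot_cache$cls <- list(model = model, inputs = inputs, labels = labels,
                           train = tr, test = te, spec = spec)
  .pilot_cache$cls
}
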