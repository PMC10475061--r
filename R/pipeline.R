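# End-to-end chain: per-frame disc localization -> stable crop region ->
# 30x64x64x1 grayscale clip -> SVP classification.

#' Run the full SVP pipeline on one video
#'
#' @param video an `svp_video` (>= 30 frames) or a clip directory path
#' @param localizer an `svpnet_localizer` or checkpoint directory
#' @param classifier an `svpnet_classifier` or checkpoint directory
#' @param margin crop margin (fraction of the disc bounding box per side)
#' @param n_frames frames fed to the classifier (contract: 30)
#' @param fallback_center center-crop when no disc is found in any frame
#' @param artifacts_dir when non-NULL, per-frame masks, the crop region and
#'   the cropped clip are written here
#' @return list with `label`, `probability`, `region`, and `masks`
#' @export
run_pipeline <- function(video, localizer, classifier, margin = 0.25,
                         n_frames = 30L, fallback_center = FALSE,
                         artifacts_dir = NULL) {
  if (is.character(video)) video <- read_clip(video)
  if (is.character(localizer)) localizer <- load_model(localizer)
  if (is.character(classifier)) classifier <- load_model(classifier)
  d <- dim(video$frames)
  if (d[1] < n_frames)
    stop_contract("video has %d frames; the classifier requires %d", d[1], n_frames)
  masks <- lapply(seq_len(n_frames), function(t)
    predict_mask(localizer, video$frames[t, , ]))
  lc <- localize_and_crop(video, masks, margin = margin, n_frames = n_frames,
                          fallback_center = fallback_center)
  pred <- predict_svp(classifier, lc$input)
  if (!is.null(artifacts_dir)) {
    dir.create(artifacts_dir, recursive = TRUE, showWarnings = FALSE)
    for (t in seq_along(masks))
      write_pgm(masks[[t]], file.path(artifacts_dir, sprintf("mask_%04d.pgm", t - 1L)))
    jsonlite::write_json(unclass(lc$region),
                         file.path(artifacts_dir, "region.json"),
                         auto_unbox = TRUE)
    write_clip(svp_video(lc$input[, , , 1], video$frame_rate),
               file.path(artifacts_dir, "clip"))
    jsonlite::write_json(list(label = pred$label, probability = pred$probability),
                         file.path(artifacts_dir, "prediction.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(label = pred$label, probability = pred$probability,
       region = lc$region, masks = masks)
}

#' Write a small versioned fixture tree
#'
#' Generates 8 labeled phantom images and 8 labeled clips with the package's
#' own writers (text P2 frames for the images, P5 for clips), plus a JSON
#' file of oracle values (mask areas, metric identities) and a manifest with
#' md5 checksums of every file. Regenerating with the same seed is
#' bit-identical.
#'
#' @param out_dir output directory
#' @param seed integer seed
#' @return the manifest (invisibly)
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img_spec <- phantom_spec()
  clip_spec <- phantom_spec(image_height = 64, image_width = 64,
                            disc_center = c(32, 32), disc_radii = c(14, 17),
                            vessel_base_width = 4, pulsation_amplitude = 0.4)
  ds <- make_dataset(8, 8, img_spec, seed = seed)
  ds$clips <- make_dataset(0, 8, clip_spec, seed = seed + 1L)$clips
  for (i in seq_along(ds$images)) {
    write_pgm(ds$images[[i]]$frame,
              file.path(out_dir, sprintf("image_%02d.pgm", i)), binary = FALSE)
    write_pgm(ds$images[[i]]$mask,
              file.path(out_dir, sprintf("mask_%02d.pgm", i)), binary = FALSE)
  }
  for (i in seq_along(ds$clips))
    write_clip(ds$clips[[i]]$clip, file.path(out_dir, sprintf("clip_%02d", i)),
               label = ds$clips[[i]]$label, spec = ds$clips[[i]]$spec)
  oracle <- list(
    image_mask_areas = vapply(ds$images, function(im) sum(im$mask), 0),
    clip_labels = vapply(ds$clips, `[[`, "", "label"),
    dice_identity_example = {
      a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(1, 0, 1, 0), 2)
      dice_iou(a, b)
    })
  jsonlite::write_json(oracle, file.path(out_dir, "oracle.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE)
  invisible(manifest)
}
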