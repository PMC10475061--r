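# Plain-format I/O: PGM images (P2 text / P5 binary), clip directories with a
# JSON manifest, and JSON model checkpoints.
#
# PGM rather than PNG keeps the package free of compiled image-codec
# dependencies; every reader/writer here round-trips bit-exactly at 8-bit
# depth.

#' Write a grayscale image as PGM
#'
#' Intensities in \[0,1\] are quantized to 8-bit. `binary = FALSE` writes the
#' plain-text P2 variant (used for committed fixtures).
#'
#' @param img numeric matrix with values in \[0,1\]
#' @param path output file path
#' @param binary write P5 (binary) rather than P2 (ASCII)
#' @return `path`, invisibly
#' @export
write_pgm <- function(img, path, binary = TRUE) {
  stopifnot(is.matrix(img))
  v <- as.integer(round(clamp01(img) * 255))
  H <- nrow(img); W <- ncol(img)
  # PGM is row-major
  rowmaj <- as.vector(t(matrix(v, H, W)))
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(W, H), "255"), con, sep = "\n")
    writeBin(as.raw(rowmaj), con)
  } else {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(c("P2", paste(W, H), "255"), con)
    writeLines(paste(rowmaj, collapse = " "), con)
  }
  invisible(path)
}

#' Read a PGM image (P2 or P5)
#'
#' @param path file path
#' @return numeric matrix with values in \[0,1\]
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop_data("not a PGM file: %s", path)
  toks <- character(0)
  # header: width height maxval, comments allowed
  while (length(toks) < 3) {
    ch <- readChar(con, 1)
    if (ch == "#") { repeat { c2 <- readChar(con, 1); if (c2 == "\n") break } ; next }
    if (grepl("[0-9]", ch)) {
      num <- ch
      repeat {
        c2 <- readChar(con, 1)
        if (!grepl("[0-9]", c2)) break
        num <- paste0(num, c2)
      }
      toks <- c(toks, num)
    }
  }
  W <- as.integer(toks[1]); H <- as.integer(toks[2]); mx <- as.integer(toks[3])
  if (magic == "P5") {
    v <- as.integer(readBin(con, "raw", n = W * H))
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    v <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])
    if (length(v) > W * H) v <- v[seq_len(W * H)]
  }
  t(matrix(v, W, H)) / mx
}

#' Write a video clip as a directory of per-frame PGMs plus a JSON manifest
#'
#' @param clip an `svp_video` object (see [svp_video()])
#' @param dir output directory (created if missing)
#' @param label optional SVP label stored in the manifest
#' @param spec optional [phantom_spec()] stored in the manifest
#' @return `dir`, invisibly
#' @export
write_clip <- function(clip, dir, label = NULL, spec = NULL) {
  stopifnot(inherits(clip, "svp_video"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nf <- dim(clip$frames)[1]
  files <- sprintf("frame_%04d.pgm", seq_len(nf) - 1L)
  for (t in seq_len(nf)) write_pgm(clip$frames[t, , ], file.path(dir, files[t]))
  manifest <- list(n_frames = nf, frame_rate = clip$frame_rate, files = files)
  if (!is.null(label)) manifest$label <- label
  if (!is.null(spec)) manifest$spec <- unclass(spec)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a clip directory written by [write_clip()] (or any PGM directory)
#'
#' @param dir directory of `frame_*.pgm` files, optionally with manifest.json
#' @param frame_rate fallback frame rate when no manifest is present
#' @return an `svp_video`
#' @export
read_clip <- function(dir, frame_rate = 30) {
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    files <- file.path(dir, manifest$files)
    frame_rate <- manifest$frame_rate
  } else {
    files <- sort(list.files(dir, pattern = "\\.pgm$", full.names = TRUE))
  }
  if (length(files) == 0) stop_data("no frames found in %s", dir)
  f1 <- read_pgm(files[1])
  frames <- array(0, dim = c(length(files), nrow(f1), ncol(f1)))
  frames[1, , ] <- f1
  for (t in seq_along(files)[-1]) frames[t, , ] <- read_pgm(files[t])
  svp_video(frames, frame_rate = frame_rate)
}

# ------------------------------------------------------------ checkpoints ----

#' Save a model checkpoint (JSON parameters + config snapshot)
#'
#' @param model a localizer or classifier model object
#' @param dir checkpoint directory
#' @return `dir`, invisibly
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- param_list(model$store)
  ser <- lapply(params, function(p) list(dim = dim(p$value) %||% length(p$value),
                                         data = as.vector(p$value)))
  jsonlite::write_json(ser, file.path(dir, "params.json"), digits = NA)
  meta <- list(type = class(model)[1], config = unclass(model$config))
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param dir checkpoint directory
#' @return the reconstructed model object
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  cfg <- meta$config
  model <- switch(meta$type,
    svpnet_localizer = build_localizer(do.call(localizer_config, cfg)),
    svpnet_classifier = build_classifier(do.call(classifier_config, cfg)),
    stop_data("unknown checkpoint type: %s", meta$type))
  ser <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  params <- param_list(model$store)
  if (!setequal(names(ser), names(params)))
    stop_data("checkpoint parameters do not match the rebuilt architecture")
  for (nm in names(ser))
    params[[nm]]$value <- array(ser[[nm]]$data, dim = ser[[nm]]$dim)
  model
}
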