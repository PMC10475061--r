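# Mask -> crop pipeline: turn per-frame disc segmentation maps into one
# stable bounding region and emit the classifier-ready clip
# (30 frames, 64x64, grayscale, [0,1]).
#
# Bounding regions are half-open 0-based intervals: rows in
# [row_start, row_end), cols in [col_start, col_end).

#' Construct a bounding region
#'
#' @param row_start,row_end,col_start,col_end 0-based half-open pixel bounds
#' @return a `bounding_region`
#' @export
bounding_region <- function(row_start, row_end, col_start, col_end) {
  if (row_start >= row_end || col_start >= col_end)
    stop_contract("degenerate bounding region")
  structure(list(row_start = as.integer(row_start), row_end = as.integer(row_end),
                 col_start = as.integer(col_start), col_end = as.integer(col_end)),
            class = "bounding_region")
}

# label 4-connected components with BFS; returns integer matrix (0 = background)
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  queue <- integer(H * W)
  for (start in which(mask == 1)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    qh <- 1L; qt <- 1L
    queue[1L] <- start
    lab[start] <- cur
    while (qh <= qt) {
      p <- queue[qh]; qh <- qh + 1L
      r <- ((p - 1L) %% H) + 1L
      c <- ((p - 1L) %/% H) + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1] < 1L || d[1] > H || d[2] < 1L || d[2] > W) next
        q <- d[1] + H * (d[2] - 1L)
        if (mask[q] == 1 && lab[q] == 0L) {
          lab[q] <- cur
          qt <- qt + 1L
          queue[qt] <- q
        }
      }
    }
  }
  lab
}

#' Bounding region of the largest disc component in a mask
#'
#' Takes the tight bounding box of the largest 4-connected foreground
#' component, expands it by `margin` (a fraction of the box size) on each
#' side, pads it to a square when the frame allows, and clamps to the frame.
#'
#' @param mask binary matrix
#' @param margin fractional expansion per side (default 0.25, roughly the
#'   "within one disc diameter" observation region)
#' @return a `bounding_region` (0-based, half-open)
#' @export
mask_to_region <- function(mask, margin = 0.25) {
  if (!is_binary_mask(mask)) stop_contract("mask must be binary")
  if (sum(mask) == 0) stop_data("no disc found: mask has no foreground pixels")
  H <- nrow(mask); W <- ncol(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab)
  best <- which.max(sizes)
  px <- which(lab == best)
  rows <- ((px - 1L) %% H) + 1L
  cols <- ((px - 1L) %/% H) + 1L
  # tight box, 0-based half-open
  r0 <- min(rows) - 1L; r1 <- max(rows); c0 <- min(cols) - 1L; c1 <- max(cols)
  mr <- round(margin * (r1 - r0)); mc <- round(margin * (c1 - c0))
  r0 <- r0 - mr; r1 <- r1 + mr; c0 <- c0 - mc; c1 <- c1 + mc
  # square-pad to the larger side (when possible), then clamp
  side <- max(r1 - r0, c1 - c0)
  ctr_r <- (r0 + r1) / 2; ctr_c <- (c0 + c1) / 2
  r0 <- round(ctr_r - side / 2); r1 <- r0 + side
  c0 <- round(ctr_c - side / 2); c1 <- c0 + side
  if (r0 < 0) { r1 <- r1 - r0; r0 <- 0L }
  if (c0 < 0) { c1 <- c1 - c0; c0 <- 0L }
  if (r1 > H) { r0 <- r0 - (r1 - H); r1 <- H }
  if (c1 > W) { c0 <- c0 - (c1 - W); c1 <- W }
  bounding_region(max(r0, 0), min(r1, H), max(c0, 0), min(c1, W))
}

#' Aggregate per-frame bounding regions into one stable region
#'
#' Per-coordinate median across frames (robust to per-frame jitter and
#' occasional localization failures), rounded to integers.
#'
#' @param regions non-empty list of `bounding_region`s
#' @return a `bounding_region`
#' @export
aggregate_regions <- function(regions) {
  if (length(regions) == 0) stop_data("no regions to aggregate")
  med <- function(f) round(stats::median(vapply(regions, `[[`, 0, f)))
  bounding_region(med("row_start"), med("row_end"),
                  med("col_start"), med("col_end"))
}

region_center <- function(region) {
  c((region$row_start + region$row_end - 1) / 2,
    (region$col_start + region$col_end - 1) / 2)
}

#' Crop a video to the classifier input contract
#'
#' Takes the first `n_frames` frames, crops each to `region`, converts RGB to
#' luminance (0.299 R + 0.587 G + 0.114 B; identity for grayscale input),
#' resizes bilinearly to `size` x `size`, and returns values in \[0,1\].
#'
#' @param video an `svp_video` (frames may be (T,H,W) or (T,H,W,3))
#' @param region a `bounding_region` within the frame bounds
#' @param n_frames number of leading frames to keep (default 30)
#' @param size output spatial size (default 64)
#' @param offset 0-based index of the first frame to use (sliding-window
#'   inference)
#' @return array (n_frames, size, size, 1) - the classifier input
#' @export
crop_clip <- function(video, region, n_frames = 30L, size = 64L, offset = 0L) {
  stopifnot(inherits(video, "svp_video"))
  d <- dim(video$frames)
  if (d[1] - offset < n_frames)
    stop_contract("video has %d usable frames, need %d", d[1] - offset, n_frames)
  if (region$row_end > d[2] || region$col_end > d[3])
    stop_contract("region exceeds the %dx%d frame", d[2], d[3])
  rows <- (region$row_start + 1L):region$row_end
  cols <- (region$col_start + 1L):region$col_end
  out <- array(0, dim = c(n_frames, size, size, 1))
  rgb <- length(d) == 4 && d[4] == 3
  for (t in seq_len(n_frames)) {
    fr <- if (rgb) {
      0.299 * video$frames[offset + t, , , 1] +
        0.587 * video$frames[offset + t, , , 2] +
        0.114 * video$frames[offset + t, , , 3]
    } else if (length(d) == 4) video$frames[offset + t, , , 1]
    else video$frames[offset + t, , ]
    cr <- fr[rows, cols, drop = FALSE]
    out[t, , , 1] <- if (nrow(cr) == size && ncol(cr) == size) cr
                     else resize_bilinear(cr, size, size)
  }
  clamp01(out)
}

#' Localize and crop: video + per-frame masks to classifier input
#'
#' @param video an `svp_video`
#' @param masks list of per-frame binary masks (length >= 1); frames whose
#'   mask is empty are skipped
#' @param margin crop margin passed to [mask_to_region()]
#' @param n_frames,size classifier contract (30, 64)
#' @param fallback_center use a centered square crop when no mask has any
#'   foreground (otherwise an error is raised)
#' @return list with `input` (classifier input array) and `region`
#' @export
localize_and_crop <- function(video, masks, margin = 0.25, n_frames = 30L,
                              size = 64L, fallback_center = FALSE) {
  regions <- list()
  for (m in masks) {
    if (sum(m) == 0) next
    regions[[length(regions) + 1L]] <- mask_to_region(m, margin)
  }
  if (length(regions) == 0) {
    if (!fallback_center) stop_data("no disc found in any frame")
    d <- dim(video$frames)
    side <- min(d[2], d[3])
    r0 <- (d[2] - side) %/% 2; c0 <- (d[3] - side) %/% 2
    region <- bounding_region(r0, r0 + side, c0, c0 + side)
  } else {
    region <- aggregate_regions(regions)
  }
  list(input = crop_clip(video, region, n_frames, size), region = region)
}
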