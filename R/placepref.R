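#' Two-arm arena specification
#'
#' A synthetic odor place-preference arena: left and right arm rectangles
#' connected through a central bowl disc. The scored arm masks exclude the
#' central bowl; the walkable region is the union of arms and bowl. All
#' geometry is in pixels of an `height x width` image.
#'
#' @param width,height Image dimensions in pixels.
#' @param arm_half_h Half-height of the arm corridor (px).
#' @param bowl_radius Central bowl radius (px).
#' @param blob_radius Rendered fly blob radius (px, >= 1).
#' @param step_scale Random-walk step SD (px/frame).
#' @param odor_arm Which arm carries the odor (`"left"` or `"right"`).
#' @return Object of class `arena_spec` with logical mask matrices
#'   `left_mask`, `right_mask`, `bowl_mask` (pairwise disjoint) and
#'   `walkable` (their union).
#' @export
arena_spec <- function(width = 120, height = 120, arm_half_h = 12,
                       bowl_radius = 16, blob_radius = 3, step_scale = 2,
                       odor_arm = c("left", "right")) {
  odor_arm <- match.arg(odor_arm)
  stopifnot(blob_radius >= 1)
  cx <- width / 2; cy <- height / 2
  xs <- matrix(rep(seq_len(width), each = height), nrow = height)
  ys <- matrix(rep(seq_len(height), times = width), nrow = height)
  bowl <- (xs - cx)^2 + (ys - cy)^2 <= bowl_radius^2
  corridor <- abs(ys - cy) <= arm_half_h & xs >= 6 & xs <= width - 5
  left <- corridor & xs < cx - bowl_radius & !bowl
  right <- corridor & xs > cx + bowl_radius & !bowl
  walkable <- bowl | corridor
  structure(list(width = width, height = height,
                 left_mask = left, right_mask = right, bowl_mask = bowl,
                 walkable = walkable, blob_radius = blob_radius,
                 step_scale = step_scale, odor_arm = odor_arm,
                 center = c(x = cx, y = cy)),
            class = "arena_spec")
}

#' Simulate a biased arena walk
#'
#' A reflected Gaussian random walk confined to the walkable region of the
#' arena, starting in the central bowl. The odor-arm bias `beta` adds a
#' constant drift (px/frame) toward the odor arm; `beta = 0` gives a
#' symmetric walk with zero expected left/right occupancy difference.
#'
#' @param arena An [arena_spec()].
#' @param beta Bias drift toward the odor arm (px/frame, >= 0).
#' @param duration_frames Number of frames.
#' @param seed Integer seed.
#' @param n_flies Number of independent walkers (default 1).
#' @return Position trace tibble `frame` (0-based), `fly`, `x`, `y`.
#' @export
simulate_walk <- function(arena, beta = 0, duration_frames, seed = 1,
                          n_flies = 1) {
  stopifnot(beta >= 0)
  dir_x <- if (arena$odor_arm == "left") -1 else 1
  out <- vector("list", n_flies)
  for (f in seq_len(n_flies)) {
    set.seed(split_seed(seed, f))
    x <- numeric(duration_frames); y <- numeric(duration_frames)
    cx <- arena$center[["x"]]; cy <- arena$center[["y"]]
    px <- cx; py <- cy
    dx <- stats::rnorm(duration_frames, beta * dir_x, arena$step_scale)
    dy <- stats::rnorm(duration_frames, 0, arena$step_scale)
    for (i in seq_len(duration_frames)) {
      nx <- px + dx[i]; ny <- py + dy[i]
      xi <- round(nx); yi <- round(ny)
      if (xi >= 1 && xi <= arena$width && yi >= 1 && yi <= arena$height &&
          arena$walkable[yi, xi]) {
        px <- nx; py <- ny
      }                                       # blocked step: stay in place
      x[i] <- px; y[i] <- py
    }
    out[[f]] <- tibble::tibble(frame = seq_len(duration_frames) - 1L,
                               fly = f, x = x, y = y)
  }
  dplyr::bind_rows(out)
}

#' Render a position trace into an image stack
#'
#' Draws one dark disc of the arena's blob radius per fly on a brighter
#' uniform background, one image per frame. Intensities are in `[0, 1]`.
#'
#' @param arena An [arena_spec()].
#' @param trace Position trace from [simulate_walk()].
#' @param bg,fg Background and blob intensities.
#' @return Numeric array `height x width x n_frames`.
#' @export
render_frames <- function(arena, trace, bg = 0.8, fg = 0.2) {
  frames <- sort(unique(trace$frame))
  arr <- array(bg, dim = c(arena$height, arena$width, length(frames)))
  r <- arena$blob_radius
  d <- 2 * ceiling(r) + 1
  offs <- expand.grid(dy = -ceiling(r):ceiling(r),
                      dx = -ceiling(r):ceiling(r))
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, ]
  for (k in seq_along(frames)) {
    rows <- trace[trace$frame == frames[k], , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      cxi <- round(rows$x[j]); cyi <- round(rows$y[j])
      yy <- cyi + offs$dy; xx <- cxi + offs$dx
      ok <- yy >= 1 & yy <= arena$height & xx >= 1 & xx <= arena$width
      arr[cbind(yy[ok], xx[ok], k)] <- fg
    }
  }
  arr
}

#' Estimate a background image by median filtering
#'
#' Per-pixel median over an evenly spaced subset of frames. Wherever a
#' moving fly occupies a pixel in fewer than half of the subset frames the
#' median recovers the static background exactly.
#'
#' @param frames Image stack (`height x width x n` array).
#' @param subset_size Number of evenly spaced frames to use (default
#'   `min(25, n)`; may equal `n`).
#' @return Background image matrix.
#' @export
estimate_background <- function(frames, subset_size = NULL) {
  stopifnot(length(dim(frames)) == 3)
  n <- dim(frames)[3]
  if (n < 3) stop("need at least 3 frames to estimate a background")
  if (is.null(subset_size)) subset_size <- min(25L, n)
  subset_size <- min(subset_size, n)
  idx <- unique(round(seq(1, n, length.out = subset_size)))
  apply(frames[, , idx, drop = FALSE], c(1, 2), stats::median)
}

#' Detect fly positions by background subtraction
#'
#' Thresholds the absolute background-subtracted frames, labels connected
#' components, and returns the centroid of every component above a
#' minimum-area cutoff ("blob detection"). Frames with no blob yield no
#' rows. When `threshold` is `NULL` an Otsu threshold over the difference
#' stack is used.
#'
#' @param frames Image stack (`height x width x n`).
#' @param background Background image from [estimate_background()].
#' @param threshold Absolute-intensity threshold, or `NULL` for Otsu.
#' @param min_area Minimum blob area in pixels (default 5).
#' @return Tibble `frame` (0-based), `blob`, `x`, `y`, `area`.
#' @export
detect_positions <- function(frames, background, threshold = NULL,
                             min_area = 5) {
  stopifnot(all(dim(frames)[1:2] == dim(background)))
  n <- dim(frames)[3]
  if (is.null(threshold)) {
    dmax <- max(abs(frames - as.vector(background)))
    diffs <- abs(frames - as.vector(background)) / max(dmax, 1e-12)
    threshold <- EBImage::otsu(diffs, range = c(0, 1)) * dmax
    rm(diffs)
  }
  out <- vector("list", n)
  for (k in seq_len(n)) {
    d <- abs(frames[, , k] - background) > threshold
    if (!any(d)) next
    lab <- EBImage::bwlabel(d)
    tab <- tabulate(lab)
    keep <- which(tab >= min_area)
    if (!length(keep)) next
    rows <- lapply(seq_along(keep), function(j) {
      px <- which(lab == keep[j], arr.ind = TRUE)
      tibble::tibble(frame = k - 1L, blob = j,
                     x = mean(px[, 2]), y = mean(px[, 1]),
                     area = nrow(px))
    })
    out[[k]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(frame = integer(), blob = integer(),
                          x = numeric(), y = numeric(), area = integer())
  }
  res
}

#' Normalized arm occupancy
#'
#' Assigns every detected centroid to the left arm, right arm, or neither
#' (central bowl and unassigned pixels are excluded) and computes the
#' normalized occupancy `(t_left - t_right) / (t_left + t_right)`;
#' alternatively the odor-arm fraction of scored time
#' (`mode = "fraction"`). Multi-fly frames pool all centroids (cumulative
#' position traces, no identity tracking).
#'
#' @param trace Tibble with `x`, `y` centroids (e.g. from
#'   [detect_positions()] or [simulate_walk()]).
#' @param arena An [arena_spec()] providing the arm masks.
#' @param mode `"difference"` (default) or `"fraction"`.
#' @return Tibble `t_left`, `t_right` (frame counts), `index` (`NA` when
#'   no frame falls in either arm).
#' @export
occupancy_index <- function(trace, arena, mode = c("difference", "fraction")) {
  mode <- match.arg(mode)
  if (nrow(trace) == 0) stop("empty position trace")
  xi <- pmin(pmax(round(trace$x), 1), arena$width)
  yi <- pmin(pmax(round(trace$y), 1), arena$height)
  ij <- cbind(yi, xi)
  inL <- arena$left_mask[ij]
  inR <- arena$right_mask[ij]
  tl <- sum(inL); tr <- sum(inR)
  idx <- if (tl + tr == 0) {
    NA_real_
  } else if (mode == "difference") {
    (tl - tr) / (tl + tr)
  } else {
    odor <- if (arena$odor_arm == "left") tl else tr
    odor / (tl + tr)
  }
  tibble::tibble(t_left = tl, t_right = tr, index = idx)
}
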