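# Radial lobed rosette silhouette: radius multiplier as a function of the
# polar angle. Lobe count, amplitude and phase are drawn per plant, giving
# leaf-like outlines rather than perfect discs.
lobe_profile <- function(theta, n_lobes, amp, phase, amp2, phase2) {
  1 + amp * cos(n_lobes * theta + phase) + amp2 * cos((n_lobes + 3) * theta + phase2)
}

#' Render a synthetic plate scene
#'
#' Draws each plant as a connected, radially lobed blob centered in its
#' well, with an exact requested pixel area and a mean per-pixel green leaf
#' index matching the requested greenness (within channel-quantization
#' error). The plate/agar background is non-green (GLI about 0), so
#' excess-green segmentation of the scene is well posed. A ground-truth
#' label mask accompanies the image: 0 is background, k marks the plant in
#' well k.
#'
#' @param wells Tibble with columns `well`, `area_px`, `greenness` (target
#'   mean GLI; values are clamped to `[0, 0.55]`, the range representable by
#'   the leaf color model). At most one row per well; wells absent from the
#'   table stay empty.
#' @param layout A [plate_layout()].
#' @param time Acquisition time in days (metadata only).
#' @param seed RNG seed controlling lobe shapes and pixel color noise.
#' @param background Mean background RGB (a neutral agar tone).
#' @param background_noise_sd Per-pixel Gaussian channel noise of the
#'   background.
#' @return An object of class `plate_scene`: list with `image` (H x W x 3
#'   integer array in `[0, 255]`), `truth_mask` (H x W integer matrix),
#'   `layout`, `time`.
#' @export
render_plate <- function(wells, layout, time = NA_real_, seed = 1L,
                         background = c(105, 100, 95),
                         background_noise_sd = 3) {
  validate_plate_layout(layout)
  if (any(duplicated(wells$well))) {
    stop_invalid("plate_scene", "at most one entry per well")
  }
  if (any(wells$area_px < 0)) {
    stop_invalid("plate_scene", "requested areas must be nonnegative")
  }
  n_wells <- nrow(layout$well_centers)
  if (any(!wells$well %in% seq_len(n_wells))) {
    stop_invalid("plate_scene", "well indices must exist in the layout")
  }
  set.seed(seed)
  h <- layout$image_shape[["height"]]
  w <- layout$image_shape[["width"]]
  npix <- h * w
  img <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) {
    img[, , ch] <- matrix(
      as.integer(pmin(pmax(round(background[ch] + rnorm(npix, 0, background_noise_sd)), 0), 255)),
      nrow = h
    )
  }
  mask <- matrix(0L, nrow = h, ncol = w)
  half <- layout$well_diameter_px / 2
  disc_area <- pi * half^2

  for (i in seq_len(nrow(wells))) {
    k <- wells$well[i]
    target <- as.integer(round(wells$area_px[i]))
    if (target == 0) next
    if (target > 0.85 * disc_area) {
      stop_invalid("plate_scene", sprintf(
        "requested area %d px exceeds the capacity of well %d (disc %.0f px)",
        target, k, disc_area
      ))
    }
    gli <- min(max(wells$greenness[i], 0), 0.55)
    cx <- layout$well_centers$x[k]
    cy <- layout$well_centers$y[k]
    # lobed outline, drawn per plant
    n_lobes <- sample(4:8, 1)
    amp <- runif(1, 0.06, 0.16)
    amp2 <- runif(1, 0.02, 0.06)
    phase <- runif(1, 0, 2 * pi)
    phase2 <- runif(1, 0, 2 * pi)
    # candidate pixels: the well's bounding box, ranked by scaled radius so
    # that taking the `target` innermost pixels yields an exact-area blob
    # whose boundary is a level set of the lobed profile
    xs <- seq.int(max(1, floor(cx - half)), min(w, ceiling(cx + half)))
    ys <- seq.int(max(1, floor(cy - half)), min(h, ceiling(cy + half)))
    dx <- rep(xs - cx, each = length(ys))
    dy <- rep(ys - cy, times = length(xs))
    rr <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    m <- rr / lobe_profile(th, n_lobes, amp, amp2 = amp2,
                           phase = phase, phase2 = phase2)
    ord <- order(m)[seq_len(target)]
    if (max(rr[ord]) > half) {
      stop_invalid("plate_scene", sprintf(
        "requested area %d px does not fit inside well %d's disc", target, k
      ))
    }
    px_x <- rep(xs, each = length(ys))[ord]
    px_y <- rep(ys, times = length(xs))[ord]
    idx <- cbind(px_y, px_x)
    mask[idx] <- k
    # leaf color: R and B jittered, G solved per pixel so each pixel's GLI
    # equals the target up to integer quantization
    Rv <- pmin(pmax(round(rnorm(target, 80, 10)), 20), 180)
    Bv <- pmin(pmax(round(rnorm(target, 60, 10)), 10), 160)
    Gv <- pmin(pmax(round((Rv + Bv) * (1 + gli) / (2 * (1 - gli))), 0), 255)
    img[cbind(idx, 1L)] <- as.integer(Rv)
    img[cbind(idx, 2L)] <- as.integer(Gv)
    img[cbind(idx, 3L)] <- as.integer(Bv)
  }
  structure(
    list(image = img, truth_mask = mask, layout = layout, time = time),
    class = "plate_scene"
  )
}

#' @export
print.plate_scene <- function(x, ...) {
  cat(sprintf("<plate_scene> %d x %d px, %d labeled plants, t = %s d\n",
              dim(x$image)[1], dim(x$image)[2],
              length(setdiff(unique(as.vector(x$truth_mask)), 0L)),
              format(x$time)))
  invisible(x)
}
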