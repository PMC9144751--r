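#' Excess-green index of an RGB image
#'
#' Per-pixel 2G - R - B, the standard scalar field for separating green
#' vegetation from a non-green background before thresholding.
#'
#' @param image H x W x 3 array of channel intensities in `[0, 255]`.
#' @return H x W numeric matrix with values in `[-510, 510]`.
#' @export
excess_green <- function(image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) {
    stop_invalid("image", "expected an H x W x 3 RGB array")
  }
  2 * image[, , 2] - image[, , 1] - image[, , 3]
}

#' Segment plants from a plate scene
#'
#' Thresholds the excess-green index, cleans the binary mask with a
#' morphological opening (3 x 3 structuring element), labels connected
#' components, and assigns to each well the largest component whose
#' centroid lies inside the well's disc. Wells with no component of at
#' least `min_object_px` pixels report zero area. Channel means are
#' computed per pixel over the final plant mask.
#'
#' @param scene A [render_plate()] scene, or any list with `image`,
#'   `layout` and optionally `time`.
#' @param threshold Excess-green cutoff in `(0, 510)`; pixels strictly
#'   above it are candidate foreground. Use [otsu_threshold()] for a
#'   data-driven alternative.
#' @param min_object_px Minimum component size kept, in pixels.
#' @return List with `mask` (H x W integer matrix; 0 background, k = plant
#'   assigned to well k) and `measurements` (tibble: `well`, `time`,
#'   `area_px`, `mean_R`, `mean_G`, `mean_B`).
#' @export
segment_plants <- function(scene, threshold = 40, min_object_px = 25) {
  if (is.null(scene$layout)) stop_invalid("plate_scene", "a layout is required")
  if (!(threshold > 0 && threshold < 510)) {
    stop_invalid("segmentation", "threshold must lie in (0, 510)")
  }
  layout <- scene$layout
  validate_plate_layout(layout)
  img <- scene$image
  exg <- excess_green(img)
  binary <- (exg > threshold) * 1
  opened <- EBImage::opening(binary, EBImage::makeBrush(3, shape = "diamond"))
  labels <- EBImage::bwlabel(opened)
  labels <- matrix(as.integer(labels), nrow = nrow(binary))
  n_comp <- max(labels)
  centers <- layout$well_centers
  half <- layout$well_diameter_px / 2
  n_wells <- nrow(centers)
  out_mask <- matrix(0L, nrow = nrow(labels), ncol = ncol(labels))
  meas <- tibble::tibble(
    well = seq_len(n_wells), time = scene$time %||% NA_real_,
    area_px = 0L, mean_R = NA_real_, mean_G = NA_real_, mean_B = NA_real_
  )
  if (n_comp > 0) {
    idx <- which(labels > 0)
    lab <- labels[idx]
    py <- (idx - 1) %% nrow(labels) + 1
    px <- (idx - 1) %/% nrow(labels) + 1
    sizes <- tabulate(lab, nbins = n_comp)
    cx <- rowsum(px, lab)[, 1] / sizes
    cy <- rowsum(py, lab)[, 1] / sizes
    # assign each component to the well whose disc contains its centroid
    d2 <- outer(cx, centers$x, `-`)^2 + outer(cy, centers$y, `-`)^2
    nearest <- max.col(-d2)
    inside <- d2[cbind(seq_len(n_comp), nearest)] <= half^2
    comp_well <- ifelse(inside, nearest, NA_integer_)
    for (k in seq_len(n_wells)) {
      cand <- which(comp_well == k & sizes >= min_object_px)
      if (length(cand) == 0) next
      keep <- cand[which.max(sizes[cand])]
      sel <- idx[lab == keep]
      rr2 <- (px[lab == keep] - centers$x[k])^2 + (py[lab == keep] - centers$y[k])^2
      if (any(rr2 > half^2)) {
        warn(sprintf("component assigned to well %d extends beyond its disc", k))
      }
      out_mask[sel] <- k
      np <- length(sel)
      meas$area_px[k] <- np
      meas$mean_R[k] <- sum(img[sel]) / np
      meas$mean_G[k] <- sum(img[sel + length(out_mask)]) / np
      meas$mean_B[k] <- sum(img[sel + 2 * length(out_mask)]) / np
    }
  }
  list(mask = out_mask, measurements = meas)
}

#' Otsu threshold on the excess-green index
#'
#' Data-driven alternative to the fixed excess-green cutoff: maximizes
#' between-class variance of the excess-green histogram.
#'
#' @param image H x W x 3 RGB array.
#' @return A scalar excess-green threshold.
#' @export
otsu_threshold <- function(image) {
  exg <- excess_green(image)
  # shift to [0, 1] for EBImage's histogram-based Otsu, then map back
  scaled <- (exg + 510) / 1020
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  th * 1020 - 510
}

#' Per-well segmentation accuracy against a ground-truth mask
#'
#' @param mask Predicted label mask (wells as labels).
#' @param truth_mask Ground-truth label mask, same coding.
#' @return Tibble per ground-truth well: `well`, `truth_px`, `pred_px`,
#'   `rel_area_error`, `dice` (2|A n B| / (|A| + |B|)).
#' @export
segmentation_accuracy <- function(mask, truth_mask) {
  wells <- sort(setdiff(unique(as.vector(truth_mask)), 0L))
  purrr::map_dfr(wells, function(k) {
    tp <- truth_mask == k
    pp <- mask == k
    nt <- sum(tp); np <- sum(pp)
    tibble::tibble(
      well = k, truth_px = nt, pred_px = np,
      rel_area_error = abs(np - nt) / nt,
      dice = 2 * sum(tp & pp) / (nt + np)
    )
  })
}

#' Assemble per-plant time series from a sequence of plate scenes
#'
#' Segments every scene and joins the per-well measurements with the plate
#' map, yielding the same long format as [simulate_growth()]. Scenes are
#' ordered by acquisition time; duplicate times are rejected.
#'
#' @param scenes List of plate scenes sharing one layout.
#' @param well_map Tibble mapping `well` to `plant_id`, `treatment`,
#'   `concentration`, `condition`.
#' @param threshold,min_object_px Passed to [segment_plants()].
#' @return Long tibble: `plant_id`, `treatment`, `concentration`,
#'   `condition`, `time_days`, `area_px`, `mean_R`, `mean_G`, `mean_B`.
#' @export
extract_time_series <- function(scenes, well_map, threshold = 40,
                                min_object_px = 25) {
  times <- purrr::map_dbl(scenes, ~ .x$time)
  if (anyNA(times)) stop_invalid("scene_series", "every scene needs a time")
  if (anyDuplicated(times)) stop_invalid("scene_series", "duplicate scene times")
  scenes <- scenes[order(times)]
  need <- c("well", "plant_id", "treatment", "concentration", "condition")
  if (!all(need %in% names(well_map))) {
    stop_invalid("well_map", paste("columns required:", paste(need, collapse = ", ")))
  }
  rows <- purrr::map(scenes, function(sc) {
    seg <- segment_plants(sc, threshold = threshold, min_object_px = min_object_px)
    dplyr::inner_join(well_map, seg$measurements, by = "well")
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$plant_id, .data$time)
  dplyr::select(out, "plant_id", "treatment", "concentration", "condition",
                time_days = "time", "area_px", "mean_R", "mean_G", "mean_B")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
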