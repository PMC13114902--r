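# Seeded synthetic COCO datasets with a ground-truth manifest of injected
# defects, so every pipeline stage is testable without external data.

#' Specification of a synthetic dataset and its injected defects
#'
#' Defaults emulate the composition of a curated endoscopy annotation set:
#' a majority of well-formed instances, roughly a quarter to a third of
#' annotations structurally defective, and a small tail of valid but
#' sub-threshold instances, with the 700 px^2 noise threshold separating
#' them from the valid-area range.  Defect classes are constructed to be
#' mutually exclusive — each instance exhibits its defining defect and no
#' other — so first-failure screening order cannot blur the counts.
#'
#' @param n_images Number of images.
#' @param image_size `(width, height)` in px.
#' @param n_valid_per_image Well-formed instances drawn on every image.
#' @param n_empty Annotations with an empty segmentation list.
#' @param n_too_few Polygons with only 2 vertices.
#' @param n_out_of_bounds Simple polygons with at least one vertex outside
#'   the image extent.
#' @param n_degenerate Near-zero-area polygons (collinear triplets or
#'   sub-pixel squares).
#' @param n_self_intersecting Crossed ("bow-tie") quadrilaterals with
#'   non-degenerate analytic area.
#' @param n_small Valid simple polygons with rasterized area below
#'   `small_area_max` (survive validation, removed by the area filter).
#' @param small_area_max Pixel-area threshold separating `SMALL` from
#'   valid instances; must be below `area_range_valid[1]`.
#' @param area_range_valid `(min, max)` rasterized pixel area for valid
#'   instances.
#' @param n_categories Number of categories.
#' @param seed Integer seed; a single RNG stream drives the whole
#'   generation and is recorded in the manifest.
#' @return A `defect_spec` list.
#' @export
defect_spec <- function(n_images = 12, image_size = c(320, 320),
                        n_valid_per_image = 2,
                        n_empty = 3, n_too_few = 2, n_out_of_bounds = 2,
                        n_degenerate = 2, n_self_intersecting = 2,
                        n_small = 3, small_area_max = 700,
                        area_range_valid = c(900, 6000),
                        n_categories = 9, seed = 1) {
  spec <- list(n_images = n_images, image_size = image_size,
               n_valid_per_image = n_valid_per_image,
               n_empty = n_empty, n_too_few = n_too_few,
               n_out_of_bounds = n_out_of_bounds,
               n_degenerate = n_degenerate,
               n_self_intersecting = n_self_intersecting,
               n_small = n_small, small_area_max = small_area_max,
               area_range_valid = area_range_valid,
               n_categories = n_categories, seed = seed)
  counts <- unlist(spec[c("n_images", "n_valid_per_image", "n_empty",
                          "n_too_few", "n_out_of_bounds", "n_degenerate",
                          "n_self_intersecting", "n_small")])
  stopifnot(all(counts >= 0), n_images >= 1, n_categories >= 1,
            length(image_size) == 2, all(image_size >= 32),
            length(area_range_valid) == 2,
            area_range_valid[1] < area_range_valid[2],
            small_area_max < area_range_valid[1])
  if (area_range_valid[2] > 0.5 * prod(image_size)) {
    stop("area_range_valid too large for image_size", call. = FALSE)
  }
  structure(spec, class = "defect_spec")
}

#' Generate a synthetic COCO dataset with a ground-truth defect manifest
#'
#' Deterministic for a fixed seed: the same spec serializes to the same
#' JSON byte for byte.  Valid and `SMALL` instances are random convex
#' polygons (vertices on a random ellipse), rejection-sampled until their
#' rasterized pixel area lands in the target range, so validation and
#' area-filter outcomes are knowable in advance and recorded per
#' annotation id in the manifest.
#'
#' @param spec A [defect_spec()].
#' @param images Also render flat synthetic image rasters (gray background,
#'   brighter filled instances) for overlay tests?  Default `FALSE`.
#' @return List: `dataset` (a `coco_dataset`), `manifest` (data frame
#'   `annotation_id`, `label` in VALID / EMPTY / TOO_FEW / OUT_OF_BOUNDS /
#'   DEGENERATE / SELF_INTERSECTING / SMALL, with the seed as an
#'   attribute), and `images` (named list of height x width x 3 arrays)
#'   when requested.
#' @export
generate_dataset <- function(spec = defect_spec(), images = FALSE) {
  stopifnot(inherits(spec, "defect_spec"))
  .with_seed(spec$seed, .generate_dataset_impl(spec, images))
}

.generate_dataset_impl <- function(spec, images) {
  w <- spec$image_size[1]; h <- spec$image_size[2]
  imgs <- data.frame(id = seq_len(spec$n_images),
                     file_name = sprintf("synthetic_%04d.png",
                                         seq_len(spec$n_images)),
                     width = w, height = h)
  attr(imgs, "coco_extra") <- rep(list(list()), spec$n_images)
  cats <- data.frame(id = seq_len(spec$n_categories),
                     name = sprintf("class_%02d", seq_len(spec$n_categories)))
  attr(cats, "coco_extra") <- rep(list(list()), spec$n_categories)

  labels <- c(rep("VALID", spec$n_images * spec$n_valid_per_image),
              rep("EMPTY", spec$n_empty),
              rep("TOO_FEW", spec$n_too_few),
              rep("OUT_OF_BOUNDS", spec$n_out_of_bounds),
              rep("DEGENERATE", spec$n_degenerate),
              rep("SELF_INTERSECTING", spec$n_self_intersecting),
              rep("SMALL", spec$n_small))
  labels <- sample(labels)                 # interleave classes across ids
  image_of <- c(rep(seq_len(spec$n_images), spec$n_valid_per_image),
                sample(spec$n_images,
                       length(labels) - spec$n_images * spec$n_valid_per_image,
                       replace = TRUE))
  image_of <- sample(image_of)

  anns <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    seg <- switch(labels[i],
      VALID = list(.sample_convex_in_area(w, h, spec$area_range_valid)),
      SMALL = list(.sample_convex_in_area(
        w, h, c(max(16, 0.05 * spec$small_area_max), 0.8 * spec$small_area_max),
        max_raster = spec$small_area_max - 1)),
      EMPTY = list(),
      TOO_FEW = list(as.numeric(c(stats::runif(1, 1, w - 1),
                                  stats::runif(1, 1, h - 1),
                                  stats::runif(1, 1, w - 1),
                                  stats::runif(1, 1, h - 1)))),
      OUT_OF_BOUNDS = list(.sample_out_of_bounds(w, h, spec$area_range_valid)),
      DEGENERATE = list(.sample_degenerate(w, h)),
      SELF_INTERSECTING = list(.sample_bowtie(w, h)))
    anns[[i]] <- list(id = i, image_id = image_of[i],
                      category_id = sample(spec$n_categories, 1),
                      segmentation = seg, rle = FALSE, extra = list())
  }
  ds <- structure(list(images = imgs, annotations = anns, categories = cats,
                       extra = list()), class = "coco_dataset")
  manifest <- data.frame(annotation_id = seq_along(labels), label = labels)
  attr(manifest, "seed") <- spec$seed
  out <- list(dataset = ds, manifest = manifest)
  if (images) out$images <- .render_synthetic_images(ds)
  out
}

# Convex polygon (vertices equally spaced on a random ellipse) whose
# rasterized pixel area falls inside `range`; rejection-sampled.
.sample_convex_in_area <- function(w, h, range, max_raster = Inf) {
  for (try in 1:200) {
    k <- sample(5:10, 1)
    target <- stats::runif(1, range[1], range[2])
    ratio <- stats::runif(1, 0.6, 1.6)
    rxry <- 2 * target / (k * sin(2 * pi / k))
    rx <- sqrt(rxry * ratio); ry <- sqrt(rxry / ratio)
    if (2 * rx > w - 6 || 2 * ry > h - 6) next
    cx <- stats::runif(1, rx + 2, w - rx - 2)
    cy <- stats::runif(1, ry + 2, h - ry - 2)
    ang <- stats::runif(1, 0, 2 * pi) + 2 * pi * (seq_len(k) - 1) / k
    poly <- cbind(cx + rx * cos(ang), cy + ry * sin(ang))
    area <- sum(rasterize_polygon(poly, w, h))
    if (area >= range[1] && area <= min(range[2], max_raster)) {
      return(as.numeric(t(poly)))
    }
  }
  stop("could not sample a polygon with rasterized area in [",
       range[1], ", ", range[2], "] on a ", w, "x", h, " image",
       call. = FALSE)
}

# Valid-shaped convex polygon shifted so at least one vertex leaves the frame.
.sample_out_of_bounds <- function(w, h, range) {
  flat <- .sample_convex_in_area(w, h, range)
  p <- decode_segmentation(flat)
  p[, 1] <- p[, 1] - (min(p[, 1]) + stats::runif(1, 1, 5))
  as.numeric(t(p))
}

# Near-zero analytic area, in bounds: collinear triplet or sub-pixel square.
.sample_degenerate <- function(w, h) {
  if (stats::runif(1) < 0.5) {
    x0 <- stats::runif(1, 5, w - 25); y0 <- stats::runif(1, 5, h - 25)
    dx <- stats::runif(1, 2, 8); dy <- stats::runif(1, 2, 8)
    as.numeric(c(x0, y0, x0 + dx, y0 + dy, x0 + 2 * dx, y0 + 2 * dy))
  } else {
    x0 <- stats::runif(1, 5, w - 6); y0 <- stats::runif(1, 5, h - 6)
    s <- stats::runif(1, 0.2, 0.9)    # shoelace area s^2 < 1
    as.numeric(c(x0, y0, x0 + s, y0, x0 + s, y0 + s, x0, y0 + s))
  }
}

# Crossed quadrilateral with unequal lobes: self-intersecting, analytic
# area well above the degeneracy threshold.
.sample_bowtie <- function(w, h) {
  s_max <- min(5, (min(w, h) - 6) / 10)
  s <- stats::runif(1, min(2, s_max), s_max)
  x0 <- stats::runif(1, 2, w - 10 * s - 2)
  y0 <- stats::runif(1, 2, h - 8 * s - 2)
  base <- matrix(c(0, 0, 10, 0, 3, 8, 7, 8), ncol = 2, byrow = TRUE)
  as.numeric(t(cbind(x0 + s * base[, 1], y0 + s * base[, 2])))
}

.render_synthetic_images <- function(ds) {
  out <- list()
  for (i in seq_len(nrow(ds$images))) {
    img <- ds$images[i, ]
    arr <- array(40, dim = c(img$height, img$width, 3))
    for (a in ds$annotations) {
      if (a$image_id != img$id || !length(a$segmentation)) next
      for (flat in a$segmentation) {
        if (length(flat) < 6 || length(flat) %% 2 != 0) next
        p <- decode_segmentation(flat)
        p[, 1] <- pmin(pmax(p[, 1], 0), img$width)
        p[, 2] <- pmin(pmax(p[, 2], 0), img$height)
        bm <- rasterize_polygon(p, img$width, img$height)
        for (ch in 1:3) {
          plane <- arr[, , ch]
          plane[bm] <- 180
          arr[, , ch] <- plane
        }
      }
    }
    out[[img$file_name]] <- arr
  }
  out
}

#' Generate a mask pair with an exact, analytically known Dice overlap
#'
#' Two equal-area blocks laid out along the rows of a shared frame; the
#' second is offset so the intersection holds exactly
#' `round(overlap_fraction * block_area)` pixels, giving an analytic
#' `DSC = 2 * overlap / (2 * block_area)`.
#'
#' @param overlap_fraction Target overlap fraction in `[0, 1]`.
#' @param block_area Pixels per mask.
#' @param frame `(width, height)` of the masks.
#' @return List: `a`, `b` (logical matrices), `overlap` (px),
#'   `dsc_expected`.
#' @export
#' @examples
#' p <- generate_mask_pair(0.75, 16, c(16, 16))
#' p$dsc_expected  # 0.75
generate_mask_pair <- function(overlap_fraction, block_area, frame) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1, block_area >= 1,
            length(frame) == 2)
  w <- frame[1]; h <- frame[2]
  overlap <- round(overlap_fraction * block_area)
  offset <- block_area - overlap
  if (block_area + offset > w * h) {
    stop("frame too small for block_area ", block_area, " at overlap ",
         overlap_fraction, call. = FALSE)
  }
  fill <- function(from, n) {
    m <- matrix(FALSE, nrow = h, ncol = w)
    idx <- seq.int(from, length.out = n)         # row-major pixel order
    r <- (idx - 1L) %/% w + 1L
    cc <- (idx - 1L) %% w + 1L
    m[cbind(r, cc)] <- TRUE
    m
  }
  a <- fill(1L, block_area)
  b <- fill(1L + offset, block_area)
  list(a = a, b = b, overlap = overlap,
       dsc_expected = 2 * overlap / (2 * block_area))
}
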