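# Rasterization of validated polygons into native-resolution binary masks.

#' Rasterize one polygon part into a logical mask
#'
#' Scanline fill under the even-odd rule evaluated at pixel centers: pixel
#' (col c, row r), 0-based, is set iff its center (c + 0.5, r + 0.5) lies
#' inside the polygon.  Centers exactly on an edge follow a top-left rule
#' (half-open spans on both axes), so adjacent polygons never double-count
#' a boundary pixel and an axis-aligned rectangle covers exactly the pixels
#' whose centers it contains.
#'
#' @param p An n x 2 vertex matrix (or flat coordinate vector), n >= 3.
#' @param width,height Mask dimensions in px (the image's native size).
#' @return A `height` x `width` logical matrix (row 1 = top row).
#' @export
rasterize_polygon <- function(p, width, height) {
  p <- .as_vertices(p)
  if (nrow(p) < 3L) stop("rasterize_polygon needs >= 3 vertices", call. = FALSE)
  width <- as.integer(width); height <- as.integer(height)
  mask <- matrix(FALSE, nrow = height, ncol = width)
  n <- nrow(p)
  x1 <- p[, 1]; y1 <- p[, 2]
  j <- c(2:n, 1L)
  x2 <- p[j, 1]; y2 <- p[j, 2]
  keep <- y1 != y2                       # horizontal edges never cross a scanline
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  if (!length(x1)) return(mask)
  ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)

  r0 <- max(0L, as.integer(floor(min(ylo) - 0.5)))
  r1 <- min(height - 1L, as.integer(ceiling(max(yhi))))
  if (r0 > r1) return(mask)
  for (r in r0:r1) {
    yc <- r + 0.5
    hit <- ylo <= yc & yc < yhi          # half-open: top edge in, bottom out
    if (!any(hit)) next
    xi <- sort(x1[hit] + (yc - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit]))
    if (length(xi) %% 2L != 0L) next     # cannot happen for a closed ring
    for (k in seq(1L, length(xi) - 1L, by = 2L)) {
      c0 <- max(0L, as.integer(ceiling(xi[k] - 0.5)))        # c + 0.5 >= lo
      c1 <- min(width - 1L, as.integer(ceiling(xi[k + 1L] - 0.5)) - 1L)  # c + 0.5 < hi
      if (c0 <= c1) mask[r + 1L, (c0:c1) + 1L] <- TRUE
    }
  }
  mask
}

#' Rasterize an annotation to a native-resolution instance mask
#'
#' Multi-part annotations produce the pixel-wise union of their parts.
#' The mask is always the full image grid so that pixel-level alignment
#' with the source image is preserved.
#'
#' @param ann Annotation record that passed validation.
#' @param img Matching one-row image record.
#' @return An `instance_mask`: list with `annotation_id`, `width`, `height`,
#'   `bitmap` (logical height x width matrix), `pixel_area` (set-pixel
#'   count) and `n_components` (8-connected foreground components).
#' @export
rasterize_annotation <- function(ann, img) {
  stopifnot(ann$image_id == img$id)
  seg <- ann$segmentation
  if (is.null(seg) || !length(seg) || isTRUE(ann$rle)) {
    stop("annotation ", ann$id, " has no polygon segmentation; run validation first",
         call. = FALSE)
  }
  w <- as.integer(img$width); h <- as.integer(img$height)
  bitmap <- matrix(FALSE, nrow = h, ncol = w)
  for (flat in seg) {
    part <- .open_ring(decode_segmentation(flat))
    bitmap <- bitmap | rasterize_polygon(part, w, h)
  }
  instance_mask(bitmap, annotation_id = ann$id)
}

#' Construct an instance mask from a bitmap
#'
#' @param bitmap Logical (or 0/1) matrix, rows = image rows top-down.
#' @param annotation_id Optional source annotation id.
#' @return An `instance_mask` with `pixel_area` and `n_components` filled in.
#' @export
instance_mask <- function(bitmap, annotation_id = NA) {
  bitmap <- bitmap != 0
  structure(list(annotation_id = annotation_id,
                 width = ncol(bitmap), height = nrow(bitmap),
                 bitmap = bitmap,
                 pixel_area = sum(bitmap),
                 n_components = count_components(bitmap)),
            class = "instance_mask")
}

#' Pixel area of a mask
#' @param m An `instance_mask` or logical matrix.
#' @return Integer count of set pixels (0 for an all-clear mask).
#' @export
pixel_area <- function(m) {
  sum(.as_bitmap(m))
}

#' Label 8-connected foreground components
#'
#' Union-find over foreground pixels; diagonal contact joins components
#' (8-connectivity), so thin diagonal structures are not spuriously split.
#'
#' @param bitmap Logical matrix.
#' @return Integer matrix of the same shape: 0 = background, components
#'   numbered 1..k in first-encounter order.
#' @export
label_components <- function(bitmap) {
  bitmap <- .as_bitmap(bitmap)
  h <- nrow(bitmap); w <- ncol(bitmap)
  labels <- matrix(0L, h, w)
  fg <- which(bitmap)                       # column-major linear indices
  if (!length(fg)) return(labels)
  pos <- integer(h * w)
  pos[fg] <- seq_along(fg)
  parent <- seq_along(fg)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  # scan order is column-major, so union with the 4 already-seen neighbors
  for (k in seq_along(fg)) {
    r <- rows[k]; cc <- cols[k]
    for (d in 1:4) {
      rr <- r + c(-1L, -1L, 0L, 1L)[d]
      c2 <- cc + c(0L, -1L, -1L, -1L)[d]
      if (rr < 1L || rr > h || c2 < 1L || c2 > w) next
      if (!bitmap[rr, c2]) next
      a <- find(k); b <- find(pos[(c2 - 1L) * h + rr])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_along(fg), find, integer(1))
  labels[fg] <- match(roots, unique(roots))
  labels
}

#' Number of 8-connected foreground components
#' @param m An `instance_mask` or logical matrix.
#' @return Integer component count (0 for an empty mask).
#' @export
count_components <- function(m) {
  max(label_components(.as_bitmap(m)), 0L)
}

#' Write a binary mask as a single-channel PNG (0/255)
#' @param m An `instance_mask` or logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(m, path) {
  png::writePNG(.as_bitmap(m) * 1.0, path)
  invisible(path)
}

#' Read a single-channel PNG as a binary mask (nonzero = foreground)
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0
}

#' @export
print.instance_mask <- function(x, ...) {
  cat("<instance_mask> annotation ", format(x$annotation_id), ": ",
      x$width, "x", x$height, ", ", x$pixel_area, " px^2 in ",
      x$n_components, " component(s)\n", sep = "")
  invisible(x)
}

.as_bitmap <- function(m) {
  if (inherits(m, "instance_mask")) m$bitmap else m != 0
}
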