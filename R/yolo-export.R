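# Export of the QC-refined dataset to the YOLO segmentation layout.

#' Build or normalize an image-level split assignment
#'
#' @param x Data frame with columns `image_id` and `split` (values
#'   `"train"` / `"val"`), or a named character vector `image_id -> split`.
#' @return Data frame `image_id`, `split`, one row per image.
#' @export
split_assignment <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("image_id", "split") %in% names(x)))
    return(x[, c("image_id", "split")])
  }
  data.frame(image_id = as.numeric(names(x)), split = unname(x))
}

#' Seeded random image-level split
#'
#' Splits at the image level so that no frame contributes annotations to
#' both sets (information leakage across splits would inflate validation
#' scores).  Datasets that ship with a predefined split should use it
#' directly via [split_assignment()].
#'
#' @param ds A `coco_dataset`.
#' @param val_fraction Fraction of images assigned to `val`.  Default 0.2.
#' @param seed Integer seed.
#' @return Split-assignment data frame.
#' @export
random_split <- function(ds, val_fraction = 0.2, seed = 1) {
  stopifnot(val_fraction >= 0, val_fraction <= 1)
  ids <- ds$images$id
  n_val <- round(val_fraction * length(ids))
  val <- .with_seed(seed, sample(ids, n_val))
  data.frame(image_id = ids,
             split = ifelse(ids %in% val, "val", "train"))
}

#' Check that no image sits in more than one split
#'
#' @param split A split assignment (rows may repeat).
#' @return List: `ok` logical, `violations` vector of image ids assigned to
#'   more than one split.
#' @export
verify_split_disjoint <- function(split) {
  sp <- split_assignment(split)
  tab <- unique(sp)
  bad <- unique(tab$image_id[duplicated(tab$image_id)])
  list(ok = length(bad) == 0L, violations = bad)
}

#' Write YOLO segmentation label files
#'
#' One `labels/<split>/<image_stem>.txt` per image.  Each line is
#' `<class_index> x1 y1 x2 y2 ...` with coordinates divided by the image
#' width/height, clamped to `[0, 1]` and printed with 6 decimals; the class
#' index is the rank of the COCO category id in ascending order (0-based).
#' Images with no retained annotations get an empty label file, which YOLO
#' trainers treat as a background frame.  Multi-part annotations are
#' written as one line per part (the YOLO dialect has no native
#' multi-polygon instance); the per-part convention is recorded in the
#' returned summary.
#'
#' @param ds A QC-refined `coco_dataset`.
#' @param split A split assignment covering every image in `ds`.
#' @param out_root Output directory root.
#' @return Summary list: `n_images`, `n_label_files`, `n_lines` per split,
#'   `class_map` (data frame `category_id`, `class_index`, `name`),
#'   `multipart_policy`.
#' @export
export_yolo_labels <- function(ds, split, out_root) {
  sp <- split_assignment(split)
  chk <- verify_split_disjoint(sp)
  if (!chk$ok) {
    stop("split leakage: image(s) ", paste(chk$violations, collapse = ", "),
         " appear in more than one split", call. = FALSE)
  }
  cat_ids <- sort(ds$categories$id)
  class_map <- data.frame(category_id = cat_ids,
                          class_index = seq_along(cat_ids) - 1L,
                          name = ds$categories$name[match(cat_ids, ds$categories$id)])

  for (s in unique(sp$split)) {
    dir.create(file.path(out_root, "labels", s), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_root, "images", s), recursive = TRUE,
               showWarnings = FALSE)
  }

  by_image <- split(ds$annotations,
                    vapply(ds$annotations, function(a) a$image_id, numeric(1)))
  n_lines <- stats::setNames(integer(length(unique(sp$split))), unique(sp$split))
  n_files <- n_lines
  for (i in seq_len(nrow(ds$images))) {
    img <- ds$images[i, ]
    s <- sp$split[match(img$id, sp$image_id)]
    if (is.na(s)) stop("image ", img$id, " has no split assignment", call. = FALSE)
    if (is.na(img$width) || is.na(img$height)) {
      stop("image ", img$id, " lacks width/height", call. = FALSE)
    }
    anns <- by_image[[as.character(img$id)]]
    lines <- character(0)
    for (a in anns) {
      ci <- class_map$class_index[match(a$category_id, class_map$category_id)]
      if (is.na(ci)) stop("annotation ", a$id, " has unknown category ",
                          a$category_id, call. = FALSE)
      for (flat in a$segmentation) {
        p <- decode_segmentation(flat)
        xs <- pmin(pmax(p[, 1] / img$width, 0), 1)
        ys <- pmin(pmax(p[, 2] / img$height, 0), 1)
        coords <- sprintf("%.6f", as.vector(rbind(xs, ys)))
        lines <- c(lines, paste(c(ci, coords), collapse = " "))
      }
    }
    stem <- tools::file_path_sans_ext(basename(img$file_name))
    writeLines(lines, file.path(out_root, "labels", s, paste0(stem, ".txt")))
    n_files[s] <- n_files[s] + 1L
    n_lines[s] <- n_lines[s] + length(lines)
  }
  list(n_images = nrow(ds$images), n_label_files = n_files,
       n_lines = n_lines, class_map = class_map,
       multipart_policy = "one line per polygon part")
}

#' Write the YOLO dataset configuration file
#'
#' YAML config naming the train/val image directories, the class count
#' `nc`, and the class names in class-index order (ascending COCO
#' category id).
#'
#' @param ds A `coco_dataset`.
#' @param split A split assignment (unused beyond documenting the layout;
#'   present so configs are always written against an exported split).
#' @param out_root Output directory root; the file is `out_root/data.yaml`.
#' @return Path of the written config, invisibly.
#' @export
write_dataset_config <- function(ds, split, out_root) {
  cat_ids <- sort(ds$categories$id)
  cfg <- list(path = normalizePath(out_root, mustWork = FALSE),
              train = "images/train",
              val = "images/val",
              nc = length(cat_ids),
              names = as.list(ds$categories$name[match(cat_ids, ds$categories$id)]))
  path <- file.path(out_root, "data.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Parse YOLO label lines back into pixel coordinates
#'
#' Inverse of [export_yolo_labels()] for round-trip checks: de-normalizes
#' by the image size.
#'
#' @param lines Character vector of label lines.
#' @param width,height Image size in px.
#' @return List of lists: `class_index`, `vertices` (n x 2 matrix).
#' @export
parse_yolo_labels <- function(lines, width, height) {
  lapply(lines, function(ln) {
    tok <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    v <- matrix(tok[-1], ncol = 2, byrow = TRUE)
    list(class_index = as.integer(tok[1]),
         vertices = cbind(x = v[, 1] * width, y = v[, 2] * height))
  })
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
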