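# COCO instance-segmentation JSON: parsing, integrity checks, serialization.

#' Parse a COCO instance-segmentation dataset from JSON text
#'
#' Reads the standard COCO dialect (`images`, `annotations`, `categories`
#' arrays) into an in-memory dataset with referential integrity enforced at
#' parse time.  Annotations with a missing or empty `segmentation` key are
#' retained here and flagged later by [validate_dataset()]; RLE-encoded
#' segmentations are likewise kept and rejected downstream with the
#' `UNSUPPORTED_RLE` reason code.  Extra COCO fields (`area`, `bbox`,
#' `iscrowd`, top-level `info`/`licenses`, ...) are preserved opaquely and
#' re-emitted by [serialize_dataset()]; the QC pipeline recomputes pixel
#' area itself and never trusts a stored `area`.
#'
#' @param json_text Length-one character vector holding COCO JSON.
#' @return A `coco_dataset`: list with `images` and `categories` data frames
#'   (`id`, `file_name`, `width`, `height` / `id`, `name`), an `annotations`
#'   list of records (`id`, `image_id`, `category_id`, `segmentation` as a
#'   list of flat numeric vectors or `NULL` when absent, plus opaque
#'   `extra` fields), and `extra` top-level members.
#' @seealso [read_coco()], [serialize_dataset()], [validate_dataset()]
#' @export
#' @examples
#' js <- '{"images":[{"id":1,"file_name":"a.png","width":10,"height":10}],
#'   "annotations":[{"id":1,"image_id":1,"category_id":1,
#'      "segmentation":[[1,1,9,1,9,9,1,9]]}],
#'   "categories":[{"id":1,"name":"lesion"}]}'
#' ds <- parse_dataset(js)
#' coco_counts(ds)
parse_dataset <- function(json_text) {
  stopifnot(is.character(json_text), length(json_text) == 1L)
  raw <- tryCatch(
    jsonlite::fromJSON(json_text, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON: ", conditionMessage(e), call. = FALSE)
  )
  for (key in c("images", "annotations", "categories")) {
    if (is.null(raw[[key]])) {
      stop("COCO schema error: missing top-level key '", key, "'", call. = FALSE)
    }
  }

  images <- .coco_table(raw$images, "image",
                        required = c("id", "file_name", "width", "height"))
  categories <- .coco_table(raw$categories, "category",
                            required = c("id", "name"))
  annotations <- lapply(raw$annotations, .coco_annotation)

  .check_unique_ids(images$id, "image")
  .check_unique_ids(categories$id, "category")
  ann_ids <- vapply(annotations, function(a) a$id, numeric(1))
  .check_unique_ids(ann_ids, "annotation")

  bad_w <- images$width < 1 | images$height < 1
  if (any(bad_w)) {
    stop("integrity error: image id ", images$id[which(bad_w)[1]],
         " has non-positive width/height", call. = FALSE)
  }
  for (a in annotations) {
    if (!a$image_id %in% images$id) {
      stop("integrity error: annotation ", a$id,
           " references missing image id ", a$image_id, call. = FALSE)
    }
    if (!a$category_id %in% categories$id) {
      stop("integrity error: annotation ", a$id,
           " references missing category id ", a$category_id, call. = FALSE)
    }
  }

  extra <- raw[setdiff(names(raw), c("images", "annotations", "categories"))]
  structure(list(images = images, annotations = annotations,
                 categories = categories, extra = extra),
            class = "coco_dataset")
}

#' Read a COCO dataset from a file or a directory of JSON files
#'
#' When `path` is a directory every `*.json` file inside is parsed and the
#' records merged; id collisions across files are integrity errors, never
#' silently renumbered.
#'
#' @param path A COCO JSON file, or a directory containing such files.
#' @return A `coco_dataset`.
#' @export
read_coco <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
    if (!length(files)) stop("no .json files found in ", path, call. = FALSE)
    parts <- lapply(files, function(f) parse_dataset(.read_utf8(f)))
    return(.merge_coco(parts))
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  parse_dataset(.read_utf8(path))
}

#' Serialize a COCO dataset back to JSON text
#'
#' Inverse of [parse_dataset()]: `parse_dataset(serialize_dataset(ds))`
#' reproduces `ds` record for record (field order is not guaranteed).
#' Opaque extra fields captured at parse time are re-emitted.
#'
#' @param ds A `coco_dataset`.
#' @param pretty Pretty-print the JSON? Default `FALSE`.
#' @return Length-one character vector of JSON.
#' @export
serialize_dataset <- function(ds, pretty = FALSE) {
  stopifnot(inherits(ds, "coco_dataset"))
  imgs <- .rows_to_records(ds$images, attr(ds$images, "coco_extra"))
  cats <- .rows_to_records(ds$categories, attr(ds$categories, "coco_extra"))
  anns <- lapply(ds$annotations, function(a) {
    rec <- list(id = a$id, image_id = a$image_id, category_id = a$category_id)
    if (!is.null(a$segmentation)) {
      rec$segmentation <- if (isTRUE(a$rle)) a$segmentation else
        lapply(a$segmentation, function(p) as.list(p))
    }
    c(rec, a$extra)
  })
  body <- c(list(images = imgs, annotations = anns, categories = cats), ds$extra)
  as.character(jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = pretty))
}

#' Write a COCO dataset to a JSON file
#' @param ds A `coco_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(ds, path) {
  writeLines(serialize_dataset(ds), path, useBytes = TRUE)
  invisible(path)
}

#' Record counts of a COCO dataset
#' @param ds A `coco_dataset`.
#' @return Named integer vector: `images`, `annotations`, `categories`.
#' @export
coco_counts <- function(ds) {
  c(images = nrow(ds$images), annotations = length(ds$annotations),
    categories = nrow(ds$categories))
}

#' Keep only a given set of annotations
#'
#' Used to materialize the QC-refined dataset: images and categories are
#' untouched, annotations outside `keep_ids` are dropped.
#'
#' @param ds A `coco_dataset`.
#' @param keep_ids Annotation ids to retain.
#' @return A `coco_dataset`.
#' @export
subset_annotations <- function(ds, keep_ids) {
  ds$annotations <- Filter(function(a) a$id %in% keep_ids, ds$annotations)
  ds
}

#' @export
print.coco_dataset <- function(x, ...) {
  n <- coco_counts(x)
  cat("<coco_dataset> ", n["images"], " images, ", n["annotations"],
      " annotations, ", n["categories"], " categories\n", sep = "")
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

.read_utf8 <- function(path) {
  paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
}

.coco_table <- function(records, what, required) {
  if (!length(records)) {
    df <- as.data.frame(stats::setNames(rep(list(vector("numeric", 0)),
                                            length(required)), required))
    if ("file_name" %in% required) df$file_name <- character(0)
    if ("name" %in% required) df$name <- character(0)
    attr(df, "coco_extra") <- list()
    return(df)
  }
  for (i in seq_along(records)) {
    miss <- setdiff(required, names(records[[i]]))
    if (length(miss)) {
      stop("COCO schema error: ", what, " record ", i,
           " lacks field '", miss[1], "'", call. = FALSE)
    }
  }
  df <- do.call(rbind, lapply(records, function(r) {
    as.data.frame(r[required], stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  attr(df, "coco_extra") <- lapply(records, function(r) {
    ex <- r[setdiff(names(r), required)]
    if (length(ex)) ex else list()
  })
  df
}

.coco_annotation <- function(r) {
  for (f in c("id", "image_id", "category_id")) {
    if (is.null(r[[f]])) {
      stop("COCO schema error: annotation lacks field '", f, "'", call. = FALSE)
    }
  }
  seg <- r$segmentation
  rle <- FALSE
  if (!is.null(seg)) {
    if (!is.null(names(seg)) && "counts" %in% names(seg)) {
      rle <- TRUE                       # RLE dict kept verbatim
    } else {
      seg <- lapply(seg, function(p) as.numeric(unlist(p)))
    }
  }
  extra <- r[setdiff(names(r), c("id", "image_id", "category_id", "segmentation"))]
  if (!length(extra)) extra <- list()
  list(id = r$id, image_id = r$image_id, category_id = r$category_id,
       segmentation = seg, rle = rle, extra = extra)
}

.check_unique_ids <- function(ids, what) {
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("integrity error: duplicate ", what, " id ", dup[1], call. = FALSE)
  }
}

.rows_to_records <- function(df, extras) {
  lapply(seq_len(nrow(df)), function(i) {
    rec <- as.list(df[i, , drop = FALSE])
    names(rec) <- names(df)
    ex <- if (!is.null(extras) && length(extras) >= i) extras[[i]] else NULL
    c(rec, ex)
  })
}

.merge_coco <- function(parts) {
  merged <- parts[[1]]
  for (p in parts[-1]) {
    merged$images <- rbind(merged$images, p$images)
    attr(merged$images, "coco_extra") <-
      c(attr(parts[[1]]$images, "coco_extra"), attr(p$images, "coco_extra"))
    merged$categories <- rbind(merged$categories, p$categories)
    merged$categories <- unique(merged$categories)
    rownames(merged$categories) <- NULL
    merged$annotations <- c(merged$annotations, p$annotations)
  }
  .check_unique_ids(merged$images$id, "image")
  .check_unique_ids(merged$categories$id, "category")
  .check_unique_ids(vapply(merged$annotations, function(a) a$id, numeric(1)),
                    "annotation")
  merged
}
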