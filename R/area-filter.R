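# Area-threshold noise suppression, area statistics, sensitivity analysis,
# and the QC accounting report.

#' Pixel-area records for the annotations that passed validation
#'
#' Rasterizes every VALID annotation at native resolution and measures its
#' pixel area — the area used by the noise filter (the stored COCO `area`
#' field is never trusted).
#'
#' @param ds A `coco_dataset`.
#' @param verdicts Result of [validate_dataset()] on `ds`.
#' @return Data frame: `annotation_id`, `image_id`, `pixel_area`.
#' @export
area_records <- function(ds, verdicts) {
  keep <- verdicts$annotation_id[verdicts$valid]
  anns <- Filter(function(a) a$id %in% keep, ds$annotations)
  rows <- lapply(anns, function(a) {
    img <- ds$images[ds$images$id == a$image_id, , drop = FALSE]
    m <- rasterize_annotation(a, img)
    data.frame(annotation_id = a$id, image_id = a$image_id,
               pixel_area = m$pixel_area)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(annotation_id = numeric(0), image_id = numeric(0),
                      pixel_area = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Split records by a minimum pixel-area threshold
#'
#' Strict inequality: an instance is removed iff `pixel_area < threshold`,
#' so an area exactly at the threshold is kept.  `kept` and `removed`
#' partition the input.
#'
#' @param records Data frame with a `pixel_area` column (see [area_records()]).
#' @param threshold Minimum area in px^2 (>= 0).  Default 700.
#' @return List with data frames `kept` and `removed` and the `threshold`.
#' @export
#' @examples
#' rec <- data.frame(annotation_id = 1:3, image_id = 1,
#'                   pixel_area = c(100, 700, 1200))
#' apply_area_filter(rec, 700)$removed$annotation_id  # 1
apply_area_filter <- function(records, threshold = 700) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("threshold must be a single non-negative number", call. = FALSE)
  }
  drop <- records$pixel_area < threshold
  list(kept = records[!drop, , drop = FALSE],
       removed = records[drop, , drop = FALSE],
       threshold = threshold)
}

#' Sensitivity of annotation retention to the area threshold
#'
#' One row per candidate threshold, each consistent with
#' [apply_area_filter()] at that threshold.  The population size is
#' attached (`attr(x, "population")`) and printed, because removal
#' percentages are only meaningful relative to the annotation set they
#' were computed on.
#'
#' @param records Area records (post-validation annotations).
#' @param thresholds Candidate thresholds in px^2.  Default
#'   `c(300, 500, 700, 1000)`.
#' @return Data frame: `threshold`, `removed`, `retained`, `removed_pct`
#'   (rounded half-up to 2 decimals).
#' @export
sensitivity_analysis <- function(records, thresholds = c(300, 500, 700, 1000)) {
  stopifnot(length(thresholds) >= 1L)
  rows <- lapply(sort(thresholds), function(t) {
    f <- apply_area_filter(records, t)
    sensitivity_row(t, nrow(f$removed), nrow(f$kept))
  })
  out <- do.call(rbind, rows)
  attr(out, "population") <- nrow(records)
  out
}

#' One sensitivity-table row from removed/retained counts
#'
#' `removed_pct = round(100 * removed / (removed + retained), 2)`,
#' rounded half-up for display (full precision is a division away).
#'
#' @param threshold Threshold in px^2.
#' @param removed,retained Annotation counts at that threshold.
#' @return One-row data frame: `threshold`, `removed`, `retained`,
#'   `removed_pct`.
#' @export
sensitivity_row <- function(threshold, removed, retained) {
  data.frame(threshold = threshold, removed = removed, retained = retained,
             removed_pct = round_half_up(100 * removed / (removed + retained), 2))
}

#' Area-distribution summary statistics
#'
#' The annotated-area distribution of real datasets is strongly
#' right-skewed, so the summary reports the median alongside the mean, the
#' 2nd percentile (a natural anchor for a noise threshold), and a
#' log10-scale histogram of the positive areas.
#'
#' Percentiles use linear interpolation between closest ranks (the
#' widespread "type 7" convention), documented so figures derived from it
#' can be cross-checked.
#'
#' @param areas Numeric vector of pixel areas, or a data frame with a
#'   `pixel_area` column.  Must be non-empty.
#' @return An `area_stats` list: `n`, `mean`, `median`, `percentile_2`,
#'   `histogram` (list of `breaks` and `counts` on the log10 scale).
#' @export
area_statistics <- function(areas) {
  if (is.data.frame(areas)) areas <- areas$pixel_area
  areas <- as.numeric(areas)
  if (!length(areas)) stop("area_statistics needs at least one area", call. = FALSE)
  pos <- areas[areas > 0]
  hg <- if (length(pos)) {
    h <- graphics::hist(log10(pos), plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  } else {
    list(breaks = numeric(0), counts = integer(0))
  }
  structure(list(n = length(areas),
                 mean = mean(areas),
                 median = stats::median(areas),
                 percentile_2 = unname(stats::quantile(areas, 0.02, type = 7)),
                 histogram = hg),
            class = "area_stats")
}

#' @export
print.area_stats <- function(x, ...) {
  cat("Area distribution (n = ", x$n, ")\n",
      "  mean:   ", format(x$mean, big.mark = ","), " px^2\n",
      "  median: ", format(x$median, big.mark = ","), " px^2\n",
      "  2nd percentile: ", format(x$percentile_2, big.mark = ","),
      " px^2\n", sep = "")
  invisible(x)
}

#' QC accounting report (raw / removed / retained)
#'
#' Accounts for every annotation exactly once: removed as structurally
#' invalid, removed as sub-threshold small, or retained.  Validation and
#' area filtering are disjoint by construction — the filter only ever sees
#' annotations that passed validation — so
#' `raw == removed_invalid + removed_small + final_retained` must hold, and
#' the constructor errors if the inputs break that conservation.
#'
#' @param verdicts Result of [validate_dataset()].
#' @param filtered Result of [apply_area_filter()] on the matching
#'   [area_records()].
#' @param split Optional split assignment (see [split_assignment()]): adds
#'   a per-split breakdown whose rows sum to the totals.
#' @param total_frames Optional frame count for the report header; taken
#'   from the split assignment when absent.
#' @return A `qc_report` list: `total_frames`, `total_annotations_raw`,
#'   `removed_invalid`, `removed_small`, `total_removed`,
#'   `final_retained`, and optionally `per_split` (data frame).
#' @export
build_qc_report <- function(verdicts, filtered, split = NULL,
                            total_frames = NA_integer_) {
  kept_ids <- filtered$kept$annotation_id
  rem_ids <- filtered$removed$annotation_id
  if (length(intersect(kept_ids, rem_ids))) {
    stop("integrity error: annotation ", intersect(kept_ids, rem_ids)[1],
         " appears in both kept and removed", call. = FALSE)
  }
  valid_ids <- verdicts$annotation_id[verdicts$valid]
  if (!setequal(c(kept_ids, rem_ids), valid_ids)) {
    stop("integrity error: filter result does not cover exactly the ",
         "validation-passing annotations", call. = FALSE)
  }

  report <- qc_counts(raw = nrow(verdicts),
                      invalid = sum(!verdicts$valid),
                      small = length(rem_ids))
  report$total_frames <- total_frames
  report$reason_counts <- table(factor(verdicts$reason, levels = VALIDATION_REASONS))

  if (!is.null(split)) {
    sp <- split_assignment(split)
    if (is.na(total_frames)) report$total_frames <- nrow(sp)
    ann_split <- sp$split[match(verdicts$image_id, sp$image_id)]
    rows <- lapply(unique(sp$split), function(s) {
      v <- verdicts[!is.na(ann_split) & ann_split == s, , drop = FALSE]
      small <- sum(rem_ids %in% v$annotation_id)
      cbind(data.frame(split = s),
            as.data.frame(qc_counts(nrow(v), sum(!v$valid), small)[
              c("total_annotations_raw", "removed_invalid", "removed_small",
                "total_removed", "final_retained")]))
    })
    report$per_split <- do.call(rbind, rows)
  }
  structure(report, class = "qc_report")
}

#' QC arithmetic from bare counts
#'
#' The conservation arithmetic of the refinement report, usable on its own
#' (e.g. to check a published summary table): total removed is the sum of
#' the two disjoint removal classes, and what is not removed is retained.
#'
#' @param raw Total annotations before QC.
#' @param invalid Annotations removed by polygon validation.
#' @param small Annotations removed by the area filter.
#' @return List: `total_annotations_raw`, `removed_invalid`,
#'   `removed_small`, `total_removed`, `final_retained`.
#' @export
#' @examples
#' qc_counts(raw = 4526, invalid = 1551, small = 31)$final_retained  # 2944
qc_counts <- function(raw, invalid, small) {
  stopifnot(raw >= 0, invalid >= 0, small >= 0, invalid + small <= raw)
  list(total_annotations_raw = raw,
       removed_invalid = invalid,
       removed_small = small,
       total_removed = invalid + small,
       final_retained = raw - invalid - small)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Annotation refinement summary\n")
  if (!is.na(x$total_frames)) cat("  Total frames             ", x$total_frames, "\n")
  cat("  Total annotations (raw)  ", x$total_annotations_raw, "\n")
  cat("  Removed invalid polygons ", x$removed_invalid, "\n")
  cat("  Removed small masks      ", x$removed_small, "\n")
  cat("  Total removed (QC)       ", x$total_removed, "\n")
  cat("  Final annotations        ", x$final_retained, "\n")
  if (!is.null(x$per_split)) {
    cat("Per split:\n")
    print(x$per_split, row.names = FALSE)
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Display rounding for report percentages: 0.625 -> 0.63 at two decimals
#' (base `round()` rounds half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Run the full QC pipeline on a dataset
#'
#' Validation -> native-resolution rasterization -> area filtering ->
#' accounting, returning every intermediate product plus the cleaned
#' dataset (retained annotations only).
#'
#' @param ds A `coco_dataset`.
#' @param cfg A [validation_config()].
#' @param threshold Minimum pixel area in px^2 (default 700).
#' @param split Optional split assignment for the per-split report.
#' @return List: `verdicts`, `areas`, `filtered`, `report`, `cleaned`.
#' @export
qc_pipeline <- function(ds, cfg = validation_config(), threshold = 700,
                        split = NULL) {
  verdicts <- validate_dataset(ds, cfg)
  areas <- area_records(ds, verdicts)
  filtered <- apply_area_filter(areas, threshold)
  report <- build_qc_report(verdicts, filtered, split = split,
                            total_frames = nrow(ds$images))
  cleaned <- subset_annotations(ds, filtered$kept$annotation_id)
  list(verdicts = verdicts, areas = areas, filtered = filtered,
       report = report, cleaned = cleaned)
}
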