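records <- function(areas) {
  data.frame(annotation_id = seq_along(areas), image_id = 1L,
             pixel_area = areas)
}

test_that("area filter removes strictly-below-threshold records and partitions input", {
  rec <- records(c(a = 100, b = 700, c = 1200))
  f <- apply_area_filter(rec, 700)
  expect_equal(f$removed$annotation_id, 1L)           # 100 only
  expect_equal(sort(f$kept$annotation_id), c(2L, 3L)) # boundary 700 kept
  expect_equal(nrow(apply_area_filter(rec, 0)$removed), 0L)
  all_small <- apply_area_filter(records(c(1, 2, 3)), 10)
  expect_equal(nrow(all_small$kept), 0L)
  expect_equal(nrow(all_small$removed), 3L)
  expect_error(apply_area_filter(rec, -1), "non-negative")

  # partition + monotonicity over random inputs and thresholds
  set.seed(5)
  areas <- sample.int(2000, 300, replace = TRUE)
  rec <- records(areas)
  prev <- integer(0)
  for (t in c(0, 50, 300, 700, 1500, 2500)) {
    f <- apply_area_filter(rec, t)
    expect_setequal(c(f$kept$annotation_id, f$removed$annotation_id),
                    rec$annotation_id)
    expect_equal(nrow(f$kept) + nrow(f$removed), nrow(rec))
    expect_true(all(prev %in% f$removed$annotation_id))  # removed sets nest
    prev <- f$removed$annotation_id
  }
})

test_that("sensitivity table rows agree with the filter and carry the population", {
  set.seed(6)
  rec <- records(sample.int(1500, 200, replace = TRUE))
  tab <- sensitivity_analysis(rec, c(1000, 300, 700, 500))
  expect_equal(tab$threshold, c(300, 500, 700, 1000))
  expect_true(all(diff(tab$removed) >= 0))
  expect_true(all(tab$removed + tab$retained == nrow(rec)))
  expect_equal(attr(tab, "population"), nrow(rec))
  for (i in seq_len(nrow(tab))) {
    f <- apply_area_filter(rec, tab$threshold[i])
    expect_equal(tab$removed[i], nrow(f$removed))
    expect_equal(tab$removed_pct[i],
                 round_half_up(100 * nrow(f$removed) / nrow(rec), 2))
  }
})

test_that("published-style removal percentages reproduce from counts", {
  expect_equal(sensitivity_row(300, 3, 3662)$removed_pct, 0.08)
  expect_equal(sensitivity_row(500, 9, 3656)$removed_pct, 0.25)
  expect_equal(sensitivity_row(700, 23, 3642)$removed_pct, 0.63)
  expect_equal(sensitivity_row(1000, 77, 3588)$removed_pct, 2.10)
})

test_that("area statistics use type-7 percentiles and a log10 histogram", {
  s <- area_statistics(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  # rank position 0.02 * (4 - 1) = 0.06 above the minimum
  s2 <- area_statistics(c(100, 200, 300, 400))
  expect_equal(s2$percentile_2, 106.0)
  s3 <- area_statistics(50)
  expect_equal(s3$mean, 50)
  expect_equal(s3$median, 50)
  expect_equal(s3$percentile_2, 50)
  expect_error(area_statistics(numeric(0)), "at least one")

  set.seed(9)
  areas <- round(rlnorm(500, log(15000), 1))
  st <- area_statistics(areas)
  expect_equal(st$n, 500)
  expect_true(st$percentile_2 >= min(areas) && st$percentile_2 <= max(areas))
  expect_true(st$median >= min(areas) && st$median <= max(areas))
  expect_equal(sum(st$histogram$counts), sum(areas > 0))
})

test_that("QC report conserves annotations and errors on inconsistent inputs", {
  gen <- generate_dataset(defect_spec(seed = 13))
  res <- qc_pipeline(gen$dataset, threshold = 700)
  rep <- res$report
  expect_equal(rep$total_removed, rep$removed_invalid + rep$removed_small)
  expect_equal(rep$final_retained,
               rep$total_annotations_raw - rep$total_removed)
  inj <- table(gen$manifest$label)
  expect_equal(rep$removed_small, unname(inj[["SMALL"]]))
  expect_equal(rep$final_retained, unname(inj[["VALID"]]))
  expect_equal(length(res$cleaned$annotations), rep$final_retained)

  # zero removals: final == raw
  clean <- generate_dataset(defect_spec(n_empty = 0, n_too_few = 0,
                                        n_out_of_bounds = 0, n_degenerate = 0,
                                        n_self_intersecting = 0, n_small = 0,
                                        seed = 14))
  rep0 <- qc_pipeline(clean$dataset, threshold = 700)$report
  expect_equal(rep0$total_removed, 0)
  expect_equal(rep0$final_retained, rep0$total_annotations_raw)

  # an annotation in both kept and removed is an integrity error
  broken <- res$filtered
  broken$removed <- rbind(broken$removed, broken$kept[1, ])
  expect_error(build_qc_report(res$verdicts, broken), "integrity")
})

test_that("per-split report rows sum to the totals", {
  gen <- generate_dataset(defect_spec(seed = 21))
  split <- random_split(gen$dataset, val_fraction = 0.25, seed = 3)
  res <- qc_pipeline(gen$dataset, threshold = 700, split = split)
  ps <- res$report$per_split
  expect_setequal(ps$split, c("train", "val"))
  for (col in c("total_annotations_raw", "removed_invalid", "removed_small",
                "total_removed", "final_retained")) {
    expect_equal(sum(ps[[col]]), res$report[[col]], info = col)
  }
  expect_true(all(ps$total_annotations_raw ==
                    ps$total_removed + ps$final_retained))
})

test_that("QC count arithmetic holds on published summary numbers", {
  qc <- qc_counts(raw = 4526, invalid = 1551, small = 31)
  expect_equal(qc$total_removed, 1582)
  expect_equal(qc$final_retained, 2944)
  expect_error(qc_counts(10, 8, 3))
})
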