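test_that("decode_segmentation pairs coordinates and rejects odd lengths", {
  tri <- decode_segmentation(c(0, 0, 4, 0, 0, 3))
  expect_equal(nrow(tri), 3L)
  expect_equal(tri[2, ], c(x = 4, y = 0))
  expect_equal(nrow(decode_segmentation(numeric(0))), 0L)
  expect_error(decode_segmentation(c(0, 0, 4)), "odd")
})

test_that("shoelace area matches closed forms and is orientation-invariant", {
  sq <- decode_segmentation(c(0, 0, 1, 0, 1, 1, 0, 1))
  expect_equal(shoelace_area(sq), 1.0)
  expect_equal(shoelace_area(decode_segmentation(c(0, 0, 4, 0, 0, 3))), 6.0)
  expect_equal(shoelace_area(decode_segmentation(c(0, 0, 1, 1, 2, 2))), 0.0)
  expect_error(shoelace_area(decode_segmentation(c(0, 0, 1, 1))), "3 vertices")

  set.seed(42)
  for (i in 1:25) {
    p <- random_convex_polygon(30, 30)
    a <- shoelace_area(p)
    expect_equal(shoelace_area(p[rev(seq_len(nrow(p))), ]), a)   # reversal
    rot <- p[c(3:nrow(p), 1:2), ]                                # rotation
    expect_equal(shoelace_area(rot), a)
  }
})

test_that("self-intersection matches canonical cases", {
  expect_true(is_self_intersecting(decode_segmentation(c(0, 0, 2, 2, 2, 0, 0, 2))))
  expect_false(is_self_intersecting(decode_segmentation(c(0, 0, 2, 0, 2, 2, 0, 2))))
  # any triangle with positive area is simple
  set.seed(1)
  for (i in 1:20) {
    tri <- random_grid_polygon(3)
    if (nrow(tri) < 3 || shoelace_area(tri) == 0) next
    expect_false(is_self_intersecting(tri))
  }
  # a vertex lying strictly inside a non-incident edge counts
  spike <- decode_segmentation(c(0, 0, 10, 0, 10, 10, 5, 0, 0, 10))
  expect_true(is_self_intersecting(spike))
  # vertex-vertex contact alone does not
  touch <- decode_segmentation(c(0, 0, 4, 0, 4, 4, 0, 0, -4, 0, -4, 4))
  expect_true(is_self_intersecting(touch) == oracle_self_intersecting(touch))
})

test_that("self-intersection agrees with the parametric all-pairs oracle", {
  set.seed(77)
  n_checked <- 0L
  while (n_checked < 400L) {
    p <- random_grid_polygon(sample(4:12, 1))
    if (nrow(p) < 4) next
    expect_equal(is_self_intersecting(p), oracle_self_intersecting(p),
                 info = paste(t(p), collapse = ","))
    n_checked <- n_checked + 1L
  }
})

test_that("validation applies checks in fixed first-failure order", {
  img <- data.frame(id = 1, file_name = "a.png", width = 100, height = 100)
  ann <- function(seg, id = 1, extra = list()) {
    list(id = id, image_id = 1, category_id = 1, segmentation = seg,
         rle = FALSE, extra = extra)
  }
  verdict <- function(a) validate_annotation(a, img)$reason

  expect_equal(verdict(ann(NULL)), "INVALID_EMPTY")
  expect_equal(verdict(ann(list())), "INVALID_EMPTY")
  expect_equal(verdict(ann(list(c(0, 0, 5)))), "INVALID_ODD_COORDS")
  expect_equal(verdict(ann(list(c(0, 0, 5, 5)))), "INVALID_TOO_FEW_VERTICES")
  expect_equal(verdict(ann(list(c(-5, 10, 20, 10, 20, 20)))),
               "INVALID_OUT_OF_BOUNDS")
  # side-0.5 square: analytic area 0.25 < epsilon 1.0
  expect_equal(verdict(ann(list(c(2, 2, 2.5, 2, 2.5, 2.5, 2, 2.5)))),
               "INVALID_DEGENERATE_AREA")
  # crossed quadrilateral with unequal lobes (nonzero analytic area, so the
  # degenerate-area check passes and self-intersection is what fires)
  expect_equal(verdict(ann(list(c(0, 0, 20, 0, 6, 16, 14, 16)))),
               "INVALID_SELF_INTERSECTING")
  # the symmetric bow-tie cancels to zero analytic area, so the earlier
  # degeneracy check claims it first
  expect_equal(verdict(ann(list(c(0, 0, 20, 20, 20, 0, 0, 20)))),
               "INVALID_DEGENERATE_AREA")
  expect_equal(verdict(ann(list(c(10, 10, 40, 10, 40, 40, 10, 40)))), "VALID")

  # out-of-bounds beats degenerate area (earlier check wins)
  expect_equal(verdict(ann(list(c(-1, 0, -0.5, 0, -0.5, 0.5, -1, 0.5)))),
               "INVALID_OUT_OF_BOUNDS")
  # coordinates exactly at the image extent pass
  expect_equal(verdict(ann(list(c(0, 0, 100, 0, 100, 100, 0, 100)))), "VALID")
  # RLE / iscrowd rejected with a dedicated code
  rle <- ann(list())
  rle$segmentation <- list(counts = "abc", size = c(100, 100))
  rle$rle <- TRUE
  expect_equal(verdict(rle), "UNSUPPORTED_RLE")
  expect_equal(verdict(ann(list(c(10, 10, 40, 10, 40, 40, 10, 40)),
                           extra = list(iscrowd = 1))), "UNSUPPORTED_RLE")
})

test_that("multi-part strictness, closing-vertex handling and config knobs", {
  img <- data.frame(id = 1, file_name = "a.png", width = 100, height = 100)
  good <- c(10, 10, 40, 10, 40, 40, 10, 40)
  two_part <- list(id = 1, image_id = 1, category_id = 1,
                   segmentation = list(good, c(1, 1, 3, 3)),
                   rle = FALSE, extra = list())
  expect_equal(validate_annotation(two_part, img)$reason,
               "INVALID_TOO_FEW_VERTICES")

  # a duplicated closing vertex is dropped before vertex counting:
  # closed triangle stays a triangle, closed 3-point ring is too few
  closed_tri <- list(id = 1, image_id = 1, category_id = 1,
                     segmentation = list(c(10, 10, 50, 10, 30, 40, 10, 10)),
                     rle = FALSE, extra = list())
  expect_equal(validate_annotation(closed_tri, img)$reason, "VALID")
  closed_seg <- list(id = 1, image_id = 1, category_id = 1,
                     segmentation = list(c(10, 10, 50, 10, 10, 10)),
                     rle = FALSE, extra = list())
  expect_equal(validate_annotation(closed_seg, img)$reason,
               "INVALID_TOO_FEW_VERTICES")

  # self-intersection screening can be switched off
  bowtie <- list(id = 1, image_id = 1, category_id = 1,
                 segmentation = list(c(0, 0, 20, 0, 6, 16, 14, 16)),
                 rle = FALSE, extra = list())
  cfg_off <- validation_config(check_self_intersection = FALSE)
  expect_equal(validate_annotation(bowtie, img, cfg_off)$reason, "VALID")
  # bounds tolerance admits slightly out-of-frame vertices
  oob <- list(id = 1, image_id = 1, category_id = 1,
              segmentation = list(c(-0.4, 10, 40, 10, 40, 40, -0.4, 40)),
              rle = FALSE, extra = list())
  expect_equal(validate_annotation(oob, img)$reason, "INVALID_OUT_OF_BOUNDS")
  expect_equal(validate_annotation(
    oob, img, validation_config(bounds_tolerance = 0.5))$reason, "VALID")
})

test_that("dataset validation is order-preserving, deterministic, manifest-exact", {
  gen <- generate_dataset(defect_spec(seed = 31))
  v1 <- validate_dataset(gen$dataset)
  v2 <- validate_dataset(gen$dataset)
  expect_identical(v1, v2)
  expect_equal(v1$annotation_id,
               vapply(gen$dataset$annotations, function(a) a$id, numeric(1)))

  injected <- table(gen$manifest$label)
  got <- table(v1$reason)
  expect_equal(unname(got[["INVALID_EMPTY"]]), unname(injected[["EMPTY"]]))
  expect_equal(unname(got[["INVALID_TOO_FEW_VERTICES"]]),
               unname(injected[["TOO_FEW"]]))
  expect_equal(unname(got[["INVALID_OUT_OF_BOUNDS"]]),
               unname(injected[["OUT_OF_BOUNDS"]]))
  expect_equal(unname(got[["INVALID_DEGENERATE_AREA"]]),
               unname(injected[["DEGENERATE"]]))
  expect_equal(unname(got[["INVALID_SELF_INTERSECTING"]]),
               unname(injected[["SELF_INTERSECTING"]]))
  # SMALL instances pass validation; they fall to the area filter
  expect_equal(unname(got[["VALID"]]),
               unname(injected[["VALID"]] + injected[["SMALL"]]))
})
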