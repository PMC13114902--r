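# Shared fixtures and independent oracles.  Oracles are deliberately
# written with different algorithms than the package code they check.

minimal_coco_json <- function() {
  paste0('{"images":[{"id":1,"file_name":"a.png","width":10,"height":10}],',
         '"annotations":[{"id":1,"image_id":1,"category_id":1,',
         '"segmentation":[[1,1,9,1,9,9,1,9]]}],',
         '"categories":[{"id":1,"name":"landmark"}]}')
}

# Build COCO JSON text from bare R lists (independent of serialize_dataset).
coco_json_from_lists <- function(images, annotations, categories, extra = NULL) {
  body <- c(list(images = images, annotations = annotations,
                 categories = categories), extra)
  as.character(jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA))
}

# Random simple-ish polygon on an integer grid: distinct vertices, may or
# may not self-intersect.
random_grid_polygon <- function(n, grid = 15L) {
  pts <- unique(cbind(sample.int(grid, n * 3, replace = TRUE),
                      sample.int(grid, n * 3, replace = TRUE)))
  pts[seq_len(min(n, nrow(pts))), , drop = FALSE]
}

# --- oracle: pairwise segment intersection via parametric line solve ------
# Counts proper crossings and endpoints strictly interior to the other
# segment; endpoint-endpoint contact does not count.
oracle_segment_pair <- function(a, b, cc, d) {
  den <- (b[1] - a[1]) * (d[2] - cc[2]) - (b[2] - a[2]) * (d[1] - cc[1])
  if (den != 0) {
    t <- ((cc[1] - a[1]) * (d[2] - cc[2]) - (cc[2] - a[2]) * (d[1] - cc[1])) / den
    u <- ((cc[1] - a[1]) * (b[2] - a[2]) - (cc[2] - a[2]) * (b[1] - a[1])) / den
    if (t < 0 || t > 1 || u < 0 || u > 1) return(FALSE)
    t_in <- t > 0 && t < 1
    u_in <- u > 0 && u < 1
    return((t_in && u_in) || (t_in && !u_in) || (u_in && !t_in))
  }
  collin <- function(p, q, z) {
    (q[1] - p[1]) * (z[2] - p[2]) - (q[2] - p[2]) * (z[1] - p[1]) == 0
  }
  between <- function(p, q, z) {
    collin(p, q, z) &&
      ((p[1] != q[1] && z[1] > min(p[1], q[1]) && z[1] < max(p[1], q[1])) ||
         (p[1] == q[1] && z[2] > min(p[2], q[2]) && z[2] < max(p[2], q[2])))
  }
  between(a, b, cc) || between(a, b, d) || between(cc, d, a) || between(cc, d, b)
}

oracle_self_intersecting <- function(p) {
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next
      if (oracle_segment_pair(p[i, ], p[nxt[i], ], p[j, ], p[nxt[j], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# --- oracle: pixel area by crossing-number test at every pixel center -----
# Ray cast toward +x; half-open edge span in y matches the top-left
# boundary convention.
oracle_point_in_polygon <- function(xc, yc, p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  x1 <- p[, 1]; y1 <- p[, 2]; x2 <- p[j, 1]; y2 <- p[j, 2]
  keep <- y1 != y2
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  span <- pmin(y1, y2) <= yc & yc < pmax(y1, y2)
  if (!any(span)) return(FALSE)
  xi <- x1[span] + (yc - y1[span]) * (x2[span] - x1[span]) / (y2[span] - y1[span])
  sum(xi > xc) %% 2L == 1L
}

oracle_pixel_area <- function(p, width, height) {
  count <- 0L
  for (r in seq_len(height) - 1L) {
    for (cc in seq_len(width) - 1L) {
      if (oracle_point_in_polygon(cc + 0.5, r + 0.5, p)) count <- count + 1L
    }
  }
  count
}

# Random convex polygon with continuous coordinates, inside a w x h frame.
random_convex_polygon <- function(w, h, k = sample(3:9, 1)) {
  rx <- runif(1, 2, w / 2 - 2)
  ry <- runif(1, 2, h / 2 - 2)
  cx <- runif(1, rx + 1, w - rx - 1)
  cy <- runif(1, ry + 1, h - ry - 1)
  ang <- sort(runif(k, 0, 2 * pi))
  cbind(cx + rx * cos(ang), cy + ry * sin(ang))
}

# --- oracle: Wilcoxon two-sided p by complete 2^n sign enumeration --------
oracle_wilcoxon_p <- function(x, y) {
  d <- as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(NA_real_)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)
  min(1, 2 * min(mean(W <= w_obs), mean(W >= w_obs)))
}

# Perimeter of a closed polygon, for the rasterization error bound.
polygon_perimeter <- function(p) {
  j <- c(2:nrow(p), 1L)
  sum(sqrt(rowSums((p[j, , drop = FALSE] - p)^2)))
}
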