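# Frame-level Dice similarity and the paired Wilcoxon signed-rank test.

#' Dice similarity coefficient between two binary masks
#'
#' `2 * |A & B| / (|A| + |B|)`.  Two empty masks score 1.0 by convention
#' (configurable): both raters agree there is nothing to segment.  An empty
#' mask against a non-empty one scores 0.
#'
#' @param a,b `instance_mask` objects or logical matrices of equal size.
#' @param empty_value Value returned when both masks are empty.  Default 1.
#' @return DSC in `[0, 1]`.
#' @export
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1:2, 1:2] <- TRUE
#' dsc(m, m)  # 1
dsc <- function(a, b, empty_value = 1) {
  a <- .as_bitmap(a); b <- .as_bitmap(b)
  if (!all(dim(a) == dim(b))) {
    stop("mask dimensions differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  }
  denom <- sum(a) + sum(b)
  if (denom == 0) return(empty_value)
  2 * sum(a & b) / denom
}

#' Frame-level DSC series over two mask sets
#'
#' For each frame id present in both sets, all instance masks of that
#' frame are OR-ed into a single class-agnostic frame mask and compared
#' with DSC.  (A per-class variant simply calls this once per category's
#' masks.)
#'
#' @param pred,ref Named lists keyed by frame id; each element is a mask
#'   or a list of masks to be unioned.
#' @param empty_value DSC convention for empty-vs-empty frames.
#' @return Data frame `frame_id`, `dsc`, with the mean DSC in
#'   `attr(x, "mean_dsc")` (printed to 3 decimals).
#' @export
frame_dsc_series <- function(pred, ref, empty_value = 1) {
  shared <- intersect(names(pred), names(ref))
  if (!length(shared)) stop("no shared frame ids between the two mask sets",
                            call. = FALSE)
  vals <- vapply(shared, function(id) {
    dsc(.union_masks(pred[[id]]), .union_masks(ref[[id]]), empty_value)
  }, numeric(1))
  out <- data.frame(frame_id = shared, dsc = unname(vals),
                    stringsAsFactors = FALSE)
  attr(out, "mean_dsc") <- mean(out$dsc)
  out
}

.union_masks <- function(x) {
  if (inherits(x, "instance_mask") || is.matrix(x)) return(.as_bitmap(x))
  Reduce(`|`, lapply(x, .as_bitmap))
}

#' Paired Wilcoxon signed-rank test
#'
#' Differences `x - y` equal to zero are discarded; ties in `|d|` receive
#' average ranks; the statistic is the sum of ranks of the positive
#' differences (W+).  For up to 25 effective pairs the two-sided p-value
#' is exact, from the full null distribution of W+ over all 2^n sign
#' assignments of the observed ranks (computed by convolution, identical
#' to complete enumeration and valid under ties); beyond that a normal
#' approximation with tie and continuity corrections is used.
#' When every difference is zero the test is degenerate: the result is
#' flagged (`method = "degenerate"`, p-value `NA`) rather than an error.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_max Largest `n_effective` for which the exact distribution
#'   is used.  Default 25.
#' @return A `wilcoxon_result`: `n_effective`, `statistic` (W+),
#'   `p_value` (two-sided), `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))$p_value  # 0.0625
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(n_effective = 0L, statistic = NA_real_,
                          p_value = NA_real_, method = "degenerate"),
                     class = "wilcoxon_result"))
  }
  r <- rank(abs(d))                       # average ranks under ties
  w_plus <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- .wilcoxon_exact_p(r, w_plus)
    method <- "exact"
  } else {
    p <- .wilcoxon_normal_p(r, w_plus, n)
    method <- "normal_approx"
  }
  structure(list(n_effective = n, statistic = w_plus,
                 p_value = p, method = method),
            class = "wilcoxon_result")
}

# Exact two-sided p over all 2^n sign vectors.  Ranks are doubled so tie-
# averaged half-integer ranks become integers; the distribution of W+ is
# then the coefficient vector of prod_i (1 + z^{2 r_i}).
.wilcoxon_exact_p <- function(r, w_plus) {
  w2 <- as.integer(round(2 * r))
  total <- sum(w2)
  f <- numeric(total + 1L)
  f[1] <- 1
  for (w in w2) {
    g <- f
    g[(w + 1L):(total + 1L)] <- g[(w + 1L):(total + 1L)] + f[1:(total + 1L - w)]
    f <- g
  }
  denom <- 2^length(r)
  obs <- round(2 * w_plus)
  idx <- 0:total
  p_le <- sum(f[idx <= obs]) / denom
  p_ge <- sum(f[idx >= obs]) / denom
  min(1, 2 * min(p_le, p_ge))
}

# Normal approximation with tie correction and continuity correction.
.wilcoxon_normal_p <- function(r, w_plus, n) {
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  dev <- w_plus - mu
  z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("Wilcoxon signed-rank test (paired, two-sided)\n")
  if (x$method == "degenerate") {
    cat("  all paired differences are zero; p-value undefined\n")
  } else {
    cat("  n (nonzero differences):", x$n_effective, "\n",
        " W+ =", x$statistic, ", p =", format.pval(x$p_value, digits = 4),
        " [", x$method, "]\n")
  }
  invisible(x)
}

#' Read a directory of mask PNGs keyed by file name
#'
#' @param dir Directory of single-channel PNG masks (nonzero = foreground).
#' @return Named list of logical matrices, keyed by file stem.
#' @export
read_mask_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  stats::setNames(lapply(files, read_mask_png),
                  tools::file_path_sans_ext(basename(files)))
}
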