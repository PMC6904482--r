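#' Intersection over union of axis-aligned boxes
#'
#' Boxes live in continuous pixel coordinates, origin at the top-left,
#' x rightward and y downward; a box covers the half-open region
#' `[x_min, x_max) x [y_min, y_max)`, so `area = (x_max - x_min) * (y_max - y_min)`.
#'
#' @param a,b A box: either a numeric vector `c(x_min, y_min, x_max, y_max)`
#'   or a data frame with those columns. When both are data frames they are
#'   compared row-wise (recycled to a common length).
#' @return Numeric vector of IoU values in `[0, 1]`. Symmetric; 1 exactly for
#'   identical boxes; 0 when interiors are disjoint.
#' @examples
#' box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 50 / 150
#' @export
box_iou <- function(a, b) {
  a <- as_box_matrix(a)
  b <- as_box_matrix(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) < n) a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  if (nrow(b) < n) b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  iw <- pmin(a[, 3L], b[, 3L]) - pmax(a[, 1L], b[, 1L])
  ih <- pmin(a[, 4L], b[, 4L]) - pmax(a[, 2L], b[, 2L])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  area_a <- (a[, 3L] - a[, 1L]) * (a[, 4L] - a[, 2L])
  area_b <- (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L])
  inter / (area_a + area_b - inter)
}

# Coerce a box representation to an n x 4 matrix (x_min, y_min, x_max, y_max)
# and check validity: x_min < x_max, y_min < y_max.
as_box_matrix <- function(x) {
  if (is.matrix(x) && ncol(x) == 4L) {
    m <- x
  } else if (is.data.frame(x)) {
    m <- cbind(x$x_min, x$y_min, x$x_max, x$y_max)
  } else if (is.numeric(x)) {
    m <- matrix(x, ncol = 4L, byrow = TRUE)
  } else {
    stop_reprocad("malformed_box", "a box must be a numeric vector or a data frame with x_min/y_min/x_max/y_max")
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop_reprocad("malformed_box", "box coordinates must be finite and non-missing")
  }
  if (any(m[, 1L] >= m[, 3L]) || any(m[, 2L] >= m[, 4L])) {
    stop_reprocad("malformed_box", "degenerate box: requires x_min < x_max and y_min < y_max")
  }
  m
}

# IoU matrix between two sets of boxes: rows = boxes in `a`, cols = boxes in `b`.
iou_matrix <- function(a, b) {
  a <- as_box_matrix(a)
  b <- as_box_matrix(b)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(matrix(0, na, nb))
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  matrix(box_iou(a[ia, , drop = FALSE], b[ib, , drop = FALSE]), na, nb)
}
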