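#' Squared-exponential covariance between time-stimulus points
#'
#' The covariance function is defined over joint time-stimulus coordinates
#' `z = (time, s1, ..., sD)` and decays with squared Euclidean distance:
#' `k(z, z') = exp(-||z - z'||^2 / (2 * length_scale^2))`. A single shared
#' length-scale divides the joint norm, so time and stimulus dimensions are
#' measured in the same abstract units. The kernel has unit prior variance:
#' `k(z, z) = 1`.
#'
#' @param a,b Query points: numeric vectors `c(time, stimulus...)`, or
#'   matrices with one point per row (first column time, remaining columns
#'   stimulus coordinates). Both must have the same number of columns.
#' @param length_scale Positive length-scale `lambda` of the kernel.
#' @return If `a` and `b` are single points, a scalar in `(0, 1]`; otherwise
#'   the matrix of pairwise covariances (rows of `a` by rows of `b`).
#' @examples
#' se_kernel(c(0, 0), c(1, 0))          # exp(-0.5)
#' se_kernel(c(0, 0, 0), c(3, 4, 0))    # exp(-12.5), ||dz|| = 5
#' @seealso [kernel_matrix()], [gp_posterior()]
#' @export
se_kernel <- function(a, b, length_scale = 1) {
  a <- .as_point_matrix(a)
  b <- .as_point_matrix(b)
  if (ncol(a) != ncol(b)) {
    stop("invalid-protocol: query points have mismatched dimension (",
         ncol(a) - 1L, " vs ", ncol(b) - 1L, " stimulus coordinates)")
  }
  .check_length_scale(length_scale)
  k <- .se_cross(a, b, length_scale)
  if (nrow(a) == 1L && nrow(b) == 1L) drop(k) else k
}

#' Gram matrix of the squared-exponential kernel
#'
#' Covariance matrix `K` with entry `(i, j)` equal to the kernel between
#' points `i` and `j`. Symmetric positive semidefinite with unit diagonal.
#'
#' @param points Matrix of query points (one per row, first column time), a
#'   data frame with a `time` column and `s*` stimulus columns, or a
#'   [stimulus_protocol()].
#' @inheritParams se_kernel
#' @return An `n x n` covariance matrix (0 x 0 for an empty input).
#' @export
kernel_matrix <- function(points, length_scale = 1) {
  Z <- .as_point_matrix(points)
  .check_length_scale(length_scale)
  if (nrow(Z) == 0L) return(matrix(0, 0L, 0L))
  K <- .se_cross(Z, Z, length_scale)
  (K + t(K)) / 2
}

# rows of A x rows of B -> covariances; clamps tiny negative squared
# distances produced by the expansion ||a-b||^2 = |a|^2 + |b|^2 - 2ab.
.se_cross <- function(A, B, length_scale) {
  if (nrow(A) == 0L || nrow(B) == 0L) return(matrix(0, nrow(A), nrow(B)))
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * length_scale^2))
}

.check_length_scale <- function(length_scale) {
  if (!is.numeric(length_scale) || length(length_scale) != 1L ||
      !is.finite(length_scale) || length_scale <= 0) {
    stop("invalid-parameter: length_scale must be a single positive number")
  }
}

# Coerce a point specification to a numeric matrix with columns
# (time, s1, ..., sD). Accepts vectors, matrices, data frames with
# time/s* columns, and stimulus_protocol objects.
.as_point_matrix <- function(x) {
  if (inherits(x, "stimulus_protocol") || is.data.frame(x)) {
    scol <- grep("^s[0-9]+$", names(x), value = TRUE)
    if (!("time" %in% names(x))) stop("invalid-protocol: no 'time' column")
    m <- as.matrix(x[, c("time", scol), drop = FALSE])
    storage.mode(m) <- "double"
    return(m)
  }
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.numeric(x)) return(matrix(as.double(x), nrow = 1L))
  stop("invalid-protocol: cannot interpret query points of class ",
       paste(class(x), collapse = "/"))
}
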