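#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats var cor sd dist hclust as.dist cutree pf p.adjust rnorm
#'   rlnorm runif predict setNames cov
#' @importFrom utils combn head
NULL

# Tolerances used for exact algebraic identities and for round-trip checks.
# They are deliberately strict: the operations below are closed-form, so any
# larger discrepancy signals a genuine bug rather than numerical noise.
.tol_identity <- 1e-10
.tol_roundtrip <- 1e-9

check_positive_parts <- function(x, what = "composition") {
  if (!is.numeric(x) || length(x) < 2L) {
    abort(sprintf("A %s must be a numeric vector with at least 2 parts.", what))
  }
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad) > 0L) {
    labs <- if (!is.null(names(x))) names(x)[bad] else as.character(bad)
    abort(sprintf(
      "All parts of a %s must be strictly positive; offending part(s): %s. Zeros must be resolved first (see `replace_zeros()`).",
      what, paste(labs, collapse = ", ")
    ))
  }
  invisible(x)
}

#' Close a composition to a constant sum
#'
#' Rescales a vector of strictly positive parts so that its components sum to
#' `kappa`, leaving every ratio between parts untouched. Closure is the
#' compositional no-op: two vectors that are positive multiples of one another
#' represent the same composition, and `close_composition()` merely picks a
#' convenient representative (proportions for `kappa = 1`, percentages for
#' `kappa = 100`).
#'
#' @param x Numeric vector of strictly positive parts (optionally named by
#'   AOI).
#' @param kappa Positive constant the closed parts should sum to. Defaults to
#'   1; use 100 for percentage display.
#' @return A numeric vector of the same length and names as `x` summing to
#'   `kappa`.
#' @examples
#' close_composition(c(Visitor = 8323, Persons = 5353, Background = 4319), 100)
#' @export
close_composition <- function(x, kappa = 1) {
  check_positive_parts(x)
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0) {
    abort("`kappa` must be a single positive number.")
  }
  x / sum(x) * kappa
}

#' Perturb one composition by another
#'
#' Perturbation is the group operation of Aitchison geometry: component-wise
#' multiplication followed by closure. Perturbing by the uniform composition
#' leaves a composition unchanged; perturbing by the component-wise inverse of
#' a composition recovers the uniform one.
#'
#' @param x,p Numeric vectors of strictly positive parts with matching length
#'   (and matching names when both are named).
#' @param kappa Closure constant for the result.
#' @return The closed component-wise product of `x` and `p`.
#' @examples
#' perturb(c(1, 2), c(2, 1))            # uniform
#' @export
perturb <- function(x, p, kappa = 1) {
  check_positive_parts(x)
  check_positive_parts(p, what = "perturbation")
  if (length(x) != length(p)) {
    abort("`x` and `p` must have the same number of parts.")
  }
  if (!is.null(names(x)) && !is.null(names(p)) && !identical(names(x), names(p))) {
    abort("`x` and `p` carry different part labels.")
  }
  close_composition(x * p, kappa)
}

#' Power-scale a composition
#'
#' Raises each part to the power `a` and closes the result. Together with
#' perturbation this completes the vector-space structure of the simplex:
#' `a = 0` returns the uniform composition (the neutral element) and `a = 1`
#' returns `x` itself (after closure).
#'
#' @inheritParams close_composition
#' @param a Real scalar power.
#' @return Closed composition with parts `x^a`.
#' @export
power_scale <- function(x, a, kappa = 1) {
  check_positive_parts(x)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a)) {
    abort("`a` must be a single finite number.")
  }
  close_composition(x^a, kappa)
}

#' Centred log-ratio (clr) transform of a single composition
#'
#' Maps a D-part composition to the D real coordinates
#' `y_j = ln(x_j / g(x))`, where `g(x)` is the geometric mean of the parts.
#' Each coordinate measures the dominance of one part relative to the whole
#' observation; the coordinates always sum to zero, and the map is invariant
#' to rescaling of `x`.
#'
#' @inheritParams close_composition
#' @return Numeric vector of clr coordinates (same names as `x`), summing to
#'   zero.
#' @seealso [clr_inverse()], [clr_transform()] for whole tables.
#' @export
clr <- function(x) {
  check_positive_parts(x)
  lx <- log(x)
  lx - mean(lx)
}

#' Invert a clr vector back to a composition
#'
#' @param y Numeric vector of clr coordinates; must sum to zero within
#'   tolerance because clr images live on that hyperplane.
#' @param kappa Closure constant for the reconstructed composition.
#' @return A composition with `clr()` image `y`.
#' @export
clr_inverse <- function(y, kappa = 1) {
  if (!is.numeric(y) || length(y) < 2L || any(!is.finite(y))) {
    abort("`y` must be a finite numeric vector with at least 2 entries.")
  }
  if (abs(sum(y)) > 1e-8) {
    abort(paste0("A clr vector must sum to 0; this one sums to ", format(sum(y)), "."))
  }
  close_composition(exp(y), kappa)
}

# Orthonormal pivot-coordinate contrast matrix (D x (D-1)). Column j contrasts
# part j against the geometric mean of all later parts; clr = V %*% z and
# z = t(V) %*% clr.
pivot_basis <- function(D) {
  V <- matrix(0, nrow = D, ncol = D - 1L)
  for (j in seq_len(D - 1L)) {
    r <- D - j
    norm <- sqrt(r / (r + 1))
    V[j, j] <- norm
    V[(j + 1L):D, j] <- -norm / r
  }
  V
}

resolve_pivot_order <- function(x, order) {
  labs <- names(x) %||% as.character(seq_along(x))
  if (is.null(order)) {
    return(seq_along(x))
  }
  if (is.character(order)) {
    if (!setequal(order, labs) || length(order) != length(labs)) {
      abort("`order` must be a permutation of the part labels.")
    }
    match(order, labs)
  } else {
    if (!setequal(order, seq_along(x))) {
      abort("`order` must be a permutation of the part indices.")
    }
    as.integer(order)
  }
}

#' Isometric log-ratio pivot coordinates of a composition
#'
#' Maps a D-part composition into D-1 orthonormal log-ratio coordinates
#' ("pivot coordinates" or balances): coordinate j contrasts part j against
#' the geometric mean of all later parts,
#' `z_j = sqrt((D-j)/(D-j+1)) * ln(x_j / gm(x_{j+1}, ..., x_D))`.
#' The map is an isometry between the Aitchison geometry of the simplex and
#' ordinary Euclidean geometry, so distances, MANOVA statistics and
#' classification rules computed on pivot coordinates do not depend on the
#' chosen part order.
#'
#' @inheritParams close_composition
#' @param order Optional permutation of the parts (labels or indices) applied
#'   before pivoting; defaults to the given part order.
#' @return Numeric vector of length `length(x) - 1`.
#' @seealso [ilr_inverse()], [ilr_transform()] for whole tables.
#' @export
ilr_pivot <- function(x, order = NULL) {
  check_positive_parts(x)
  perm <- resolve_pivot_order(x, order)
  y <- clr(x[perm])
  drop(crossprod(pivot_basis(length(x)), y))
}

#' Invert pivot coordinates back to a composition
#'
#' @param z Numeric vector of D-1 pivot coordinates.
#' @param order Permutation used when the coordinates were computed; the
#'   returned parts are put back into the original order.
#' @param kappa Closure constant.
#' @param parts Optional part labels for the result.
#' @return Composition whose [ilr_pivot()] image (under the same `order`)
#'   equals `z`.
#' @export
ilr_inverse <- function(z, order = NULL, kappa = 1, parts = NULL) {
  if (!is.numeric(z) || length(z) < 1L || any(!is.finite(z))) {
    abort("`z` must be a finite numeric vector.")
  }
  D <- length(z) + 1L
  y <- drop(pivot_basis(D) %*% z)
  x <- exp(y)
  template <- setNames(rep(1, D), parts)
  perm <- resolve_pivot_order(template, order)
  out <- numeric(D)
  out[perm] <- x
  names(out) <- parts
  close_composition(out, kappa)
}

#' Aitchison distance between two compositions
#'
#' The Euclidean distance between the clr (equivalently ilr) images of two
#' compositions. It depends only on the ratios between parts, so it is
#' unchanged by closure or rescaling of either argument and by a common
#' perturbation of both — unlike the ordinary Euclidean distance on raw or
#' percentage data, which changes with the chosen representation.
#'
#' @param x,z Numeric vectors of strictly positive parts over the same part
#'   list.
#' @return A single nonnegative number.
#' @examples
#' aitchison_distance(c(8323, 5353, 4319), c(2187, 1377.3, 1036))
#' @export
aitchison_distance <- function(x, z) {
  check_positive_parts(x)
  check_positive_parts(z)
  if (length(x) != length(z)) {
    abort("`x` and `z` must have the same number of parts.")
  }
  if (!is.null(names(x)) && !is.null(names(z)) && !identical(names(x), names(z))) {
    abort("`x` and `z` carry different part labels.")
  }
  sqrt(sum((clr(x) - clr(z))^2))
}
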