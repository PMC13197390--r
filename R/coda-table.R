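# Table-level compositional statistics.
#
# The user-facing convention throughout the package: a "composition table" is
# a wide data frame with one row per observation, optional id columns
# (`participant`, `task`, or anything non-numeric), and one strictly positive
# numeric column per AOI/part. `part_cols()` resolves which columns are parts.

#' Identify the part (AOI) columns of a composition table
#'
#' @param data A wide data frame of compositions.
#' @param parts Optional character vector naming the part columns. When
#'   `NULL`, all numeric columns except `participant` and `task` are taken to
#'   be parts.
#' @return Character vector of part column names.
#' @export
part_cols <- function(data, parts = NULL) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (is.null(parts)) {
    numeric_cols <- names(data)[vapply(data, is.numeric, logical(1))]
    parts <- setdiff(numeric_cols, c("participant", "task"))
  } else {
    missing <- setdiff(parts, names(data))
    if (length(missing) > 0L) {
      abort(paste0("Part column(s) not found: ", paste(missing, collapse = ", ")))
    }
  }
  if (length(parts) < 2L) {
    abort("A composition table needs at least 2 part columns.")
  }
  parts
}

comp_values <- function(data, parts, require_positive = TRUE) {
  m <- as.matrix(data[parts])
  if (!is.numeric(m)) abort("Part columns must be numeric.")
  if (require_positive && any(!is.finite(m) | m <= 0)) {
    bad <- parts[apply(m, 2, function(v) any(!is.finite(v) | v <= 0))]
    abort(paste0(
      "Part column(s) with nonpositive or missing entries: ",
      paste(bad, collapse = ", "),
      ". Resolve zeros first (see `replace_zeros()`)."
    ))
  }
  m
}

id_cols <- function(data, parts) {
  setdiff(names(data), parts)
}

#' Centred log-ratio transform of a composition table
#'
#' Applies [clr()] row-wise. Id columns are carried through unchanged; each
#' returned part column holds the clr coordinate of that part, and the part
#' columns of every row sum to zero.
#'
#' @inheritParams part_cols
#' @return A tibble with the same columns as `data`, part columns replaced by
#'   clr coordinates.
#' @export
clr_transform <- function(data, parts = NULL) {
  parts <- part_cols(data, parts)
  m <- comp_values(data, parts)
  lm_ <- log(m)
  y <- lm_ - rowMeans(lm_)
  out <- tibble::as_tibble(data)
  out[parts] <- y
  out
}

#' Pivot (ilr) coordinates of a composition table
#'
#' Applies [ilr_pivot()] row-wise, producing `D - 1` coordinate columns named
#' `z1 ... z{D-1}`. Any orthonormal log-ratio basis gives the same downstream
#' MANOVA, distance, and classification results; the pivot basis is used for
#' its simple interpretation (coordinate j contrasts part j against all later
#' parts).
#'
#' @inheritParams part_cols
#' @param order Optional permutation of the part labels applied before
#'   pivoting.
#' @return A tibble with the id columns of `data` plus coordinate columns.
#' @export
ilr_transform <- function(data, parts = NULL, order = NULL) {
  parts <- part_cols(data, parts)
  m <- comp_values(data, parts)
  template <- setNames(rep(1, length(parts)), parts)
  perm <- resolve_pivot_order(template, order)
  lm_ <- log(m)
  y <- lm_ - rowMeans(lm_)
  z <- y[, perm, drop = FALSE] %*% pivot_basis(length(parts))
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  dplyr::bind_cols(
    tibble::as_tibble(data[id_cols(data, parts)]),
    tibble::as_tibble(z)
  )
}

#' Compositional (geometric) mean of a composition table
#'
#' The closure of the column-wise geometric means — the centre of a
#' compositional sample. Unlike the arithmetic mean of percentages, it is
#' equivariant under perturbation and invariant to per-row rescaling of the
#' raw data.
#'
#' @inheritParams part_cols
#' @param kappa Closure constant of the returned mean (100 gives percentages).
#' @return Named numeric vector summing to `kappa`.
#' @export
compositional_mean <- function(data, parts = NULL, kappa = 1) {
  parts <- part_cols(data, parts)
  m <- comp_values(data, parts)
  if (nrow(m) < 1L) abort("Need at least one observation.")
  g <- exp(colMeans(log(m)))
  close_composition(setNames(g, parts), kappa)
}

#' Variation matrix of a composition table
#'
#' Element (j, k) is the sample variance of the log-ratio
#' `ln(x_j / x_k)` across observations. Entries near zero flag pairs of parts
#' that are close to proportional throughout the sample (their ratio is
#' stable); large entries flag pairs whose relative dominance fluctuates.
#'
#' @inheritParams part_cols
#' @param divisor `"unbiased"` (default) uses the n-1 variance divisor;
#'   `"ml"` uses n. Published totals computed with the other convention
#'   differ by the factor (n-1)/n.
#' @return An object of class `variation_matrix`: a list with the D x D
#'   matrix `t`, the scalar `totvar`, the sample size `n`, and the divisor
#'   used. Its [tidy()][generics::tidy] method returns the pairs in long
#'   form.
#' @export
variation_matrix <- function(data, parts = NULL, divisor = c("unbiased", "ml")) {
  divisor <- match.arg(divisor)
  parts <- part_cols(data, parts)
  m <- comp_values(data, parts)
  n <- nrow(m)
  if (n < 2L) abort("The variation matrix needs at least 2 observations.")
  lm_ <- log(m)
  # var of log-ratio columns, computed for all pairs at once via the clr
  # covariance: var(y_j - y_k) = c_jj + c_kk - 2 c_jk with y the clr matrix.
  y <- lm_ - rowMeans(lm_)
  cv <- stats::cov(y)
  if (divisor == "ml") cv <- cv * (n - 1) / n
  d <- diag(cv)
  t_mat <- outer(d, d, "+") - 2 * cv
  t_mat[abs(t_mat) < .tol_identity] <- 0
  dimnames(t_mat) <- list(parts, parts)
  structure(
    list(
      t = t_mat,
      totvar = sum(t_mat) / (2 * length(parts)),
      n = n,
      divisor = divisor,
      parts = parts
    ),
    class = "variation_matrix"
  )
}

#' @export
print.variation_matrix <- function(x, ...) {
  cat("Variation matrix (", x$n, " observations, ", x$divisor,
    " divisor)\n",
    sep = ""
  )
  print(round(x$t, 3))
  cat("Total variance:", format(x$totvar, digits = 4), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.variation_matrix <- function(x, ...) {
  pairs <- which(upper.tri(x$t), arr.ind = TRUE)
  tibble::tibble(
    part1 = x$parts[pairs[, 1]],
    part2 = x$parts[pairs[, 2]],
    variance = x$t[pairs]
  )
}

#' Total variance of a compositional sample
#'
#' The double sum of the variation matrix divided by 2D; equivalently, the
#' sum of the variances of the clr coordinates (same variance divisor). It is
#' zero exactly when all rows are proportional, and serves as the scalar
#' dispersion of the sample in the Aitchison geometry.
#'
#' @inheritParams variation_matrix
#' @return A single nonnegative number.
#' @export
total_variance <- function(data, parts = NULL, divisor = c("unbiased", "ml")) {
  variation_matrix(data, parts, divisor)$totvar
}

#' Replace zero dwell times by a fraction of the column minimum
#'
#' Log-ratio methods require strictly positive parts, but an AOI that a
#' participant never fixated yields a zero. This simple multiplicative-style
#' rule replaces each zero in part column j by `fraction` times the smallest
#' positive value observed in that column, leaving positive entries
#' untouched. An AOI with no positive entries at all cannot be imputed and is
#' rejected: merge it with a neighbouring AOI (see [aggregate_aois()]) or
#' drop it.
#'
#' @inheritParams part_cols
#' @param fraction Positive multiplier of the column-minimum positive value
#'   (default 0.65).
#' @param quiet Suppress the replacement log message.
#' @return `data` with zeros replaced; the number of replacements per column
#'   is attached as attribute `"zero_replacements"` and reported via a
#'   message.
#' @export
replace_zeros <- function(data, parts = NULL, fraction = 0.65, quiet = FALSE) {
  parts <- part_cols(data, parts)
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0) {
    abort("`fraction` must be a single positive number (0 would recreate zeros).")
  }
  m <- comp_values(data, parts, require_positive = FALSE)
  if (any(!is.finite(m) | m < 0)) {
    abort("Dwell times must be nonnegative and finite.")
  }
  out <- tibble::as_tibble(data)
  replaced <- setNames(integer(length(parts)), parts)
  for (p in parts) {
    v <- out[[p]]
    zero <- v == 0
    if (any(zero)) {
      pos <- v[v > 0]
      if (length(pos) == 0L) {
        abort(paste0(
          "AOI column '", p, "' is all zero and cannot be imputed; ",
          "merge this sparsely visited area into a neighbour or drop it."
        ))
      }
      v[zero] <- fraction * min(pos)
      out[[p]] <- v
      replaced[p] <- sum(zero)
    }
  }
  if (!quiet && sum(replaced) > 0) {
    inform(paste0(
      "Replaced ", sum(replaced), " zero cell(s): ",
      paste0(names(replaced)[replaced > 0], "=", replaced[replaced > 0],
        collapse = ", "
      )
    ))
  }
  attr(out, "zero_replacements") <- replaced
  out
}
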