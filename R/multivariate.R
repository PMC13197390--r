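# Principal component analysis and hierarchical clustering, each in a
# compositional (clr / Aitchison) and a classical (raw ms, Euclidean) mode.

#' Principal component analysis of a composition table
#'
#' Singular value decomposition of the column mean-centred clr matrix
#' (`mode = "clr"`, compositional PCA) or of the column mean-centred raw
#' dwell-time matrix (`mode = "raw"`, classical PCA). Scores are `U %*% D`;
#' loadings are the right singular vectors. In clr mode each loading vector
#' sums to zero — principal components are log-contrasts — and the singular
#' values tie back to the total variance via
#' `sum(lambda_k^2) / (n - 1) = total_variance(data)`.
#'
#' The SVD sign ambiguity is resolved deterministically: each loading is
#' flipped so that its largest-magnitude entry is positive.
#'
#' @param data Wide composition table.
#' @param parts Optional part column names.
#' @param mode `"clr"` or `"raw"`.
#' @return An object of class `coda_pca`: list with `scores` (n x r),
#'   `loadings` (D x r), `singular_values`, `explained` (variance shares from
#'   squared singular values), `explained_sv` (shares of the singular values
#'   themselves), `mode`, `center`, `n`, `parts`, and the id columns of
#'   `data` as `meta`.
#' @export
coda_pca <- function(data, parts = NULL, mode = c("clr", "raw")) {
  mode <- match.arg(mode)
  parts <- part_cols(data, parts)
  if (mode == "clr") {
    m <- comp_values(data, parts)
    lm_ <- log(m)
    y <- lm_ - rowMeans(lm_)
  } else {
    y <- comp_values(data, parts, require_positive = FALSE)
  }
  n <- nrow(y)
  if (n < 2L) abort("PCA needs at least 2 observations.")
  center <- colMeans(y)
  yc <- sweep(y, 2, center)
  if (max(abs(yc)) < .tol_identity) {
    abort("All rows are identical; there is no variation to decompose.")
  }
  sv <- svd(yc)
  # after centring the rank is at most n - 1; in clr mode the zero-sum
  # constraint removes one more dimension. Trailing null components carry an
  # arbitrary basis (in clr mode one not summing to zero), so they are
  # dropped rather than reported.
  r_keep <- max(1L, min(n - 1L, ncol(yc) - (mode == "clr")))
  sv$d <- sv$d[seq_len(r_keep)]
  sv$u <- sv$u[, seq_len(r_keep), drop = FALSE]
  sv$v <- sv$v[, seq_len(r_keep), drop = FALSE]
  # deterministic sign: largest-|entry| of each loading made positive
  flip <- vapply(seq_len(ncol(sv$v)), function(k) {
    v <- sv$v[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  v <- sweep(sv$v, 2, flip, "*")
  u <- sweep(sv$u, 2, flip, "*")
  lambda <- sv$d
  scores <- u %*% diag(lambda, nrow = length(lambda))
  rownames(v) <- parts
  colnames(v) <- paste0("PC", seq_along(lambda))
  colnames(scores) <- colnames(v)
  structure(
    list(
      scores = scores,
      loadings = v,
      singular_values = lambda,
      explained = lambda^2 / sum(lambda^2),
      explained_sv = lambda / sum(lambda),
      mode = mode,
      center = setNames(center, parts),
      n = n,
      parts = parts,
      meta = tibble::as_tibble(data[id_cols(data, parts)])
    ),
    class = "coda_pca"
  )
}

#' @export
print.coda_pca <- function(x, ...) {
  cat("PCA (", x$mode, " mode): ", x$n, " observations, ",
    length(x$parts), " parts\n",
    sep = ""
  )
  cat(
    "Explained variance (first components):",
    paste0(round(100 * head(x$explained, 4), 1), "%", collapse = ", "), "\n"
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.coda_pca <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    dplyr::bind_cols(x$meta, tibble::as_tibble(x$scores))
  } else {
    dplyr::bind_cols(
      tibble::tibble(part = x$parts),
      tibble::as_tibble(x$loadings)
    )
  }
}

#' @exportS3Method generics::glance
glance.coda_pca <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n = x$n,
    n_parts = length(x$parts),
    explained_pc1 = x$explained[1],
    explained_pc2 = if (length(x$explained) > 1) x$explained[2] else NA_real_,
    total_variance = sum(x$singular_values^2) / (x$n - 1)
  )
}

#' Biplot link length between two part vertices
#'
#' In a clr (covariance) biplot the squared distance between the vertices of
#' parts j and k — loading rows scaled by the singular values, divided by
#' sqrt(n - 1) — estimates the variance of the pairwise log-ratio
#' `ln(x_j / x_k)`. With all components retained the identity is exact;
#' truncating to the displayed components can only shrink the link, so short
#' links on a two-component biplot are suggestive (not proof) of
#' proportional parts.
#'
#' @param pca A `coda_pca` fit with `mode = "clr"`.
#' @param j,k Part names or indices.
#' @param n_components Number of leading components retained (default: all).
#' @return A tibble with the squared `link` and, for reference, the
#'   variation-matrix entry implied by the full decomposition
#'   (`t_jk_full`).
#' @export
biplot_links <- function(pca, j, k, n_components = NULL) {
  if (!inherits(pca, "coda_pca")) abort("`pca` must be a `coda_pca` object.")
  if (pca$mode != "clr") {
    abort("Biplot links are a clr-biplot construct; refit with mode = \"clr\".")
  }
  idx <- function(p) if (is.character(p)) match(p, pca$parts) else as.integer(p)
  ji <- idx(j)
  ki <- idx(k)
  if (is.na(ji) || is.na(ki)) abort("Unknown part in `j` or `k`.")
  r <- length(pca$singular_values)
  keep <- seq_len(min(n_components %||% r, r))
  dv <- (pca$loadings[ji, keep] - pca$loadings[ki, keep]) *
    pca$singular_values[keep]
  dv_full <- (pca$loadings[ji, ] - pca$loadings[ki, ]) * pca$singular_values
  tibble::tibble(
    part1 = pca$parts[ji],
    part2 = pca$parts[ki],
    n_components = length(keep),
    link = sum(dv^2) / (pca$n - 1),
    t_jk_full = sum(dv_full^2) / (pca$n - 1)
  )
}

#' Hierarchical clustering of observations
#'
#' Complete-linkage agglomeration of the rows of a composition table under
#' the Aitchison metric (Euclidean distance between clr images — clustering
#' by relative structure) or the plain Euclidean metric on raw dwell times
#' (clustering dominated by overall viewing time). Two observations with
#' proportional dwell-time vectors have Aitchison distance zero regardless of
#' how different their totals are, so the two metrics can group participants
#' very differently.
#'
#' @param data Wide composition table.
#' @param parts Optional part column names.
#' @param metric `"aitchison"` or `"euclidean-raw"`.
#' @return An [hclust] object; leaf labels combine the id columns, and the
#'   metric is recorded in attribute `"metric"`.
#' @export
cluster_observations <- function(data, parts = NULL,
                                 metric = c("aitchison", "euclidean-raw")) {
  metric <- match.arg(metric)
  parts <- part_cols(data, parts)
  if (nrow(data) < 2L) abort("Clustering needs at least 2 observations.")
  m <- if (metric == "aitchison") {
    lm_ <- log(comp_values(data, parts))
    lm_ - rowMeans(lm_)
  } else {
    comp_values(data, parts, require_positive = FALSE)
  }
  ids <- id_cols(data, parts)
  labels <- if (length(ids) > 0) {
    do.call(paste, c(data[ids], sep = "_"))
  } else {
    as.character(seq_len(nrow(data)))
  }
  rownames(m) <- labels
  hc <- hclust(dist(m), method = "complete")
  attr(hc, "metric") <- metric
  hc
}

#' Hierarchical clustering of AOIs from a variation matrix
#'
#' Complete-linkage clustering of the parts, using the log-ratio variance
#' `t_jk` (or optionally its square root) as the dissimilarity between AOIs.
#' Parts that remain nearly proportional across the sample merge at low
#' heights; erratic parts join late.
#'
#' @param vm A [variation_matrix] object.
#' @param use_sqrt Use `sqrt(t_jk)` instead of `t_jk` as the dissimilarity.
#' @return An [hclust] object with attribute `"metric" = "variation"`.
#' @export
cluster_parts <- function(vm, use_sqrt = FALSE) {
  if (!inherits(vm, "variation_matrix")) {
    abort("`vm` must be a `variation_matrix` object.")
  }
  d <- if (use_sqrt) sqrt(vm$t) else vm$t
  hc <- hclust(as.dist(d), method = "complete")
  attr(hc, "metric") <- "variation"
  hc
}
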