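# Compositional and classical MANOVA, pairwise tests with Holm correction,
# balanced-design clr task effects, and Gaussian discriminant classification
# with stratified cross-validation.

# Build the response matrix for a given mode: ilr pivot coordinates of the
# composition (p = D - 1) or the raw dwell times (p = D).
response_matrix <- function(data, parts, mode, order = NULL) {
  if (mode == "ilr") {
    z <- ilr_transform(data, parts, order = order)
    as.matrix(z[setdiff(names(z), id_cols(data, parts))])
  } else {
    comp_values(data, parts, require_positive = FALSE)
  }
}

#' Compositional (or classical) one-way MANOVA with Pillai's trace
#'
#' Tests equality of group mean compositions across the levels of `group`.
#' In `mode = "ilr"` the compositions are mapped to isometric log-ratio
#' coordinates, where the group model becomes an ordinary Gaussian MANOVA;
#' any orthonormal log-ratio basis yields identical test results. In
#' `mode = "raw"` the test is the classical MANOVA on the dwell times in ms.
#'
#' Pillai's trace is `V = tr(B (B + W)^{-1})` with `B` and `W` the between-
#' and within-group cross-product matrices. The F approximation uses the
#' standard constants `s = min(p, K - 1)`, `m = (|p - K + 1| - 1) / 2`,
#' `n* = (N - K - p - 1) / 2`, giving
#' `F = ((2n* + s + 1) / (2m + s + 1)) * V / (s - V)` on
#' `df = (s (2m + s + 1), s (2n* + s + 1))`. The effect size is partial
#' eta-squared `V / s`.
#'
#' @param data Wide composition table.
#' @param parts Optional part column names.
#' @param group Name of the grouping column (default `"task"`).
#' @param mode `"ilr"` (compositional) or `"raw"` (classical).
#' @param order Optional pivot order (results are invariant to it).
#' @return An object of class `coda_manova` with the statistic, F, dfs,
#'   p-value, partial eta-squared, group means (as compositions in ilr
#'   mode), and the pooled within-group covariance.
#' @export
coda_manova <- function(data, parts = NULL, group = "task",
                        mode = c("ilr", "raw"), order = NULL) {
  mode <- match.arg(mode)
  parts <- part_cols(data, parts)
  if (!group %in% names(data)) abort(paste0("No grouping column `", group, "`."))
  g <- factor(data[[group]])
  K <- nlevels(g)
  if (K < 2L) abort("MANOVA needs at least 2 groups.")
  Y <- response_matrix(data, parts, mode, order)
  p <- ncol(Y)
  N <- nrow(Y)
  nk <- table(g)
  if (any(nk <= p)) {
    abort("Each group must have more observations than response dimensions.")
  }
  grand <- colMeans(Y)
  means <- rowsum(Y, g) / as.vector(nk)
  W <- matrix(0, p, p)
  for (lev in levels(g)) {
    Yk <- Y[g == lev, , drop = FALSE]
    Ykc <- sweep(Yk, 2, means[lev, ])
    W <- W + crossprod(Ykc)
  }
  Mc <- sweep(means, 2, grand)
  B <- crossprod(Mc * sqrt(as.vector(nk)))
  Tm <- B + W
  qrT <- qr(Tm)
  if (qrT$rank < p) {
    abort(paste0(
      "Total cross-product matrix is singular (rank ", qrT$rank, " < ", p,
      "); merge AOIs or reduce the number of parts."
    ))
  }
  V <- sum(diag(solve(Tm, B)))
  q <- K - 1
  s <- min(p, q)
  m_const <- (abs(p - q) - 1) / 2
  n_star <- (N - K - p - 1) / 2
  df1 <- s * (2 * m_const + s + 1)
  df2 <- s * (2 * n_star + s + 1)
  f_stat <- ((2 * n_star + s + 1) / (2 * m_const + s + 1)) * V / (s - V)
  p_value <- pf(f_stat, df1, df2, lower.tail = FALSE)
  group_means <- if (mode == "ilr") {
    purrr::map(seq_len(K), function(k) {
      ilr_inverse(means[k, ], order = order, kappa = 100, parts = parts)
    }) |> setNames(levels(g))
  } else {
    purrr::map(seq_len(K), ~ setNames(means[.x, ], parts)) |>
      setNames(levels(g))
  }
  structure(
    list(
      mode = mode, group = group, K = K, p = p, N = N, n_k = as.vector(nk),
      levels = levels(g),
      pillai = V, f_stat = f_stat, df1 = df1, df2 = df2,
      p_value = p_value, partial_eta2 = V / s, s = s,
      group_means = group_means,
      pooled_cov = W / (N - K)
    ),
    class = "coda_manova"
  )
}

#' @export
print.coda_manova <- function(x, ...) {
  cat("MANOVA (", x$mode, " mode), ", x$K, " groups of `", x$group, "`\n",
    sep = ""
  )
  cat(sprintf(
    "  Pillai = %.4g, F(%g, %g) = %.4g, p = %.3g, partial eta^2 = %.3g\n",
    x$pillai, x$df1, x$df2, x$f_stat, x$p_value, x$partial_eta2
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.coda_manova <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, pillai = x$pillai, f_stat = x$f_stat,
    df1 = x$df1, df2 = x$df2, p_value = x$p_value,
    partial_eta2 = x$partial_eta2, n = x$N, n_groups = x$K
  )
}

#' @exportS3Method generics::tidy
tidy.coda_manova <- function(x, ...) {
  purrr::imap_dfr(x$group_means, function(mu, lev) {
    tibble::tibble(group = lev, part = names(mu), mean = unname(mu))
  })
}

#' Pillai F-approximation degrees of freedom
#'
#' Exposes the df arithmetic of the Pillai F approximation used by
#' [coda_manova()]: `df1 = s (2m + s + 1)` and `df2 = s (2n* + s + 1)` with
#' `s = min(p, K - 1)`, `m = (|p - K + 1| - 1)/2`, `n* = (N - K - p - 1)/2`.
#'
#' @param K Number of groups.
#' @param p Response dimension (D - 1 in ilr mode, D in raw mode).
#' @param N Total number of observations.
#' @return Named numeric vector with `df1` and `df2`.
#' @export
pillai_df <- function(K, p, N) {
  q <- K - 1
  s <- min(p, q)
  m_const <- (abs(p - q) - 1) / 2
  n_star <- (N - K - p - 1) / 2
  c(df1 = s * (2 * m_const + s + 1), df2 = s * (2 * n_star + s + 1))
}

# Holm step-down adjustment, written out so the arithmetic is inspectable:
# sort ascending, multiply p_(i) by (m - i + 1), enforce monotonicity by
# cumulative max, cap at 1. Agrees with stats::p.adjust(method = "holm").
holm_step_down <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- pmin(1, cummax(p[ord] * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' All pairwise MANOVA tests with Holm correction
#'
#' Runs [coda_manova()] on every pair of group levels and applies the Holm
#' step-down correction to the p-values. Pairs whose test fails (for example
#' through a singular covariance) are skipped with a warning.
#'
#' @inheritParams coda_manova
#' @return A tibble: `group1`, `group2`, `pillai`, `f_stat`, `df1`, `df2`,
#'   `p_value`, `p_adjusted`.
#' @export
pairwise_manova <- function(data, parts = NULL, group = "task",
                            mode = c("ilr", "raw")) {
  mode <- match.arg(mode)
  parts <- part_cols(data, parts)
  levs <- sort(unique(data[[group]]))
  if (length(levs) < 2L) abort("Need at least 2 groups for pairwise tests.")
  pairs <- utils::combn(seq_along(levs), 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(i) {
    l1 <- levs[pairs[1, i]]
    l2 <- levs[pairs[2, i]]
    sub <- data[data[[group]] %in% c(l1, l2), , drop = FALSE]
    fit <- tryCatch(coda_manova(sub, parts, group, mode), error = function(e) {
      warn(paste0("Pair (", l1, ", ", l2, ") skipped: ", conditionMessage(e)))
      NULL
    })
    if (is.null(fit)) {
      return(NULL)
    }
    tibble::tibble(
      group1 = l1, group2 = l2, pillai = fit$pillai, f_stat = fit$f_stat,
      df1 = fit$df1, df2 = fit$df2, p_value = fit$p_value
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- holm_step_down(out$p_value)
  out
}

#' Balanced-design task effects on a clr coordinate (or raw ms)
#'
#' For a complete balanced design (every participant saw every task), the
#' fixed task effects of a random-intercept model reduce to a closed form:
#' the effect of task t is the mean over participants of that participant's
#' task-t value minus their own across-task mean. Centring within
#' participant removes participant-specific level differences — the role the
#' random intercept plays — and the effects sum to zero across tasks by
#' construction.
#'
#' In `mode = "clr"` the analysed value is the clr coordinate of one AOI, so
#' effects act multiplicatively on the relative dominance of that AOI:
#' `exp(effect)` is the factor by which the AOI's dominance in that task
#' exceeds the participant's own across-task mean. In `mode = "raw"` the
#' value is the dwell time in ms and effects are additive mean differences.
#'
#' @param data Wide composition table with `participant` and `task` columns,
#'   balanced and complete.
#' @param aoi The part whose coordinate is modelled.
#' @param parts Optional part column names.
#' @param mode `"clr"` or `"raw"`.
#' @return A tibble: `task`, `effect`, and in clr mode `multiplier`
#'   (`exp(effect)`).
#' @export
clr_task_effects <- function(data, aoi, parts = NULL, mode = c("clr", "raw")) {
  mode <- match.arg(mode)
  parts <- part_cols(data, parts)
  if (!aoi %in% parts) abort(paste0("`aoi` must be one of: ", paste(parts, collapse = ", ")))
  if (!all(c("participant", "task") %in% names(data))) {
    abort("`data` needs `participant` and `task` columns.")
  }
  counts <- table(data$participant, data$task)
  if (any(counts != 1L)) {
    abort(paste0(
      "The closed-form estimator requires a complete balanced design ",
      "(one row per participant x task); fit an explicit mixed model for ",
      "unbalanced data."
    ))
  }
  value <- if (mode == "clr") {
    clr_transform(data, parts)[[aoi]]
  } else {
    data[[aoi]]
  }
  df <- tibble::tibble(
    participant = data$participant, task = data$task, value = value
  )
  centred <- df |>
    dplyr::group_by(.data$participant) |>
    dplyr::mutate(dev = .data$value - mean(.data$value)) |>
    dplyr::ungroup()
  out <- centred |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(effect = mean(.data$dev), .groups = "drop")
  if (mode == "clr") out$multiplier <- exp(out$effect)
  out
}

#' Fit a Gaussian discriminant classifier (LDA / QDA)
#'
#' Classifies observations into groups via Bayes' rule on Gaussian class
#' densities of the response coordinates: ilr pivot coordinates of the
#' composition (`mode = "ilr"`, so the rule respects the Aitchison geometry
#' and is invariant to the choice of log-ratio basis) or raw dwell times
#' (`mode = "raw"`). LDA pools a common covariance across classes (divisor
#' N - K); QDA estimates one covariance per class (divisor n_k - 1). Priors
#' default to the empirical class shares.
#'
#' @param data Wide composition table.
#' @param parts Optional part column names.
#' @param group Grouping column (default `"task"`).
#' @param kind `"lda"` or `"qda"`.
#' @param mode `"ilr"` or `"raw"`.
#' @param priors Optional numeric vector of prior class probabilities, named
#'   by class or in class-level order; must sum to 1.
#' @return An object of class `gaze_classifier` with means, covariances,
#'   priors and bookkeeping; see [predict.gaze_classifier()].
#' @export
fit_discriminant <- function(data, parts = NULL, group = "task",
                             kind = c("lda", "qda"), mode = c("ilr", "raw"),
                             priors = NULL) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  parts <- part_cols(data, parts)
  g <- factor(data[[group]])
  K <- nlevels(g)
  if (K < 2L) abort("Classification needs at least 2 classes.")
  Y <- response_matrix(data, parts, mode)
  p <- ncol(Y)
  N <- nrow(Y)
  nk <- as.vector(table(g))
  if (kind == "qda" && any(nk <= p)) {
    abort(paste0(
      "QDA needs n_k > p in every class; deficient class(es): ",
      paste(levels(g)[nk <= p], collapse = ", ")
    ))
  }
  if (kind == "lda" && (N - K) <= p) {
    abort("LDA needs N - K > p for a full-rank pooled covariance.")
  }
  means <- rowsum(Y, g) / nk
  covs <- NULL
  pooled <- NULL
  if (kind == "lda") {
    W <- matrix(0, p, p)
    for (i in seq_len(K)) {
      Yk <- Y[g == levels(g)[i], , drop = FALSE]
      W <- W + crossprod(sweep(Yk, 2, means[i, ]))
    }
    pooled <- W / (N - K)
    if (inherits(try(chol(pooled), silent = TRUE), "try-error")) {
      abort("Pooled covariance is singular; merge AOIs or reduce dimensions.")
    }
  } else {
    covs <- purrr::map(seq_len(K), function(i) {
      Yk <- Y[g == levels(g)[i], , drop = FALSE]
      S <- crossprod(sweep(Yk, 2, means[i, ])) / (nk[i] - 1)
      if (inherits(try(chol(S), silent = TRUE), "try-error")) {
        abort(paste0(
          "Covariance of class '", levels(g)[i], "' is singular."
        ))
      }
      S
    }) |> setNames(levels(g))
  }
  if (is.null(priors)) {
    priors <- setNames(nk / N, levels(g))
  } else {
    if (!is.null(names(priors))) priors <- priors[levels(g)]
    if (length(priors) != K || any(is.na(priors)) ||
      abs(sum(priors) - 1) > 1e-8) {
      abort("`priors` must cover every class and sum to 1.")
    }
    priors <- setNames(as.numeric(priors), levels(g))
  }
  structure(
    list(
      kind = kind, mode = mode, group = group, parts = parts,
      levels = levels(g), priors = priors,
      means = means, pooled_cov = pooled, class_covs = covs,
      n = N, n_k = setNames(nk, levels(g)), p = p
    ),
    class = "gaze_classifier"
  )
}

#' @export
print.gaze_classifier <- function(x, ...) {
  cat(toupper(x$kind), " classifier (", x$mode, " mode): ",
    length(x$levels), " classes, ", x$p, " coordinates, n = ", x$n, "\n",
    sep = ""
  )
  invisible(x)
}

# Gaussian log-density up to a common additive constant.
gauss_logdens <- function(Y, mu, Sigma) {
  ch <- chol(Sigma)
  dev <- sweep(Y, 2, mu)
  z <- backsolve(ch, t(dev), transpose = TRUE)
  -sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

#' Predict task membership from a fitted discriminant classifier
#'
#' @param object A [fit_discriminant()] fit.
#' @param newdata Wide composition table with the same part columns.
#' @param ... Unused.
#' @return A tibble with the id columns of `newdata`, the predicted class
#'   `.class`, and one posterior-probability column per class (rows sum
#'   to 1).
#' @export
predict.gaze_classifier <- function(object, newdata, ...) {
  parts <- object$parts
  Y <- response_matrix(newdata, parts, object$mode)
  K <- length(object$levels)
  logd <- vapply(seq_len(K), function(k) {
    Sigma <- if (object$kind == "lda") object$pooled_cov else object$class_covs[[k]]
    gauss_logdens(Y, object$means[k, ], Sigma)
  }, numeric(nrow(Y)))
  if (nrow(Y) == 1L) logd <- matrix(logd, nrow = 1)
  logpost <- sweep(logd, 2, log(object$priors), "+")
  logpost <- logpost - apply(logpost, 1, max)
  post <- exp(logpost)
  post <- post / rowSums(post)
  colnames(post) <- object$levels
  pred <- object$levels[max.col(post, ties.method = "first")]
  dplyr::bind_cols(
    tibble::as_tibble(newdata[id_cols(newdata, parts)]),
    tibble::tibble(.class = pred),
    tibble::as_tibble(post)
  )
}

#' Stratified k-fold cross-validation of a discriminant classifier
#'
#' Assigns observations to folds stratified by class (each class's rows are
#' shuffled under `seed` and dealt round-robin across folds), trains the
#' classifier on each training split and pools the held-out predictions into
#' an overall accuracy and a confusion matrix. The fold assignment — and
#' hence the whole report — is a deterministic function of the seed.
#'
#' @inheritParams fit_discriminant
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment (required).
#' @return Object of class `cv_report`: `accuracy`, `confusion` (K x K
#'   matrix, rows = true class), `folds`, `fold_assignment`, `seed`,
#'   `kind`, `mode`. `glance()` and `tidy()` methods summarise it.
#' @export
cross_validate <- function(data, parts = NULL, group = "task",
                           kind = c("lda", "qda"), mode = c("ilr", "raw"),
                           folds = 10L, seed, priors = NULL) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  parts <- part_cols(data, parts)
  if (missing(seed) || !is.numeric(seed)) {
    abort("A numeric `seed` is required for reproducible fold assignment.")
  }
  if (folds < 2L) abort("`folds` must be at least 2.")
  g <- factor(data[[group]])
  if (any(table(g) < folds)) {
    abort("Every class needs at least `folds` observations for stratification.")
  }
  n <- nrow(data)
  fold_id <- integer(n)
  withr::with_seed(as.integer(seed), {
    for (lev in levels(g)) {
      idx <- which(g == lev)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  truth <- as.character(g)
  pred <- character(n)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit <- fit_discriminant(data[!test, , drop = FALSE], parts, group,
      kind = kind, mode = mode, priors = priors
    )
    pred[test] <- predict(fit, data[test, , drop = FALSE])$.class
  }
  levs <- levels(g)
  confusion <- table(
    factor(truth, levels = levs),
    factor(pred, levels = levs)
  )
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("true", "predicted")
  structure(
    list(
      accuracy = mean(pred == truth),
      confusion = confusion,
      folds = folds,
      fold_assignment = fold_id,
      seed = as.integer(seed),
      kind = kind, mode = mode, levels = levs, n = n
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV, %s (%s mode): accuracy %.1f%% (chance %.1f%%)\n",
    x$folds, toupper(x$kind), x$mode, 100 * x$accuracy,
    100 / length(x$levels)
  ))
  print(x$confusion)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, mode = x$mode, folds = x$folds, n = x$n,
    accuracy = x$accuracy, chance = 1 / length(x$levels), seed = x$seed
  )
}

#' @exportS3Method generics::tidy
tidy.cv_report <- function(x, ...) {
  df <- as.data.frame.table(x$confusion, responseName = "n")
  tibble::as_tibble(df)
}
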