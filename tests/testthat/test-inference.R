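# MANOVA, pairwise Holm tests, balanced task effects, discriminant
# classification and cross-validation.

make_grouped <- function(n_per = 12, K = 3, D = 4, seed = 100, shift = 0.8) {
  rows <- purrr::map(seq_len(K), function(k) {
    m <- withr::with_seed(seed + k, matrix(exp(rnorm(n_per * D, 0, 0.5)), n_per))
    m[, 1] <- m[, 1] * exp(shift * (k - 1))
    colnames(m) <- paste0("A", seq_len(D))
    dplyr::bind_cols(
      tibble::tibble(
        participant = sprintf("g%d_%02d", k, seq_len(n_per)), task = k
      ),
      tibble::as_tibble(m)
    )
  })
  dplyr::bind_rows(rows)
}

test_that("Pillai statistic, F and p agree with the reference MANOVA implementation", {
  tbl <- make_grouped()
  for (mode in c("ilr", "raw")) {
    fit <- coda_manova(tbl, mode = mode)
    Y <- if (mode == "ilr") {
      as.matrix(ilr_transform(tbl)[paste0("z", 1:3)])
    } else {
      as.matrix(tbl[paste0("A", 1:4)])
    }
    ref <- summary(stats::manova(Y ~ factor(tbl$task)), test = "Pillai")$stats
    expect_equal(fit$pillai, unname(ref[1, "Pillai"]), tolerance = 1e-9)
    expect_equal(fit$f_stat, unname(ref[1, "approx F"]), tolerance = 1e-9)
    expect_equal(fit$df1, unname(ref[1, "num Df"]))
    expect_equal(fit$df2, unname(ref[1, "den Df"]))
    expect_equal(fit$p_value, unname(ref[1, "Pr(>F)"]), tolerance = 1e-9)
  }
})

test_that("ilr MANOVA is invariant to pivot order and row rescaling", {
  tbl <- make_grouped(seed = 110)
  fit <- coda_manova(tbl)
  for (ord in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    alt <- coda_manova(tbl, order = paste0("A", ord))
    expect_equal(alt$pillai, fit$pillai, tolerance = 1e-9)
    expect_equal(alt$f_stat, fit$f_stat, tolerance = 1e-9)
    expect_equal(alt$p_value, fit$p_value, tolerance = 1e-9)
  }
  scl <- withr::with_seed(111, exp(rnorm(nrow(tbl))))
  scaled <- tbl
  scaled[paste0("A", 1:4)] <- as.matrix(tbl[paste0("A", 1:4)]) * scl
  alt <- coda_manova(scaled)
  expect_equal(alt$pillai, fit$pillai, tolerance = 1e-9)
  # raw mode, in contrast, is changed by rescaling
  expect_gt(
    abs(coda_manova(scaled, mode = "raw")$pillai -
      coda_manova(tbl, mode = "raw")$pillai),
    1e-6
  )
})

test_that("two-group Pillai test coincides with Hotelling's T squared", {
  tbl <- make_grouped(K = 2, seed = 120)
  fit <- coda_manova(tbl)
  Y <- as.matrix(ilr_transform(tbl)[paste0("z", 1:3)])
  g <- tbl$task
  n1 <- sum(g == 1)
  n2 <- sum(g == 2)
  m1 <- colMeans(Y[g == 1, ])
  m2 <- colMeans(Y[g == 2, ])
  S <- (crossprod(sweep(Y[g == 1, ], 2, m1)) +
    crossprod(sweep(Y[g == 2, ], 2, m2))) / (n1 + n2 - 2)
  t2 <- n1 * n2 / (n1 + n2) *
    drop(t(m1 - m2) %*% solve(S, m1 - m2))
  p <- ncol(Y)
  f_ref <- (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p) * t2
  p_ref <- pf(f_ref, p, n1 + n2 - p - 1, lower.tail = FALSE)
  expect_equal(fit$f_stat, f_ref, tolerance = 1e-9)
  expect_equal(fit$p_value, p_ref, tolerance = 1e-9)
})

test_that("MANOVA guards reject degenerate designs", {
  tbl <- make_grouped()
  expect_error(coda_manova(tbl[tbl$task == 1, ]), "2 groups")
  expect_error(coda_manova(tbl[c(1:12, 13:15, 25:36), ]), "more observations")
  sing <- tbl
  sing$A2 <- sing$A1 * 2 # proportional parts make ilr covariance singular
  expect_error(coda_manova(sing), "singular")
})

test_that("Holm step-down matches hand-computed cases and the stats reference", {
  holm <- gazecoda:::holm_step_down
  expect_equal(holm(c(0.01, 0.01, 0.01)), c(0.03, 0.03, 0.03))
  expect_equal(holm(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  for (seed in 1:5) {
    p <- withr::with_seed(seed, runif(7))
    expect_equal(holm(p), p.adjust(p, method = "holm"))
  }
})

test_that("pairwise MANOVA covers all pairs and reduces to the single test for K = 2", {
  tbl <- make_grouped(K = 3, seed = 130)
  pw <- pairwise_manova(tbl)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_adjusted >= pw$p_value))
  two <- tbl[tbl$task %in% c(1, 2), ]
  pw2 <- pairwise_manova(two)
  expect_equal(nrow(pw2), 1)
  expect_equal(pw2$p_adjusted, pw2$p_value)
  expect_equal(pw2$p_value, coda_manova(two)$p_value)
})

test_that("balanced task effects centre, recover constructed shifts and reject imbalance", {
  # no within-participant variation: all effects zero
  flat <- tidyr::expand_grid(participant = c("a", "b"), task = 1:3) |>
    dplyr::mutate(A = 2, B = 3, C = 5)
  eff0 <- clr_task_effects(flat, "A")
  expect_equal(eff0$effect, rep(0, 3))

  # constructed per-task perturbations: truth derived from the task means
  mu <- pooled_mean_composition()
  delta <- c(0.5, -0.3, 0.4, -0.6, 0, 0.2, -0.2)
  means <- t(vapply(seq_along(delta), function(k) {
    p <- setNames(rep(1, 7), names(mu))
    p["Man"] <- exp(delta[k])
    unname(perturb(mu, p, kappa = 100))
  }, numeric(7)))
  colnames(means) <- names(mu)
  cm <- t(apply(means, 1, clr))[, "Man"]
  truth <- cm - mean(cm)
  sim <- simulate_experiment(
    n_participants = 200, task_means = means,
    sigma_p = 0.3, sigma_e = 0.4, seed = 140
  )
  wide <- to_composition_matrix(sim, quiet = TRUE)
  eff <- clr_task_effects(wide, "Man")
  expect_equal(sum(eff$effect), 0, tolerance = 1e-12)
  expect_lt(max(abs(eff$effect - unname(truth))), 0.1)
  expect_equal(eff$multiplier, exp(eff$effect))

  unbal <- wide[-1, ]
  expect_error(clr_task_effects(unbal, "Man"), "balanced")
})

test_that("discriminant fits separate what is separable and normalise posteriors", {
  n <- 40
  tbl <- tibble::tibble(
    participant = sprintf("p%02d", 1:(2 * n)),
    task = rep(1:2, each = n),
    A = exp(c(
      withr::with_seed(150, rnorm(n, -5, 0.5)),
      withr::with_seed(151, rnorm(n, 5, 0.5))
    )),
    B = 1
  )
  fit <- fit_discriminant(tbl, kind = "lda")
  pred <- predict(fit, tbl)
  expect_equal(mean(pred$.class == as.character(tbl$task)), 1)
  post <- as.matrix(pred[c("1", "2")])
  expect_equal(unname(rowSums(post)), rep(1, 2 * n), tolerance = 1e-12)

  # agreement with the reference LDA on the same coordinates
  skip_if_not_installed("MASS")
  tbl2 <- make_grouped(seed = 152)
  Z <- ilr_transform(tbl2)
  fit2 <- fit_discriminant(tbl2, kind = "lda")
  ref <- MASS::lda(as.matrix(Z[paste0("z", 1:3)]), grouping = factor(tbl2$task))
  ref_pred <- predict(ref, as.matrix(Z[paste0("z", 1:3)]))
  expect_equal(predict(fit2, tbl2)$.class, as.character(ref_pred$class))
})

test_that("QDA uses class covariances and rejects deficient classes", {
  tbl <- make_grouped(n_per = 20, seed = 160)
  fit <- fit_discriminant(tbl, kind = "qda")
  expect_length(fit$class_covs, 3)
  pred <- predict(fit, tbl)
  expect_gt(mean(pred$.class == as.character(tbl$task)), 0.5)
  tiny <- tbl[c(1:20, 21:23, 41:60), ]
  expect_error(fit_discriminant(tiny, kind = "qda"), "n_k > p")
})

test_that("classifier decisions are invariant to the ilr pivot order", {
  tbl <- make_grouped(seed = 170)
  base <- fit_discriminant(tbl, kind = "lda")
  pred_base <- predict(base, tbl)$.class
  reordered <- tbl[c("participant", "task", "A3", "A1", "A4", "A2")]
  alt <- fit_discriminant(reordered, parts = c("A3", "A1", "A4", "A2"))
  expect_equal(predict(alt, reordered)$.class, pred_base)
})

test_that("cross-validation is seed-deterministic and finds separable structure", {
  tbl <- make_grouped(n_per = 30, K = 3, shift = 3, seed = 180)
  cv1 <- cross_validate(tbl, folds = 5, seed = 9)
  cv2 <- cross_validate(tbl, folds = 5, seed = 9)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_identical(cv1$confusion, cv2$confusion)
  expect_equal(cv1$accuracy, 1) # strongly separated groups
  expect_equal(sum(cv1$confusion), nrow(tbl))
  expect_equal(unname(rowSums(cv1$confusion)), rep(30, 3))
  cv3 <- cross_validate(tbl, folds = 5, seed = 10)
  expect_false(identical(cv1$fold_assignment, cv3$fold_assignment))
  expect_error(cross_validate(tbl, folds = 5), "seed")
  expect_error(cross_validate(tbl, folds = 40, seed = 1), "at least")
})
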