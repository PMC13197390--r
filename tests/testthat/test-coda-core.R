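# The Aitchison-geometry kernel: closure, perturbation, log-ratio
# transforms, distances, and descriptive compositional statistics.

test_that("closure rescales to kappa while preserving ratios", {
  expect_equal(close_composition(c(1, 1, 1)), rep(1 / 3, 3))
  # the two-observer percentage closures, at the printed one-decimal precision
  expect_equal(round(unname(close_composition(p74, 100)), 1), c(46.3, 29.7, 24.0))
  expect_equal(round(unname(close_composition(p101, 100)), 1), c(47.5, 29.9, 22.5))
  x <- c(3, 5, 9)
  cl <- close_composition(x, 42)
  expect_equal(sum(cl), 42)
  expect_equal(cl[1] / cl[3], x[1] / x[3])
  expect_error(close_composition(c(1, -2, 3)), "positive")
  expect_error(close_composition(c(a = 1, b = 0, c = 3)), "b")
  expect_error(close_composition(c(1, 2), kappa = 0), "kappa")
})

test_that("perturbation is the commutative group operation with uniform neutral element", {
  x <- c(0.2, 0.3, 0.5)
  expect_equal(perturb(x, c(1, 1, 1)), x)
  expect_equal(perturb(c(1, 2), c(2, 1)), c(0.5, 0.5))
  for (seed in 1:5) {
    a <- rand_comp(4, seed)
    b <- rand_comp(4, seed + 100)
    expect_equal(perturb(a, b), perturb(b, a))
    # inverse element: perturbing by 1/a recovers the uniform composition
    expect_equal(perturb(a, 1 / a), rep(0.25, 4))
  }
  expect_error(perturb(c(1, 2), c(1, 2, 3)), "same number")
})

test_that("power scaling completes the simplex vector space", {
  x <- c(1, 2, 5)
  expect_equal(power_scale(x, 0), rep(1 / 3, 3))
  expect_equal(power_scale(x, 1), close_composition(x))
  expect_equal(power_scale(c(1, 2), 2), c(0.2, 0.8))
})

test_that("clr centres logs, sums to zero and is scale invariant", {
  expect_equal(clr(c(1, 1, 1)), c(0, 0, 0))
  # frozen from an independent evaluation of log(x) - mean(log(x))
  expect_equal(round(unname(clr(p74)), 4), c(0.3658, -0.0756, -0.2902))
  for (seed in 1:10) {
    x <- rand_comp(6, seed)
    y <- clr(x)
    expect_lt(abs(sum(y)), 1e-10)
    expect_equal(clr(x * 7.3), y)
  }
  expect_error(clr(c(1, 0, 2)), "positive")
})

test_that("clr inverse round-trips and rejects off-hyperplane input", {
  expect_equal(clr_inverse(c(0, 0, 0)), rep(1 / 3, 3))
  m <- log(2) / 3
  expect_equal(clr_inverse(c(log(2) - m, -m, -m), kappa = 4), c(2, 1, 1))
  for (seed in 1:10) {
    x <- close_composition(rand_comp(5, seed))
    expect_equal(clr_inverse(clr(x)), x, tolerance = 1e-9)
  }
  expect_error(clr_inverse(c(1, 2, 3)), "sum to 0")
})

test_that("pivot coordinates have the closed form, isometry and round-trip properties", {
  expect_equal(ilr_pivot(rep(1, 5)), rep(0, 4))
  expect_equal(ilr_pivot(c(4, 1)), sqrt(1 / 2) * log(4))
  expect_equal(
    ilr_inverse(sqrt(1 / 2) * log(4)),
    close_composition(c(4, 1)),
    tolerance = 1e-4
  )
  expect_equal(ilr_inverse(c(0, 0, 0)), rep(0.25, 4))
  for (seed in 1:10) {
    x <- rand_comp(6, seed)
    z <- rand_comp(6, seed + 50)
    # isometry: coordinate distance equals clr distance equals Aitchison
    expect_equal(
      sqrt(sum((ilr_pivot(x) - ilr_pivot(z))^2)),
      sqrt(sum((clr(x) - clr(z))^2)),
      tolerance = 1e-9
    )
    expect_equal(
      ilr_inverse(ilr_pivot(x)), close_composition(x),
      tolerance = 1e-9
    )
  }
  # permuted pivot order: same norm, different coordinates, faithful inverse
  x <- c(a = 2, b = 7, c = 1, d = 4)
  z1 <- ilr_pivot(x)
  z2 <- ilr_pivot(x, order = c("d", "b", "a", "c"))
  expect_equal(sum(z1^2), sum(z2^2), tolerance = 1e-10)
  expect_equal(
    ilr_inverse(z2, order = c("d", "b", "a", "c"), parts = names(x)),
    close_composition(x),
    tolerance = 1e-9
  )
  expect_error(ilr_pivot(x, order = c("a", "b")), "permutation")
})

test_that("Aitchison distance matches the printed example and its invariances", {
  expect_equal(round(aitchison_distance(p74, p101), 3), 0.068)
  x <- rand_comp(5, 3)
  expect_equal(aitchison_distance(x, x), 0)
  expect_equal(aitchison_distance(x, 17 * x), 0)
  for (seed in 1:8) {
    a <- rand_comp(5, seed)
    b <- rand_comp(5, seed + 20)
    p <- rand_comp(5, seed + 40)
    expect_equal(
      aitchison_distance(perturb(p, a), perturb(p, b)),
      aitchison_distance(a, b),
      tolerance = 1e-9
    )
  }
})

test_that("compositional mean is the closed geometric mean and perturbation-equivariant", {
  tbl <- tibble::tibble(A = c(2, 2, 2), B = c(6, 6, 6))
  expect_equal(compositional_mean(tbl), c(A = 0.25, B = 0.75))
  tbl2 <- tibble::tibble(A = c(1, 2), B = c(2, 1))
  expect_equal(compositional_mean(tbl2), c(A = 0.5, B = 0.5))
  base <- rand_comp_table(20, 4, seed = 11)
  p <- rand_comp(4, 99)
  pert <- base
  pert[paste0("A", 1:4)] <- sweep(as.matrix(base[paste0("A", 1:4)]), 2, p, "*")
  expect_equal(
    compositional_mean(pert),
    perturb(compositional_mean(base), p),
    tolerance = 1e-9
  )
})

test_that("variation matrix matches hand-computed and brute-force values", {
  prop <- tibble::tibble(A = c(1, 2), B = c(2, 4), C = c(4, 8))
  vm0 <- variation_matrix(prop)
  expect_true(all(vm0$t == 0))
  expect_equal(vm0$totvar, 0)

  two <- tibble::tibble(A = c(1, 1), B = c(1, 2), C = c(1, 4))
  vm <- variation_matrix(two)
  expect_equal(vm$t["A", "B"], log(2)^2 / 2, tolerance = 1e-10)
  expect_equal(vm$t["A", "C"], log(4)^2 / 2, tolerance = 1e-10)
  expect_equal(vm$t["B", "C"], log(2)^2 / 2, tolerance = 1e-10)
  expect_equal(vm$totvar, (log(2)^2 + log(4)^2 / 2) / 3, tolerance = 1e-10)
  expect_equal(vm$totvar, 0.4804530, tolerance = 1e-6)

  tbl <- rand_comp_table(15, 5, seed = 21)
  m <- as.matrix(tbl[paste0("A", 1:5)])
  vm2 <- variation_matrix(tbl)
  expect_equal(unname(vm2$t), oracle_variation(m), tolerance = 1e-9)
  vm_ml <- variation_matrix(tbl, divisor = "ml")
  expect_equal(unname(vm_ml$t), oracle_variation(m, "ml"), tolerance = 1e-9)
  expect_equal(vm_ml$totvar, vm2$totvar * 14 / 15, tolerance = 1e-10)
  expect_error(variation_matrix(tbl[1, ]), "at least 2")
})

test_that("total variance equals both the double sum and the clr column variances", {
  for (seed in 1:6) {
    tbl <- rand_comp_table(12, 4, seed = seed)
    tv <- total_variance(tbl)
    y <- clr_transform(tbl)
    clr_var <- sum(apply(as.matrix(y[paste0("A", 1:4)]), 2, var))
    expect_equal(tv, clr_var, tolerance = 1e-9)
    # scale invariance: rescaling rows changes nothing
    scaled <- tbl
    scl <- withr::with_seed(seed, exp(rnorm(12)))
    scaled[paste0("A", 1:4)] <- as.matrix(tbl[paste0("A", 1:4)]) * scl
    expect_equal(total_variance(scaled), tv, tolerance = 1e-9)
  }
})

test_that("zero replacement imputes a fraction of the column minimum", {
  clean <- tibble::tibble(A = c(1, 2), B = c(3, 4))
  expect_equal(replace_zeros(clean, quiet = TRUE)[c("A", "B")], clean,
    ignore_attr = TRUE
  )
  tbl <- tibble::tibble(A = c(100, 200, 0), B = c(5, 6, 7))
  out <- suppressMessages(replace_zeros(tbl))
  expect_equal(out$A[3], 65)
  expect_equal(out$A[1:2], c(100, 200))
  expect_equal(unname(attr(out, "zero_replacements")["A"]), 1L)
  expect_error(replace_zeros(tbl, fraction = 0), "positive")
  allzero <- tibble::tibble(A = c(0, 0), B = c(1, 2))
  expect_error(replace_zeros(allzero), "merge")
})
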