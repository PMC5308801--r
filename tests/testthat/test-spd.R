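test_that("covariance estimation matches hand-computed and brute-force values", {
  # hand evaluation: alternating ±1 signals, perfectly anti-correlated
  # (rank one, so the singularity flag fires too)
  x <- rbind(c(1, -1, 1, -1), c(-1, 1, -1, 1))
  expect_warning(cx <- estimate_covariance(x), "positive definite")
  expect_equal(unname(cx), matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)
  # constant signals give the zero matrix and a non-SPD warning
  xc <- rbind(c(1, 1, 1), c(2, 2, 2))
  expect_warning(cc <- estimate_covariance(xc), "positive definite")
  expect_equal(unname(cc), matrix(0, 2, 2), ignore_attr = TRUE)
  # random input equals the elementwise double-loop oracle
  set.seed(5)
  x <- matrix(rnorm(4 * 50), 4)
  expect_lt(max(abs(estimate_covariance(x) - brute_cov(x))) /
              max(abs(brute_cov(x))), 1e-12)
  # shrinkage adds trace/N loading on the diagonal
  s <- estimate_covariance(x, shrinkage = 0.1)
  expect_equal(s, estimate_covariance(x) + 0.1 * mean(diag(brute_cov(x))) *
                 diag(4))
  expect_error(estimate_covariance(x[, 1, drop = FALSE]),
               class = "riemsway_input_error")
})

test_that("the Riemannian distance has its closed forms and metric axioms", {
  expect_equal(riemann_distance(diag(2), diag(2)), 0)
  expect_equal(riemann_distance(diag(2), diag(c(4, 4))), sqrt(2) * log(4))
  expect_error(riemann_distance(diag(2), diag(3)),
               class = "riemsway_input_error")
  set.seed(21)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    a <- rand_spd(n); b <- rand_spd(n); cc <- rand_spd(n)
    dab <- riemann_distance(a, b)
    expect_gte(dab, 0)
    expect_lt(abs(dab - riemann_distance(b, a)), 1e-10)
    expect_lte(dab, riemann_distance(a, cc) + riemann_distance(cc, b) + 1e-8)
    # inversion invariance
    expect_lt(abs(dab - riemann_distance(solve(a), solve(b))) / dab, 1e-8)
  }
})

test_that("the log-Euclidean mean matches commuting-matrix closed forms", {
  set.seed(3)
  a <- rand_spd(4)
  expect_equal(logeuclid_mean(list(a, a)), a, tolerance = 1e-10)
  expect_equal(logeuclid_mean(list(a)), a, tolerance = 1e-12)
  m <- logeuclid_mean(list(diag(c(1, 4)), diag(c(4, 1))))
  expect_equal(m, diag(c(2, 2)), tolerance = 1e-10)
  expect_error(logeuclid_mean(list()), class = "riemsway_input_error")
  # commutes with joint rotation (similarity acts inside the matrix log)
  v <- rand_orth(4)
  mats <- replicate(3, rand_spd(4), simplify = FALSE)
  lhs <- logeuclid_mean(purrr::map(mats, ~ v %*% .x %*% t(v)))
  rhs <- v %*% logeuclid_mean(mats) %*% t(v)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-8)
})

test_that("tangent projection vectorizes with norm-preserving weights", {
  # scalar case: diag(e^2, e^2) at reference I has tangent matrix diag(2,2)
  expect_equal(tangent_project(diag(c(exp(2), exp(2))), diag(2)),
               c(2, 0, 2))
  # projecting the reference itself gives the zero vector
  set.seed(9)
  a <- rand_spd(5)
  expect_equal(tangent_project(a, a), rep(0, 15), tolerance = 1e-10)
  # row-major upper-triangle order with sqrt(2) off-diagonal weights
  s <- matrix(c(1, 2, 2, 3), 2)
  v <- riemsway:::upper_vec(s)
  expect_equal(v, c(1, 2 * sqrt(2), 3))
  expect_equal(riemsway:::upper_unvec(v), s)
  # norm equivalence with the distance to the reference
  for (i in 1:10) {
    n <- sample(2:8, 1)
    cc <- rand_spd(n); ref <- rand_spd(n)
    expect_lt(abs(sqrt(sum(tangent_project(cc, ref)^2)) -
                    riemann_distance(cc, ref)) /
                riemann_distance(cc, ref), 1e-8)
  }
})

test_that("the feature pipeline produces the documented dimensions", {
  d <- small_mk2()
  tm <- fit_tangent_model(d[1:10, ])                 # 48-channel trials
  expect_equal(dim(tm$features), c(10, 48 * 49 / 2))
  tms <- fit_tangent_model(d[1:10, ], subset = "spine4")
  expect_equal(ncol(tms$features), 78)
  # a singleton list projects to exactly zero
  tm1 <- fit_tangent_model(d[1, ], shrinkage = 1e-6)
  expect_equal(max(abs(tm1$features)), 0, tolerance = 1e-9)
  # projecting the training trials through predict reproduces the features
  expect_equal(predict(tms, d[1:10, ]), tms$features, tolerance = 1e-12)
  # tidy output carries metadata plus one column per coordinate
  td <- tidy(tms)
  expect_equal(dim(td), c(10, 4 + 78))
})

test_that("feature export writes a CSV plus a reconstructable sidecar", {
  tm <- fit_tangent_model(small_mk2()[1:4, ], subset = "spine4")
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(tm, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 4)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$shrinkage, tm$shrinkage)
  expect_equal(as.matrix(side$reference), unname(tm$reference),
               tolerance = 1e-12)
})
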