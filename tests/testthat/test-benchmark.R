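test_that("block downsampling averages non-overlapping blocks", {
  x <- matrix(seq_len(40), 1, dimnames = list("cop_x", NULL))
  tr <- sway_trials("S01", 1, 1, "KFP",
                    list(rbind(x, cop_y = 0)), rate = 600)
  out <- block_downsample(tr, 30)
  expect_equal(out$rate, 30)
  expect_equal(unname(out$samples[[1]]["cop_x", ]),
               c(mean(1:20), mean(21:40)))
  # constant stays constant; factor 1 is the identity
  expect_equal(unname(block_downsample(tr, 30)$samples[[1]]["cop_y", ]),
               c(0, 0))
  expect_identical(block_downsample(tr, 600)$samples[[1]], tr$samples[[1]])
  # a trailing partial block is dropped
  tr41 <- sway_trials("S01", 1, 1, "KFP",
                      list(matrix(rnorm(2 * 41), 2,
                                  dimnames = list(c("cop_x", "cop_y"), NULL))),
                      rate = 600)
  expect_equal(ncol(block_downsample(tr41, 30)$samples[[1]]), 2)
  expect_error(block_downsample(tr, 70), class = "riemsway_input_error")
})

make_pair <- function(ax, ay, bx = NULL, by = NULL, rate_kfp = 30) {
  xm <- rbind(SpineMid_x = ax, SpineMid_y = rnorm(length(ax)),
              SpineMid_z = ay)
  xk <- rbind(cop_x = if (is.null(bx)) ax else bx,
              cop_y = if (is.null(by)) ay else by)
  list(mk2 = sway_trials("S01", 1, 1, "MK2", list(xm), rate = 30),
       kfp = sway_trials("S01", 1, 1, "KFP", list(xk), rate = rate_kfp))
}

test_that("per-axis correlation behaves at its fixed points", {
  set.seed(41)
  a <- rnorm(120); b <- rnorm(120)
  p <- make_pair(a, b)
  res <- correlate_pair(p$mk2, p$kfp)
  expect_equal(res$axis, c("x", "z"))
  expect_equal(res$r, c(1, 1))
  expect_equal(res$rmse, c(0, 0), tolerance = 1e-12)
  # negation flips the correlation
  pn <- make_pair(a, b, bx = -a)
  expect_equal(correlate_pair(pn$mk2, pn$kfp)$r[1], -1)
  # affine rescaling of either input changes nothing (standardized first)
  ps <- make_pair(a, b, bx = 3.2 * a + 7, by = -0.4 * b)
  res_s <- correlate_pair(ps$mk2, ps$kfp)
  expect_equal(abs(res_s$r), c(1, 1), tolerance = 1e-12)
  # perfectly anti-phased unit-sd series differ by twice their sd
  expect_equal(res_s$rmse[2], 2 * sqrt(119 / 120), tolerance = 1e-12)
  # zero variance is an undefined correlation
  pz <- make_pair(a, b, bx = rep(1, 120))
  expect_error(correlate_pair(pz$mk2, pz$kfp),
               class = "riemsway_numeric_error")
})

test_that("downsampling a noiseless linear pair keeps r = 1", {
  set.seed(42)
  a <- cumsum(rnorm(120))                 # smooth-ish trajectory
  b <- cumsum(rnorm(120))
  up <- function(v) approx(seq_along(v), v, n = 120 * 20)$y
  p <- make_pair(a, b, bx = up(a)[1:2400], by = up(b)[1:2400],
                 rate_kfp = 600)
  # not exactly the block means, so allow near-1 rather than exact
  res <- correlate_pair(p$mk2, p$kfp)
  expect_true(all(res$r > 0.99))
})

test_that("the dataset benchmark summarises per-subject agreement", {
  cfg <- synthetic_config(n_subjects = 3, n_tasks = 2, frames = 80,
                          template_separation = 2, cop_noise_sd = 0,
                          seed = 13)
  d <- generate_dataset(cfg)
  expect_warning(rep <- benchmark_dataset(d[-1, ]), "unpaired")
  rep <- suppressWarnings(benchmark_dataset(d))
  # 2 tasks x 3 joints x 2 axes
  expect_equal(nrow(rep), 2 * 3 * 2)
  expect_true(all(rep$mean_r >= -1 & rep$mean_r <= 1))
  expect_true(all(rep$sd_r >= 0))
  expect_equal(unique(rep$n), 3)
  # noise-free COP is a linear read-out of SpineMid; the only losses are
  # the half-frame smear of block-averaging the interpolated 600 Hz trace
  # (population r ~ 0.988 at this smoothness) and 80-frame sampling noise
  sm <- dplyr::filter(rep, joint == "SpineMid")
  expect_true(all(sm$mean_r >= 0.95))
  # summary means lie inside the range of contributing per-subject values
  pt <- tidy(rep) |>
    dplyr::group_by(task, joint, axis, subject) |>
    dplyr::summarise(r = mean(r), .groups = "drop_last") |>
    dplyr::summarise(lo = min(r), hi = max(r), .groups = "drop")
  j <- dplyr::inner_join(rep, pt, by = c("task", "joint", "axis"))
  expect_true(all(j$mean_r >= j$lo - 1e-12 & j$mean_r <= j$hi + 1e-12))
  # wide layout: one row per task, one column per joint-axis pair
  wide <- benchmark_table(rep)
  expect_equal(dim(wide), c(2, 1 + 6))
})
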