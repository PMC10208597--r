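test_that("cpp_series subtracts ICP from ABP samplewise", {
  abp <- cv_ts(rep(80, 100), 100, channels = "ABP")
  icp <- cv_ts(rep(15, 100), 100, channels = "ICP")
  expect_true(all(ts_values(cpp_series(abp, icp)) == 65))
  zero <- cv_ts(rep(0, 100), 100, channels = "ICP")
  expect_identical(ts_values(cpp_series(abp, zero))[, 1L],
                   ts_values(abp)[, 1L])
  # pulsatile ABP with constant ICP: CPP pulsatility equals ABP pulsatility
  puls <- cv_ts(80 + sin(1:100 / 5), 100, channels = "ABP")
  cpp <- cpp_series(puls, icp)
  expect_identical(ts_values(cpp)[, 1L] - mean(ts_values(cpp)),
                   ts_values(puls)[, 1L] - mean(ts_values(puls)))
  expect_error(cpp_series(abp, cv_ts(rep(1, 50), 100)), "cv_curve_misaligned")
})

test_that("CPP binning is half-open on a 3 mmHg grid and discards singletons", {
  w <- fake_windows(cpp = c(64.0, 65.9), z = c(2, 4))
  cur <- bin_curve(w)
  expect_identical(nrow(cur), 1L)
  expect_equal(cur$center, 64.5)          # bin [63, 66)
  expect_equal(cur$value, 3)
  expect_identical(cur$n, 2L)

  w2 <- fake_windows(cpp = c(64, 65, 70), z = c(2, 4, 9))
  cur2 <- bin_curve(w2)
  expect_false(any(abs(cur2$center - 70.5) < 1e-9))  # singleton bin dropped
  expect_identical(attr(cur2, "n_discarded"), 1L)

  # exact edge 66 goes to the upper bin
  w3 <- fake_windows(cpp = c(66, 66.5, 65.9, 65.0), z = c(1, 1, 1, 1))
  cur3 <- bin_curve(w3)
  expect_equal(cur3$center, c(64.5, 67.5))
  expect_identical(cur3$n, c(2L, 2L))
})

test_that("binning matches a brute-force groupby on 1000 random windows", {
  set.seed(66)
  cpp <- runif(1000, 40, 95)
  z <- rlnorm(1000)
  cur <- bin_curve(fake_windows(cpp, z))
  edges <- floor(cpp / 3) * 3
  for (i in seq_len(nrow(cur))) {
    v <- z[edges == cur$center[i] - 1.5]
    expect_equal(cur$value[i], mean(v), tolerance = 1e-12)
    expect_equal(cur$se[i], stats::sd(v) / sqrt(length(v)), tolerance = 1e-12)
    expect_identical(cur$n[i], length(v))
  }
  # count conservation: retained + discarded = accepted
  expect_identical(sum(cur$n) + attr(cur, "n_discarded"),
                   attr(cur, "n_accepted"))
})

test_that("normalization divides by the 65 mmHg bin and is idempotent", {
  cur <- curve_from_values(seq(49.5, 79.5, 3), c(4, 3, 2, 2, 2, 2, 3, 4, 5, 6, 7))
  cur$value[6] <- 2                      # bin [63,66) -> center 64.5, value 2
  norm <- normalize_curve(cur)
  expect_equal(norm$value[norm$center == 64.5], 1)
  expect_equal(norm$value, cur$value / 2)
  expect_equal(normalize_curve(norm)$value, norm$value)  # idempotent
  cur0 <- cur; cur0$value[6] <- 0
  expect_error(normalize_curve(cur0), "cv_curve_degenerate_reference")
  cur_missing <- cur[cur$center != 64.5, ]
  attr(cur_missing, "bin_width") <- 3
  expect_error(normalize_curve(cur_missing), "cv_curve_no_reference")
})

test_that("cohort averaging takes per-bin means and cross-subject SE", {
  c1 <- curve_from_values(c(60.5, 63.5, 66.5) + 1, c(1, 2, 3))
  expect_error(cohort_average(list(c1)), "length")
  two <- cohort_average(list(c1, c1))
  expect_equal(two$value, c1$value)
  expect_equal(two$se, c(0, 0, 0))

  c2 <- c1; c2$value <- c(3, 2, 1)
  avg <- cohort_average(list(c1, c2))
  expect_equal(avg$value, c(2, 2, 2))
  expect_equal(avg$se[1], 1)             # sd(1,3)/sqrt(2) = sqrt(2)/sqrt(2)

  set.seed(77)
  curves <- lapply(1:3, function(i)
    curve_from_values(seq(43.5, 91.5, 3), rlnorm(17)))
  got <- cohort_average(curves)
  for (i in seq_len(nrow(got))) {
    vals <- sapply(curves, function(c) c$value[c$center == got$center[i]])
    expect_equal(got$value[i], mean(vals), tolerance = 1e-12)
    expect_equal(got$se[i], stats::sd(vals) / sqrt(3), tolerance = 1e-12)
  }
  cbad <- curve_from_values(c(44, 47, 50), 1:3)  # different anchoring
  expect_error(cohort_average(list(curves[[1]], cbad)),
               "cv_curve_incompatible_grids")
})

test_that("limit estimation recovers noiseless breakpoints exactly", {
  gt <- ground_truth(lla = 60, ula = 72)
  centers <- seq(46.5, 94.5, 3)
  tent <- curve_from_values(centers, gt$z_fun(centers, 1L))
  lim <- estimate_limits(tent, "tent")
  expect_equal(c(lim$lla, lim$ula), c(60, 72))
  expect_lt(lim$sse, 1e-20)

  lassen <- curve_from_values(centers, gt$f_fun(centers))
  liml <- estimate_limits(lassen, "plateau")
  expect_equal(c(liml$lla, liml$ula), c(60, 72))

  expect_error(estimate_limits(tent[1:4, ], "tent"), "cv_curve_too_few_bins")
})

test_that("limit estimation equals an independent exhaustive SSE scan", {
  set.seed(88)
  gt <- ground_truth(lla = 57, ula = 75)
  centers <- seq(43.5, 94.5, 3)
  y <- gt$z_fun(centers, 1L) + rnorm(length(centers), sd = 0.03)
  cur <- curve_from_values(centers, y)
  lim <- estimate_limits(cur, "tent")
  # independent scan: solve each constrained 3-segment fit via normal equations
  cand <- seq(min(centers), max(centers), by = 1.5)
  best <- list(sse = Inf)
  for (b1 in cand) for (b2 in cand[cand > b1]) {
    if (sum(centers < b1) < 2 || sum(centers > b2) < 2 ||
        sum(centers >= b1 & centers <= b2) < 2) next
    X <- cbind(1, centers, pmax(centers - b1, 0), pmax(centers - b2, 0))
    beta <- tryCatch(solve(crossprod(X), crossprod(X, y)), error = function(e) NULL)
    if (is.null(beta)) next
    s <- cumsum(beta[2:4])
    if (!(s[1] < 0 && s[2] > 0 && s[3] < 0)) next
    sse <- sum((y - X %*% beta)^2)
    if (sse < best$sse) best <- list(sse = sse, lla = b1, ula = b2)
  }
  expect_equal(c(lim$lla, lim$ula), c(best$lla, best$ula))
  expect_equal(lim$sse, best$sse, tolerance = 1e-9)
})

test_that("normalized cohort curves are invariant to per-subject rescaling", {
  set.seed(99)
  ws <- lapply(1:3, function(s)
    fake_windows(runif(120, 42, 95), rlnorm(120)))
  build <- function(wlist, scale) {
    cur <- lapply(seq_along(wlist), function(i) {
      w <- wlist[[i]]
      w$z_cbv <- w$z_cbv * scale[i]
      normalize_curve(bin_curve(w))
    })
    cohort_average(cur)
  }
  a <- build(ws, c(1, 1, 1))
  b <- build(ws, c(17.3, 0.004, 2.2))
  expect_equal(a$value, b$value, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
})
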