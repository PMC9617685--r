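test_that("gaussian_loglik matches the closed form and the cost identity", {
  # [0, 2] with no changepoints: -log(2*pi) - 1
  expect_equal(gaussian_loglik(c(0, 2)), -log(2 * pi) - 1)

  set.seed(5)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    y <- rnorm(n) + 4 * (seq_len(n) > n / 3)
    cps <- sort(sample(seq_len(n - 1), sample(0:4, 1)))
    fl <- ascept:::sd_floor_for(y)
    expect_equal(
      gaussian_loglik(y, cps, fl),
      -0.5 * ascept:::total_cost(y, cps, fl)
    )
    # and against an independent per-segment density sum
    b <- ascept:::segment_bounds(cps, n)
    ll <- sum(vapply(seq_len(nrow(b)), function(j) {
      -0.5 * density_sum_cost(y[b[j, 1]:b[j, 2]], fl)
    }, numeric(1)))
    expect_equal(gaussian_loglik(y, cps, fl), ll)
  }
})

test_that("simulate_null_series is seeded, segment-faithful, label-preserving", {
  set.seed(8)
  y <- c(rnorm(40, 0), rnorm(40, 6))
  d <- as.Date("2021-06-01") + 0:79
  s <- as_series(y, labels = d)

  a <- simulate_null_series(s, 40, seed = 99)
  b <- simulate_null_series(s, 40, seed = 99)
  expect_identical(a$values, b$values)
  expect_identical(a$labels, d)
  expect_equal(a$n, 80L)

  # degenerate length-1 segment draws at the floor scale around its value
  fl <- 0.5
  draws <- vapply(1:200, function(i) {
    simulate_null_series(c(3, 10, 3.2), c(1, 2), seed = i, sd_floor = fl)$values[2]
  }, numeric(1))
  expect_lt(abs(mean(draws) - 10), 5 * fl / sqrt(200))
  expect_lt(abs(sd(draws) - fl), 0.2 * fl)

  # per-segment sample means stay in a 99.9% normal band around the
  # segment estimates
  fl2 <- ascept:::sd_floor_for(y)
  ms <- ascept:::segment_mu_sd(y, 40, fl2)
  sims <- vapply(1:400, function(i) {
    v <- simulate_null_series(s, 40, seed = 1000 + i, sd_floor = fl2)$values
    c(mean(v[1:40]), mean(v[41:80]))
  }, numeric(2))
  for (seg in 1:2) {
    mu <- ms$mu[c(1, 41)][seg]
    sdm <- ms$sd[c(1, 41)][seg] / sqrt(40)
    z <- (mean(sims[seg, ]) - mu) / (sdm / sqrt(400))
    expect_lt(abs(z), 3.3)
  }
})

test_that("empirical_pvalue has add-one bounds and honest degenerate cases", {
  set.seed(13)
  y <- c(rnorm(30), rnorm(30, 5))

  # identical sets: all deltas zero, p = 1
  mc <- empirical_pvalue(y, 30, 30, n_sim = 99, seed = 1)
  expect_equal(mc$observed_delta, 0)
  expect_true(all(mc$null_deltas == 0))
  expect_equal(mc$p_value, 1)

  # bounds and reproducibility
  mc1 <- empirical_pvalue(y, integer(0), 30, n_sim = 199, seed = 7)
  mc2 <- empirical_pvalue(y, integer(0), 30, n_sim = 199, seed = 7)
  expect_identical(mc1$null_deltas, mc2$null_deltas)
  expect_gte(mc1$p_value, 1 / 200)
  expect_lte(mc1$p_value, 1)
  # a 5-sigma shift is decisively significant
  expect_equal(mc1$p_value, 1 / 200)

  expect_error(empirical_pvalue(y, integer(0), 30, n_sim = 0), "n_sim")
})

test_that("nested refinements never lower the maximized likelihood", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    y <- rnorm(n) + 3 * (seq_len(n) > n / 2)
    k <- sample(1:4, 1)
    Tk1 <- sort(sample(seq_len(n - 1), k + 2))
    Tk <- sort(sample(Tk1, k))
    mc <- empirical_pvalue(y, Tk, Tk1, n_sim = 1, seed = i)
    expect_gte(mc$observed_delta, -1e-8)
  }
})

test_that("select_stage1 walks the path and stops at non-rejection", {
  set.seed(23)
  y <- c(rnorm(50), rnorm(50, 6), rnorm(50, -4))
  raw <- crops_sweep(y, 0.5, 50 * log(150))
  path <- build_candidate_path(raw, y)

  st <- suppressWarnings(
    select_stage1(y, path, alpha = 0.01, n_sim = 199, seed = 31)
  )
  expect_s3_class(st, "ascept_stage1")
  ps <- vapply(st$tests, `[[`, numeric(1), "p_value")
  if (length(ps) > 1) {
    expect_true(all(ps[-length(ps)] <= 0.01))
  }
  if (!st$exhausted) {
    expect_gt(ps[length(ps)], 0.01)
  }
  # the two genuine shifts are found
  expect_true(any(abs(st$selected - 50) <= 1))
  expect_true(any(abs(st$selected - 100) <= 1))

  # reproducibility of the whole walk
  st2 <- suppressWarnings(
    select_stage1(y, path, alpha = 0.01, n_sim = 199, seed = 31)
  )
  expect_identical(st$selected, st2$selected)
  expect_identical(
    vapply(st$tests, `[[`, numeric(1), "p_value"),
    vapply(st2$tests, `[[`, numeric(1), "p_value")
  )

  # a path holding only the empty set needs no tests
  p0 <- build_candidate_path(
    list(list(beta_lo = 1, beta_hi = 2, positions = integer(0), cost = 0)), y
  )
  st0 <- select_stage1(y, p0, n_sim = 9, seed = 1)
  expect_length(st0$tests, 0)
  expect_equal(st0$selected, integer(0))

  expect_error(select_stage1(y, path, alpha = 1.2), "alpha")
})

test_that("false-positive frequency on noise decreases with alpha", {
  reject <- function(alpha) {
    sum(vapply(1:12, function(i) {
      s <- generate_noise(200, seed = 500 + i)
      raw <- crops_sweep(s, 0.05 * log(200), 50 * log(200))
      path <- build_candidate_path(raw, s)
      st <- suppressWarnings(
        select_stage1(s, path, alpha = alpha, n_sim = 199, seed = 700 + i)
      )
      length(st$selected) > 0
    }, logical(1)))
  }
  r05 <- reject(0.05)
  r01 <- reject(0.01)
  expect_lte(r01, r05)
  expect_lte(r01, 6) # at most half the runs
})
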