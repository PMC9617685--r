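test_that("segment_cost matches closed forms and the density-sum oracle", {
  # hand computation: [0, 2] has MLE variance 1
  expect_equal(segment_cost(c(0, 2)), 2 * (log(2 * pi) + 1))

  # constant segment: variance constrained up to the floor; cost equals the
  # density sum at (mean, floor) exactly
  fl <- 0.01
  expect_equal(
    segment_cost(c(4, 4, 4), sd_floor = fl),
    density_sum_cost(c(4, 4, 4), fl)
  )
  expect_equal(
    segment_cost(c(4, 4, 4), sd_floor = fl),
    3 * (log(2 * pi) + log(fl^2))
  )

  # density-sum identity on random segments, floored or not
  set.seed(11)
  for (i in 1:25) {
    n <- sample(1:30, 1)
    y <- rnorm(n, sd = sample(c(1e-6, 0.5, 3), 1))
    fl <- sample(c(1e-8, 1e-3, 0.2), 1)
    expect_equal(segment_cost(y, fl), density_sum_cost(y, fl))
  }

  expect_error(segment_cost(numeric(0)), "empty")
  expect_error(segment_cost(c(1, NA)), "finite")
})

test_that("segment_cost is permutation- and location-invariant", {
  set.seed(7)
  y <- rnorm(20, mean = 3)
  expect_equal(segment_cost(sample(y)), segment_cost(y))
  expect_equal(segment_cost(y + 17.5), segment_cost(y))
})

test_that("pelt finds the documented solutions on simple inputs", {
  # huge penalty: never worth splitting
  set.seed(2)
  y <- rnorm(50)
  expect_equal(as.integer(pelt(y, penalty = 1e6)), integer(0))

  # clear +8 shift after index 5; the penalty sits between the
  # carve-everything regime (cheap degenerate segments) and no-split
  set.seed(3)
  y <- c(rnorm(5), rnorm(5, mean = 8))
  fl <- ascept:::sd_floor_for(y)
  cp <- pelt(y, penalty = 25)
  expect_equal(as.integer(cp), 5L)
  expect_equal(
    attr(cp, "objective"),
    exhaustive_objective(y, 25, sd_floor = fl)
  )

  expect_error(pelt(y, penalty = -1), "nonnegative")
  expect_error(pelt(rnorm(3), penalty = 1, min_seg_len = 2), "too short")
})

test_that("pelt objective equals exhaustive search on random small series", {
  set.seed(123)
  for (i in 1:30) {
    n <- sample(4:11, 1)
    shift <- sample(c(0, 3, 8), 1)
    y <- rnorm(n) + shift * (seq_len(n) > n / 2)
    msl <- sample(1:2, 1)
    if (n < 2 * msl) msl <- 1L
    beta <- runif(1, 0.05, 12)
    fl <- ascept:::sd_floor_for(y)
    got <- attr(pelt(y, beta, min_seg_len = msl, sd_floor = fl), "objective")
    want <- exhaustive_objective(y, beta, min_seg_len = msl, sd_floor = fl)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("pelt honors the minimum segment length", {
  set.seed(9)
  y <- c(rnorm(10), rnorm(10, 6))
  for (msl in c(1L, 3L, 5L)) {
    cp <- pelt(y, penalty = log(20), min_seg_len = msl)
    lens <- diff(c(0L, as.integer(cp), 20L))
    expect_true(all(lens >= msl))
  }
})

test_that("crops_sweep recovers consistent, monotone penalty intervals", {
  set.seed(21)
  y <- c(rnorm(30), rnorm(30, 5), rnorm(30, -2))

  # degenerate range = single pelt call
  raw1 <- crops_sweep(y, 2, 2)
  expect_length(raw1, 1L)
  expect_equal(raw1[[1]]$positions, as.integer(pelt(y, 2)))

  raw <- crops_sweep(y, 0.2, 50 * log(90))
  m <- vapply(raw, function(e) e$n_changepoints, integer(1))
  blo <- vapply(raw, function(e) e$beta_lo, numeric(1))
  # entries ordered by increasing penalty; counts weakly decreasing
  expect_true(!is.unsorted(blo))
  expect_true(all(diff(m) <= 0))

  # self-consistency: pelt at each interval midpoint reproduces the entry
  pick <- unique(round(seq(1, length(raw), length.out = min(6, length(raw)))))
  for (e in raw[pick]) {
    mid <- (e$beta_lo + min(e$beta_hi, e$beta_lo * 2 + 10)) / 2
    expect_equal(as.integer(pelt(y, mid)), e$positions)
  }

  expect_error(crops_sweep(y, 0, 1), "beta_min")
  expect_error(crops_sweep(y, 3, 1), "beta_min")
})

test_that("candidate path starts at the empty set, deduplicated, indexable", {
  set.seed(31)
  y <- c(rnorm(40), rnorm(40, 6))
  raw <- crops_sweep(y, 0.5, 50 * log(80))
  path <- build_candidate_path(raw, y)

  expect_s3_class(path, "ascept_path")
  expect_equal(path_entry(path, 0), integer(0))
  sizes <- vapply(path$entries, function(e) length(e$positions), integer(1))
  expect_true(all(diff(sizes) >= 0))
  # no two consecutive entries identical
  for (k in seq_len(path$K)) {
    expect_false(identical(path_entry(path, k - 1), path_entry(path, k)))
  }
  expect_error(path_entry(path, path$K + 1), "out of range")

  # unpenalized cost is non-increasing along the path
  fl <- ascept:::sd_floor_for(y)
  costs <- vapply(
    path$entries,
    function(e) ascept:::total_cost(y, e$positions, fl), numeric(1)
  )
  expect_true(all(diff(costs) <= 1e-8))

  expect_error(build_candidate_path(list(), y), "nonempty")
})
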