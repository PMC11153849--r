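test_that("hardness is squared error with its symmetry", {
  expect_equal(spe_hardness(0.9, 0), 0.81)
  expect_equal(spe_hardness(0.3, 1), 0.49)
  expect_equal(spe_hardness(0.5, 0.5), 0)
  s <- runif(20)
  expect_equal(spe_hardness(s, 0), spe_hardness(1 - s, 1))
  # for negatives, hardness is monotone in the score: noise = high score
  s <- sort(runif(10))
  expect_true(all(diff(spe_hardness(s, 0)) >= 0))
})

test_that("bucket assignment uses half-open intervals with closed top", {
  expect_equal(spe_assign_buckets(0, 4), 1L)
  expect_equal(spe_assign_buckets(1, 4), 4L)
  expect_equal(spe_assign_buckets(0.25, 4), 2L)
  expect_equal(spe_assign_buckets(c(0.1, 0.24999, 0.99), 4), c(1L, 1L, 4L))
  expect_error(spe_assign_buckets(1.2, 4), "\\[0, 1\\]")
  expect_error(spe_assign_buckets(-0.1, 4), "\\[0, 1\\]")
})

test_that("self-paced factor grows from zero along the log schedule", {
  expect_equal(spe_self_paced_factor(0, 50), 0)
  expect_equal(spe_self_paced_factor(25, 50), log(2))
  b <- sapply(0:49, spe_self_paced_factor, total_epochs = 50)
  expect_true(all(diff(b) > 0))
  expect_equal(b[50], -log(1 / 50))
  expect_error(spe_self_paced_factor(50, 50), "smaller")
})

test_that("bucket weights are normalized inverse shifted hardness", {
  w <- spe_bucket_weights(c(0.1, 0.3), 0.1)
  expect_equal(w, c(2 / 3, 1 / 3))
  # equal hardness gives equal weights over occupied buckets
  expect_equal(spe_bucket_weights(c(0.2, NA, 0.2), 0.5),
               c(0.5, 0, 0.5))
  # larger beta flattens the ratio
  r <- sapply(c(0.1, 0.5, 2, 10), function(b) {
    w <- spe_bucket_weights(c(0.1, 0.4), b); w[1] / w[2]
  })
  expect_true(all(diff(r) < 0))
  expect_error(spe_bucket_weights(c(NA, NA), 1), "empty")
  # epsilon floor handles h = beta = 0
  expect_equal(spe_bucket_weights(c(0, 0.5), 0)[1], 1, tolerance = 1e-10)
})

test_that("count allocation follows largest remainder with capping", {
  expect_equal(spe_allocate_counts(c(2 / 3, 1 / 3), 9, c(100, 100)),
               c(6L, 3L))
  expect_equal(spe_allocate_counts(rep(0.2, 5), 10, rep(100, 5)),
               rep(2L, 5))
  expect_equal(spe_allocate_counts(c(0.9, 0.1), 10, c(3, 100)),
               c(3L, 7L))
  # shortfall only when the pool itself is too small
  expect_equal(sum(spe_allocate_counts(c(0.5, 0.5), 10, c(3, 4))), 7)
})

test_that("allocation matches the step-by-step oracle exhaustively", {
  set.seed(31)
  for (rep in 1:300) {
    k <- sample(1:5, 1)
    P <- sample(0:12, 1)
    sizes <- sample(0:8, k, replace = TRUE)
    h <- ifelse(sizes > 0, runif(k), NA)
    if (all(sizes == 0)) next
    w <- spe_bucket_weights(h, runif(1, 0, 2))
    got <- spe_allocate_counts(w, P, sizes)
    want <- oracle_allocate(w, P, sizes)
    expect_equal(got, as.integer(want))
    expect_true(all(got <= sizes))
    expect_equal(sum(got), min(P, sum(sizes[w > 0])))
  }
})

test_that("one sampling iteration composes the pipeline correctly", {
  set.seed(32)
  pool <- as.matrix(expand.grid(drug = 1:10, microbe = 1:10))
  # iteration 0 with equal scores: one occupied bucket, all |P| drawn from it
  sel <- spe_sample_iteration(pool, rep(0.3, 100), k = 10, iteration = 0,
                              total_epochs = 50, positives_count = 12)
  expect_equal(nrow(sel), 12)
  d <- attr(sel, "diagnostics")
  expect_equal(d$beta, 0)
  expect_equal(sum(d$sizes > 0), 1)
  expect_equal(sum(d$allocations), 12)
  # determinism under a fixed seed
  scores <- runif(100)
  s1 <- with_seed_draw(99, spe_sample_iteration(pool, scores, 5, 3, 20, 15))
  s2 <- with_seed_draw(99, spe_sample_iteration(pool, scores, 5, 3, 20, 15))
  expect_identical(s1, s2)
  # buckets partition the pool
  expect_equal(sum(attr(s1, "diagnostics")$sizes), nrow(pool))
  # no duplicate pairs within a draw
  expect_equal(anyDuplicated(paste(s1[, 1], s1[, 2])), 0)
})

test_that("late iterations shift mass toward hard buckets", {
  set.seed(33)
  pool <- cbind(rep(1:20, each = 10), rep(1:10, 20))
  scores <- runif(200)           # hardness = scores^2, spread over buckets
  H <- spe_hardness(scores, 0)
  mean_drawn <- function(i, ndraw = 1000) {
    mean(replicate(ndraw, {
      sel <- spe_sample_iteration(pool, scores, 10, i, 100, 50)
      keys <- match(paste(sel[, 1], sel[, 2]), paste(pool[, 1], pool[, 2]))
      mean(H[keys])
    }))
  }
  early <- mean_drawn(1)
  late <- mean_drawn(99)
  expect_gt(late, early)
  # the late draw tracks the analytic expectation sum(W_l * h_l)
  bucket <- spe_assign_buckets(H, 10)
  hbar <- tapply(H, factor(bucket, levels = 1:10), mean)
  sizes <- tabulate(bucket, 10)
  for (i in c(1, 99)) {
    w <- spe_bucket_weights(ifelse(sizes > 0, hbar, NA),
                            spe_self_paced_factor(i, 100))
    alloc <- spe_allocate_counts(w, 50, sizes)
    expected <- sum(alloc * hbar[sizes > 0 | TRUE], na.rm = TRUE) / sum(alloc)
    got <- if (i == 1) early else late
    expect_lt(abs(got - expected), 0.02)
  }
})

test_that("initial undersampling draws the right number of distinct pairs", {
  set.seed(34)
  pool <- cbind(rep(1:10, each = 10), rep(1:10, 10))
  sel <- initial_random_undersample(pool, 10)
  expect_equal(nrow(sel), 10)
  expect_equal(anyDuplicated(paste(sel[, 1], sel[, 2])), 0)
  s1 <- with_seed_draw(7, initial_random_undersample(pool, 10))
  s2 <- with_seed_draw(7, initial_random_undersample(pool, 10))
  expect_identical(s1, s2)
  small <- pool[1:5, ]
  expect_warning(sel2 <- initial_random_undersample(small, 10), "smaller")
  expect_equal(nrow(sel2), 5)
  expect_error(initial_random_undersample(pool[0, , drop = FALSE], 3),
               "empty")
})
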