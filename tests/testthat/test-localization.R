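test_that("reference model: uniform frames, scale invariance, pooling stability", {
  u <- matrix(7, 40, 40)
  ref_u <- build_reference(u, q = 0.995)
  expect_equal(ref_u$median, 7)
  expect_equal(ref_u$t_q, 1)
  # scaling a frame leaves the normalized reference unchanged
  img <- make_cell_image(bench_spec(0, 42))
  r1 <- build_reference(img$frame, masks = img$mask)
  r3 <- build_reference(3 * img$frame, masks = img$mask)
  expect_equal(r3$median, 3 * r1$median)
  expect_equal(r3$sample, r1$sample)
  expect_equal(r3$t_q, r1$t_q)
  # pooling two frames moves the tail threshold by < 2%
  img2 <- make_cell_image(bench_spec(0, 43))
  r12 <- build_reference(list(img$frame, img2$frame),
                         masks = list(img$mask, img2$mask))
  expect_lt(abs(r12$t_q - r1$t_q) / r1$t_q, 0.02)
  expect_error(build_reference(img$frame, q = 0.4), "q")
  expect_error(build_reference(matrix(5, 10, 10)), "pixels")
})

test_that("localization score is null-calibrated and scale invariant", {
  ref <- bench_reference()
  # null frames resampled from the reference pool score ~0
  set.seed(3)
  mask <- matrix(TRUE, 40, 50)
  sc <- replicate(200, {
    fr <- matrix(sample(ref$sample * ref$median, 2000, TRUE), 40, 50)
    localization_score(fr, ref, mask = mask)
  })
  expect_lt(abs(mean(sc)), 3 * stats::sd(sc) / sqrt(length(sc)))
  # single resampled frame within 3 binomial standard errors of 0
  expect_lt(abs(sc[1]), 3 * sqrt(0.005 * 0.995 / 2000))
  # nuclear enrichment raises the score
  img0 <- make_cell_image(bench_spec(0, 11))
  img4 <- make_cell_image(bench_spec(0.4, 11))
  s0 <- localization_score(img0$frame, ref, img0$mask)
  s4 <- localization_score(img4$frame, ref, img4$mask)
  expect_gt(s4, s0 + 0.02)
  # invariance under any positive rescaling (with and without masks;
  # the maskless Otsu inclusion is scale-equivariant)
  expect_identical(s4, localization_score(7.3 * img4$frame, ref, img4$mask))
  expect_identical(localization_score(img0$frame, ref),
                   localization_score(0.02 * img0$frame, ref))
  expect_error(localization_score(matrix(5, 10, 10), ref,
                                  mask = matrix(TRUE, 10, 10)), "pixels")
})

test_that("score recovery is strictly monotone in the true nuclear fraction", {
  ref <- bench_reference()
  fs <- seq(0, 0.6, by = 0.1)
  means <- vapply(fs, function(f) {
    mean(vapply(1:12, function(r) {
      img <- make_cell_image(bench_spec(f, 5000 + round(1000 * f) * 37 + r))
      localization_score(img$frame, ref, img$mask)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_equal(stats::cor(fs, means, method = "spearman"), 1)
})

test_that("time-series scoring is stateless and order-preserving", {
  ref <- bench_reference()
  imgs <- lapply(1:6, function(i)
    make_cell_image(bench_spec(if (i <= 3) 0 else 0.5, 300 + i)))
  frames <- lapply(imgs, `[[`, "frame")
  masks <- lapply(imgs, `[[`, "mask")
  ts <- score_timeseries(frames, 1:6, ref, masks)
  expect_equal(ts$time, 1:6)
  # step increase where the nuclear fraction steps
  expect_gt(min(ts$score[4:6]), max(ts$score[1:3]) + 0.02)
  # pure per-frame map: reversing the stack reverses the scores
  rev_ts <- score_timeseries(rev(frames), 1:6, ref, rev(masks))
  expect_equal(rev_ts$score, rev(ts$score))
  expect_error(score_timeseries(frames, c(1, 1, 2, 3, 4, 5), ref, masks),
               "increasing")
})

test_that("steady-state score reports mean and standard error over a window", {
  s <- data.frame(time = 1:3, score = c(0.1, 0.1, 0.1))
  res <- steady_state_score(s)
  expect_equal(res$mean, 0.1)
  expect_equal(res$se, 0)
  res <- steady_state_score(data.frame(time = 1:3, score = c(0, 0.1, 0.2)))
  expect_equal(res$mean, 0.1)
  expect_equal(res$se, 0.1 / sqrt(3), tolerance = 1e-6)
  expect_error(steady_state_score(s, window = c(1, 2)), "3 frames")
  # seeded plateau series: mean within 2 SEM of a common asymptote
  ref <- bench_reference()
  imgs <- lapply(1:8, function(i) make_cell_image(bench_spec(0.3, 700 + i)))
  ts <- score_timeseries(lapply(imgs, `[[`, "frame"), 1:8, ref,
                         lapply(imgs, `[[`, "mask"))
  res <- steady_state_score(ts)
  one <- localization_score(imgs[[1]]$frame, ref, imgs[[1]]$mask)
  expect_lt(abs(res$mean - one), max(2 * res$se, 0.01))
})

test_that("activated-cell median isolates the active component", {
  expect_true(is.na(activated_median(c(1, 2, 3), 10)))
  expect_equal(activated_median(c(1, 2, 3), -Inf), 2)
  expect_error(activated_median(numeric(0), 1), "non-empty")
  # 70/30 basal/active lognormal mixture: threshold between the modes
  # recovers the active component median (10) within 5%
  tp <- make_trace_population(population_spec(
    n_cells = 1000, weights = c(0.7, 0, 0.3),
    log_mean = log(c(1, 10, 10)), log_sd = 0.3, seed = 5))
  expect_lt(abs(activated_median(tp$intensity, 3) - 10) / 10, 0.05)
})

test_that("hysteretic nuclear localization is visible in image scores", {
  # drive the nuclear fraction with the regulon model through a
  # rich -> intermediate -> rich excursion and image the result
  p <- regulon_params()
  traj <- simulate_regulon(p, data.frame(duration = c(6, 12, 12),
                                         s_out = c(1000, 50, 1000)),
                           record_every = 100L)
  f_of <- function(t) 0.5 * traj$n[which.min(abs(traj$time - t))]
  ref <- bench_reference()
  score_at <- function(t, seed) {
    img <- make_cell_image(bench_spec(f_of(t), seed))
    localization_score(img$frame, ref, img$mask)
  }
  pre <- vapply(1:4, function(i) score_at(1 + i, 900 + i), numeric(1))
  post <- vapply(1:4, function(i) score_at(25 + i, 950 + i), numeric(1))
  # post-recovery scores stay elevated: the committed plateau keeps Pho4
  # partially nuclear even after return to rich phosphate
  expect_gt(mean(post), mean(pre) + 0.02)
})
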