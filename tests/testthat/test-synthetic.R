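test_that("reference clouds are deterministic, separated and ellipsoidal", {
  spec <- synthetic_spec(n_landmarks = 100, rng_seed = 5)
  ref1 <- make_reference(spec)
  ref2 <- make_reference(spec)
  expect_identical(ref1$points, ref2$points)
  expect_identical(ref1$names, sprintf("c%04d", 1:100))
  expect_gt(min(dist(ref1$points)), 0)
  # different seed, different cloud
  ref3 <- make_reference(synthetic_spec(n_landmarks = 100, rng_seed = 6))
  expect_false(isTRUE(all.equal(ref1$points, ref3$points)))
  # 2:1:1 aspect: x-extent about twice y/z extents
  ext <- apply(ref1$points, 2, function(v) diff(range(v)))
  expect_gt(ext[1] / ext[2], 1.5)
  expect_gt(ext[1] / ext[3], 1.5)
})

test_that("member sampling reduces to the identity in the zero-noise
           limit", {
  spec <- synthetic_spec(n_landmarks = 50, jitter_sigma = 0,
                         warp_amplitude = 0, frac_inconsistent = 0,
                         rng_seed = 2)
  ref <- make_reference(spec)
  m <- sample_member(ref, spec, member_seed = 99)
  expect_equal(m$cloud$points, ref$points)
  expect_identical(m$cloud$names, ref$names)
  expect_length(m$events_realized, 0)
})

test_that("all members share the name set when no events are designated", {
  spec <- synthetic_spec(n_landmarks = 60, frac_inconsistent = 0,
                         rng_seed = 3)
  ref <- make_reference(spec)
  ms <- lapply(1:3, function(i) sample_member(ref, spec, 10 + i))
  for (m in ms) expect_setequal(m$cloud$names, ref$names)
})

test_that("jitter magnitude matches the Gaussian norm expectation", {
  spec <- synthetic_spec(n_landmarks = 1000, jitter_sigma = 0.02,
                         warp_amplitude = 0, frac_inconsistent = 0,
                         rng_seed = 8)
  ref <- make_reference(spec)
  diam <- max(dist(ref$points))
  m <- sample_member(ref, spec, member_seed = 77)
  disp <- sqrt(rowSums((m$cloud$points - ref$points)^2))
  # E|N(0, sigma^2 I_3)| = sigma * sqrt(2/pi) * sqrt(... ) = 2 sigma sqrt(2/pi)
  expected <- 0.02 * diam * 2 * sqrt(2 / pi)
  expect_lt(abs(mean(disp) - expected) / expected, 0.1)
})

test_that("division and death events are realized as splits and removals", {
  spec <- synthetic_spec(n_landmarks = 80, frac_inconsistent = 0.1,
                         rng_seed = 13)
  ref <- make_reference(spec)
  evs <- embalign:::designate_events(ref, spec)
  expect_length(evs, 8)
  expect_setequal(unique(vapply(evs, `[[`, "", "kind")),
                  c("division", "death"))
  found_div <- found_death <- FALSE
  for (s in 1:10) {
    m <- sample_member(ref, spec, s, evs)
    for (ev in m$events_realized) {
      if (ev$kind == "division") {
        expect_false(ev$subject %in% m$cloud$names)
        expect_true(all(ev$daughters %in% m$cloud$names))
        d <- sqrt(sum((m$cloud$points[m$cloud$names == ev$daughters[1], ] -
                       m$cloud$points[m$cloud$names == ev$daughters[2], ])^2))
        expect_gt(d, 0)
        found_div <- TRUE
      } else {
        expect_false(ev$subject %in% m$cloud$names)
        found_death <- TRUE
      }
    }
  }
  expect_true(found_div && found_death)
})

test_that("unlabeled generation strips names, permutes order and returns a
           covering ground truth", {
  spec <- synthetic_spec(n_landmarks = 70, rng_seed = 4)
  ref <- make_reference(spec)
  out <- make_unlabeled(ref, spec, seed = 40)
  expect_false(is_labeled(out$cloud))
  expect_equal(sort(as.integer(names(out$truth$true_names))),
               seq_len(n_landmarks(out$cloud)))
  # correspondence entries resolve to points whose true name matches
  expect_equal(unname(out$truth$true_names[as.character(out$corr$index)]),
               out$corr$identity)
  expect_equal(nrow(out$corr), 6)
})

test_that("anisotropic distortion contracts the stated axis", {
  spec <- synthetic_spec(n_landmarks = 200, jitter_sigma = 0,
                         warp_amplitude = 0, frac_inconsistent = 0,
                         anisotropy = c(1, 1, 0.7), rng_seed = 15)
  ref <- make_reference(spec)
  out <- make_unlabeled(ref, spec, seed = 50)
  # singular values of the best linear map ref -> unlabeled are ~ (1,1,0.7)
  iu <- order(as.integer(names(out$truth$true_names)))
  X <- ref$points[match(out$truth$true_names, ref$names), ]
  f <- affine_fit(X, out$cloud$points)
  sv <- svd(f$A)$d
  expect_equal(sv, c(1, 1, 0.7), tolerance = 0.02)
})

test_that("generated ensembles keep a plausible consistent-adjacency
           fraction", {
  spec <- synthetic_spec(rng_seed = 1)   # defaults: n=150, 3 members
  bench <- make_benchmark(spec)
  n_cons <- nrow(bench$model$consistent_edges$edges)
  n_union <- nrow(bench$model$profile)
  mean_edges <- mean(vapply(bench$model$graphs,
                            function(g) nrow(g$edges), 0))
  frac <- n_cons / mean_edges
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.60)
})

test_that("benchmark generation is bit-reproducible", {
  b1 <- make_benchmark(synthetic_spec(n_landmarks = 50, rng_seed = 77))
  b2 <- make_benchmark(synthetic_spec(n_landmarks = 50, rng_seed = 77))
  expect_identical(b1$unlabeled$points, b2$unlabeled$points)
  expect_identical(b1$truth$true_names, b2$truth$true_names)
  expect_identical(lapply(b1$model$labeled_clouds, `[[`, "points"),
                   lapply(b2$model$labeled_clouds, `[[`, "points"))
})
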