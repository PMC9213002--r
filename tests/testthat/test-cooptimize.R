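div_ev <- lineage_event("division", "P", c("Pa", "Pp"), time = 2)
death_ev <- lineage_event("death", "D", time = -1)

test_that("modifications edit the labeled cloud as hypothesized", {
  cl <- landmark_cloud(rbind(c(1, 0, 0), c(3, 0, 0), c(0, 5, 0), c(7, 7, 7)),
                       names = c("Pa", "Pp", "Q", "D"))
  # merge: daughters replaced by parent at their midpoint
  merged <- apply_modification(cl, modification("merge_daughters", div_ev))
  expect_setequal(merged$names, c("P", "Q", "D"))
  expect_equal(merged$points[merged$names == "P", ], c(x = 2, y = 0, z = 0))
  # split: parent replaced by two co-located daughters
  split <- apply_modification(merged, modification("split_parent", div_ev))
  expect_setequal(split$names, c("Pa", "Pp", "Q", "D"))
  expect_equal(split$points[split$names == "Pa", ],
               split$points[split$names == "Pp", ])
  expect_equal(unname(split$points[split$names == "Pa", ]), c(2, 0, 0))
  # death: one landmark removed, others untouched
  dead <- apply_modification(cl, modification("remove_death", death_ev))
  expect_setequal(dead$names, c("Pa", "Pp", "Q"))
  expect_equal(dead$points[dead$names == "Q", ], cl$points[3, ])
})

test_that("modifications require their subjects to be present", {
  cl <- landmark_cloud(rbind(c(0, 0, 0), c(1, 1, 1)), names = c("X", "Y"))
  expect_error(apply_modification(cl, modification("merge_daughters", div_ev)),
               "Pa")
  expect_error(apply_modification(cl, modification("remove_death", death_ev)),
               "D")
  expect_error(apply_modification(cl, modification("split_parent", div_ev)),
               "P")
  expect_error(modification("remove_death", div_ev), "death event")
  expect_error(modification("merge_daughters", death_ev), "division event")
})

# A fixture where co-optimization must fire: members all contain cell "dd"
# (with >= accept_threshold consistent adjacencies) but the unlabeled sample
# lacks it because its death has already happened.
death_fixture <- function(seed = 404) {
  set.seed(seed)
  base <- matrix(runif(60, 0, 10), 20, 3)
  nm <- c(sprintf("c%02d", 1:19), "dd")
  members <- lapply(1:3, function(i)
    landmark_cloud(base + matrix(rnorm(60, 0, 0.02), 20, 3), names = nm))
  ev <- lineage_event("death", "dd", time = 1)
  model <- build_ensemble_model(members, list(ev), stage_time = 0,
                                window_minutes = 13)
  unl <- landmark_cloud(base[-20, , drop = FALSE] +
                          matrix(rnorm(57, 0, 0.02), 19, 3))
  list(model = model, unl = unl, truth = setNames(nm[-20], 1:19))
}

test_that("a true death in the unlabeled sample is detected and accepted", {
  fx <- death_fixture()
  deg <- sum(fx$model$consistent_edges$edges == "dd")
  expect_gte(deg, 3)   # enough constraints to clear the acceptance threshold
  co <- suppressWarnings(
    cooptimize_labeled(fx$model$labeled_clouds[[1]], fx$unl, fx$model,
                       run_config()))
  log <- co$modifications
  expect_equal(nrow(log), 1)
  expect_equal(log$kind, "remove_death")
  expect_true(log$accepted)
  expect_gte(log$delta_violations, 3)
  expect_false("dd" %in% co$cloud$names)
  expect_equal(unname(co$assignment$mapping), unname(fx$truth))
})

test_that("empty inconsistent list returns the baseline alignment", {
  fx <- death_fixture()
  model2 <- build_ensemble_model(fx$model$labeled_clouds, list(),
                                 stage_time = 0, window_minutes = 13)
  co <- suppressWarnings(
    cooptimize_labeled(model2$labeled_clouds[[1]], fx$unl, model2,
                       run_config()))
  expect_equal(nrow(co$modifications), 0)
  expect_identical(co$cloud$names, model2$labeled_clouds[[1]]$names)
})

test_that("acceptance requires a violation drop of at least the threshold", {
  fx <- death_fixture()
  # with an infinite threshold nothing is ever accepted (ablation mode)
  co_inf <- suppressWarnings(
    cooptimize_labeled(fx$model$labeled_clouds[[1]], fx$unl, fx$model,
                       run_config(accept_threshold = Inf)))
  expect_equal(nrow(co_inf$modifications), 0)
  expect_true("dd" %in% co_inf$cloud$names)
  # with a threshold above the achievable drop the change is rejected
  deg <- sum(fx$model$consistent_edges$edges == "dd")
  co_hi <- suppressWarnings(
    cooptimize_labeled(fx$model$labeled_clouds[[1]], fx$unl, fx$model,
                       run_config(accept_threshold = deg + 50)))
  expect_false(any(co_hi$modifications$accepted))
  expect_true("dd" %in% co_hi$cloud$names)
})

test_that("accepted modifications always clear the threshold and the final
           alignment never exceeds the initial violations", {
  for (seed in 1:3) {
    spec <- synthetic_spec(n_landmarks = 60, rng_seed = seed)
    bench <- make_benchmark(spec)
    cfg <- run_config(correction_iters_inner = 20L,
                      correction_iters_final = 60L, rng_seed = seed)
    member <- bench$model$labeled_clouds[[1]]
    pre <- embalign:::prealign_fit(member, bench$unlabeled, bench$corr, cfg)
    w <- apply_transform(pre, bench$unlabeled)
    co <- suppressWarnings(cooptimize_labeled(member, w, bench$model, cfg))
    log <- co$modifications
    if (nrow(log))
      expect_true(all(log$delta_violations[log$accepted] >=
                        cfg$accept_threshold))
    init <- co$traces[[1]][1]
    expect_lte(co$assignment$violations$total, init)
    for (tr in co$traces) expect_true(all(diff(tr) <= 0))
  }
})

test_that("constraint edges follow identity remapping through
           modifications", {
  al <- embalign:::update_alias(list(), modification("merge_daughters", div_ev))
  es <- embalign:::compile_edge_struct(rbind(c("Pa", "Q"), c("Pa", "Pp")), al)
  # Pa-Q becomes P-Q; the sibling edge Pa-Pp collapses and is dropped
  expect_equal(es$a, "P")
  expect_equal(es$b, "Q")
  al2 <- embalign:::update_alias(list(), modification("split_parent", div_ev))
  es2 <- embalign:::compile_edge_struct(rbind(c("P", "Q")), al2)
  expect_length(es2$multi, 1)
  expect_setequal(es2$multi[[1]]$a, c("Pa", "Pp"))
  al3 <- embalign:::update_alias(list(), modification("remove_death", death_ev))
  es3 <- embalign:::compile_edge_struct(rbind(c("D", "Q"), c("Q", "R")), al3)
  expect_equal(es3$a, "Q")   # D edge left the constraint set
  expect_equal(es3$b, "R")
})
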