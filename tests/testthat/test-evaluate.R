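test_that("ground truth uses inclusive planar projection of the inclusions", {
  ph <- small_phantom(diameter = 8, center = c(20, 15, 7.5))
  expect_identical(as.character(ground_truth_labels(ph, cbind(20, 15))),
                   "tumor")
  expect_identical(as.character(ground_truth_labels(ph, cbind(24, 15))),
                   "tumor")    # boundary: planar distance exactly r
  expect_identical(as.character(ground_truth_labels(ph, cbind(24.1, 15))),
                   "healthy")
  # depth is ignored: a deep small inclusion is still truth-tumor
  deep <- phantom(inclusions = list(inclusion(c(50, 30, 12), 3)))
  expect_identical(as.character(ground_truth_labels(deep, cbind(50, 30))),
                   "tumor")
})

test_that("truth-tumor count matches brute-force circle membership", {
  ph <- make_reference_phantom()
  grid <- phantom_lattice(ph, step = 2, margin = 2)
  truth <- ground_truth_labels(ph, grid)
  brute <- sum(apply(grid, 1, function(p) {
    any(vapply(ph$inclusions, function(inc) {
      sum((p - inc$center[1:2])^2) <= (inc$diameter / 2)^2
    }, logical(1)))
  }))
  expect_identical(sum(truth == "tumor"), brute)
  expect_gt(brute, 0)
})

test_that("confusion counts, class-conditional rates and identities", {
  t4 <- c("tumor", "tumor", "healthy", "healthy")
  perfect <- confusion(t4, t4)
  expect_identical(unname(perfect$counts[c("TP", "TN", "FP", "FN")]),
                   c(2L, 2L, 0L, 0L))
  expect_equal(perfect$rates[["TP"]], 100)
  expect_equal(perfect$rates[["TN"]], 100)
  expect_equal(perfect$accuracy, 100)
  flipped <- confusion(rev(t4), t4)
  expect_equal(flipped$rates[["TP"]], 0)
  expect_equal(flipped$rates[["TN"]], 0)
  hand <- confusion(c("tumor", "healthy", "tumor", "healthy"), t4)
  expect_identical(unname(hand$counts[c("TP", "TN", "FP", "FN")]),
                   c(1L, 1L, 1L, 1L))
  expect_true(all(hand$rates == 50))
  expect_equal(hand$accuracy, 50)
  # rate identities hold exactly
  expect_equal(hand$rates[["TP"]] + hand$rates[["FN"]], 100)
  expect_equal(hand$rates[["TN"]] + hand$rates[["FP"]], 100)
  expect_equal(hand$accuracy + hand$misclassification_rate, 100)
  expect_identical(sum(hand$counts), hand$n)
})

test_that("single-class truth yields NA for the undefined rate pair", {
  s <- confusion(c("tumor", "healthy"), c("tumor", "tumor"))
  expect_identical(unname(s$counts[c("TP", "FN")]), c(1L, 1L))
  expect_true(is.na(s$rates[["TN"]]) && is.na(s$rates[["FP"]]))
  expect_equal(s$rates[["TP"]], 50)
})

test_that("pooling counts then computing rates equals rates over pooled points", {
  set.seed(43)
  preds <- truths <- list()
  parts <- lapply(1:7, function(i) {
    truth <- sample(c("healthy", "tumor"), 40, replace = TRUE,
                    prob = c(0.8, 0.2))
    pred <- ifelse(runif(40) < 0.85, truth,
                   ifelse(truth == "tumor", "healthy", "tumor"))
    preds[[i]] <<- pred; truths[[i]] <<- truth
    confusion(pred, truth)
  })
  pooled <- pool_confusion(parts)
  direct <- confusion(unlist(preds), unlist(truths))
  expect_identical(pooled$counts, direct$counts)
  expect_equal(pooled$rates, direct$rates)
})

test_that("summarize_methods scores all maps and emits category grids", {
  ph <- small_phantom(diameter = 12, center = c(20, 15, 7.5))
  grid <- phantom_lattice(ph, step = 2, margin = 2)
  truth <- ground_truth_labels(ph, grid)
  good <- label_map(as.character(truth), grid)
  bad <- label_map(rep("healthy", length(truth)), grid)
  ms <- summarize_methods(ph, list(stiffness = good, ultrasound = bad,
                                   and = fuse_and(good, bad),
                                   or = fuse_or(good, bad)), grid = grid)
  expect_named(ms$summaries, c("stiffness", "ultrasound", "and", "or"))
  expect_equal(ms$summaries$or$rates[["TP"]], 100)
  expect_identical(ms$summaries$and$counts[["TP"]], 0L)
  # category grid tallies agree with the confusion counts
  tab <- table(ms$categories$stiffness)
  expect_identical(as.integer(tab[c("TP", "TN", "FP", "FN")]),
                   unname(ms$summaries$stiffness$counts[c("TP", "TN", "FP", "FN")]))
  # union / intersection count bounds
  expect_lte(ms$summaries$or$counts[["FN"]],
             min(ms$summaries$stiffness$counts[["FN"]],
                 ms$summaries$ultrasound$counts[["FN"]]))
  expect_lte(ms$summaries$and$counts[["FP"]],
             min(ms$summaries$stiffness$counts[["FP"]],
                 ms$summaries$ultrasound$counts[["FP"]]))
})
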