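test_that("pair selection maximizes the target difference among feasible pairs", {
  # candidate set where one pair isolates aperture exactly
  norm <- rbind(
    c(0.0, 0.5, 0.5, 0.5),
    c(1.0, 0.5, 0.5, 0.5),   # differs from row 1 on aperture only
    c(0.2, 0.9, 0.1, 0.5),
    c(0.9, 0.1, 0.9, 0.5)
  )
  sc <- toy_scores(norm)
  p <- select_pair(sc, "aperture", epsilon = 0.2)
  expect_equal(c(p$near_optimal, p$sub_optimal), c(1, 2))
  expect_false(p$relaxed)
  expect_equal(unname(p$delta), c(1, 0, 0, 0))

  # agrees with the exhaustive oracle on random candidate sets
  set.seed(11)
  for (rep in 1:20) {
    sc <- toy_scores(matrix(runif(4 * 8), 8))
    for (cr in c("aperture", "nga", "torque", "visibility")) {
      p <- select_pair(sc, cr, epsilon = 0.3)
      if (!p$relaxed) {
        o <- oracle_select_pair(sc, cr, epsilon = 0.3)
        expect_equal(c(p$near_optimal, p$sub_optimal), o$pair)
        expect_equal(unname(p$delta[cr]), unname(o$delta), tolerance = 1e-12)
      }
      expect_gt(p$delta[[cr]], 0)
    }
  }
})

test_that("degenerate and infeasible candidate sets are handled", {
  expect_error(select_pair(toy_scores(matrix(0.5, 1, 4)), "nga"), "at least 2")
  # two identical candidates: no pair differs on the criterion
  expect_error(select_pair(toy_scores(matrix(0.5, 2, 4, byrow = TRUE)), "nga"),
               "no candidate pair")
  # feasibility impossible at epsilon = 0 with coupled criteria -> relaxed flag
  norm <- cbind(seq(0, 1, length.out = 6), seq(1, 0, length.out = 6),
                seq(0, 1, length.out = 6), seq(0, 1, length.out = 6))
  p <- select_pair(toy_scores(norm), "aperture", epsilon = 0)
  expect_true(p$relaxed)
  expect_gt(p$delta[["aperture"]], 0)
})

test_that("the optimality-difference vector is antisymmetric under role swap", {
  set.seed(3)
  sc <- toy_scores(matrix(runif(20), 5))
  nm <- as.matrix(sc[, paste0("norm_", c("aperture", "nga", "torque", "visibility"))])
  for (i in 1:5) for (j in 1:5) {
    expect_equal(nm[j, ] - nm[i, ], -(nm[i, ] - nm[j, ]))
  }
})

test_that("design assigns criteria in blocks and emits the delta matrix", {
  objs <- generate_fixtures(5)
  scores <- lapply(objs, enumerate_grasps)
  d <- design_experiment(scores, per_criterion_count = 4, seed = 5)
  expect_equal(nrow(d$pairs), 16)
  expect_equal(as.integer(table(d$pairs$criterion)[c("aperture", "nga", "torque", "visibility")]),
               rep(4L, 4))
  expect_equal(dim(d$delta_matrix), c(4, 16))
  expect_true(all(d$pairs$delta > 0))
  expect_true(all(d$pairs$near_color %in% c("blue", "green")))
  # every selected grasp passed force closure during enumeration
  for (k in seq_len(16)) {
    sc <- scores[[k]]
    expect_true(all(sc$fc_flag[c(d$grasp_pairs[[k]]$near_optimal,
                                 d$grasp_pairs[[k]]$sub_optimal)]))
  }
  # small designs and insufficient object sets
  d4 <- design_experiment(scores[1:4], per_criterion_count = 1, seed = 1)
  expect_equal(nrow(d4$pairs), 4)
  expect_error(design_experiment(scores[1:3], per_criterion_count = 1), "need 4 objects")
})

test_that("counterbalance report accumulates signed off-target differences", {
  pairs <- data.frame(
    object = c("a", "b"), criterion = "aperture",
    delta_aperture = c(0.8, 0.9), delta_nga = c(0.1, -0.1),
    delta_torque = c(0, 0), delta_visibility = c(0.05, 0.15),
    stringsAsFactors = FALSE
  )
  rep_ <- counterbalance_report(pairs)
  expect_equal(rep_$signed_sum[rep_$off_target == "nga"], 0)
  expect_equal(rep_$signed_sum[rep_$off_target == "torque"], 0)
  expect_equal(rep_$signed_sum[rep_$off_target == "visibility"], 0.2)
  # matches direct accumulation on a designed experiment
  objs <- generate_fixtures(2)
  scores <- lapply(objs, enumerate_grasps)
  d <- design_experiment(scores, seed = 2)
  cb <- counterbalance_report(d)
  for (r in seq_len(nrow(cb))) {
    sel <- d$pairs$criterion == cb$block[r]
    expect_equal(cb$signed_sum[r],
                 sum(d$pairs[[paste0("delta_", cb$off_target[r])]][sel]))
  }
})
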