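cube_face_grasp <- function(axis = 1, span_cm = 2.5, offset = c(0, 0, 0)) {
  # contacts at the centers of two opposite faces spaced span_cm apart
  lo <- c(1.25, 1.25, 1.25); lo[axis] <- 0
  hi <- lo; hi[axis] <- span_cm
  n <- c(0, 0, 0); n[axis] <- 1
  make_grasp(list(position = lo + offset, normal = -n),
             list(position = hi + offset, normal = n))
}

test_that("combinatorial budget reproduces the fingertip-sampling estimate", {
  expect_equal(combinatorial_budget(300, 3), list(n_locations = 100, n_ordered_pairs = 10000))
  expect_equal(combinatorial_budget(3, 3)$n_ordered_pairs, 1)
  expect_equal(combinatorial_budget(30, 3), list(n_locations = 10, n_ordered_pairs = 100))
  expect_error(combinatorial_budget(-1, 3), "positive")
})

test_that("force closure accepts opposed normals and rejects same-side or skew pairs", {
  expect_true(force_closure(cube_face_grasp(1), mu = 0.1))
  expect_true(force_closure(cube_face_grasp(3), mu = 0.5))
  # same face: connecting line orthogonal to both normals
  same <- make_grasp(list(position = c(0, 0.5, 0.5), normal = c(-1, 0, 0)),
                     list(position = c(0, 2.0, 1.5), normal = c(-1, 0, 0)))
  expect_false(force_closure(same, mu = 0.5))
  # perpendicular faces of one cube: required 45 deg > cone half-angle 26.57 deg
  perp <- make_grasp(list(position = c(0, 1.25, 1.25), normal = c(-1, 0, 0)),
                     list(position = c(1.25, 1.25, 2.5), normal = c(0, 0, 1)))
  expect_false(force_closure(perp, mu = 0.5))
  expect_true(force_closure(perp, mu = 1.5))  # wide cones admit it
  # digit-swap symmetry
  g <- cube_face_grasp(2)
  swapped <- make_grasp(g$index, g$thumb)
  expect_identical(force_closure(g, 0.5), force_closure(swapped, 0.5))
  degen <- make_grasp(list(position = c(0, 0, 0), normal = c(1, 0, 0)),
                      list(position = c(0, 0, 0), normal = c(-1, 0, 0)))
  expect_error(force_closure(degen), "coincident")
})

test_that("aperture and its hinge penalty match the worked grip examples", {
  expect_equal(aperture(cube_face_grasp(1, 2.5)), 2.5)    # one-cube grip
  expect_equal(aperture(cube_face_grasp(1, 12.5)), 12.5)  # five-cube span
  expect_equal(aperture_cost(2.5), 0)
  expect_equal(aperture_cost(12.5), 10)
  expect_equal(aperture_cost(1.0), 0)
  # non-decreasing, identically zero up to the threshold
  ap <- seq(0, 15, by = 0.1)
  cost <- aperture_cost(ap)
  expect_true(all(diff(cost) >= 0))
  expect_true(all(cost[ap <= 2.5] == 0))
  expect_true(all(cost[ap > 2.5] > 0))
})

test_that("natural-grasp-axis cost is the acute undirected angle", {
  nga <- c(1, 0, 0)
  expect_equal(nga_cost(cube_face_grasp(1), nga), 0)
  expect_equal(nga_cost(cube_face_grasp(3), nga), pi / 2)
  # flipping the axis leaves the cost unchanged
  g <- cube_face_grasp(1)
  flipped <- make_grasp(g$index, g$thumb)
  expect_equal(nga_cost(flipped, nga), 0)
  expect_equal(nga_cost(cube_face_grasp(2), c(sqrt(0.5), sqrt(0.5), 0)), pi / 4)
})

test_that("torque matches m*g*d and the per-cube moment oracle", {
  cube <- single_cube()
  expect_equal(torque_magnitude(cube_face_grasp(1), cube), 0)  # line through COM
  # horizontal line offset 0.5 cm perpendicular from the COM
  off <- cube_face_grasp(1, 5, offset = c(0, -0.5, 0))
  expect_equal(torque_magnitude(off, cube), 0.0096875 * 9.81 * 0.005, tolerance = 1e-12)
  # digit-swap symmetry
  swapped <- make_grasp(off$index, off$thumb)
  expect_equal(torque_magnitude(off, cube), torque_magnitude(swapped, cube))

  # oracle equivalence on random grasps over random posed objects
  set.seed(42)
  for (rep in 1:100) {
    obj <- build_object(random_polycube(sample(2:10, 1), seed = rep),
                        materials = sample(c("wood", "brass"), 1),
                        pose = list(yaw_deg = runif(1, 0, 360),
                                    translation_cm = c(runif(2, -5, 5), 0)))
    sc <- sample_contacts(obj, 1)
    ij <- sample.int(nrow(sc), 2)
    g <- make_grasp(ij[1], ij[2], sc)
    expect_equal(torque_magnitude(g, obj), oracle_torque(g, obj), tolerance = 1e-8)
  }
})

test_that("torque is blind to mass in the vertical plane of the grasp line and grows off it", {
  # grasp line along x through the centers of the base row
  g <- make_grasp(list(position = c(0, 1.25, 1.25), normal = c(-1, 0, 0)),
                  list(position = c(7.5, 1.25, 1.25), normal = c(1, 0, 0)))
  base <- build_object(cbind(0:2, 0, 0))
  # extra cube directly above the line: centroid in the vertical plane y = 1.25
  stacked <- build_object(rbind(cbind(0:2, 0, 0), c(1, 0, 1)))
  expect_equal(torque_magnitude(g, base), torque_magnitude(g, stacked), tolerance = 1e-12)
  # moving the grasp line perpendicular away from the COM strictly increases torque
  tq <- vapply(0:3, function(k) {
    gk <- make_grasp(list(position = c(0, 1.25 + 0.5 * k, 1.25), normal = c(-1, 0, 0)),
                     list(position = c(7.5, 1.25 + 0.5 * k, 1.25), normal = c(1, 0, 0)))
    torque_magnitude(gk, base)
  }, 0)
  expect_true(all(diff(tq) > 0))
})

test_that("occlusion cost matches the scalar ray-slab oracle and its limiting cases", {
  rod <- rod_object(5)
  cfg <- grasp_config()
  sc <- sample_contacts(rod, 1)
  pts <- as.matrix(sc[, c("x", "y", "z")])
  set.seed(7)
  for (rep in 1:20) {
    ij <- sample.int(nrow(sc), 2)
    g <- make_grasp(ij[1], ij[2], sc)
    box <- graspquality:::.hand_slab(g, cfg$viewpoint_cm, cfg$hand_depth_cm,
                                     cfg$hand_width_cm)
    expect_equal(visibility_cost(g, rod, cfg, surface_points = pts),
                 oracle_occlusion(pts, cfg$viewpoint_cm, box))
  }
  # empty hand volume occludes nothing
  none <- grasp_config(hand_depth_cm = 0)
  g <- make_grasp(1, 10, sc)
  expect_equal(visibility_cost(g, rod, none, surface_points = pts), 0)
  # an oversized slab between viewer and object occludes everything
  big <- grasp_config(hand_depth_cm = 60, hand_width_cm = 60)
  g2 <- make_grasp(list(position = c(0, 1.25, 1.25), normal = c(-1, 0, 0)),
                   list(position = c(12.5, 1.25, 1.25), normal = c(1, 0, 0)))
  expect_equal(visibility_cost(g2, rod, big, surface_points = pts), 1)
  inside <- grasp_config(viewpoint_cm = c(1, 1, 1))
  expect_error(visibility_cost(g2, rod, inside, surface_points = pts), "inside")
})

test_that("enumeration keeps only force-closure pairs and normalizes per object", {
  cube <- single_cube()
  g <- enumerate_grasps(cube)
  expect_equal(nrow(g), 3)  # the three opposite-face axes
  expect_true(all(g$fc_flag))
  expect_true(all(abs(g$aperture_cm - 2.5) < 1e-12))

  # contacts restricted to a single face admit no grasp
  sc <- sample_contacts(cube, 2)
  one_face <- sc[sc$face_id == sc$face_id[1], ]
  expect_equal(nrow(enumerate_grasps(cube, one_face)), 0)

  rod <- rod_object(6, c(rep("wood", 3), rep("brass", 3)))
  sc <- sample_contacts(rod, 1)
  g <- enumerate_grasps(rod, sc)
  expect_lte(nrow(g), choose(nrow(sc), 2))
  for (cr in c("aperture", "nga", "torque", "visibility")) {
    nc <- g[[paste0("norm_", cr)]]
    expect_true(all(nc >= 0 & nc <= 1))
    if (diff(range(g[[paste0("cost_", cr)]])) > 1e-12) {
      expect_equal(min(nc), 0)
      expect_equal(max(nc), 1)
    }
  }
  expect_equal(g$combined_cost,
               as.numeric(as.matrix(g[, paste0("norm_", c("aperture", "nga",
                                                          "torque", "visibility"))]) %*%
                            rep(0.25, 4)))
  # a criterion constant across candidates normalizes to all zeros
  g0 <- enumerate_grasps(cube)
  expect_true(all(g0$norm_aperture == 0))
})
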