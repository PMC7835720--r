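#' Grasp scoring under four optimality criteria
#'
#' Candidate grasps are unordered thumb-index contact pairs on the exposed
#' surface. A grasp is admissible only under force closure: the line joining
#' the two contacts must lie inside both friction cones. Admissible grasps are
#' scored on four criteria -- grip aperture, misalignment with the natural
#' grasp axis, gravitational torque about the grasp axis, and the fraction of
#' the object the hand occludes from the participant's viewpoint -- and the
#' four raw costs are min-max normalized within each object's candidate set.
#'
#' @name grasp_model
NULL

#' Model configuration
#'
#' @param aperture_threshold_cm largest comfortable precision-grip aperture;
#'   apertures up to this incur no penalty (default 2.5 cm).
#' @param friction_mu Coulomb friction coefficient of the digit-surface
#'   contact; the friction-cone half-angle is `atan(friction_mu)`
#'   (default 0.5, about 26.6 degrees).
#' @param nga_dir unit 3-vector giving the natural grasp axis: the preferred
#'   thumb-index axis orientation. Default is horizontal, rotated 45 degrees
#'   from the frontal (participant-to-object, +y) axis toward +x.
#' @param gravity_ms2 gravitational acceleration (default 9.81).
#' @param viewpoint_cm participant eye position in world cm; default 34 cm on
#'   the participant's side of the object along -y and 30 cm above the table.
#' @param hand_depth_cm,hand_width_cm extent of the rectangular hand slab used
#'   by the occlusion model: the slab spans the two contacts and is extruded
#'   toward the participant by `hand_depth_cm` (default 10) with thickness
#'   `hand_width_cm` (default 3).
#' @param weights nonnegative length-4 weights over the criteria
#'   (aperture, nga, torque, visibility), normalized to sum to 1; default
#'   uniform.
#' @return a list of class `grasp_config`
#' @export
grasp_config <- function(aperture_threshold_cm = 2.5,
                         friction_mu = 0.5,
                         nga_dir = c(sin(pi / 4), cos(pi / 4), 0),
                         gravity_ms2 = 9.81,
                         viewpoint_cm = c(0, -34, 30),
                         hand_depth_cm = 10,
                         hand_width_cm = 3,
                         weights = rep(0.25, 4)) {
  if (aperture_threshold_cm <= 0) stopf("grasp_config: aperture_threshold_cm must be > 0")
  if (friction_mu <= 0) stopf("grasp_config: friction_mu must be > 0")
  if (any(weights < 0) || sum(weights) <= 0) stopf("grasp_config: weights must be >= 0 and not all zero")
  structure(list(
    aperture_threshold_cm = aperture_threshold_cm,
    friction_mu = friction_mu,
    nga_dir = unitize(nga_dir),
    gravity_ms2 = gravity_ms2,
    viewpoint_cm = viewpoint_cm,
    hand_depth_cm = hand_depth_cm,
    hand_width_cm = hand_width_cm,
    weights = weights / sum(weights)
  ), class = "grasp_config")
}

criterion_names <- c("aperture", "nga", "torque", "visibility")

#' Combinatorial budget of digit placements
#'
#' For a surface of given area coarsely sampled in fingertip-sized patches,
#' the number of candidate contact locations and of ordered thumb-index
#' configurations. A 300 cm^2 sphere at 3 cm^2 patches yields about 100
#' locations and 10,000 configurations.
#'
#' @param surface_area_cm2,patch_area_cm2 positive areas
#' @return list with `n_locations` and `n_ordered_pairs`
#' @export
combinatorial_budget <- function(surface_area_cm2, patch_area_cm2) {
  if (surface_area_cm2 <= 0 || patch_area_cm2 <= 0) {
    stopf("combinatorial_budget: areas must be positive")
  }
  n <- round(surface_area_cm2 / patch_area_cm2)
  list(n_locations = n, n_ordered_pairs = n^2)
}

#' Two-contact force closure
#'
#' TRUE iff the line between the contacts lies inside both friction cones:
#' the angle between each contact's outward normal and the direction toward
#' the other contact's opposite (i.e. from the other contact to this one) is
#' at most `atan(mu)`. Thumb and forefinger pushing on the same face of an
#' object fail this test and cannot lift it. Symmetric under digit swap.
#'
#' @param grasp list with `thumb` and `index`, each a list with `position`
#'   (cm) and outward unit `normal` (see [make_grasp()])
#' @param mu friction coefficient
#' @return logical flag
#' @export
force_closure <- function(grasp, mu = 0.5) {
  d <- grasp$index$position - grasp$thumb$position
  if (sqrt(sum(d^2)) < 1e-9) stopf("force_closure: coincident contact positions")
  half <- atan(mu)
  a_thumb <- vec_angle(grasp$thumb$normal, -d)  # index -> thumb direction
  a_index <- vec_angle(grasp$index$normal, d)   # thumb -> index direction
  (a_thumb <= half + 1e-12) && (a_index <= half + 1e-12)
}

#' Construct a grasp from two contact points
#'
#' @param thumb,index each a list with `position` (length-3 cm) and unit
#'   `normal`, or a row index into a `sample_contacts()` data.frame supplied
#'   via `contacts`
#' @param contacts optional contact table from [sample_contacts()]
#' @return list of class `grasp`
#' @export
make_grasp <- function(thumb, index, contacts = NULL) {
  as_cp <- function(x) {
    if (is.numeric(x) && length(x) == 1 && !is.null(contacts)) {
      list(position = as.numeric(contacts[x, c("x", "y", "z")]),
           normal = as.numeric(contacts[x, c("nx", "ny", "nz")]),
           face_id = contacts$face_id[x])
    } else x
  }
  structure(list(thumb = as_cp(thumb), index = as_cp(index)), class = "grasp")
}

#' Grip aperture and its penalty
#'
#' Aperture is the Euclidean thumb-index distance. Precision grips are
#' comfortable only up to a threshold aperture (default 2.5 cm); the penalty
#' is the hinge `max(0, aperture - a0)` in cm of excess, zero on `[0, a0]`.
#'
#' @param grasp a `grasp`
#' @return aperture in cm
#' @export
aperture <- function(grasp) {
  sqrt(sum((grasp$index$position - grasp$thumb$position)^2))
}

#' @rdname aperture
#' @param aperture_cm aperture value(s), cm
#' @param a0 zero-penalty threshold, cm
#' @return penalty in cm of excess (vectorized)
#' @export
aperture_cost <- function(aperture_cm, a0 = 2.5) {
  if (a0 <= 0) stopf("aperture_cost: a0 must be > 0")
  pmax(0, aperture_cm - a0)
}

#' Misalignment with the natural grasp axis
#'
#' Acute angle between the undirected thumb-index axis and the natural grasp
#' axis, in [0, pi/2]; invariant to flipping either axis.
#'
#' @param grasp a `grasp`
#' @param nga_dir unit 3-vector
#' @return angle in radians
#' @export
nga_cost <- function(grasp, nga_dir = grasp_config()$nga_dir) {
  d <- grasp$index$position - grasp$thumb$position
  if (sqrt(sum(d^2)) < 1e-9) stopf("nga_cost: degenerate grasp")
  axis_angle(d, nga_dir)
}

#' Gravitational torque about the grasp axis
#'
#' Magnitude of the moment of the object's weight about the line through the
#' two contacts: `|((COM - p) x m g ghat) . ahat|` with `p` a point on the
#' line, `ahat` its unit direction and `ghat = -z`. Zero iff the center of
#' mass lies in the vertical plane containing the contact line. Large values
#' mean the object tends to rotate out of the grip unless countered by grip
#' force.
#'
#' @param grasp a `grasp`
#' @param obj a `rigid_object`
#' @param g gravitational acceleration, m/s^2
#' @return torque magnitude in N m
#' @export
torque_magnitude <- function(grasp, obj, g = 9.81) {
  d <- grasp$index$position - grasp$thumb$position
  if (sqrt(sum(d^2)) < 1e-9) stopf("torque_magnitude: degenerate grasp")
  a_hat <- unitize(d)
  com_m <- center_of_mass(obj) / 100          # cm -> m
  p_m <- grasp$thumb$position / 100
  F <- object_mass(obj) / 1000 * g * c(0, 0, -1)  # weight, N
  abs(sum(cross3(com_m - p_m, F) * a_hat))
}

# oriented hand slab for the occlusion model: spans the two contacts,
# thickness hand_width_cm, extruded toward the viewer by hand_depth_cm
.hand_slab <- function(grasp, viewpoint, depth, width) {
  p1 <- grasp$thumb$position; p2 <- grasp$index$position
  u <- unitize(p2 - p1)                       # along the grasp axis
  mid <- (p1 + p2) / 2
  toward <- viewpoint - mid
  vt <- toward - sum(toward * u) * u          # viewer direction, axis-orthogonal
  if (sqrt(sum(vt^2)) < 1e-9) vt <- c(0, -1, 0) - sum(c(0, -1, 0) * u) * u
  v <- unitize(vt)
  w <- cross3(u, v)
  hl <- c(sqrt(sum((p2 - p1)^2)) / 2 + width / 2, depth / 2, width / 2)
  list(center = mid + v * depth / 2, axes = rbind(u, v, w), half = hl)
}

# fraction of sample points whose ray to the viewpoint hits the box
# (vectorized slab test in the box frame)
.occluded_fraction <- function(points, viewpoint, box) {
  P <- sweep(points, 2, box$center, `-`) %*% t(box$axes)
  E <- matrix(viewpoint - box$center, nrow(points), 3, byrow = TRUE) %*% t(box$axes)
  D <- E - P
  tmin <- rep(0, nrow(P)); tmax <- rep(1, nrow(P)); hit <- rep(TRUE, nrow(P))
  for (k in 1:3) {
    par <- abs(D[, k]) < 1e-12
    miss_par <- par & (P[, k] < -box$half[k] | P[, k] > box$half[k])
    t1 <- (-box$half[k] - P[, k]) / D[, k]
    t2 <- (box$half[k] - P[, k]) / D[, k]
    lo <- pmin(t1, t2); hi <- pmax(t1, t2)
    tmin <- ifelse(par, tmin, pmax(tmin, lo))
    tmax <- ifelse(par, tmax, pmin(hi, tmax))
    hit <- hit & !miss_par
  }
  # exclude the sample point itself sitting exactly on the box surface
  mean(hit & (tmax - tmin > 1e-9) & (tmax > 1e-6))
}

#' Occluded fraction of the object surface
#'
#' Fraction of surface sample points whose line of sight to the viewpoint is
#' blocked by a rectangular hand slab spanning the two contacts and extruded
#' toward the participant. Only the ordering of grasps by this cost is
#' meaningful; the slab is a deliberately coarse stand-in for the hand.
#'
#' @param grasp a `grasp`
#' @param obj a `rigid_object`
#' @param config a `grasp_config`
#' @param surface_points optional n x 3 matrix of sample points (defaults to
#'   the face-center contact sample of `obj`)
#' @return occluded fraction in [0, 1]
#' @export
visibility_cost <- function(grasp, obj, config = grasp_config(),
                            surface_points = NULL) {
  if (is.null(surface_points)) {
    sc <- sample_contacts(obj, 1)
    surface_points <- as.matrix(sc[, c("x", "y", "z")])
  }
  vp <- config$viewpoint_cm
  bb_lo <- apply(surface_points, 2, min); bb_hi <- apply(surface_points, 2, max)
  if (all(vp >= bb_lo - 1e-9) && all(vp <= bb_hi + 1e-9)) {
    stopf("visibility_cost: viewpoint lies inside the object")
  }
  if (config$hand_depth_cm <= 0 || config$hand_width_cm <= 0) return(0)
  box <- .hand_slab(grasp, vp, config$hand_depth_cm, config$hand_width_cm)
  .occluded_fraction(surface_points, vp, box)
}

#' Enumerate and score admissible grasps on an object
#'
#' Scores every unordered pair of candidate contacts that passes force
#' closure. Raw costs are grip-aperture excess (cm), natural-grasp-axis
#' misalignment (rad), gravitational torque (N m) and occluded fraction;
#' [normalize_costs()] maps them to per-object normalized costs in [0, 1]
#' and a weighted combined cost. Rows are in deterministic enumeration order
#' (contact index, lower first).
#'
#' @param obj a `rigid_object`
#' @param contacts contact table from [sample_contacts()] (default grid 1)
#' @param config a `grasp_config`
#' @param normalize min-max normalize costs within the candidate set
#' @return data.frame of class `grasp_scores`, one row per admissible grasp
#' @export
enumerate_grasps <- function(obj, contacts = sample_contacts(obj, 1),
                             config = grasp_config(), normalize = TRUE) {
  n <- nrow(contacts)
  if (n < 2) {
    return(.empty_scores())
  }
  pos <- as.matrix(contacts[, c("x", "y", "z")])
  nrm <- as.matrix(contacts[, c("nx", "ny", "nz")])
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  # exclude same-face pairs and run the friction-cone test vectorized
  i <- pairs[, 1]; j <- pairs[, 2]
  keep <- contacts$face_id[i] != contacts$face_id[j]
  i <- i[keep]; j <- j[keep]
  d <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  ok <- len > 1e-9
  dhat <- d / pmax(len, 1e-12)
  cos_half <- cos(atan(config$friction_mu))
  ci <- -rowSums(nrm[i, , drop = FALSE] * dhat)   # thumb normal vs index->thumb
  cj <- rowSums(nrm[j, , drop = FALSE] * dhat)    # index normal vs thumb->index
  fc <- ok & (ci >= cos_half - 1e-12) & (cj >= cos_half - 1e-12)
  i <- i[fc]; j <- j[fc]
  if (!length(i)) return(.empty_scores())

  com <- center_of_mass(obj)
  mass <- object_mass(obj)
  sc_pts <- pos  # occlusion sampled at the same face-center budget
  rows <- lapply(seq_along(i), function(k) {
    g <- make_grasp(i[k], j[k], contacts)
    ap <- aperture(g)
    data.frame(
      grasp_id = sprintf("g%04d", k),
      thumb_contact = i[k], index_contact = j[k],
      thumb_x = g$thumb$position[1], thumb_y = g$thumb$position[2], thumb_z = g$thumb$position[3],
      index_x = g$index$position[1], index_y = g$index$position[2], index_z = g$index$position[3],
      fc_flag = TRUE,
      aperture_cm = ap,
      torque_Nm = torque_magnitude(g, obj, config$gravity_ms2),
      nga_rad = nga_cost(g, config$nga_dir),
      occluded_frac = visibility_cost(g, obj, config, surface_points = sc_pts),
      stringsAsFactors = FALSE
    )
  })
  scores <- do.call(rbind, rows)
  scores$cost_aperture <- aperture_cost(scores$aperture_cm, config$aperture_threshold_cm)
  scores$cost_nga <- scores$nga_rad
  scores$cost_torque <- scores$torque_Nm
  scores$cost_visibility <- scores$occluded_frac
  attr(scores, "object") <- obj$name
  attr(scores, "mass_g") <- mass
  attr(scores, "com_cm") <- com
  class(scores) <- c("grasp_scores", "data.frame")
  if (normalize) scores <- normalize_costs(scores, config$weights)
  scores
}

.empty_scores <- function() {
  s <- data.frame(grasp_id = character(0))
  class(s) <- c("grasp_scores", "data.frame")
  s
}

#' Min-max normalize criterion costs within an object's candidate set
#'
#' Per criterion, `(c - min)/(max - min)` over the candidate grasps of the
#' object, so the best candidate scores 0 and the worst 1 (normalized,
#' arbitrary units); a criterion constant across candidates normalizes to 0
#' for all. The combined cost is the weighted sum of normalized costs.
#'
#' @param scores a `grasp_scores` data.frame
#' @param weights length-4 nonnegative weights (aperture, nga, torque,
#'   visibility), renormalized to sum to 1
#' @return `scores` with `norm_*` columns and `combined_cost`
#' @export
normalize_costs <- function(scores, weights = rep(0.25, 4)) {
  if (nrow(scores) < 1) stopf("normalize_costs: need at least one score")
  weights <- weights / sum(weights)
  for (cr in criterion_names) {
    raw <- scores[[paste0("cost_", cr)]]
    rng <- range(raw)
    scores[[paste0("norm_", cr)]] <-
      if (diff(rng) < 1e-12) rep(0, length(raw)) else (raw - rng[1]) / diff(rng)
  }
  nm <- as.matrix(scores[, paste0("norm_", criterion_names)])
  scores$combined_cost <- as.numeric(nm %*% weights)
  scores
}

#' Write a scored-grasp table to CSV
#' @param scores a `grasp_scores` data.frame
#' @param path output path
#' @export
write_grasp_csv <- function(scores, path) {
  df <- as.data.frame(scores)
  df <- cbind(object = attr(scores, "object") %||% NA_character_, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
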