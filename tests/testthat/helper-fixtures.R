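# shared builders and independent oracles for the test suite

rod_object <- function(n = 10, materials = "wood", ...) {
  build_object(cbind(0:(n - 1), 0, 0), materials, ...)
}

single_cube <- function(materials = "wood", ...) {
  build_object(matrix(c(0, 0, 0), 1), materials, ...)
}

# brute-force exposed-face count: all faces minus those shared by two cells
oracle_exposed_faces <- function(cells) {
  key <- apply(cells, 1, paste, collapse = ",")
  dirs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  n <- 0L
  for (i in seq_len(nrow(cells))) {
    for (d in seq_len(6)) {
      if (!(paste(cells[i, ] + dirs[d, ], collapse = ",") %in% key)) n <- n + 1L
    }
  }
  n
}

# random connected polycube grown by a seeded random walk over free neighbours
random_polycube <- function(n_cells, seed) {
  set.seed(seed)
  cells <- matrix(c(0L, 0L, 0L), 1)
  dirs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  key <- "0,0,0"
  while (nrow(cells) < n_cells) {
    base <- cells[sample.int(nrow(cells), 1), ]
    cand <- base + dirs[sample.int(6, 1), ]
    k <- paste(cand, collapse = ",")
    if (!(k %in% key)) {
      cells <- rbind(cells, cand)
      key <- c(key, k)
    }
  }
  cells
}

# independent torque oracle: sum per-cube gravity moments about the grasp line
# (the implementation works from the aggregate center of mass instead)
oracle_torque <- function(grasp, obj, g = 9.81) {
  a_hat <- (grasp$index$position - grasp$thumb$position)
  a_hat <- a_hat / sqrt(sum(a_hat^2))
  p <- grasp$thumb$position / 100
  R <- local({
    th <- obj$pose$yaw_deg * pi / 180
    rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  })
  tau <- 0
  for (i in seq_len(nrow(obj$cells))) {
    centroid <- as.numeric(R %*% ((obj$cells[i, ] + 0.5) * obj$side_cm)) +
      obj$pose$translation_cm
    m_kg <- obj$side_cm^3 * obj$densities[[obj$materials[i]]] / 1000
    Fi <- m_kg * g * c(0, 0, -1)
    r <- centroid / 100 - p
    cr <- c(r[2] * Fi[3] - r[3] * Fi[2], r[3] * Fi[1] - r[1] * Fi[3],
            r[1] * Fi[2] - r[2] * Fi[1])
    tau <- tau + sum(cr * a_hat)
  }
  abs(tau)
}

# scalar per-point ray-slab oracle for the occlusion model
oracle_occlusion <- function(points, viewpoint, box) {
  hits <- 0L
  for (r in seq_len(nrow(points))) {
    P <- as.numeric((points[r, ] - box$center) %*% t(box$axes))
    E <- as.numeric((viewpoint - box$center) %*% t(box$axes))
    D <- E - P
    tmin <- 0; tmax <- 1; ok <- TRUE
    for (k in 1:3) {
      if (abs(D[k]) < 1e-12) {
        if (P[k] < -box$half[k] || P[k] > box$half[k]) ok <- FALSE
      } else {
        t1 <- (-box$half[k] - P[k]) / D[k]; t2 <- (box$half[k] - P[k]) / D[k]
        tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
      }
    }
    if (ok && tmax - tmin > 1e-9 && tmax > 1e-6) hits <- hits + 1L
  }
  hits / nrow(points)
}

# hand-built scored-candidate table with known normalized costs, for the
# pair-selection oracle tests
toy_scores <- function(norm) {
  n <- nrow(norm)
  df <- data.frame(
    grasp_id = sprintf("g%02d", seq_len(n)),
    fc_flag = TRUE,
    norm_aperture = norm[, 1], norm_nga = norm[, 2],
    norm_torque = norm[, 3], norm_visibility = norm[, 4],
    stringsAsFactors = FALSE
  )
  attr(df, "object") <- "toy"
  class(df) <- c("grasp_scores", "data.frame")
  df
}

# exhaustive pair-selection oracle over ordered candidate pairs
oracle_select_pair <- function(scores, criterion, epsilon) {
  crits <- c("aperture", "nga", "torque", "visibility")
  nm <- as.matrix(scores[, paste0("norm_", crits)])
  n <- nrow(nm)
  best <- NULL; best_delta <- -Inf
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    delta <- nm[j, ] - nm[i, ]   # optimality difference, near = i
    names(delta) <- crits
    if (delta[criterion] <= 1e-12) next
    if (all(abs(delta[setdiff(crits, criterion)]) <= epsilon)) {
      if (delta[criterion] > best_delta) {
        best_delta <- delta[criterion]; best <- c(i, j)
      }
    }
  }
  list(pair = best, delta = best_delta)
}

# minimal design stub for observer/analysis tests: 16 pairs, varied deltas
stub_design <- function(n_pairs = 16, deltas = seq(0.3, 1, length.out = n_pairs)) {
  data.frame(
    object = sprintf("obj%02d", seq_len(n_pairs)),
    criterion = rep(c("aperture", "nga", "torque", "visibility"),
                    length.out = n_pairs),
    delta = deltas,
    stringsAsFactors = FALSE
  )
}
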