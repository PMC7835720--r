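#' Polycube stimulus objects
#'
#' The stimuli are rigid solids built from face-connected unit cubes on an
#' integer lattice, each cube made of beech wood or brass. The default cube
#' side is 2.5 cm, so an all-wood 10-cube object weighs about 97 g at the
#' default wood density. Objects sit on the table plane z = 0 in a
#' right-handed frame with z up (gravity along -z) and y pointing from the
#' participant toward the object; the only admissible pose is a rotation
#' about the vertical axis (the objects stand on a turntable) plus a
#' horizontal translation.
#'
#' @name polycube
NULL

.default_densities <- c(wood = 0.62, brass = 8.5)

# the six axis-aligned outward face directions of a lattice cube
.face_dirs <- rbind(
  "x-" = c(-1, 0, 0), "x+" = c(1, 0, 0),
  "y-" = c(0, -1, 0), "y+" = c(0, 1, 0),
  "z-" = c(0, 0, -1), "z+" = c(0, 0, 1)
)

#' Build a rigid polycube object
#'
#' @param cells integer matrix (n x 3) or list of integer 3-vectors of lattice
#'   positions; one cube side per lattice unit.
#' @param materials character vector, one material per cell (recycled if
#'   length one). Any material name is allowed as long as `densities` covers it.
#' @param side_cm cube side length in cm (default 2.5).
#' @param densities named numeric vector, g/cm^3 per material.
#' @param pose list with `yaw_deg` (rotation about z) and `translation_cm`
#'   (length-3, cm); defaults to the identity pose.
#' @param name optional object identifier.
#'
#' @return An object of class `rigid_object` with derived exposed faces, mass
#'   and center of mass.
#' @export
build_object <- function(cells, materials = "wood", side_cm = 2.5,
                         densities = .default_densities,
                         pose = list(yaw_deg = 0, translation_cm = c(0, 0, 0)),
                         name = "object") {
  if (is.list(cells)) cells <- do.call(rbind, cells)
  cells <- matrix(as.integer(round(cells)), ncol = 3)
  n <- nrow(cells)
  if (n < 1) stopf("build_object: need at least one cell")
  key0 <- apply(cells, 1, paste, collapse = ",")
  if (anyDuplicated(key0)) {
    stopf("build_object: duplicate lattice cell(s): %s",
          paste(unique(key0[duplicated(key0)]), collapse = "; "))
  }
  materials <- rep_len(as.character(materials), n)
  if (!is.numeric(side_cm) || side_cm <= 0) stopf("build_object: side_cm must be > 0")

  key <- apply(cells, 1, paste, collapse = ",")
  ## face connectivity: breadth-first flood over the 6-neighbourhood
  if (n > 1) {
    seen <- logical(n); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (d in seq_len(6)) {
        nb <- paste(cells[i, ] + .face_dirs[d, ], collapse = ",")
        j <- match(nb, key)
        if (!is.na(j) && !seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
      }
    }
    if (!all(seen)) {
      stopf("build_object: cells do not form one face-connected component (%d of %d reachable)",
            sum(seen), n)
    }
  }

  obj <- structure(list(
    name = name, cells = cells, materials = materials, side_cm = side_cm,
    densities = densities, pose = .check_pose(pose)
  ), class = "rigid_object")
  obj$faces <- .exposed_faces(obj)
  obj
}

.check_pose <- function(pose) {
  pose <- list(yaw_deg = pose$yaw_deg %||% 0,
               translation_cm = pose$translation_cm %||% c(0, 0, 0))
  stopifnot(length(pose$translation_cm) == 3, is.finite(pose$yaw_deg))
  pose
}

# rotation-about-z matrix for the object's pose
.pose_rot <- function(obj) {
  th <- obj$pose$yaw_deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

# apply the pose to points (rows, cm) / to direction vectors
.pose_points <- function(obj, p) {
  R <- .pose_rot(obj)
  sweep(p %*% t(R), 2, obj$pose$translation_cm, `+`)
}
.pose_dirs <- function(obj, v) v %*% t(.pose_rot(obj))

# faces not shared between two cells, in object (unposed) coordinates
.exposed_faces <- function(obj) {
  key <- apply(obj$cells, 1, paste, collapse = ",")
  s <- obj$side_cm
  out <- list()
  for (i in seq_len(nrow(obj$cells))) {
    for (d in seq_len(6)) {
      nb <- paste(obj$cells[i, ] + .face_dirs[d, ], collapse = ",")
      if (nb %in% key) next
      center <- (obj$cells[i, ] + 0.5) * s + .face_dirs[d, ] * s / 2
      out[[length(out) + 1L]] <- list(
        face_id = paste0(key[i], ":", rownames(.face_dirs)[d]),
        cell = i, dir = d, center = center, normal = .face_dirs[d, ]
      )
    }
  }
  out
}

#' Number of exposed faces of a polycube object
#' @param obj a `rigid_object`
#' @return integer face count
#' @export
n_exposed_faces <- function(obj) length(obj$faces)

#' Object mass in grams
#'
#' Mass is the sum over cubes of side^3 times the density of the cube's
#' material; it does not depend on the pose.
#'
#' @param obj a `rigid_object`
#' @return mass in grams
#' @export
object_mass <- function(obj) {
  missing <- setdiff(unique(obj$materials), names(obj$densities))
  if (length(missing)) {
    stopf("object_mass: no density configured for material(s): %s",
          paste(missing, collapse = ", "))
  }
  sum(obj$side_cm^3 * obj$densities[obj$materials])
}

#' Center of mass in world coordinates (cm)
#'
#' Mass-weighted mean of the cube centroids, mapped through the object's pose.
#' Grasping far from this point induces large gravitational torques.
#'
#' @param obj a `rigid_object`
#' @return length-3 numeric, cm
#' @export
center_of_mass <- function(obj) {
  m <- obj$side_cm^3 * obj$densities[obj$materials]
  if (any(is.na(m))) stopf("center_of_mass: missing density")
  centroids <- (obj$cells + 0.5) * obj$side_cm
  com <- colSums(centroids * m) / sum(m)
  as.numeric(.pose_points(obj, matrix(com, 1)))
}

#' Sample candidate contact points on the exposed surface
#'
#' Discretizes each exposed cube face into a `per_face_grid` x `per_face_grid`
#' grid of candidate digit placements with outward unit normals, in world
#' coordinates. The default grid of 1 (face centers) matches a coarse
#' fingertip-sized surface budget of roughly one hundred locations for a
#' 10-cube object and keeps exhaustive pair enumeration cheap.
#'
#' @param obj a `rigid_object`
#' @param per_face_grid points per face edge (>= 1)
#' @return data.frame with columns face_id, x, y, z, nx, ny, nz, ordered by
#'   face then grid index
#' @export
sample_contacts <- function(obj, per_face_grid = 1) {
  g <- as.integer(per_face_grid)
  if (g < 1) stopf("sample_contacts: per_face_grid must be >= 1")
  s <- obj$side_cm
  offs <- (seq_len(g) - 0.5) / g - 0.5   # in (-0.5, 0.5), cube-side units
  rows <- list()
  for (f in obj$faces) {
    n <- f$normal
    # two in-plane tangent axes
    t1 <- if (abs(n[1]) == 1) c(0, 1, 0) else c(1, 0, 0)
    t2 <- cross3(n, t1)
    for (a in offs) for (b in offs) {
      p <- f$center + (a * t1 + b * t2) * s
      rows[[length(rows) + 1L]] <- c(p, n)
    }
  }
  m <- do.call(rbind, rows)
  pos <- .pose_points(obj, m[, 1:3, drop = FALSE])
  nrm <- .pose_dirs(obj, m[, 4:6, drop = FALSE])
  data.frame(
    face_id = rep(vapply(obj$faces, `[[`, "", "face_id"), each = g * g),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
    stringsAsFactors = FALSE
  )
}

#' @export
print.rigid_object <- function(x, ...) {
  cat(sprintf("<rigid_object '%s'>: %d cubes (side %.2f cm), %d exposed faces\n",
              x$name, nrow(x$cells), x$side_cm, length(x$faces)))
  tab <- table(x$materials)
  cat("  materials:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  mass %.2f g, COM (%.2f, %.2f, %.2f) cm\n",
              object_mass(x), center_of_mass(x)[1], center_of_mass(x)[2],
              center_of_mass(x)[3]))
  invisible(x)
}

#' Read / write object specifications as JSON
#'
#' The interchange format is a JSON object with fields `name`, `side_cm`,
#' `cells: [{pos: [i,j,k], material: "wood"|"brass"}]` and an optional
#' `pose: {yaw_deg, translation_cm}`. The writer additionally emits the
#' derived `mass_g` and `com_cm` for inspection; the reader ignores them.
#'
#' @param path file path
#' @param densities density map used to validate/derive mass
#' @return `read_object_json`: a `rigid_object`; `write_object_json`: the path,
#'   invisibly.
#' @export
read_object_json <- function(path, densities = .default_densities) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(spec$cells) || !length(spec$cells)) stopf("object spec '%s': no cells", path)
  cells <- t(vapply(spec$cells, function(c) as.integer(unlist(c$pos)), integer(3)))
  materials <- vapply(spec$cells, function(c) c$material %||% "wood", "")
  pose <- list(
    yaw_deg = spec$pose$yaw_deg %||% 0,
    translation_cm = as.numeric(unlist(spec$pose$translation_cm %||% c(0, 0, 0)))
  )
  build_object(cells, materials, side_cm = spec$side_cm %||% 2.5,
               densities = densities, pose = pose,
               name = spec$name %||% basename(path))
}

#' @rdname read_object_json
#' @param obj a `rigid_object`
#' @export
write_object_json <- function(obj, path) {
  spec <- list(
    name = obj$name,
    side_cm = obj$side_cm,
    cells = lapply(seq_len(nrow(obj$cells)), function(i) {
      list(pos = as.integer(obj$cells[i, ]), material = obj$materials[i])
    }),
    pose = obj$pose,
    mass_g = object_mass(obj),
    com_cm = center_of_mass(obj)
  )
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
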