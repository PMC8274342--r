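#' @useDynLib earlypet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rbinom runif sd cor pchisq qtukey quantile median
#' @importFrom utils read.csv write.csv read.delim write.table head
#' @importFrom graphics plot axis segments
NULL

# ---- triangulated mesh container ----------------------------------------

new_pet_mesh <- function(vertices, triangles, thickness, hemi, extra = list()) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 3,
            is.matrix(triangles), ncol(triangles) == 3)
  if (min(triangles) < 1 || max(triangles) > nrow(vertices))
    stop("triangle indices out of range")
  m <- list(vertices = vertices, triangles = triangles,
            thickness = thickness, hemi = hemi)
  m$normals <- vertex_normals(vertices, triangles)
  m$area <- vertex_areas(vertices, triangles)
  m$edges <- mesh_edges(triangles)
  m$edge_length <- sqrt(rowSums((vertices[m$edges[, 1], , drop = FALSE] -
                                 vertices[m$edges[, 2], , drop = FALSE])^2))
  m <- c(m, extra)
  class(m) <- "pet_mesh"
  m
}

#' Number of vertices of a mesh
#' @param mesh a `pet_mesh`
#' @return integer vertex count
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @exportS3Method base::print
print.pet_mesh <- function(x, ...) {
  cat(sprintf("<pet_mesh> %d vertices, %d triangles, total area %.0f mm^2\n",
              n_vertices(x), nrow(x$triangles), sum(x$area)))
  if (!is.null(x$parcel))
    cat(sprintf("  %d parcels; cortex mask: %d vertices\n",
                length(unique(stats::na.omit(x$parcel))), sum(x$cortex)))
  if (!is.null(x$patches))
    cat("  patches:", paste(names(x$patches), collapse = ", "), "\n")
  invisible(x)
}

# Unique undirected edges from a triangle index matrix.
mesh_edges <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# Barycentric vertex areas: one third of each incident triangle.
vertex_areas <- function(vertices, triangles) {
  v1 <- vertices[triangles[, 1], , drop = FALSE]
  v2 <- vertices[triangles[, 2], , drop = FALSE]
  v3 <- vertices[triangles[, 3], , drop = FALSE]
  cr <- cross3(v2 - v1, v3 - v1)
  ta <- 0.5 * sqrt(rowSums(cr^2))
  a <- numeric(nrow(vertices))
  for (k in 1:3) {
    s <- tapply(ta, triangles[, k], sum)
    a[as.integer(names(s))] <- a[as.integer(names(s))] + s / 3
  }
  a
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Area-weighted average of incident face normals, unit length.
vertex_normals <- function(vertices, triangles) {
  v1 <- vertices[triangles[, 1], , drop = FALSE]
  v2 <- vertices[triangles[, 2], , drop = FALSE]
  v3 <- vertices[triangles[, 3], , drop = FALSE]
  fn <- cross3(v2 - v1, v3 - v1)  # length ~ 2*area, so already area-weighted
  nrm <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      s <- tapply(fn[, d], triangles[, k], sum)
      nrm[as.integer(names(s)), d] <- nrm[as.integer(names(s)), d] + s
    }
  }
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm / len
}

# ---- icosphere ----------------------------------------------------------

icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c( p, 0, -1), c(p, 0,  1), c(-p, 0, -1), c(-p, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, triangles = f)
}

subdivide_once <- function(v, f) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  mid <- new.env(hash = TRUE)
  nv <- nrow(v)
  verts <- v
  get_mid <- function(a, b) {
    k <- key(a, b)
    idx <- mid[[k]]
    if (is.null(idx)) {
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      mid[[k]] <- idx
    }
    idx
  }
  newf <- matrix(0L, nrow(f) * 4, 3)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
    ab <- get_mid(a, b); bc <- get_mid(b, c3); ca <- get_mid(c3, a)
    newf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(c3, ca, bc), c(ab, bc, ca))
  }
  list(vertices = verts, triangles = newf)
}

icosphere <- function(subdivisions) {
  s <- icosahedron()
  for (i in seq_len(subdivisions)) s <- subdivide_once(s$vertices, s$triangles)
  s
}

# ---- cortical two-hemisphere mesh ---------------------------------------

#' Build a two-hemisphere spherical cortical mesh with parcels and patches
#'
#' Each hemisphere is an icosphere.  A medial-facing cap is excluded from
#' cortical statistics and subdivided into named reference-region patches
#' standing in for non-cortical structures (pons, cerebellum, cerebellar
#' grey matter and cerebral white matter), so that reference-region scaling
#' can be exercised on purely surface-based data.  The remaining cortex is
#' split into 34 parcels per hemisphere by latitude/longitude bands (a
#' Desikan-Killiany-sized parcellation) and carries a "vulnerable" patch, a
#' contiguous lateral temporo-parietal-like cap where disease effects are
#' simulated.
#'
#' Patch geometry (in unit-sphere coordinates, `u` = medial component):
#' cortex `u <= 0.55`; medial wall `0.55 < u <= 0.72`; cerebral WM
#' `0.72 < u <= 0.82`; cerebellum `0.82 < u <= 0.92` (its upper part,
#' `u > 0.855`, doubles as cerebellar GM); pons `u > 0.92`.
#'
#' @param subdivisions icosphere subdivision level per hemisphere
#'   (4 gives 2562 vertices per hemisphere)
#' @param radius sphere radius in mm
#' @param thickness_mm cortical thickness assigned to every vertex (mm)
#' @return a `pet_mesh` with fields `parcel`, `cortex`, `neocortex`,
#'   `patches` (named list of vertex index vectors: `medial_wall`,
#'   `vulnerable`, `pons`, `cerebellum`, `cerebellar_GM`, `cerebral_WM`),
#'   `unit` (unit-sphere coordinates) and `hemi`
#' @examples
#' m <- cortical_mesh(subdivisions = 2)
#' sum(m$cortex)
#' @export
cortical_mesh <- function(subdivisions = 4, radius = 70, thickness_mm = 2.5) {
  ico <- icosphere(subdivisions)
  nv <- nrow(ico$vertices)
  # left hemisphere: medial direction +x; right: mirrored
  verts <- rbind(ico$vertices * radius + matrix(c(-radius - 5, 0, 0), nv, 3, byrow = TRUE),
                 ico$vertices * radius * matrix(c(-1, 1, 1), nv, 3, byrow = TRUE) +
                   matrix(c(radius + 5, 0, 0), nv, 3, byrow = TRUE))
  tris <- rbind(ico$triangles, ico$triangles[, c(1, 3, 2)] + nv)
  unit <- rbind(ico$vertices, ico$vertices * matrix(c(-1, 1, 1), nv, 3, byrow = TRUE))
  hemi <- rep(c("L", "R"), each = nv)
  u_med <- ifelse(hemi == "L", unit[, 1], -unit[, 1])  # medial-facing component

  m <- new_pet_mesh(verts, tris, rep(thickness_mm, 2 * nv), hemi,
                    extra = list(unit = unit))

  cortex <- u_med <= 0.55
  patches <- list(
    medial_wall  = which(u_med > 0.55 & u_med <= 0.72),
    cerebral_WM  = which(u_med > 0.72 & u_med <= 0.82),
    cerebellum   = which(u_med > 0.82 & u_med <= 0.92),
    cerebellar_GM = which(u_med > 0.855 & u_med <= 0.92),
    pons         = which(u_med > 0.92))
  # vulnerable cap: lateral/posterior/superior direction, 50 degrees, with
  # a cosine severity taper (1 at the cap centre, 0 at its rim)
  cap <- function(dir, ang_deg) {
    vd <- cbind(ifelse(hemi == "L", -dir[1], dir[1]), dir[2], dir[3])
    vd <- vd / sqrt(rowSums(vd^2))
    cosang <- rowSums(unit * vd)
    cmax <- cos(ang_deg * pi / 180)
    w <- pmax(0, (cosang - cmax) / (1 - cmax))
    w[!cortex] <- 0
    w
  }
  m$vulnerable_weight <- cap(c(0.25, -0.65, 0.55), 65)
  patches$vulnerable <- which(m$vulnerable_weight > 0)
  # "decoupled" cap: a frontal-like region of mild disease where perfusion
  # is at least as affected as metabolism (neurovascular decoupling)
  # plateaued profile: full severity over the inner cap, steep rim, so the
  # decoupled pattern's extent is insensitive to scaling shifts
  m$decoupled_weight <- pmin(1, cap(c(0.35, 0.75, 0.2), 28) / 0.35)
  m$decoupled_weight[m$vulnerable_weight > 0] <- 0   # keep caps disjoint
  patches$decoupled <- which(m$decoupled_weight > 0)

  # 34 parcels per hemisphere: 5 latitude bands x 7 longitude sectors,
  # with the two sparsest cells merged into their neighbours
  parcel <- rep(NA_character_, 2 * nv)
  for (h in c("L", "R")) {
    idx <- which(hemi == h & cortex)
    z <- unit[idx, 3]
    lat <- cut(z, breaks = quantile(z, probs = seq(0, 1, length.out = 6)),
               labels = FALSE, include.lowest = TRUE)
    phi <- atan2(unit[idx, 2], ifelse(h == "L", -unit[idx, 1], unit[idx, 1]))
    lon <- cut(phi, breaks = seq(-pi, pi, length.out = 8),
               labels = FALSE, include.lowest = TRUE)
    cell <- (lat - 1) * 7 + lon            # 1..35
    cell[cell == 35] <- 34                 # merge -> 34 parcels
    parcel[idx] <- sprintf("%s_p%02d", tolower(h), cell)
  }
  m$parcel <- parcel
  m$cortex <- cortex
  # neocortical mask: cortex minus sensorimotor-like (top) and
  # occipital-like (bottom) latitude bands
  band <- rep(NA_integer_, 2 * nv)
  band[!is.na(parcel)] <- (as.integer(sub(".*_p", "", parcel[!is.na(parcel)])) - 1) %/% 7 + 1
  m$neocortex <- cortex & !is.na(band) & band >= 2 & band <= 4
  m$patches <- patches
  m
}

#' Build a flat regular triangulated grid mesh
#'
#' A planar equilateral-ish triangular lattice used to calibrate and test
#' the surface smoothing kernel (impulse response, conservation).
#'
#' @param nx,ny number of vertices along each axis
#' @param spacing lattice spacing in mm
#' @return a `pet_mesh`; all vertices belong to `cortex`
#' @export
flat_mesh <- function(nx = 41, ny = 41, spacing = 1) {
  ij <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  x <- (ij$i - 1) * spacing + (ij$j %% 2) * spacing / 2
  y <- (ij$j - 1) * spacing * sqrt(3) / 2
  verts <- cbind(x, y, 0)
  idx <- function(i, j) (j - 1) * nx + i
  tris <- NULL
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      a <- idx(i, j); b <- idx(i + 1, j); c3 <- idx(i, j + 1); d <- idx(i + 1, j + 1)
      # pick the short diagonal so every edge has length ~= spacing
      if (j %% 2 == 1) tris <- rbind(tris, c(a, b, d), c(a, d, c3))
      else             tris <- rbind(tris, c(a, b, c3), c(b, d, c3))
    }
  }
  m <- new_pet_mesh(verts, tris, rep(2.5, nrow(verts)), rep("L", nrow(verts)))
  m$cortex <- rep(TRUE, nrow(verts))
  m$parcel <- rep("p01", nrow(verts))
  m$patches <- list()
  m
}

# ---- geodesic utilities -------------------------------------------------

mesh_graph <- function(mesh) {
  igraph::graph_from_edgelist(mesh$edges, directed = FALSE)
}

#' Geodesic (edge-path) distances from a set of source vertices
#'
#' @param mesh a `pet_mesh`
#' @param from integer vertex indices
#' @return numeric vector: for each vertex, shortest weighted path length to
#'   the nearest source vertex (0 for sources)
#' @export
geodesic_distance <- function(mesh, from) {
  g <- mesh_graph(mesh)
  d <- igraph::distances(g, v = from, weights = mesh$edge_length)
  apply(d, 2, min)
}

#' Erode a mesh patch by a geodesic margin
#'
#' Removes patch vertices whose geodesic distance to the patch complement is
#' at most `radius_mm`.  Used to keep reference-region means away from patch
#' boundaries, mirroring the 4-mm spherical erosion applied to volumetric
#' reference masks.
#'
#' @param mesh a `pet_mesh`
#' @param patch integer vertex indices
#' @param radius_mm erosion radius (mm, >= 0)
#' @return integer vertex indices of the eroded patch (possibly empty)
#' @export
erode_patch <- function(mesh, patch, radius_mm = 4) {
  stopifnot(radius_mm >= 0)
  if (radius_mm == 0 || length(patch) == 0) return(patch)
  outside <- setdiff(seq_len(n_vertices(mesh)), patch)
  if (length(outside) == 0) return(patch)
  # distance to the complement is attained at complement vertices adjacent
  # to the patch, so those suffice as sources
  inpatch <- logical(n_vertices(mesh))
  inpatch[patch] <- TRUE
  e <- mesh$edges
  touch <- c(e[inpatch[e[, 1]] & !inpatch[e[, 2]], 2],
             e[!inpatch[e[, 1]] & inpatch[e[, 2]], 1])
  touch <- unique(touch)
  if (length(touch) == 0) return(patch)   # patch is a whole component
  g <- mesh_graph(mesh)
  d <- igraph::distances(g, v = touch, to = patch, weights = mesh$edge_length)
  patch[apply(d, 2, min) > radius_mm]
}
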