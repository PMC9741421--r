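#' Structured triangulation of a disk
#'
#' Builds the concentric-ring ("hexagonal") triangulation of a disk: ring
#' \eqn{k} (of \code{n_rings}) carries \eqn{6k} equally spaced vertices at
#' radius \eqn{k \cdot R / n}, plus one center vertex. The construction has
#' exactly \eqn{3n^2 + 3n + 1} nodes and \eqn{6n^2} triangles; at
#' \code{n_rings = 32} this reproduces the 3169-node / 6144-element mesh used
#' for the ring-scanning breast-phantom geometry.
#'
#' @param n_rings positive integer refinement level \eqn{n}.
#' @param diameter_mm disk diameter in mm.
#' @return an object of class \code{dot_mesh}: a list with
#'   \code{node_coords} (N x 2, mm), \code{elements} (M x 3 node indices,
#'   positively oriented), \code{boundary_nodes} (outer-ring indices in
#'   increasing angle), \code{n_rings}, \code{diameter_mm}, and
#'   \code{node_ring} (ring index per node, 0 = center).
#' @export
build_disk_mesh <- function(n_rings, diameter_mm) {
  if (length(n_rings) != 1L || !is.finite(n_rings) || n_rings < 1 ||
      n_rings != round(n_rings)) {
    stop("`n_rings` must be a positive integer")
  }
  if (length(diameter_mm) != 1L || !is.finite(diameter_mm) || diameter_mm <= 0) {
    stop("`diameter_mm` must be a positive length")
  }
  n <- as.integer(n_rings)
  R <- diameter_mm / 2
  h <- R / n

  n_nodes <- 3L * n * n + 3L * n + 1L
  coords <- matrix(0, n_nodes, 2)
  node_ring <- integer(n_nodes)
  # center node is index 1; ring k starts at offset 2 + 3k(k-1)
  ring_offset <- function(k) 2L + 3L * k * (k - 1L)
  for (k in seq_len(n)) {
    j <- 0:(6L * k - 1L)
    ang <- 2 * pi * j / (6 * k)
    idx <- ring_offset(k) + j
    coords[idx, 1] <- k * h * cos(ang)
    coords[idx, 2] <- k * h * sin(ang)
    node_ring[idx] <- k
  }

  elems <- matrix(0L, 6L * n * n, 3L)
  m <- 0L
  for (k in seq_len(n)) {
    ok <- ring_offset(k)
    ik <- if (k > 1L) ring_offset(k - 1L) else 1L
    nk <- 6L * k
    nkm <- if (k > 1L) 6L * (k - 1L) else 1L
    for (s in 0:5) {
      O <- ok + ((s * k + 0:k) %% nk)              # k+1 outer nodes
      I <- if (k > 1L) ik + ((s * (k - 1L) + 0:(k - 1L)) %% nkm) else rep(1L, 1L)
      for (i in seq_len(k)) {                      # upward triangles
        m <- m + 1L
        elems[m, ] <- c(O[i], O[i + 1L], I[min(i, length(I))])
      }
      if (k > 1L) {                                # downward triangles
        for (i in seq_len(k - 1L)) {
          m <- m + 1L
          elems[m, ] <- c(O[i + 1L], I[i + 1L], I[i])
        }
      }
    }
  }

  # enforce positive (counter-clockwise) orientation
  a <- signed_areas(coords, elems)
  flip <- which(a < 0)
  if (length(flip)) {
    tmp <- elems[flip, 2L]
    elems[flip, 2L] <- elems[flip, 3L]
    elems[flip, 3L] <- tmp
  }

  boundary <- ring_offset(n) + 0:(6L * n - 1L)
  structure(list(
    node_coords = coords,
    elements = elems,
    boundary_nodes = boundary,
    n_rings = n,
    diameter_mm = diameter_mm,
    node_ring = node_ring
  ), class = "dot_mesh")
}

#' @export
print.dot_mesh <- function(x, ...) {
  cat(sprintf("<dot_mesh> %d rings, %d nodes, %d elements, diameter %.6g mm\n",
              x$n_rings, nrow(x$node_coords), nrow(x$elements), x$diameter_mm))
  invisible(x)
}

# signed area of each triangle (positive = CCW)
signed_areas <- function(coords, elems) {
  x1 <- coords[elems[, 1], 1]; y1 <- coords[elems[, 1], 2]
  x2 <- coords[elems[, 2], 1]; y2 <- coords[elems[, 2], 2]
  x3 <- coords[elems[, 3], 1]; y3 <- coords[elems[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

# barycentric coordinates of points (P x 2) w.r.t. one triangle
barycentric_coords <- function(p, v1, v2, v3) {
  det <- (v2[1] - v1[1]) * (v3[2] - v1[2]) - (v3[1] - v1[1]) * (v2[2] - v1[2])
  l1 <- ((v2[1] - p[, 1]) * (v3[2] - p[, 2]) - (v3[1] - p[, 1]) * (v2[2] - p[, 2])) / det
  l2 <- ((v3[1] - p[, 1]) * (v1[2] - p[, 2]) - (v1[1] - p[, 1]) * (v3[2] - p[, 2])) / det
  cbind(l1, l2, 1 - l1 - l2)
}

# Locate points in the mesh: returns element index and barycentric weights.
# Uses the ring structure for candidate bands, brute force as fallback.
# points outside the disk (radius > R) get element NA.
locate_points <- function(mesh, points, tol = 1e-9) {
  n <- mesh$n_rings
  R <- mesh$diameter_mm / 2
  h <- R / n
  np <- nrow(points)
  elem_id <- rep(NA_integer_, np)
  bary <- matrix(NA_real_, np, 3)

  r <- sqrt(rowSums(points^2))
  inside <- r <= R * (1 + 1e-12)
  if (!any(inside)) return(list(element = elem_id, bary = bary))

  # band of each element = ring index of its outermost node
  elem_band <- apply(matrix(mesh$node_ring[mesh$elements], ncol = 3), 1, max)
  pt_band <- pmin(pmax(ceiling(r / h - 1e-12), 1L), n)

  co <- mesh$node_coords
  for (k in sort(unique(pt_band[inside]))) {
    pk <- which(inside & pt_band == k)
    cand <- which(elem_band >= k - 1L & elem_band <= k + 1L)
    todo <- pk
    for (e in cand) {
      if (!length(todo)) break
      v <- mesh$elements[e, ]
      b <- barycentric_coords(points[todo, , drop = FALSE],
                              co[v[1], ], co[v[2], ], co[v[3], ])
      hit <- which(b[, 1] >= -tol & b[, 2] >= -tol & b[, 3] >= -tol)
      if (length(hit)) {
        elem_id[todo[hit]] <- e
        bary[todo[hit], ] <- b[hit, , drop = FALSE]
        todo <- todo[-hit]
      }
    }
    if (length(todo)) {
      # nearest-element fallback for points on the rim of the band search
      cent <- (co[mesh$elements[, 1], ] + co[mesh$elements[, 2], ] +
                 co[mesh$elements[, 3], ]) / 3
      for (p in todo) {
        d2 <- (cent[, 1] - points[p, 1])^2 + (cent[, 2] - points[p, 2])^2
        e <- which.min(d2)
        v <- mesh$elements[e, ]
        b <- barycentric_coords(points[p, , drop = FALSE],
                                co[v[1], ], co[v[2], ], co[v[3], ])
        b <- pmax(b, 0); b <- b / sum(b)
        elem_id[p] <- e
        bary[p, ] <- b
      }
    }
  }
  list(element = elem_id, bary = bary)
}

#' Export a mesh as plain-text node/element tables
#'
#' Writes `<prefix>_nodes.csv` (node, x, y, ring, boundary flag) and
#' `<prefix>_elements.csv` (element, n1, n2, n3), a portable exchange form
#' readable by any mesh tool.
#'
#' @param mesh a \code{dot_mesh}.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
export_mesh <- function(mesh, prefix) {
  nodes <- data.frame(
    node = seq_len(nrow(mesh$node_coords)),
    x_mm = mesh$node_coords[, 1], y_mm = mesh$node_coords[, 2],
    ring = mesh$node_ring,
    boundary = seq_len(nrow(mesh$node_coords)) %in% mesh$boundary_nodes
  )
  elems <- data.frame(element = seq_len(nrow(mesh$elements)),
                      n1 = mesh$elements[, 1], n2 = mesh$elements[, 2],
                      n3 = mesh$elements[, 3])
  f1 <- paste0(prefix, "_nodes.csv"); f2 <- paste0(prefix, "_elements.csv")
  utils::write.csv(nodes, f1, row.names = FALSE)
  utils::write.csv(elems, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
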