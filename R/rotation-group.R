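#' Icosahedral reference geometry
#'
#' Vertices of the standard icosahedron (cyclic permutations of
#' `(0, +/-1, +/-phi)`), together with the symmetry-axis directions derived
#' from it: 12 vertex directions (five-fold axes), 20 face-centroid
#' directions (three-fold axes) and 30 edge-midpoint directions (two-fold
#' axes). All directions are unit vectors.
#'
#' @return A list with matrices `vertices` (12 x 3), `face_centroids`
#'   (20 x 3) and `edge_midpoints` (30 x 3), each row a unit vector.
#' @keywords internal
icosahedron_geometry <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0,  1,  phi), c(0, -1,  phi), c(0,  1, -phi), c(0, -1, -phi),
    c( 1,  phi, 0), c(-1,  phi, 0), c( 1, -phi, 0), c(-1, -phi, 0),
    c( phi, 0,  1), c( phi, 0, -1), c(-phi, 0,  1), c(-phi, 0, -1)
  )
  # edges connect vertices at squared distance 4 (edge length 2)
  d2 <- as.matrix(stats::dist(v))^2
  edges <- which(abs(d2 - 4) < 1e-9 & upper.tri(d2), arr.ind = TRUE)
  stopifnot(nrow(edges) == 30L)
  # faces are triangles of mutually adjacent vertices
  adj <- abs(d2 - 4) < 1e-9
  faces <- list()
  for (i in 1:10) for (j in which(adj[i, ] & seq_len(12) > i))
    for (k in which(adj[i, ] & adj[j, ] & seq_len(12) > j))
      faces[[length(faces) + 1L]] <- c(i, j, k)
  stopifnot(length(faces) == 20L)

  unit_rows <- function(m) m / sqrt(rowSums(m^2))
  # one representative direction per axis line (antipodal pairs collapse)
  dedupe_lines <- function(m) {
    key <- apply(round(m, 8) + 0, 1, paste, collapse = ",")
    nkey <- apply(round(-m, 8) + 0, 1, paste, collapse = ",")
    m[key < nkey, , drop = FALSE]
  }
  vertices <- unit_rows(v)
  face_centroids <- unit_rows(t(vapply(faces, function(f) colMeans(v[f, ]),
                                       numeric(3))))
  edge_midpoints <- unit_rows(t(apply(edges, 1, function(e) colMeans(v[e, ]))))
  list(
    vertices = vertices,
    face_centroids = face_centroids,
    edge_midpoints = edge_midpoints,
    axes_fivefold = dedupe_lines(vertices),      #  6 axis lines
    axes_threefold = dedupe_lines(face_centroids), # 10 axis lines
    axes_twofold = dedupe_lines(edge_midpoints),   # 15 axis lines
    raw_vertices = v,
    faces = faces,
    edges = edges
  )
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation by `theta` radians about the unit vector `axis`
#' (right-hand rule).
#'
#' @param axis numeric length-3 unit vector.
#' @param theta rotation angle in radians.
#' @return 3 x 3 orthogonal matrix.
#' @keywords internal
rotation_about <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

mat_key <- function(m) paste(sprintf("%.6f", round(m, 6) + 0), collapse = ",")

#' Build the icosahedral rotation group
#'
#' Generates the 60 proper rotations of the icosahedral group I by closing
#' the set generated by one five-fold rotation (72 degrees about a vertex
#' direction) and one three-fold rotation (120 degrees about the centroid
#' of an adjacent face) of the standard icosahedron.
#'
#' @return An object of class `rotation_set`: a list of 60 orthogonal
#'   3 x 3 matrices, with attributes `identity_index` and `orders`
#'   (element orders, which are 1, 2, 3 or 5).
#' @examples
#' g <- build_rotation_group()
#' length(g)            # 60
#' table(attr(g, "orders"))
#' @export
build_rotation_group <- function() {
  geo <- icosahedron_geometry()
  g5 <- rotation_about(geo$vertices[1, ], 2 * pi / 5)
  # a face containing vertex 1
  f1 <- which(vapply(geo$faces, function(f) 1L %in% f, logical(1)))[1]
  g3 <- rotation_about(geo$face_centroids[f1, ], 2 * pi / 3)

  elems <- list(diag(3))
  keys <- new.env(parent = emptyenv())
  assign(mat_key(diag(3)), TRUE, envir = keys)
  frontier <- list(diag(3))
  gens <- list(g5, g3)
  iter <- 0L
  while (length(frontier) > 0L) {
    iter <- iter + 1L
    if (iter > 100L) stop("group closure not reached; bad generators")
    nxt <- list()
    for (e in frontier) for (g in gens) {
      p <- g %*% e
      k <- mat_key(p)
      if (!exists(k, envir = keys, inherits = FALSE)) {
        assign(k, TRUE, envir = keys)
        elems[[length(elems) + 1L]] <- p
        nxt[[length(nxt) + 1L]] <- p
      }
    }
    frontier <- nxt
  }
  if (length(elems) != 60L)
    stop("group closure produced ", length(elems), " elements, expected 60")

  orders <- vapply(elems, function(m) {
    p <- diag(3)
    for (k in 1:5) {
      p <- p %*% m
      if (max(abs(p - diag(3))) < 1e-8) return(k)
    }
    stop("element order exceeds 5; not an icosahedral rotation")
  }, integer(1))
  idx_id <- which(orders == 1L)
  structure(elems, class = "rotation_set",
            identity_index = idx_id, orders = orders)
}

#' @export
print.rotation_set <- function(x, ...) {
  cat("<rotation_set>: ", length(x), " proper rotations of the icosahedral group\n",
      "element orders: ", paste(names(table(attr(x, "orders"))),
                                table(attr(x, "orders")),
                                sep = "x", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a rotation set
#'
#' @param x a `rotation_set`.
#' @param ... unused.
#' @return A tibble with one row per group element: its order, rotation
#'   angle (degrees) and trace.
#' @export
tidy.rotation_set <- function(x, ...) {
  tibble::tibble(
    element = seq_along(x),
    order = attr(x, "orders"),
    trace = vapply(x, function(m) sum(diag(m)), numeric(1)),
    angle_deg = round(acos(pmin(1, pmax(-1, (vapply(x, function(m) sum(diag(m)), numeric(1)) - 1) / 2))) * 180 / pi, 6)
  )
}
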