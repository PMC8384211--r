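#' Frame configuration for lattice construction
#'
#' Fixes the free conventions in the lattice build: the representative
#' coat-protein point inside one fundamental domain and the chirality /
#' axis-ordering conventions that decide which rotation gets which move
#' label.
#'
#' The representative point is a strictly off-axis convex combination of
#' one icosahedron vertex, the centroid of an adjacent face and the
#' midpoint of an adjacent edge, projected to the unit sphere; any generic
#' choice of weights yields the same lattice up to relabelling.
#'
#' The sign conventions (`sense_fivefold`, `sense_threefold`) and the
#' choice of which flanking three-fold axis counts as "closest"
#' (`threefold_order`) are not derivable from the move definitions alone:
#' they are fixed so that the enumerated pseudo-Hamiltonian path counts
#' match the published reference counts for move sets \{2,3,4,5\} (64
#' paths) and \{3,4,6,7\} (826 paths), and so that the mutual-exclusion
#' composite move2 o move4 is a fixed-point-free involution. The defaults
#' below are the validated assignment.
#'
#' @param weights numeric length 3, convex weights on (vertex, face
#'   centroid, edge midpoint) for the representative point.
#' @param sense_fivefold +1 or -1: handedness of move 3 (+72 degrees about
#'   the outward closest five-fold axis when +1; move 4 is its inverse,
#'   moves 8/9 are the squares of 3/4).
#' @param sense_threefold +1 or -1: handedness of move 2 about the closest
#'   three-fold axis (move 5 is its inverse); moves 6/7 use the same
#'   convention about the second-closest three-fold.
#' @param threefold_order `"nearest"` or `"swapped"`: whether moves 2/5
#'   act about the angularly nearest three-fold axis and 6/7 about the
#'   second nearest, or the other way round.
#' @return A list of class `frame_config`.
#' @export
lattice_frame <- function(weights = c(0.50, 0.32, 0.18),
                          sense_fivefold = -1,
                          sense_threefold = 1,
                          threefold_order = c("nearest", "swapped")) {
  stopifnot(length(weights) == 3, all(weights > 0),
            sense_fivefold %in% c(-1, 1), sense_threefold %in% c(-1, 1))
  threefold_order <- match.arg(threefold_order)
  structure(list(weights = weights / sum(weights),
                 sense_fivefold = sense_fivefold,
                 sense_threefold = sense_threefold,
                 threefold_order = threefold_order),
            class = "frame_config")
}

# nearest axis index among rows of `axes` to point x, by angular distance
# to the axis line; the returned direction is the axis end on x's side.
closest_axes <- function(x, axes, n = 1L) {
  d <- abs(axes %*% x)           # |cos angle| to each axis line
  ord <- order(d, decreasing = TRUE)
  if (any(abs(d[ord[seq_len(n)]] - d[ord[seq_len(n) + 1L]]) < 1e-9))
    stop("representative point equidistant to two symmetry axes; ",
         "perturb the frame weights")
  ord[seq_len(n)]
}

signed_axis <- function(axes, i, x) {
  a <- axes[i, ]
  if (sum(a * x) < 0) -a else a
}

#' Build the 60-position T=1 capsid lattice
#'
#' Constructs the lattice on which RNA paths and assembly are defined: the
#' orbit of a representative coat-protein point under the 60 icosahedral
#' rotations, the per-position assignment of the four flanking symmetry
#' axes, the nine move permutations, the mutual-exclusion pairing and the
#' coat-protein contact graph.
#'
#' Moves are rotations about a position's own flanking axes: move 1 is 180
#' degrees about its closest two-fold axis; moves 2/5 are +/-120 degrees
#' about one flanking three-fold and 6/7 about the other; moves 3/4 are
#' +/-72 degrees and moves 8/9 +/-144 degrees about its five-fold axis.
#' The mutual-exclusion partner of a position is the combinatorial
#' composite move2(move4(p)) (equivalently move3(move5(p))), a
#' fixed-point-free involution splitting the 60 positions into 30 pairs of
#' sterically clashing binding-site orientations. Contact edges are the
#' edges generated by moves 1, 3 and 4; the contact graph is the 3-regular
#' 90-edge truncated-icosahedron graph.
#'
#' @param frame a [lattice_frame()] configuration.
#' @return An object of class `capsid_lattice`: list with `points` (60 x 3
#'   unit vectors, rows ordered lexicographically), `move_maps` (60 x 9
#'   integer matrix, column k the permutation of move k), `exclusion`
#'   (integer length 60), `contact_edges` (two-column integer matrix, 90
#'   rows), `axes` (tibble of per-position axis assignments), `frame`.
#' @examples
#' lat <- build_lattice()
#' length(unique(pmin(seq_len(60), lat$exclusion)))  # 30 exclusion pairs
#' @export
build_lattice <- function(frame = lattice_frame()) {
  geo <- icosahedron_geometry()
  grp <- build_rotation_group()

  v1 <- geo$raw_vertices[1, ]
  f1 <- which(vapply(geo$faces, function(f) 1L %in% f, logical(1)))[1]
  face_c <- colMeans(geo$raw_vertices[geo$faces[[f1]], ])
  e_in_f <- geo$edges[apply(geo$edges, 1, function(e) all(e %in% geo$faces[[f1]])) &
                        apply(geo$edges, 1, function(e) 1L %in% e), , drop = FALSE]
  edge_m <- colMeans(geo$raw_vertices[e_in_f[1, ], ])
  w <- frame$weights
  ref <- w[1] * v1 / sqrt(sum(v1^2)) + w[2] * face_c / sqrt(sum(face_c^2)) +
    w[3] * edge_m / sqrt(sum(edge_m^2))
  ref <- ref / sqrt(sum(ref^2))

  pts <- t(vapply(grp, function(g) as.numeric(g %*% ref), numeric(3)))
  key <- apply(round(pts, 8) + 0, 1, paste, collapse = ",")
  if (anyDuplicated(key))
    stop("orbit has fewer than 60 distinct points; representative point ",
         "lies on a symmetry axis - perturb the frame weights")
  pts <- pts[order(key), , drop = FALSE]

  n <- 60L
  find_pos <- function(y) {
    d <- pts %*% y
    i <- which.max(d)
    if (d[i] < 1 - 1e-8) stop("rotated point does not land on the orbit")
    i
  }

  ax5 <- integer(n); ax3a <- integer(n); ax3b <- integer(n); ax2 <- integer(n)
  move_maps <- matrix(0L, n, 9L)
  for (p in seq_len(n)) {
    x <- pts[p, ]
    ax5[p] <- closest_axes(x, geo$axes_fivefold, 1L)
    i3 <- closest_axes(x, geo$axes_threefold, 2L)
    if (frame$threefold_order == "swapped") i3 <- rev(i3)
    ax3a[p] <- i3[1]; ax3b[p] <- i3[2]
    ax2[p] <- closest_axes(x, geo$axes_twofold, 1L)

    a5 <- signed_axis(geo$axes_fivefold, ax5[p], x)
    a3a <- signed_axis(geo$axes_threefold, ax3a[p], x)
    a3b <- signed_axis(geo$axes_threefold, ax3b[p], x)
    a2 <- signed_axis(geo$axes_twofold, ax2[p], x)
    s5 <- frame$sense_fivefold; s3 <- frame$sense_threefold

    ang <- list(
      `1` = list(a2, pi),
      `2` = list(a3a,  s3 * 2 * pi / 3), `5` = list(a3a, -s3 * 2 * pi / 3),
      `6` = list(a3b,  s3 * 2 * pi / 3), `7` = list(a3b, -s3 * 2 * pi / 3),
      `3` = list(a5,  s5 * 2 * pi / 5), `4` = list(a5, -s5 * 2 * pi / 5),
      `8` = list(a5,  s5 * 4 * pi / 5), `9` = list(a5, -s5 * 4 * pi / 5)
    )
    for (k in 1:9) {
      r <- ang[[as.character(k)]]
      move_maps[p, k] <- find_pos(as.numeric(rotation_about(r[[1]], r[[2]]) %*% x))
    }
  }

  exclusion <- move_maps[move_maps[, 4L], 2L]  # move 4 then move 2

  ce <- rbind(cbind(seq_len(n), move_maps[, 1L]),
              cbind(seq_len(n), move_maps[, 3L]))
  ce <- unique(t(apply(ce, 1, sort)))
  ce <- ce[order(ce[, 1], ce[, 2]), , drop = FALSE]

  structure(list(
    points = pts,
    move_maps = move_maps,
    exclusion = as.integer(exclusion),
    contact_edges = ce,
    axes = tibble::tibble(position = seq_len(n), fivefold = ax5,
                          threefold_1 = ax3a, threefold_2 = ax3b,
                          twofold = ax2),
    frame = frame
  ), class = "capsid_lattice")
}

#' @export
print.capsid_lattice <- function(x, ...) {
  cat("<capsid_lattice>: 60 coat-protein positions (T=1)\n",
      "moves: 9 permutations; exclusion pairs: ",
      length(unique(pmin(seq_len(60), x$exclusion))),
      "; contact edges: ", nrow(x$contact_edges), "\n", sep = "")
  invisible(x)
}

is_permutation <- function(p) length(p) == 60L && setequal(p, seq_len(60L))

perm_compose <- function(p, q) p[q]  # apply q first, then p

#' Validate a capsid lattice
#'
#' Checks every structural invariant of the lattice: that each move map is
#' a permutation, the inverse pairs (1 self-inverse, 5 = inv 2, 4 = inv 3,
#' 7 = inv 6, 9 = inv 8), the rotation orders (moves 2/6 cube to the
#' identity, move 3 has order five), the composite identities move 8 =
#' move 3 squared and move 9 = move 4 squared, the cycle structure (move 3
#' decomposes into 12 five-cycles, move 2 into 20 three-cycles), the
#' mutual-exclusion pairing (fixed-point-free involution, equal to both
#' move2 o move4 and move3 o move5), and the contact graph (3-regular, 90
#' edges, connected; move-1 edges a perfect matching whose removal leaves
#' 12 disjoint pentagons).
#'
#' @param lattice a `capsid_lattice`.
#' @return A tibble with columns `check` and `pass`; a correct lattice
#'   passes every row.
#' @export
validate_lattice <- function(lattice) {
  m <- lattice$move_maps
  n <- 60L
  id <- seq_len(n)
  ex <- lattice$exclusion

  cyc_lens <- function(p) {
    if (!is_permutation(p)) return(integer(0))  # cycle walk needs a bijection
    seen <- logical(n); out <- integer(0)
    for (i in id) if (!seen[i]) {
      l <- 0L; j <- i
      repeat { seen[j] <- TRUE; l <- l + 1L; j <- p[j]; if (j == i) break }
      out <- c(out, l)
    }
    out
  }

  g <- igraph::graph_from_edgelist(lattice$contact_edges, directed = FALSE)
  no1 <- lattice$contact_edges[m[lattice$contact_edges[, 1], 1L] !=
                                 lattice$contact_edges[, 2], , drop = FALSE]
  g_no1 <- igraph::graph_from_edgelist(no1, directed = FALSE)
  comp <- igraph::components(g_no1)

  checks <- list(
    "each move map is a permutation" =
      all(apply(m, 2, is_permutation)),
    "move 1 is self-inverse" = all(m[m[, 1], 1] == id),
    "move 5 inverts move 2" = all(m[m[, 2], 5] == id),
    "move 4 inverts move 3" = all(m[m[, 3], 4] == id),
    "move 7 inverts move 6" = all(m[m[, 6], 7] == id),
    "move 9 inverts move 8" = all(m[m[, 8], 9] == id),
    "move 2 has order 3" = all(m[m[m[, 2], 2], 2] == id),
    "move 6 has order 3" = all(m[m[m[, 6], 6], 6] == id),
    "move 3 has order 5" = {
      p <- id; for (i in 1:5) p <- m[p, 3]; all(p == id)
    },
    "move 8 = move 3 squared" = all(m[m[, 3], 3] == m[, 8]),
    "move 9 = move 4 squared" = all(m[m[, 4], 4] == m[, 9]),
    "move 3 decomposes into 12 five-cycles" =
      all(cyc_lens(m[, 3]) == 5L) && length(cyc_lens(m[, 3])) == 12L,
    "move 2 decomposes into 20 three-cycles" =
      all(cyc_lens(m[, 2]) == 3L) && length(cyc_lens(m[, 2])) == 20L,
    "exclusion is a fixed-point-free involution" =
      all(ex != id) && all(ex[ex] == id),
    "exclusion equals move2 o move4" = all(m[m[, 4], 2] == ex),
    "exclusion equals move3 o move5" = all(m[m[, 5], 3] == ex),
    "contact graph has 90 edges" = nrow(lattice$contact_edges) == 90L,
    "contact graph is 3-regular" = all(igraph::degree(g) == 3L),
    "contact graph is connected" = igraph::is_connected(g),
    "move-1 edges form a perfect matching" =
      all(m[, 1] != id) && all(m[m[, 1], 1] == id),
    "removing move-1 edges leaves 12 pentagons" =
      comp$no == 12L && all(comp$csize == 5L) &&
        all(igraph::degree(g_no1) == 2L)
  )
  tibble::tibble(check = names(checks),
                 pass = vapply(checks, isTRUE, logical(1)))
}

#' Convert a lattice to an igraph object
#'
#' Vertices are the 60 positions with their axis assignments as
#' attributes; there is one edge per unordered position pair related by
#' any move, with attributes `move` (smallest move label relating the
#' pair), `contact` (generated by moves 1/3/4) and `exclusion`.
#'
#' @param lattice a `capsid_lattice`.
#' @return An igraph graph.
#' @export
as_lattice_graph <- function(lattice) {
  m <- lattice$move_maps
  el <- do.call(rbind, lapply(1:9, function(k)
    cbind(a = pmin(seq_len(60L), m[, k]), b = pmax(seq_len(60L), m[, k]),
          move = k)))
  el <- el[!duplicated(el[, c("a", "b")]), , drop = FALSE]  # min move label
  ex <- unique(cbind(a = pmin(seq_len(60L), lattice$exclusion),
                     b = pmax(seq_len(60L), lattice$exclusion), move = 0L))
  all_e <- rbind(el, ex)
  g <- igraph::graph_from_edgelist(all_e[, 1:2, drop = FALSE],
                                   directed = FALSE)
  ck <- paste(lattice$contact_edges[, 1], lattice$contact_edges[, 2])
  igraph::E(g)$move <- all_e[, "move"]
  igraph::E(g)$contact <- paste(all_e[, 1], all_e[, 2]) %in% ck &
    all_e[, "move"] > 0L
  igraph::E(g)$exclusion <- all_e[, "move"] == 0L
  igraph::V(g)$fivefold <- lattice$axes$fivefold
  igraph::V(g)$threefold_1 <- lattice$axes$threefold_1
  igraph::V(g)$threefold_2 <- lattice$axes$threefold_2
  igraph::V(g)$twofold <- lattice$axes$twofold
  g
}

#' Export a lattice
#'
#' Writes the lattice either as GraphML (via igraph) or as a plain JSON
#' document containing points, move maps, exclusion pairing and contact
#' edges.
#'
#' @param lattice a `capsid_lattice`.
#' @param path output file path.
#' @param format `"graphml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_lattice <- function(lattice, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_lattice_graph(lattice), path, format = "graphml")
  } else {
    jsonlite::write_json(list(
      points = round(lattice$points, 10),
      move_maps = lattice$move_maps,
      exclusion = lattice$exclusion,
      contact_edges = lattice$contact_edges,
      frame = unclass(lattice$frame)
    ), path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}
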