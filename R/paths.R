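#' Count (and optionally enumerate) pseudo-Hamiltonian RNA paths
#'
#' Exhaustive depth-first search for all RNA paths compatible with a move
#' set: ordered sequences of 30 lattice positions, consecutive positions
#' related by a move in the set, visiting exactly one member of each of
#' the 30 mutual-exclusion pairs. The search starts from a fixed position
#' (all positions are symmetry-equivalent) and prunes any extension onto
#' an occupied position or onto the exclusion partner of an occupied
#' position.
#'
#' Counting convention (frozen, recorded in the result): paths are counted
#' as directed 5'-to-3' move sequences from the fixed start, one
#' representative per symmetry class; a path and its reversal are counted
#' separately. Under this convention move set \{2,3,4,5\} has exactly 64
#' paths.
#'
#' @param lattice a [build_lattice()] lattice.
#' @param moves a [move_set()] (or vector coercible to one).
#' @param enumerate if `TRUE`, store the enumerated move sequences (up to
#'   `max_paths`) in the result.
#' @param node_limit abort after this many node expansions; the census is
#'   then flagged incomplete. Move sets with 8 or 9 moves are
#'   computationally prohibitive and need an explicit generous limit.
#' @param max_paths maximum number of paths stored when `enumerate = TRUE`.
#' @param start start position (1..60); counts are start-independent.
#' @return An object of class `path_census`: list with `move_set`,
#'   `n_path`, `complete`, `nodes`, `runtime_s`, `counting_convention`,
#'   and (if enumerated) `paths`, an integer matrix with 29 move-label
#'   columns, one row per path.
#' @examples
#' lat <- build_lattice()
#' count_paths(lat, move_set(c(2, 3, 4, 5)))$n_path  # 64
#' @export
count_paths <- function(lattice, moves, enumerate = FALSE,
                        node_limit = 1e13, max_paths = 1e6, start = 1L) {
  moves <- move_set(moves)
  t0 <- Sys.time()
  res <- cpp_count_paths(lattice$move_maps, lattice$exclusion,
                         as.integer(moves), as.integer(start),
                         enumerate, node_limit, max_paths)
  out <- list(
    move_set = moves,
    n_path = res$count,
    complete = res$complete,
    nodes = res$nodes,
    runtime_s = as.numeric(Sys.time() - t0, units = "secs"),
    counting_convention = "directed-fixed-start",
    start = as.integer(start)
  )
  if (enumerate) out$paths <- res$paths
  structure(out, class = "path_census")
}

#' @export
print.path_census <- function(x, ...) {
  cat("<path_census> move set {", paste(unclass(x$move_set), collapse = ","),
      "}: ", format(x$n_path, big.mark = ","), " pseudo-Hamiltonian paths",
      if (!x$complete) " (INCOMPLETE: node limit hit)", "\n", sep = "")
  invisible(x)
}

#' @rdname count_paths
#' @param x a `path_census`.
#' @param ... unused.
#' @return `glance()`: a one-row tibble summarising the census.
#' @export
glance.path_census <- function(x, ...) {
  tibble::tibble(
    n_moves = length(x$move_set),
    move_set = paste(unclass(x$move_set), collapse = ","),
    n_path = x$n_path,
    complete = x$complete,
    nodes = x$nodes,
    convention = x$counting_convention,
    runtime_s = x$runtime_s
  )
}

#' @rdname count_paths
#' @return `tidy()`: a tibble of enumerated paths (requires
#'   `enumerate = TRUE`), with the canonical label of each.
#' @export
tidy.path_census <- function(x, ...) {
  if (is.null(x$paths)) stop("census was not enumerated; rerun count_paths(enumerate = TRUE)")
  tibble::tibble(path = seq_len(nrow(x$paths)),
                 label = apply(x$paths, 1, paste, collapse = "-"))
}

#' Reconstruct lattice positions from a move sequence
#'
#' @param lattice a lattice.
#' @param moves integer vector of 29 move labels.
#' @param start start position.
#' @return integer vector of 30 positions.
#' @export
path_positions <- function(lattice, moves, start = 1L) {
  pos <- integer(length(moves) + 1L)
  pos[1] <- start
  for (i in seq_along(moves)) pos[i + 1L] <- lattice$move_maps[pos[i], moves[i]]
  pos
}

#' Infer move labels along a position path
#'
#' For consecutive positions, the move label relating them (the smallest
#' label if several relate the same pair, preferring labels in
#' `restrict`).
#'
#' @param lattice a lattice.
#' @param positions integer vector of lattice positions.
#' @param restrict optional move set to prefer/require.
#' @return integer vector of move labels (`NA` where no move relates a
#'   consecutive pair).
#' @export
path_moves <- function(lattice, positions, restrict = NULL) {
  n <- length(positions)
  if (n < 2L) return(integer(0))
  vapply(seq_len(n - 1L), function(i) {
    k <- which(lattice$move_maps[positions[i], ] == positions[i + 1L])
    if (!is.null(restrict)) {
      kr <- intersect(k, restrict)
      if (length(kr)) k <- kr
    }
    if (length(k)) as.integer(k[1]) else NA_integer_
  }, integer(1))
}

#' Is a walk a pseudo-Hamiltonian path?
#'
#' Independent validity oracle for enumerator and simulator output,
#' implemented directly from the definition: 30 distinct positions,
#' consecutive positions related by a move of the set, and exactly one
#' member of each mutual-exclusion pair visited.
#'
#' @param lattice a lattice.
#' @param positions integer vector of lattice positions (the candidate
#'   walk, 5' to 3').
#' @param moves the active [move_set()].
#' @return `TRUE` or `FALSE`.
#' @export
is_pseudo_hamiltonian <- function(lattice, positions, moves) {
  moves <- move_set(moves)
  if (length(positions) != 30L) return(FALSE)
  if (anyDuplicated(positions)) return(FALSE)
  if (!all(positions %in% seq_len(60L))) return(FALSE)
  lab <- path_moves(lattice, positions, restrict = moves)
  if (anyNA(lab) || !all(lab %in% moves)) return(FALSE)
  pair_id <- pmin(seq_len(60L), lattice$exclusion)
  visited <- pair_id[positions]
  length(unique(visited)) == 30L
}

#' Canonical label of an RNA path
#'
#' The group of 60 lattice rotations acts simply transitively on
#' positions and commutes with the moves, so two directed paths are
#' symmetry-equivalent exactly when their move sequences coincide: the
#' canonical label is the move sequence itself, hyphen-separated.
#' With `identify_reversal = TRUE` a path and its reversal (reversed
#' sequence of inverse moves) receive the lexicographically smaller of the
#' two labels.
#'
#' @param moves integer vector of 29 move labels, or a matrix with one
#'   path per row.
#' @param identify_reversal collapse a path with its reversal? The
#'   package's frozen counting convention does not.
#' @return character vector of labels.
#' @export
canonical_label <- function(moves, identify_reversal = FALSE) {
  if (is.matrix(moves)) return(apply(moves, 1, canonical_label,
                                     identify_reversal = identify_reversal))
  if (anyNA(moves) || !all(moves %in% 1:9))
    stop("invalid path: move labels must be in 1..9")
  lab <- paste(moves, collapse = "-")
  if (identify_reversal) {
    rev_lab <- paste(rev(move_inverse(moves)), collapse = "-")
    lab <- min(lab, rev_lab)
  }
  lab
}

#' Classify assembled RNA paths by type
#'
#' Tallies canonical path labels from simulated capsids, the analysis
#' behind the observation that optimised RNAs under move set \{2,3,4,5\}
#' funnel into two dominant path types that differ only in the final
#' moves around the nucleating five-fold axis.
#'
#' @param paths paths to classify: a character vector of labels, an
#'   integer matrix of move labels (29 columns), or a list of integer
#'   move-label vectors.
#' @param census optional enumerated [count_paths()] census; when given,
#'   each classified path is checked for membership and a `in_census`
#'   column added.
#' @param prefix_top number of top path types over which the longest
#'   common move-prefix is reported.
#' @return A tibble with columns `label`, `count`, `freq` (descending),
#'   with attributes `common_prefix` (the longest shared leading move
#'   subsequence among the `prefix_top` most frequent types) and
#'   `n_paths`.
#' @export
classify_paths <- function(paths, census = NULL, prefix_top = 2L) {
  labels <-
    if (is.character(paths)) paths
    else if (is.matrix(paths)) canonical_label(paths)
    else if (is.list(paths)) vapply(paths, canonical_label, character(1))
    else stop("unsupported path representation")
  tab <- sort(table(labels), decreasing = TRUE)
  out <- tibble::tibble(label = names(tab),
                        count = as.integer(tab),
                        freq = as.integer(tab) / length(labels))
  if (!is.null(census)) {
    if (is.null(census$paths))
      stop("census must be enumerated for membership checks")
    cl <- canonical_label(census$paths)
    out$in_census <- out$label %in% cl
  }
  top <- utils::head(out$label, prefix_top)
  cp <- if (length(top) >= 1L) {
    seqs <- lapply(strsplit(top, "-"), as.integer)
    n <- min(lengths(seqs))
    k <- 0L
    while (k < n && length(unique(vapply(seqs, `[`, integer(1), k + 1L))) == 1L)
      k <- k + 1L
    if (k > 0L) seqs[[1]][seq_len(k)] else integer(0)
  } else integer(0)
  attr(out, "common_prefix") <- cp
  attr(out, "n_paths") <- length(labels)
  out
}
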