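#' Move sets
#'
#' A move set is the subset of the nine RNA moves active during assembly.
#' Because the capsid is icosahedrally symmetric, a physically meaningful
#' move set is closed under inverses: it contains move 2 iff 5, 3 iff 4,
#' 6 iff 7 and 8 iff 9 (move 1 is self-inverse).
#'
#' @param moves integer vector, subset of 1..9.
#' @param complete if `TRUE`, missing inverse partners are added rather
#'   than raising an error.
#' @return A sorted integer vector of class `move_set`.
#' @examples
#' move_set(c(2, 3, 4, 5))
#' move_set(c(2, 3), complete = TRUE)  # adds 4 and 5
#' @export
move_set <- function(moves, complete = FALSE) {
  moves <- sort(unique(as.integer(moves)))
  if (length(moves) == 0 || !all(moves %in% 1:9))
    stop("moves must be a non-empty subset of 1..9")
  partner <- c(1L, 5L, 4L, 3L, 2L, 7L, 6L, 9L, 8L)
  missing <- setdiff(partner[moves], moves)
  if (length(missing)) {
    if (!complete)
      stop("move set not closed under inverses; missing: ",
           paste(missing, collapse = ", "))
    moves <- sort(c(moves, missing))
  }
  structure(moves, class = "move_set")
}

#' @export
print.move_set <- function(x, ...) {
  cat("<move_set> {", paste(unclass(x), collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Inverse of each move label
#' @param moves integer move labels.
#' @return integer vector of the inverse labels.
#' @keywords internal
move_inverse <- function(moves) c(1L, 5L, 4L, 3L, 2L, 7L, 6L, 9L, 8L)[moves]

# moves that create a coat-protein contact edge
CONTACT_MOVES <- c(1L, 3L, 4L)

#' Parse a move-set string like "2,3,4,5" or "2345"
#' @param x character scalar.
#' @return a `move_set`.
#' @export
parse_move_set <- function(x) {
  if (grepl(",", x)) move_set(as.integer(strsplit(x, ",")[[1]]))
  else move_set(as.integer(strsplit(x, "")[[1]]))
}
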