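# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

test_lattice <- function() {
  if (is.null(.fixtures$lat)) .fixtures$lat <- build_lattice()
  .fixtures$lat
}

# enumerated census for the flagship move set
census_2345 <- function() {
  if (is.null(.fixtures$cen2345))
    .fixtures$cen2345 <- count_paths(test_lattice(), move_set(c(2, 3, 4, 5)),
                                     enumerate = TRUE)
  .fixtures$cen2345
}

# small, fast kinetic setting for unit tests (not the study conditions)
quick_params <- function(...) {
  kinetic_params(t_max = 1e6, q_window = 2e5, ...)
}

# a small optimised-style variant: strong 3'-terminal pair, medium
# shoulder, weak elsewhere — used where tests need an efficiently
# assembling RNA without paying for a GA run
end_site_variant <- function() {
  c(rep(-4, 26), -6, -6, -12, -12)
}

# one reduced-scale GA run shared by the acceptance tests
shared_ga <- function() {
  if (is.null(.fixtures$ga)) {
    cfg <- ga_config(pop_size = 48L, survivors = 12L, offspring = 36L,
                     copies = 150L, generations = 14L, top_n = 10L,
                     spread_tol = 0.5)
    .fixtures$ga <- evolve(test_lattice(), move_set(c(2, 3, 4, 5)),
                           seed = 20260715,
                           ga = cfg,
                           params = kinetic_params(t_max = 3e6,
                                                   q_window = 4e5))
  }
  .fixtures$ga
}

# independent pure-R depth-first enumeration of pseudo-Hamiltonian paths,
# written directly from the definition; oracle for the compiled search
r_reference_paths <- function(lattice, moves, start = 1L) {
  moves <- sort(unique(as.integer(moves)))
  mm <- lattice$move_maps
  ex <- lattice$exclusion
  out <- list()
  rec <- function(p, visited, labels) {
    if (length(visited) == 30L) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (m in moves) {
      q <- mm[p, m]
      if (q %in% visited) next
      if (ex[q] %in% visited) next
      rec(q, c(visited, q), c(labels, m))
    }
  }
  rec(start, start, integer(0))
  out
}

# permutation each rotation induces on the lattice positions
group_permutations <- function(lattice) {
  if (!is.null(.fixtures$gperm)) return(.fixtures$gperm)
  grp <- build_rotation_group()
  pts <- lattice$points
  .fixtures$gperm <- lapply(grp, function(g) {
    img <- pts %*% t(g)
    apply(img %*% t(pts), 1, which.max)
  })
  .fixtures$gperm
}
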