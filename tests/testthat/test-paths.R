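test_that("compiled search agrees with an independent R enumeration", {
  lat <- test_lattice()
  ref <- r_reference_paths(lat, c(2, 3, 4, 5))
  cen <- census_2345()
  expect_equal(length(ref), cen$n_path)
  ref_labels <- sort(vapply(ref, paste, character(1), collapse = "-"))
  cpp_labels <- sort(apply(cen$paths, 1, paste, collapse = "-"))
  expect_identical(ref_labels, cpp_labels)
})

test_that("move sets that cannot leave their local orbit have no paths", {
  lat <- test_lattice()
  expect_equal(count_paths(lat, move_set(c(2, 5)))$n_path, 0)
  expect_equal(count_paths(lat, move_set(c(3, 4, 8, 9)))$n_path, 0)
})

test_that("counts are independent of the start vertex", {
  lat <- test_lattice()
  for (mv in list(c(2, 3, 4, 5), c(2, 5, 6, 7))) {
    n1 <- count_paths(lat, move_set(mv), start = 1L)$n_path
    n2 <- count_paths(lat, move_set(mv), start = 23L)$n_path
    expect_equal(n1, n2)
  }
})

test_that("the node limit flags an incomplete census", {
  lat <- test_lattice()
  cen <- count_paths(lat, move_set(c(2, 3, 4, 5)), node_limit = 100)
  expect_false(cen$complete)
})

test_that("every enumerated path is pseudo-Hamiltonian and reversible", {
  lat <- test_lattice()
  cen <- census_2345()
  ms <- move_set(c(2, 3, 4, 5))
  for (i in c(1, 17, 40, 64)) {
    pos <- path_positions(lat, cen$paths[i, ])
    expect_true(is_pseudo_hamiltonian(lat, pos, ms))
    # reversal with inverted moves is also valid
    expect_true(is_pseudo_hamiltonian(lat, rev(pos), ms))
    expect_equal(path_moves(lat, rev(pos), restrict = ms),
                 rev(move_inverse(cen$paths[i, ])))
  }
  # corrupt paths are rejected: teleporting a distant position breaks the
  # move relation
  pos <- path_positions(lat, cen$paths[1, ])
  expect_false(is_pseudo_hamiltonian(lat, pos[c(15, 2:14, 1, 16:30)], ms))
  both_members <- replace(pos, 30, lat$exclusion[pos[1]])
  expect_false(is_pseudo_hamiltonian(lat, both_members, ms))
  expect_false(is_pseudo_hamiltonian(lat, pos[1:29], ms))
})

test_that("canonical labels are symmetry-invariant and separate the census", {
  lat <- test_lattice()
  cen <- census_2345()
  labels <- canonical_label(cen$paths)
  expect_equal(length(unique(labels)), 64L)
  # a rotated copy of a path has the same label
  gp <- group_permutations(lat)
  pos <- path_positions(lat, cen$paths[7, ])
  for (gi in c(3, 25, 58)) {
    rotated <- gp[[gi]][pos]
    expect_equal(canonical_label(path_moves(lat, rotated)),
                 labels[7])
  }
  # reversal identification collapses a path and its reverse
  rev_moves <- rev(move_inverse(cen$paths[7, ]))
  expect_false(canonical_label(rev_moves) == labels[7])
  expect_equal(canonical_label(rev_moves, identify_reversal = TRUE),
               canonical_label(cen$paths[7, ], identify_reversal = TRUE))
})

test_that("subset move sets contribute all their paths to supersets", {
  lat <- test_lattice()
  cen_small <- census_2345()
  cen_big <- count_paths(lat, move_set(c(1, 2, 3, 4, 5)), enumerate = TRUE,
                         max_paths = 2e5)
  expect_gte(cen_big$n_path, cen_small$n_path)
  expect_true(all(canonical_label(cen_small$paths) %in%
                    canonical_label(cen_big$paths)))
})

test_that("classification tallies labels, membership and common prefixes", {
  lat <- test_lattice()
  cen <- census_2345()
  one <- classify_paths(rep(canonical_label(cen$paths[1, ]), 5))
  expect_equal(nrow(one), 1L)
  expect_equal(one$freq, 1)
  # two census paths sharing a long prefix
  labs <- canonical_label(cen$paths)
  pref25 <- substr(labs, 1, 49)  # 25 moves, hyphen-separated
  grp <- split(seq_along(labs), pref25)
  pair <- grp[[which(lengths(grp) >= 2)[1]]][1:2]
  cls <- classify_paths(c(labs[pair[1]], labs[pair[1]], labs[pair[2]]),
                        census = cen)
  expect_true(all(cls$in_census))
  expect_gte(length(attr(cls, "common_prefix")), 25L)
  expect_equal(attr(cls, "n_paths"), 3L)
})
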