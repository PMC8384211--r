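test_that("the default lattice satisfies every structural invariant", {
  lat <- test_lattice()
  rep <- validate_lattice(lat)
  expect_true(all(rep$pass), info = paste(rep$check[!rep$pass], collapse = "; "))
  expect_equal(nrow(lat$points), 60L)
  expect_equal(length(unique(pmin(seq_len(60), lat$exclusion))), 30L)
})

test_that("moves commute with the icosahedral symmetry action", {
  lat <- test_lattice()
  gp <- group_permutations(lat)
  m <- lat$move_maps
  set.seed(5)
  for (gi in sample(60, 12)) {
    sig <- gp[[gi]]
    for (k in 1:9) expect_equal(sig[m[, k]], m[sig, k])
  }
})

test_that("exclusion composite identities hold and square to the identity", {
  lat <- test_lattice()
  m <- lat$move_maps
  ex24 <- m[m[, 4], 2]
  ex35 <- m[m[, 5], 3]
  expect_identical(ex24, ex35)
  expect_identical(ex24[ex24], seq_len(60L))
  expect_true(all(ex24 != seq_len(60L)))
  expect_identical(as.integer(ex24), lat$exclusion)
})

test_that("two generic frames give the same lattice up to relabelling", {
  lat1 <- test_lattice()
  lat2 <- build_lattice(lattice_frame(weights = c(0.42, 0.25, 0.33)))
  # match positions by their (unique) flanking-axis signature
  sig <- function(l) paste(l$axes$fivefold, l$axes$threefold_1,
                           l$axes$threefold_2, l$axes$twofold)
  s1 <- sig(lat1); s2 <- sig(lat2)
  expect_false(anyDuplicated(s1) > 0)
  phi <- match(s1, s2)
  expect_false(anyNA(phi))
  for (k in 1:9)
    expect_equal(phi[lat1$move_maps[, k]], lat2$move_maps[phi, k])
  expect_equal(phi[lat1$exclusion], lat2$exclusion[phi])
})

test_that("a corrupted lattice fails validation", {
  lat <- test_lattice()
  bad <- lat
  tmp <- bad$move_maps[1, 3]
  bad$move_maps[1, 3] <- bad$move_maps[1, 4]
  bad$move_maps[1, 4] <- tmp
  rep <- validate_lattice(bad)
  expect_false(all(rep$pass))
  expect_false(rep$pass[rep$check == "move 4 inverts move 3"])
})

test_that("degenerate frames are rejected", {
  # representative point collapses onto a vertex: orbit smaller than 60
  expect_error(build_lattice(lattice_frame(weights = c(1, 1e-9, 1e-9))))
})

test_that("graph export carries moves, contacts and exclusion pairs", {
  lat <- test_lattice()
  g <- as_lattice_graph(lat)
  expect_equal(igraph::vcount(g), 60)
  expect_equal(sum(igraph::E(g)$contact), 90)
  expect_equal(sum(igraph::E(g)$exclusion), 30)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_lattice(lat, f, format = "graphml")
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g2), 60)
  expect_equal(sum(igraph::E(g2)$contact), 90)
  fj <- withr::local_tempfile(fileext = ".json")
  write_lattice(lat, fj, format = "json")
  j <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(dim(j$move_maps), c(60L, 9L))
  expect_equal(as.integer(j$exclusion), lat$exclusion)
})

test_that("contact graph is the truncated-icosahedron graph", {
  lat <- test_lattice()
  g <- igraph::graph_from_edgelist(lat$contact_edges, directed = FALSE)
  expect_true(igraph::is_connected(g))
  expect_true(all(igraph::degree(g) == 3))
  # girth 5 and exactly 12 pentagonal faces after removing the matching
  m1 <- lat$move_maps[, 1]
  keep <- lat$contact_edges[m1[lat$contact_edges[, 1]] !=
                              lat$contact_edges[, 2], , drop = FALSE]
  comp <- igraph::components(igraph::graph_from_edgelist(keep,
                                                         directed = FALSE))
  expect_equal(comp$no, 12)
  expect_true(all(comp$csize == 5))
})
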