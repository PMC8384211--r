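test_that("identical seeds give bit-identical simulations", {
  lat <- test_lattice()
  ms <- move_set(c(2, 3, 4, 5))
  r1 <- run_assembly(lat, end_site_variant(), ms, seed = 42, n_rna = 40,
                     params = quick_params())
  r2 <- run_assembly(lat, end_site_variant(), ms, seed = 42, n_rna = 40,
                     params = quick_params())
  expect_identical(r1$n_cap, r2$n_cap)
  expect_identical(r1$paths, r2$paths)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$t_end, r2$t_end)
  r3 <- run_assembly(lat, end_site_variant(), ms, seed = 43, n_rna = 40,
                     params = quick_params())
  expect_false(identical(r1$t_end, r3$t_end))
})

test_that("state invariants hold at every shell event (debug mode)", {
  lat <- test_lattice()
  expect_no_error(
    run_assembly(lat, end_site_variant(), move_set(c(2, 3, 4, 5)),
                 seed = 7, n_rna = 15, params = quick_params(),
                 debug = TRUE))
  expect_no_error(
    run_assembly(lat, uniform_variant(-9), move_set(c(1, 2, 3, 4, 5)),
                 seed = 8, n_rna = 10, params = quick_params(),
                 debug = TRUE))
})

test_that("no coat protein means no binding and no capsids", {
  lat <- test_lattice()
  r <- run_assembly(lat, uniform_variant(-9), move_set(c(2, 3, 4, 5)),
                    seed = 5, n_rna = 20,
                    params = quick_params(cp_per_rna = 0))
  expect_equal(r$n_cap, 0)
  expect_equal(unname(r$events[["bind"]]), 0)
})

test_that("move sets without move 1 or moves 3/4 never assemble", {
  lat <- test_lattice()
  set.seed(99)
  for (mv in list(c(2, 5, 6, 7), c(2, 5, 8, 9), c(6, 7, 8, 9))) {
    for (sd in c(1, 77)) {
      v <- random_variant()
      r <- run_assembly(lat, v, move_set(mv), seed = sd, n_rna = 25,
                        params = quick_params())
      expect_equal(r$n_cap, 0)
      expect_equal(unname(r$events[["nucleate"]]), 0)
    }
  }
})

test_that("free coat protein at rest matches the binding equilibrium", {
  lat <- test_lattice()
  p <- kinetic_params(t_max = 3e6, q_window = 2.9e6)  # binding only, long
  n <- 200
  r <- run_assembly(lat, uniform_variant(-9), move_set(c(2, 5, 6, 7)),
                    seed = 13, n_rna = n, params = p)
  bound <- r$cp_total - r$free_cp
  b <- p$k_bind / p$cp_ref_factor   # per-PS binding rate over free fraction
  u <- p$k_bind * exp(-9 / p$rt)
  occ <- b / (b + u)                # equilibrium occupancy (free CP ~ total)
  expect_lt(abs(bound / (30 * n) - occ), 0.02)
})

test_that("completed capsids carry valid pseudo-Hamiltonian paths", {
  lat <- test_lattice()
  ms <- move_set(c(2, 3, 4, 5))
  r <- run_assembly(lat, end_site_variant(), ms, seed = 31, n_rna = 60,
                    params = kinetic_params())
  expect_gt(r$n_cap, 0)
  cen <- census_2345()
  census_labels <- canonical_label(cen$paths)
  for (k in seq_len(r$n_cap)) {
    path <- extract_path(r, k, lat)
    expect_length(path$positions, 30L)
    expect_true(all(path$moves %in% ms))
    expect_true(is_pseudo_hamiltonian(lat, path$positions, ms))
    expect_true(path$label %in% census_labels)
  }
  expect_error(extract_path(r, r$n_cap + 1L, lat), "out of range")
})

test_that("result accessors summarise the run", {
  lat <- test_lattice()
  r <- run_assembly(lat, end_site_variant(), move_set(c(2, 3, 4, 5)),
                    seed = 3, n_rna = 30, params = quick_params())
  g <- glance(r)
  expect_equal(g$n_rna, 30)
  expect_equal(g$n_cap, r$n_cap)
  td <- tidy(r)
  expect_equal(nrow(td), 30)
  expect_equal(sum(td$status == "complete"), r$n_cap)
  labs <- capsid_path_labels(r, lat)
  expect_length(labs, r$n_cap)
})

test_that("variant input is validated", {
  lat <- test_lattice()
  expect_error(run_assembly(lat, rep(-9, 29), move_set(c(2, 3, 4, 5)),
                            seed = 1, n_rna = 5))
  expect_error(run_assembly(lat, rep(9, 30), move_set(c(2, 3, 4, 5)),
                            seed = 1, n_rna = 5), "negative")
  expect_error(run_assembly(lat, rep(-9, 30), move_set(c(2, 3, 4, 5)),
                            n_rna = 5), "seed")
})
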