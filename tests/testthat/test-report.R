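test_that("the move-set summary table reports counts and rounded yields", {
  lat <- test_lattice()
  tab <- make_table1(lat, list(c(2, 3, 4, 5), c(2, 5, 6, 7)), seed = 3,
                     n_rna = 60, params = quick_params())
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$n_path, c(64, 1342))
  expect_equal(tab$n_cap[tab$move_set == "2,5,6,7"], 0)
  expect_equal(tab$n_cap_rounded, round(tab$n_cap / 10) * 10)
  small <- tab$n_cap > 0 & tab$n_cap < 10
  expect_true(all(tab$n_cap_label[small] == "<10"))
  expect_false(is.null(attr(tab, "config_hash")))
  # empty input gives an empty table
  expect_equal(nrow(make_table1(lat, list(), seed = 1, n_rna = 10,
                                params = quick_params())), 0L)
})

test_that("the profile-comparison table has the six canonical profiles", {
  lat <- test_lattice()
  cfg <- ga_config(pop_size = 6L, survivors = 2L, offspring = 4L,
                   copies = 20L, generations = 1L, top_n = 2L,
                   spread_tol = 1e-9)
  ga <- evolve(lat, move_set(c(2, 3, 4, 5)), seed = 4, ga = cfg,
               params = quick_params())
  tab <- make_table2(lat, ga, seed = 11, n_seeds = 2, copies = 30,
                     params = quick_params())
  expect_equal(tab$profile,
               c("uniform_-4", "uniform_-8", "uniform_-10", "optimal",
                 "knockout", "nucleation_only"))
  expect_equal(tab$n_seeds, rep(2L, 6))
  expect_true(all(tab$mean_yield_pct >= 0 & tab$mean_yield_pct <= 100))
  expect_false(anyNA(tab$sd_yield_pct))
})

test_that("path reports pool results and survive a CSV round trip", {
  lat <- test_lattice()
  r <- run_assembly(lat, end_site_variant(), move_set(c(2, 3, 4, 5)),
                    seed = 31, n_rna = 50, params = kinetic_params())
  expect_gt(r$n_cap, 1)
  tab <- report_paths(list(r, r), lat)
  expect_equal(sum(tab$count), 2L * r$n_cap)
  expect_equal(sum(tab$freq), 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_report(make_table1(lat, list(c(2, 5, 6, 7)), seed = 1, n_rna = 20,
                           params = quick_params()), f)
  lines <- readLines(f)
  expect_true(any(grepl("^# config_hash:", lines)))
  back <- utils::read.csv(f, comment.char = "#")
  expect_equal(back$n_path, 1342)
})

test_that("plots build without evaluation errors", {
  lat <- test_lattice()
  cfg <- ga_config(pop_size = 6L, survivors = 2L, offspring = 4L,
                   copies = 15L, generations = 2L, top_n = 2L,
                   spread_tol = 1e-9)
  ga <- evolve(lat, move_set(c(2, 3, 4, 5)), seed = 2, ga = cfg,
               params = quick_params())
  p1 <- ggplot2::ggplot_build(autoplot(ga))
  expect_s3_class(p1$plot, "ggplot")
  h <- landscape_histogram(lat, move_set(c(2, 3, 4, 5)), seed = 6,
                           n_variants = 4, copies = 10,
                           params = quick_params())
  p2 <- ggplot2::ggplot_build(autoplot(h))
  expect_s3_class(p2$plot, "ggplot")
  p3 <- ggplot2::ggplot_build(plot_variant(end_site_variant()))
  expect_s3_class(p3$plot, "ggplot")
})
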