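#' Combinatorial and assembly summary across move sets
#'
#' For each move set: the number of moves, the exact pseudo-Hamiltonian
#' path count (skipped above `count_limit` expansions, as for the
#' computationally prohibitive 8- and 9-move sets), and the number of
#' capsids assembled from a uniform-affinity ensemble
#' (dG_ps = -9 kcal/mol by default), with the count also rounded to the
#' nearest 10 and rendered `"<10"` for small non-zero values (the
#' reporting convention used for this table).
#'
#' @param lattice a lattice.
#' @param move_sets list of move sets (vectors).
#' @param seed integer seed for the simulations.
#' @param n_rna RNA copies per simulation.
#' @param dg_ps uniform PS affinity (kcal/mol).
#' @param params [kinetic_params()].
#' @param count_limit DFS node budget per move set; counts above it are
#'   reported `NA` (skipped).
#' @return A tibble with columns `n_moves`, `move_set`, `n_path`,
#'   `n_path_complete`, `n_cap`, `n_cap_rounded`, `n_cap_label`,
#'   `yield_pct`, `runtime_s`, `seed`; attribute `config_hash`.
#' @export
make_table1 <- function(lattice, move_sets, seed, n_rna = 2000,
                        dg_ps = -9, params = kinetic_params(),
                        count_limit = 5e10) {
  rows <- lapply(move_sets, function(mv) {
    mv <- move_set(mv)
    t0 <- Sys.time()
    cen <- count_paths(lattice, mv, node_limit = count_limit)
    res <- run_assembly(lattice, uniform_variant(dg_ps), mv,
                        seed = seed, n_rna = n_rna, params = params)
    rounded <- round(res$n_cap / 10) * 10
    tibble::tibble(
      n_moves = length(mv),
      move_set = paste(unclass(mv), collapse = ","),
      n_path = if (cen$complete) cen$n_path else NA_real_,
      n_path_complete = cen$complete,
      n_cap = res$n_cap,
      n_cap_rounded = rounded,
      n_cap_label = if (res$n_cap > 0 && res$n_cap < 10) "<10"
                    else format(rounded, scientific = FALSE),
      yield_pct = res$yield_pct,
      runtime_s = as.numeric(Sys.time() - t0, units = "secs"),
      seed = seed)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "config_hash") <- rlang::hash(list(move_sets, seed, n_rna,
                                               dg_ps, unclass(params)))
  out
}

#' Assembly efficiency of optimised vs uniform PS distributions
#'
#' For one move set and a completed GA run: mean yield over `n_seeds`
#' independent simulations for the uniform -4, -8 and -10 kcal/mol
#' profiles, the GA-optimal variant, its nucleation-site knockout, and
#' the nucleation-site-only variant.
#'
#' @param lattice a lattice.
#' @param ga_result an [evolve()] result for the move set.
#' @param seed base seed; the `n_seeds` replicate seeds derive from it.
#' @param n_seeds replicate simulations per profile.
#' @param copies RNA copies per simulation.
#' @param params [kinetic_params()].
#' @return A tibble with one row per profile: `profile`, `mean_yield_pct`,
#'   `sd_yield_pct`, `n_seeds`; attribute `config_hash`.
#' @export
make_table2 <- function(lattice, ga_result, seed, n_seeds = 5,
                        copies = 2000, params = kinetic_params()) {
  moves <- ga_result$move_set
  best <- ga_result$best_variant
  site <- nucleation_site(best)
  profiles <- list(
    `uniform_-4` = uniform_variant(-4),
    `uniform_-8` = uniform_variant(-8),
    `uniform_-10` = uniform_variant(-10),
    optimal = best,
    knockout = knockout(best, site),
    nucleation_only = nucleation_only(best, site))
  rows <- lapply(names(profiles), function(nm) {
    ys <- vapply(seq_len(n_seeds), function(k)
      run_assembly(lattice, profiles[[nm]], moves,
                   seed = derive_seed(seed, k + 1000L * match(nm, names(profiles))),
                   n_rna = copies, params = params)$yield_pct,
      numeric(1))
    tibble::tibble(profile = nm, mean_yield_pct = mean(ys),
                   sd_yield_pct = stats::sd(ys), n_seeds = n_seeds)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "config_hash") <- rlang::hash(list(unclass(moves), best, seed,
                                               n_seeds, copies,
                                               unclass(params)))
  attr(out, "nucleation_site") <- site
  out
}

#' Path-type frequency report for assembled capsids
#'
#' Pools the completed-capsid paths of one or more assembly results and
#' tallies canonical path types with their relative frequencies, plus the
#' longest common move prefix of the dominant types.
#'
#' @param results an `assembly_result` or list of them (same move set).
#' @param lattice the lattice.
#' @param ... passed to [classify_paths()].
#' @return The [classify_paths()] tibble.
#' @export
report_paths <- function(results, lattice, ...) {
  if (inherits(results, "assembly_result")) results <- list(results)
  labels <- unlist(lapply(results, capsid_path_labels, lattice = lattice))
  classify_paths(labels, ...)
}

#' Write a report table as CSV with a reproducibility header
#'
#' Prepends `#`-prefixed comment lines carrying the configuration hash
#' (when present) so that any table can be traced to the run that made it.
#'
#' @param x a tibble from [make_table1()], [make_table2()] or
#'   [report_paths()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  h <- attr(x, "config_hash")
  if (!is.null(h)) writeLines(paste0("# config_hash: ", h), con)
  writeLines(paste0("# written: capsidpath ",
                    as.character(utils::packageVersion("capsidpath"))), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}
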