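#' Affinity bands for reporting packaging-signal strength
#'
#' The conventional colour bands for PS-CP binding free energies: weak
#' (-4.0 to -5.9), medium (-6.0 to -8.9) and strong (-9.0 to -12.0)
#' kcal/mol. The strong-band threshold also defines nucleation-site
#' detection.
#'
#' @param weak,medium,strong numeric length-2 band edges (kcal/mol).
#' @return A list of class `affinity_bands`.
#' @export
affinity_bands <- function(weak = c(-5.9, -4.0),
                           medium = c(-8.9, -6.0),
                           strong = c(-12.0, -9.0)) {
  structure(list(weak = weak, medium = medium, strong = strong),
            class = "affinity_bands")
}

#' Classify PS affinities into bands
#'
#' @param dg numeric vector of binding free energies (kcal/mol).
#' @param bands an [affinity_bands()] object.
#' @return factor with levels weak/medium/strong.
#' @export
band_of <- function(dg, bands = affinity_bands()) {
  cut(dg, breaks = c(-Inf, bands$strong[2], bands$medium[2], Inf),
      labels = c("strong", "medium", "weak"))
}

#' Random and uniform RNA variants
#'
#' An RNA variant is its vector of 30 packaging-signal binding free
#' energies (kcal/mol), index 1 the 5'-most PS. `random_variant()` draws
#' the 30 values i.i.d. uniform within `bounds` (uses the R RNG; seed
#' with [set.seed()]); `uniform_variant()` repeats one value.
#'
#' @param bounds numeric length-2 lower/upper bounds (kcal/mol).
#' @param n_ps number of packaging signals.
#' @return numeric vector of length `n_ps`.
#' @export
random_variant <- function(bounds = c(-12, -4), n_ps = 30L) {
  stats::runif(n_ps, min(bounds), max(bounds))
}

#' @rdname random_variant
#' @param dg single binding free energy repeated for every PS.
#' @export
uniform_variant <- function(dg, n_ps = 30L) rep(as.numeric(dg), n_ps)

#' Assembly fitness of an RNA variant
#'
#' Runs a homogeneous-ensemble assembly simulation and returns the yield:
#' the percentage of the `copies` RNAs packaged into complete capsids.
#'
#' @param lattice a lattice.
#' @param variant length-30 vector of PS binding free energies.
#' @param moves the active move set.
#' @param seed integer seed.
#' @param copies RNA copies simulated.
#' @param params [kinetic_params()].
#' @return yield percentage (scalar).
#' @export
fitness <- function(lattice, variant, moves, seed, copies = 2000,
                    params = kinetic_params()) {
  run_assembly(lattice, variant, moves, seed = seed, n_rna = copies,
               params = params)$yield_pct
}

#' Genetic-algorithm configuration
#'
#' Each generation every variant's fitness is (re-)evaluated with a fresh
#' derived seed, the top `survivors` are retained unchanged, and
#' `offspring` new variants are created by copying the survivors
#' round-robin and redrawing each PS uniformly within `bounds` with
#' probability `mutation_prob`. The run stops after `generations`
#' generations or once the spread of the top `top_n` fitnesses falls
#' below `spread_tol` percentage points.
#'
#' `ga_profile()` returns named configurations: `"full"` is the
#' published-scale setting (1024 variants, 2000 copies, 30 generations);
#' `"desk"` and `"mini"` are reduced settings for interactive work and
#' test suites.
#'
#' @param pop_size population size.
#' @param survivors variants retained each generation.
#' @param offspring new variants per generation
#'   (`survivors + offspring = pop_size`).
#' @param mutation_prob per-PS mutation probability.
#' @param bounds affinity bounds (kcal/mol).
#' @param copies RNA copies per fitness evaluation.
#' @param generations generation cap.
#' @param top_n,spread_tol convergence rule: stop when
#'   `max - min` fitness of the best `top_n` variants is below
#'   `spread_tol` (percentage points).
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 1024L, survivors = 256L,
                      offspring = 768L, mutation_prob = 0.05,
                      bounds = c(-12, -4), copies = 2000L,
                      generations = 30L, top_n = 20L, spread_tol = 1) {
  stopifnot(survivors + offspring == pop_size,
            mutation_prob > 0, mutation_prob < 1,
            survivors >= 1, top_n >= 2)
  structure(list(pop_size = as.integer(pop_size),
                 survivors = as.integer(survivors),
                 offspring = as.integer(offspring),
                 mutation_prob = mutation_prob,
                 bounds = sort(as.numeric(bounds)),
                 copies = as.integer(copies),
                 generations = as.integer(generations),
                 top_n = as.integer(top_n),
                 spread_tol = spread_tol),
            class = "ga_config")
}

#' @rdname ga_config
#' @param profile one of `"full"`, `"desk"`, `"mini"`.
#' @export
ga_profile <- function(profile = c("full", "desk", "mini")) {
  switch(match.arg(profile),
    full = ga_config(),
    desk = ga_config(pop_size = 64L, survivors = 16L, offspring = 48L,
                     copies = 200L, generations = 15L, top_n = 10L),
    mini = ga_config(pop_size = 32L, survivors = 8L, offspring = 24L,
                     copies = 100L, generations = 8L, top_n = 5L))
}

# deterministic stream of engine seeds derived from a master seed
derive_seed <- function(master, k) {
  (((master %% 2147483399) * 48271 + k) %% 2147483399) + 1
}

#' Optimise packaging-signal affinities by genetic algorithm
#'
#' Elitist GA over the 30-dimensional space of PS binding free energies,
#' maximising assembly yield for a move set. Survivor genotypes reappear
#' unchanged in the next generation; fitness is stochastic and
#' re-evaluated every generation.
#'
#' @param lattice a lattice.
#' @param moves the active move set.
#' @param seed master integer seed (drives initialisation, mutation and
#'   every per-evaluation engine seed).
#' @param ga a [ga_config()].
#' @param params [kinetic_params()] for the fitness evaluations.
#' @param init optional initial population (30 x pop_size matrix).
#' @param verbose print per-generation progress.
#' @return An object of class `ga_result`: list with `trajectory` (tibble:
#'   generation, best, mean_top, spread_top, mean), `population` (final
#'   30 x pop matrix, fitness-ordered), `fitness` (final fitnesses),
#'   `best_variant`, `best_fitness`, `converged`, `config`, `seed`.
#' @export
evolve <- function(lattice, moves, seed, ga = ga_profile("desk"),
                   params = kinetic_params(), init = NULL,
                   verbose = FALSE) {
  moves <- move_set(moves)
  if (missing(seed)) stop("an explicit integer seed is required")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  pop <- if (is.null(init)) {
    matrix(stats::runif(30L * ga$pop_size, ga$bounds[1], ga$bounds[2]),
           nrow = 30L)
  } else {
    stopifnot(nrow(init) == 30L, ncol(init) == ga$pop_size)
    init
  }

  traj <- vector("list", ga$generations)
  eval_k <- 0L
  converged <- FALSE
  fit <- numeric(ga$pop_size)
  for (g in seq_len(ga$generations)) {
    fit <- vapply(seq_len(ga$pop_size), function(j) {
      eval_k <<- eval_k + 1L
      fitness(lattice, pop[, j], moves,
              seed = derive_seed(seed, eval_k),
              copies = ga$copies, params = params)
    }, numeric(1))
    ord <- order(fit, decreasing = TRUE)
    pop <- pop[, ord, drop = FALSE]
    fit <- fit[ord]
    topn <- fit[seq_len(min(ga$top_n, ga$pop_size))]
    traj[[g]] <- tibble::tibble(
      generation = g, best = fit[1], mean_top = mean(topn),
      spread_top = max(topn) - min(topn), mean = mean(fit))
    if (verbose)
      message(sprintf("generation %d: best %.1f%% (top-%d spread %.1f)",
                      g, fit[1], ga$top_n, max(topn) - min(topn)))
    if (g > 1 && max(topn) - min(topn) < ga$spread_tol) {
      converged <- TRUE
      traj <- traj[seq_len(g)]
      break
    }
    if (g < ga$generations) {
      parents <- pop[, rep(seq_len(ga$survivors),
                           length.out = ga$offspring), drop = FALSE]
      mut <- matrix(stats::runif(length(parents)) < ga$mutation_prob,
                    nrow = 30L)
      parents[mut] <- stats::runif(sum(mut), ga$bounds[1], ga$bounds[2])
      pop <- cbind(pop[, seq_len(ga$survivors), drop = FALSE], parents)
    }
  }
  structure(list(
    trajectory = dplyr::bind_rows(traj),
    population = pop,
    fitness = fit,
    best_variant = pop[, 1],
    best_fitness = fit[1],
    converged = converged,
    config = ga,
    move_set = moves,
    seed = seed
  ), class = "ga_result")
}

# save/restore the global RNG state so evolve() is self-contained
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result> move set {", paste(unclass(x$move_set), collapse = ","),
      "}: best fitness ", sprintf("%.1f%%", x$best_fitness),
      " after ", max(x$trajectory$generation), " generations",
      if (x$converged) " (converged)", "\n", sep = "")
  invisible(x)
}

#' @rdname evolve
#' @param x a `ga_result`.
#' @param ... unused.
#' @return `tidy()`: the per-generation trajectory tibble.
#' @export
tidy.ga_result <- function(x, ...) x$trajectory

#' @rdname evolve
#' @return `glance()`: one-row summary tibble.
#' @export
glance.ga_result <- function(x, ...) {
  tibble::tibble(
    move_set = paste(unclass(x$move_set), collapse = ","),
    generations = max(x$trajectory$generation),
    best_fitness = x$best_fitness,
    converged = x$converged,
    pop_size = x$config$pop_size,
    copies = x$config$copies,
    seed = x$seed)
}

#' Locate the nucleation site of an RNA variant
#'
#' The longest contiguous run of strong-band PSs (binding free energy at
#' or below the strong-band threshold, -9.0 kcal/mol by default);
#' efficiently assembling variants typically carry a run of 2-4.
#'
#' @param variant length-30 affinity vector.
#' @param bands an [affinity_bands()].
#' @return Integer vector of the PS indices in the site (empty if the
#'   variant has no strong PS).
#' @export
nucleation_site <- function(variant, bands = affinity_bands()) {
  strong <- variant <= bands$strong[2]
  if (!any(strong)) return(integer(0))
  r <- rle(strong)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)[which.max(r$lengths[r$values])]
  seq.int(starts[i], ends[i])
}

#' Nucleation-site knockout and nucleation-only variants
#'
#' `knockout()` replaces the nucleation site with weak PSs (-4 kcal/mol);
#' `nucleation_only()` replaces everything except the site. Applying both
#' yields the all-weak variant.
#'
#' @param variant length-30 affinity vector.
#' @param site PS indices of the nucleation site; detected with
#'   [nucleation_site()] when omitted.
#' @param weak_dg replacement affinity (kcal/mol).
#' @return modified variant.
#' @export
knockout <- function(variant, site = nucleation_site(variant),
                     weak_dg = -4) {
  variant[site] <- weak_dg
  variant
}

#' @rdname knockout
#' @export
nucleation_only <- function(variant, site = nucleation_site(variant),
                            weak_dg = -4) {
  variant[setdiff(seq_along(variant), site)] <- weak_dg
  variant
}

#' Assembly-fitness landscape histogram
#'
#' Draws `n_variants` random RNA variants, evaluates each one's assembly
#' yield in an independent simulation, and bins the yields — a
#' one-dimensional picture of the 30-dimensional fitness landscape.
#'
#' @param lattice a lattice.
#' @param moves move set.
#' @param seed master seed.
#' @param n_variants number of random variants.
#' @param copies RNA copies per evaluation.
#' @param params [kinetic_params()].
#' @param bounds affinity bounds for the random draws.
#' @param binwidth histogram bin width in yield percentage points.
#' @return A tibble of class `landscape_histogram` with columns
#'   `bin_lo`, `bin_hi`, `count`; the raw yields are in
#'   `attr(, "yields")`.
#' @export
landscape_histogram <- function(lattice, moves, seed, n_variants = 1024L,
                                copies = 2000L,
                                params = kinetic_params(),
                                bounds = c(-12, -4), binwidth = 5) {
  moves <- move_set(moves)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  yields <- vapply(seq_len(n_variants), function(j) {
    v <- stats::runif(30L, bounds[1], bounds[2])
    fitness(lattice, v, moves, seed = derive_seed(seed, j),
            copies = copies, params = params)
  }, numeric(1))
  edges <- seq(0, 100, by = binwidth)
  if (edges[length(edges)] < 100) edges <- c(edges, 100)
  counts <- table(cut(yields, edges, include.lowest = TRUE))
  out <- tibble::tibble(bin_lo = edges[-length(edges)],
                        bin_hi = edges[-1],
                        count = as.integer(counts))
  attr(out, "yields") <- yields
  attr(out, "move_set") <- moves
  class(out) <- c("landscape_histogram", class(out))
  out
}
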