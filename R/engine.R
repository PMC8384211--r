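#' Kinetic parameters for the assembly simulator
#'
#' Free energies are in kcal/mol; time is in arbitrary units (only rate
#' ratios matter for the equilibrium yields the model observes).
#'
#' The binding propensity per free PS is `k_bind * free_cp / cp_ref`,
#' where `cp_ref = cp_ref_factor * cp_total` is a reference copy number
#' playing the role of the standard-state concentration; unbinding is
#' `k_bind * exp(dg_ps / rt)` (detailed balance). With the defaults, the
#' equilibrium occupancy of a PS spans roughly 0.1 at -4 kcal/mol to
#' essentially 1 at -9 kcal/mol and below, the regime in which
#' packaging-signal affinity heterogeneity can steer nucleation.
#' `k_attach` sets the shell attachment rate; its default is commensurate
#' with the binding timescale so that zero-contact placements are
#' transient but not dominant event traffic.
#'
#' @param dg_cs coat-protein contact free energy, kcal/mol (default -4.0).
#' @param rt thermal energy, kcal/mol (default 0.593, 25 degrees C).
#' @param k_bind CP-PS association rate scale.
#' @param k_attach CP:PS to shell association rate scale.
#' @param cp_per_rna coat-protein copies supplied per RNA (default 60, a
#'   full capsid's worth; only the 30 path positions are modelled, so CP
#'   is never limiting).
#' @param cp_ref_factor reference copy number as a multiple of `cp_total`.
#' @param t_max simulation horizon.
#' @param q_window quiescence window: the run stops when no
#'   shell-composition change has occurred for this long.
#' @return A list of class `kinetic_params`.
#' @export
kinetic_params <- function(dg_cs = -4.0, rt = 0.593,
                           k_bind = 1, k_attach = 3e-3, k_nuc = 1e-5,
                           phi = 0.9,
                           fill_contacts = FALSE, require_contact = FALSE,
                           cp_per_rna = 60, cp_ref_factor = 7500,
                           t_max = 6e6, q_window = 4e5) {
  stopifnot(dg_cs < 0, rt > 0, k_bind > 0, k_attach > 0, k_nuc > 0,
            phi >= 0, phi <= 1,
            cp_per_rna >= 0, cp_ref_factor > 0, t_max > 0, q_window > 0)
  structure(list(dg_cs = dg_cs, rt = rt, k_bind = k_bind,
                 k_attach = k_attach, k_nuc = k_nuc, phi = phi,
                 fill_contacts = fill_contacts,
                 require_contact = require_contact,
                 cp_per_rna = cp_per_rna,
                 cp_ref_factor = cp_ref_factor, t_max = t_max,
                 q_window = q_window),
            class = "kinetic_params")
}

as_dg_matrix <- function(variants, n_rna) {
  if (is.matrix(variants)) {
    stopifnot(nrow(variants) == 30L)
    if (!is.null(n_rna) && n_rna != ncol(variants))
      stop("n_rna disagrees with ncol(variants)")
    variants
  } else {
    stopifnot(length(variants) == 30L)
    if (is.null(n_rna)) stop("n_rna required for a homogeneous ensemble")
    matrix(rep(as.numeric(variants), n_rna), nrow = 30L)
  }
}

#' Simulate co-assembly of an RNA ensemble
#'
#' Gillespie stochastic simulation of capsid assembly around RNAs carrying
#' 30 packaging signals, under a move set and the mutual-exclusion rule.
#' Coat proteins bind packaging signals reversibly; a pair of
#' sequence-adjacent CP:PS complexes nucleates a shell via a contact move
#' (1, 3 or 4); the shell grows by placing the CP:PS just 5' or 3' of the
#' in-shell interval at a move image of the interval end (the target and
#' its exclusion partner must be unoccupied); terminal units detach at a
#' rate set by the contact energy they forfeit. An RNA is packaged when
#' all 30 PSs are in-shell, which forces its path to be
#' pseudo-Hamiltonian.
#'
#' @param lattice a [build_lattice()] lattice.
#' @param variants a length-30 numeric vector of PS binding free energies
#'   (kcal/mol, index 1 = 5'-most PS) for a homogeneous ensemble, or a
#'   30 x n matrix of per-RNA profiles.
#' @param moves the active [move_set()].
#' @param seed integer RNG seed (required; same seed, same result,
#'   bit-for-bit).
#' @param n_rna ensemble size for a homogeneous ensemble.
#' @param params a [kinetic_params()] object.
#' @param debug if `TRUE`, state invariants (interval contiguity,
#'   exclusion, move validity, CP conservation) are asserted after every
#'   shell event.
#' @return An object of class `assembly_result`: list with `n_cap`,
#'   `yield_pct`, `paths` (n_cap x 30 matrix of positions, 5' to 3'),
#'   `status` (per RNA: 0 unnucleated, 1 partial, 2 complete), `events`
#'   (named counts), `t_end`, `quiescent`, `hit_tmax`, `seed`,
#'   `move_set`.
#' @examples
#' lat <- build_lattice()
#' res <- run_assembly(lat, rep(-9, 30), move_set(c(2, 3, 4, 5)),
#'                     seed = 1, n_rna = 50)
#' res$yield_pct
#' @export
run_assembly <- function(lattice, variants, moves, seed,
                         n_rna = NULL, params = kinetic_params(),
                         debug = FALSE) {
  moves <- move_set(moves)
  if (missing(seed)) stop("an explicit integer seed is required")
  dg <- as_dg_matrix(variants, n_rna)
  n <- ncol(dg)
  if (any(dg >= 0)) stop("PS binding free energies must be negative")
  cp_total <- params$cp_per_rna * n
  res <- cpp_run_assembly(
    lattice$move_maps, lattice$exclusion, lattice$contact_edges,
    as.integer(moves), dg,
    params$dg_cs, params$rt, params$k_bind, params$k_attach,
    params$k_nuc, params$phi,
    params$fill_contacts, params$require_contact,
    cp_total, params$cp_ref_factor * max(cp_total, 1),
    params$t_max, params$q_window, as.numeric(seed), debug)
  structure(list(
    n_rna = n,
    n_cap = res$n_cap,
    yield_pct = 100 * res$n_cap / n,
    paths = res$paths,
    t_complete = res$t_complete,
    status = res$status,
    shell_pos = res$shell_pos,
    lo = res$lo,
    hi = res$hi,
    events = res$events,
    t_end = res$t_end,
    quiescent = res$quiescent,
    hit_tmax = res$hit_tmax,
    free_cp = res$free_cp,
    cp_total = cp_total,
    seed = seed,
    move_set = moves,
    params = params
  ), class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("<assembly_result> move set {",
      paste(unclass(x$move_set), collapse = ","), "}: ",
      x$n_cap, "/", x$n_rna, " capsids (",
      sprintf("%.1f%%", x$yield_pct), ")",
      if (x$hit_tmax) " [t_max reached before quiescence]", "\n", sep = "")
  invisible(x)
}

#' @rdname run_assembly
#' @param x an `assembly_result`.
#' @param ... unused.
#' @return `glance()`: a one-row tibble with yield and event counts.
#' @export
glance.assembly_result <- function(x, ...) {
  tibble::tibble(
    move_set = paste(unclass(x$move_set), collapse = ","),
    n_rna = x$n_rna, n_cap = x$n_cap, yield_pct = x$yield_pct,
    quiescent = x$quiescent, hit_tmax = x$hit_tmax,
    t_end = x$t_end,
    n_bind = x$events[["bind"]], n_unbind = x$events[["unbind"]],
    n_nucleate = x$events[["nucleate"]], n_attach = x$events[["attach"]],
    n_detach = x$events[["detach"]], seed = x$seed)
}

#' @rdname run_assembly
#' @return `tidy()`: a tibble with one row per RNA (terminal status).
#' @export
tidy.assembly_result <- function(x, ...) {
  tibble::tibble(
    rna = seq_len(x$n_rna),
    status = c("unnucleated", "partial", "complete")[x$status + 1L])
}

#' Extract the RNA path of a completed capsid
#'
#' The 5'-to-3' ordered lattice positions of one completed capsid from a
#' simulation, with the inferred move labels. The order is by packaging
#' signal index, not by placement time.
#'
#' @param result an [run_assembly()] result.
#' @param capsid capsid index (1..n_cap).
#' @param lattice the lattice the simulation ran on.
#' @return A list with `positions` (length 30), `moves` (length 29) and
#'   `label` (canonical path label).
#' @export
extract_path <- function(result, capsid, lattice) {
  if (result$n_cap < 1) stop("no completed capsids in this result")
  if (capsid < 1 || capsid > result$n_cap) stop("capsid index out of range")
  positions <- result$paths[capsid, ]
  mv <- path_moves(lattice, positions, restrict = result$move_set)
  if (anyNA(mv)) stop("incomplete capsid record: positions not move-related")
  list(positions = positions, moves = mv, label = canonical_label(mv))
}

#' Canonical labels of all completed capsid paths
#'
#' @param result an [run_assembly()] result.
#' @param lattice the lattice.
#' @return character vector of one label per completed capsid.
#' @export
capsid_path_labels <- function(result, lattice) {
  if (result$n_cap == 0) return(character(0))
  apply(result$paths, 1, function(p)
    canonical_label(path_moves(lattice, p, restrict = result$move_set)))
}
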