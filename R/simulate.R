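#' Default synthetic simulation panel
#'
#' The 15-locus normalized panel with the bundled synthetic per-locus
#' mutation rates, as a named rate vector.
#'
#' @return Named numeric vector, locus -> rate/generation.
#' @export
default_sim_rates <- function() {
  synthetic_locus_rates()$rates[normalized_panel()]
}

#' Simulation configuration
#'
#' @param n Sample size (lineages drawn).
#' @param rates Named per-locus mutation rates (mutations/locus/generation);
#'   default the bundled synthetic 15-locus panel.
#' @param tmrca Genealogy depth in generations (>= 0).
#' @param genealogy \code{"star"} (independent lineages, the regime where
#'   rho dating is unbiased) or \code{"kingman"} (correlated coalescent
#'   genealogy).
#' @param founder Named integer founder repeat vector; default all loci
#'   at 20 repeats.
#' @param population_label Population name written into the table.
#' @param seed Integer seed; every simulator is bit-reproducible given it.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n, rates = default_sim_rates(), tmrca,
                       genealogy = c("star", "kingman"),
                       founder = NULL, population_label = "SimPop",
                       seed = NULL) {
  genealogy <- match.arg(genealogy)
  if (n < 1L) stop("n must be >= 1")
  if (tmrca < 0) stop("tmrca must be >= 0")
  if (is.null(names(rates)) || any(rates < 0)) {
    stop("rates must be a named, non-negative vector")
  }
  if (is.null(founder)) {
    founder <- stats::setNames(rep(20L, length(rates)), names(rates))
  }
  if (!identical(sort(names(founder)), sort(names(rates)))) {
    stop("founder loci must match rate loci")
  }
  list(n = as.integer(n), rates = rates, tmrca = tmrca,
       genealogy = genealogy,
       founder = stats::setNames(as.integer(founder[names(rates)]),
                                 names(rates)),
       population_label = population_label, seed = seed)
}

# net displacement of a symmetric +/-1 random walk after Poisson(lambda)
# steps, drawn for each element of lambda (vectorized)
.smm_steps <- function(lambda) {
  k <- stats::rpois(length(lambda), lambda)
  2L * stats::rbinom(length(k), k, 0.5) - k
}

#' Simulate haplotypes on a star genealogy
#'
#' Each of n lineages descends independently from the founder for
#' \code{tmrca} generations; at each locus the mutation count is
#' Poisson(\eqn{\mu_l \cdot T}) and every mutation moves the repeat count
#' by +1 or -1 with equal probability.
#'
#' @param config A [sim_config()] with \code{genealogy = "star"}.
#' @return A normalized [haplotype_table()].
#' @export
simulate_star <- function(config) {
  if (!is.null(config$seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(config$seed)
  }
  L <- length(config$rates)
  lam <- rep(config$rates * config$tmrca, each = config$n)
  disp <- matrix(.smm_steps(lam), nrow = config$n,
                 dimnames = list(NULL, names(config$rates)))
  reps <- sweep(disp, 2L, config$founder, `+`)
  haplotype_table(sprintf("%s_%04d", config$population_label,
                          seq_len(config$n)),
                  config$population_label, reps, normalized = TRUE)
}

#' Simulate haplotypes on a Kingman coalescent genealogy
#'
#' Draws a random n-coalescent tree (via \pkg{ape}), rescales its depth to
#' \code{tmrca} generations, places the founder at the root, and drops
#' stepwise mutations on each branch as Poisson(\eqn{\mu_l \times} branch
#' length). Shared internal branches make lineages correlated — the regime
#' where rho dating is downwardly biased.
#'
#' @param config A [sim_config()] with n >= 2.
#' @param return_tree Also return the genealogy (default FALSE).
#' @return A normalized [haplotype_table()]; if \code{return_tree}, a list
#'   with \code{table} and \code{tree} (an \pkg{ape} phylo with branch
#'   lengths in generations).
#' @export
simulate_kingman <- function(config, return_tree = FALSE) {
  if (config$n < 2L) stop("kingman genealogy needs n >= 2")
  if (!is.null(config$seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(config$seed)
  }
  tree <- ape::rcoal(config$n,
                     tip.label = sprintf("%s_%04d", config$population_label,
                                         seq_len(config$n)))
  depth <- max(ape::node.depth.edgelength(tree))
  if (config$tmrca > 0 && depth > 0) {
    tree$edge.length <- tree$edge.length * (config$tmrca / depth)
  } else {
    tree$edge.length <- tree$edge.length * 0
  }
  n_nodes <- ape::Nnode(tree) + config$n
  states <- matrix(NA_integer_, n_nodes, length(config$rates),
                   dimnames = list(NULL, names(config$rates)))
  root <- config$n + 1L
  states[root, ] <- config$founder
  # process edges parents-first (an edge is ready once its parent has a state)
  remaining <- seq_len(nrow(tree$edge))
  while (length(remaining)) {
    ready <- remaining[!is.na(states[tree$edge[remaining, 1L], 1L])]
    for (e in ready) {
      par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
      states[child, ] <- states[par, ] +
        .smm_steps(config$rates * tree$edge.length[e])
    }
    remaining <- setdiff(remaining, ready)
  }
  reps <- states[seq_len(config$n), , drop = FALSE]
  tab <- haplotype_table(tree$tip.label, config$population_label, reps,
                         normalized = TRUE)
  if (return_tree) list(table = tab, tree = tree) else tab
}

#' Simulate a genealogy-appropriate haplotype table
#'
#' Dispatches on \code{config$genealogy}.
#'
#' @param config A [sim_config()].
#' @return A normalized [haplotype_table()].
#' @export
simulate_haplotypes <- function(config) {
  switch(config$genealogy,
         star = simulate_star(config),
         kingman = simulate_kingman(config))
}

#' Simulate two diverged populations for Rst calibration
#'
#' A common founder evolves for \code{split_time} generations along each of
#' two independent ancestral branches, producing two population founders;
#' each population then evolves from its own founder under its
#' configuration (star or kingman genealogy, its own depth). With
#' \code{split_time = 0} the populations share the founder and expected Rst
#' is ~0; deep splits with shallow within-population depth drive Rst
#' toward 1.
#'
#' @param configA,configB [sim_config()]s sharing the same rate panel;
#'   their \code{seed} fields are ignored in favour of \code{seed}.
#' @param split_time Generations before present at which the populations'
#'   ancestral lineages separate (i.e. length of each independent ancestral
#'   branch).
#' @param seed Integer seed for the whole two-population draw.
#' @return A two-population normalized [haplotype_table()].
#' @export
simulate_split <- function(configA, configB, split_time, seed = NULL) {
  if (split_time < 0) stop("split_time must be >= 0")
  if (!identical(names(configA$rates), names(configB$rates))) {
    stop("the two configurations must share one rate panel")
  }
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  rates <- configA$rates
  founderA <- configA$founder + .smm_steps(rates * split_time)
  founderB <- configA$founder + .smm_steps(rates * split_time)
  cA <- configA; cA$founder <- stats::setNames(founderA, names(rates))
  cB <- configB; cB$founder <- stats::setNames(founderB, names(rates))
  cA$seed <- cB$seed <- NULL  # inherit the ambient seeded stream
  bind_tables(simulate_haplotypes(cA), simulate_haplotypes(cB))
}
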