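#' Modal founder haplotype
#'
#' The presumed founder for rho-style dating: the per-locus modal repeat
#' value. Ties are broken toward the value minimizing the total absolute
#' distance to all observations at that locus, then toward the smaller
#' repeat, so the founder is deterministic.
#'
#' @param table A normalized [haplotype_table()]; incomplete records are
#'   removed first.
#' @return An object of class \code{founder_haplotype}: list with
#'   \code{repeats} (named integer vector) and \code{selection_rule}.
#' @export
modal_founder <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  if (!table$normalized) stop("requires a normalized table")
  tab <- suppressWarnings(filter_complete(table))
  if (n_samples(tab) < 1L) stop("empty table: no complete haplotype to root on")
  root <- apply(tab$repeats, 2L, function(x) {
    cnt <- table(x)
    modes <- as.integer(names(cnt)[cnt == max(cnt)])
    if (length(modes) > 1L) {
      tot <- vapply(modes, function(v) sum(abs(x - v)), numeric(1))
      modes <- modes[tot == min(tot)]
    }
    min(modes)
  })
  founder_haplotype(root, selection_rule = "modal")
}

#' Construct a founder haplotype
#'
#' @param repeats Named integer vector of repeat counts (complete).
#' @param selection_rule Tag: \code{"modal"} or \code{"user-supplied"}.
#' @return A \code{founder_haplotype}.
#' @export
founder_haplotype <- function(repeats, selection_rule = "user-supplied") {
  if (is.null(names(repeats)) || anyNA(repeats)) {
    stop("founder must be a complete named repeat vector")
  }
  structure(list(repeats = stats::setNames(as.integer(repeats), names(repeats)),
                 selection_rule = selection_rule),
            class = "founder_haplotype")
}

# per-locus mean absolute and squared founder distances on complete records
.founder_distances <- function(table, root) {
  stopifnot(inherits(table, "haplotype_table"),
            inherits(root, "founder_haplotype"))
  if (!table$normalized) stop("requires a normalized table")
  tab <- suppressWarnings(filter_complete(table))
  loci <- panel_loci(tab)
  if (!all(loci %in% names(root$repeats))) {
    stop("founder does not cover the table's panel")
  }
  n <- n_samples(tab)
  if (n < 1L) stop("no complete haplotypes")
  diff <- sweep(tab$repeats, 2L, root$repeats[loci])
  list(n = n,
       mean_abs = colMeans(abs(diff)),
       mean_sq = colMeans(diff^2))
}

#' Rho statistic: mean mutational distance from the founder
#'
#' \deqn{\rho = \frac{1}{n}\sum_{i}\sum_{l} |x_{il} - r_l|}
#' with the star-genealogy standard deviation \eqn{\sqrt{\rho/n}}. Divided
#' by the summed per-locus mutation rate, rho estimates the TMRCA in
#' generations.
#'
#' @param table A normalized [haplotype_table()].
#' @param root A \code{founder_haplotype} (default: [modal_founder()]).
#' @return List with \code{rho}, \code{sd} (\eqn{\sqrt{\rho/n}}), \code{n},
#'   and \code{per_locus} mean absolute distances.
#' @export
rho_statistic <- function(table, root = modal_founder(table)) {
  fd <- .founder_distances(table, root)
  rho <- sum(fd$mean_abs)
  list(rho = rho, sd = sqrt(rho / fd$n), n = fd$n, per_locus = fd$mean_abs)
}

#' Mutation-rate-weighted rho dating
#'
#' Each locus yields its own age estimate \eqn{t_l = \bar d_l / \mu_l}
#' (mean absolute founder distance over that locus's mutation rate); the
#' combined age is the mean of the per-locus ages, so a mutation observed
#' at a slow locus counts for proportionally more elapsed time than one at
#' a fast locus. The weighted statistic is reported on the rho scale as
#' \eqn{\rho_w = T \cdot L \cdot \bar\mu}; with equal per-locus rates it
#' reduces exactly to the unweighted rho.
#'
#' @param table A normalized [haplotype_table()].
#' @param root A \code{founder_haplotype}.
#' @param rates A \code{mutation_rate_table} covering every panel locus.
#' @return List with \code{rho_w}, \code{age_generations}, \code{per_locus_ages},
#'   \code{n}.
#' @export
weighted_rho <- function(table, root = modal_founder(table), rates) {
  fd <- .founder_distances(table, root)
  mu <- rates_for_panel(rates, names(fd$mean_abs))
  t_l <- fd$mean_abs / mu
  T_gen <- mean(t_l)
  L <- length(mu)
  list(rho_w = T_gen * L * mean(mu), age_generations = T_gen,
       per_locus_ages = t_l, n = fd$n)
}

#' Second-moment (ASD, "quadratic") founder dating
#'
#' Average squared distance from the founder per locus,
#' \eqn{ASD_l = \frac{1}{n}\sum_i (x_{il} - r_l)^2}; the age is
#' \eqn{T = \sum_l ASD_l / \sum_l \mu_l}. Under a symmetric single-step
#' random walk the second moment grows linearly in time even when back
#' mutations erase net displacement, which is what makes this estimator
#' robust at depths where rho saturates.
#'
#' @param table A normalized [haplotype_table()].
#' @param root A \code{founder_haplotype}.
#' @param rates A \code{mutation_rate_table} covering every panel locus.
#' @return List with \code{asd} (summed across loci), \code{age_generations},
#'   \code{per_locus} ASD values, \code{n}.
#' @export
asd_quadratic_age <- function(table, root = modal_founder(table), rates) {
  fd <- .founder_distances(table, root)
  mu <- rates_for_panel(rates, names(fd$mean_sq))
  list(asd = sum(fd$mean_sq),
       age_generations = sum(fd$mean_sq) / sum(mu),
       per_locus = fd$mean_sq, n = fd$n)
}

#' Convert an age in generations to years
#'
#' @param age_generations Non-negative age in generations.
#' @param generation_time Years per generation (commonly 25 or 30).
#' @param round_years Round to integer years for display (default TRUE).
#' @return Age in years.
#' @export
to_years <- function(age_generations, generation_time, round_years = TRUE) {
  if (generation_time <= 0) stop("generation_time must be positive")
  if (any(age_generations < 0)) stop("age must be non-negative")
  y <- age_generations * generation_time
  if (round_years) round(y) else y
}

#' TMRCA report for one population: all three estimators
#'
#' Runs [modal_founder()] (unless a root is supplied), then rho, weighted
#' rho, and ASD dating, at each requested generation time. The rho age SD
#' comes from the analytic \eqn{\sqrt{\rho/n}}; weighted-rho and ASD SDs
#' come from a seeded nonparametric bootstrap over individuals.
#'
#' @param table A normalized [haplotype_table()] for one population.
#' @param rates A \code{mutation_rate_table}.
#' @param generation_times Numeric vector of years/generation (default
#'   c(25, 30)).
#' @param root Optional \code{founder_haplotype}.
#' @param n_bootstrap Bootstrap resamples for weighted/ASD SDs (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return Data frame: population, n, method, statistic, generation_time,
#'   age_generations, years, sd_years. For n = 1 a warning notes that the
#'   TMRCA of a single lineage is undefined and ages are reported as 0.
#' @export
date_population <- function(table, rates, generation_times = c(25, 30),
                            root = NULL, n_bootstrap = 1000L, seed = NULL) {
  stopifnot(inherits(table, "haplotype_table"))
  tab <- suppressWarnings(filter_complete(table))
  pop <- if (length(unique(tab$populations)) == 1L)
    unique(tab$populations) else "combined"
  n <- n_samples(tab)
  if (n < 1L) stop("no complete haplotypes to date")
  if (n == 1L) warning("TMRCA is undefined for a single individual; ages are 0")
  if (is.null(root)) root <- modal_founder(tab)
  mu <- rates_for_panel(rates, panel_loci(tab))

  r <- rho_statistic(tab, root)
  wr <- weighted_rho(tab, root, rates)
  aq <- asd_quadratic_age(tab, root, rates)
  age_rho <- r$rho / sum(mu)
  sd_rho_gen <- r$sd / sum(mu)

  boot_sd <- c(weighted_rho = NA_real_, asd = NA_real_)
  if (n >= 2L && n_bootstrap > 0L) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    if (!is.null(seed)) set.seed(seed)
    bw <- ba <- numeric(n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      res <- subset_table(tab, rows = sample.int(n, n, replace = TRUE))
      # resampling keeps sample ids unique via suffixing
      res$samples <- make.unique(res$samples)
      rownames(res$repeats) <- res$samples
      bw[b] <- weighted_rho(res, root, rates)$age_generations
      ba[b] <- asd_quadratic_age(res, root, rates)$age_generations
    }
    boot_sd <- c(weighted_rho = stats::sd(bw), asd = stats::sd(ba))
  }

  rows <- list()
  for (gt in generation_times) {
    rows[[length(rows) + 1L]] <- data.frame(
      population = pop, n = n,
      method = c("rho", "weighted_rho", "asd_quadratic"),
      statistic = c(r$rho, wr$rho_w, aq$asd),
      generation_time = gt,
      age_generations = c(age_rho, wr$age_generations, aq$age_generations),
      years = to_years(c(age_rho, wr$age_generations, aq$age_generations), gt),
      sd_years = round(c(sd_rho_gen, boot_sd[["weighted_rho"]],
                         boot_sd[["asd"]]) * gt),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' TMRCA report across populations
#'
#' Applies [date_population()] to every population in the table and binds
#' the per-population reports into one table mirroring the usual
#' published layout (population, n, method, generation time, statistic,
#' age, SD).
#'
#' @inheritParams date_population
#' @param min_n Populations with fewer complete haplotypes are skipped with
#'   a message (default 2).
#' @return Data frame of stacked per-population reports.
#' @export
tmrca_report <- function(table, rates, generation_times = c(25, 30),
                         n_bootstrap = 1000L, seed = NULL, min_n = 2L) {
  stopifnot(inherits(table, "haplotype_table"))
  pops <- sort(unique(table$populations))
  out <- list()
  for (i in seq_along(pops)) {
    sub <- suppressWarnings(filter_complete(
      subset_table(table, population = pops[i])))
    if (n_samples(sub) < min_n) {
      message("skipping population '", pops[i], "': fewer than ", min_n,
              " complete haplotypes")
      next
    }
    out[[length(out) + 1L]] <- date_population(
      sub, rates, generation_times = generation_times,
      n_bootstrap = n_bootstrap,
      seed = if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max)
  }
  if (!length(out)) stop("no population had enough complete haplotypes")
  do.call(rbind, out)
}
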