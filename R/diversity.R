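#' Haplogroup carrier frequency
#'
#' Proportion of sampled males carrying the haplogroup-defining mutation,
#' reported both as a raw proportion and as the integer percentage used in
#' map labels.
#'
#' @param carriers Number of carriers (0..total).
#' @param total Number of individuals sampled.
#' @return List with \code{proportion} and \code{percent} (integer-rounded).
#' @export
haplogroup_frequency <- function(carriers, total) {
  if (length(total) != 1L || total <= 0) {
    stop("frequency undefined: total must be a positive count")
  }
  if (carriers < 0 || carriers > total) {
    stop("carriers must lie in [0, total]")
  }
  p <- carriers / total
  list(proportion = p, percent = as.integer(round(100 * p)))
}

#' Nei's average gene diversity across loci
#'
#' For each locus l, the unbiased gene diversity
#' \deqn{h_l = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}
#' over the allele (repeat-count) frequencies \eqn{p_i} at that locus,
#' ignoring missing calls at that locus. Returns the mean of \eqn{h_l}
#' across loci and its standard deviation across loci.
#'
#' @param table A normalized [haplotype_table()] with at least 2 records.
#' @return List with \code{gd} (mean across loci), \code{sd} (SD across
#'   loci), and \code{per_locus} (named vector of \eqn{h_l}).
#' @export
nei_average_gene_diversity <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  if (!table$normalized) stop("requires a normalized table")
  if (n_samples(table) < 2L) {
    stop("insufficient sample: gene diversity needs n >= 2")
  }
  h <- apply(table$repeats, 2L, function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2L) return(NA_real_)
    p <- tabulate(factor(x)) / n
    n * (1 - sum(p^2)) / (n - 1)
  })
  list(gd = mean(h, na.rm = TRUE),
       sd = stats::sd(h, na.rm = TRUE),
       per_locus = h)
}

#' Whole-haplotype Nei gene diversity
#'
#' Gene diversity treating the entire multi-locus haplotype as one allele:
#' the small-sample-corrected probability that two random individuals carry
#' distinct haplotypes. Complements [nei_average_gene_diversity()], which
#' averages per-locus diversities.
#'
#' @param table A normalized [haplotype_table()]; incomplete records are
#'   removed first.
#' @return Numeric diversity in [0, 1].
#' @export
nei_haplotype_diversity <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  if (!table$normalized) stop("requires a normalized table")
  tab <- filter_complete(table)
  n <- n_samples(tab)
  if (n < 2L) stop("insufficient sample: haplotype diversity needs n >= 2")
  key <- apply(tab$repeats, 1L, paste, collapse = "-")
  p <- as.numeric(table(key)) / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Mean microsatellite variance (Vp)
#'
#' Intra-haplogroup diversity: the mean across loci of the unbiased sample
#' variance of repeat counts, computed on complete haplotypes only (units:
#' squared repeat units).
#'
#' @param table A normalized [haplotype_table()].
#' @return List with \code{vp}, \code{per_locus} variances, and
#'   \code{n_complete}.
#' @export
vp_mean_variance <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  if (!table$normalized) stop("requires a normalized table")
  tab <- suppressWarnings(filter_complete(table))
  n <- n_samples(tab)
  if (n < 2L) stop("insufficient sample: Vp needs >= 2 complete haplotypes")
  v <- apply(tab$repeats, 2L, stats::var)
  list(vp = mean(v), per_locus = v, n_complete = n)
}

#' Haplotype reiteration and cross-population sharing
#'
#' Per population: number of distinct (complete) haplotypes and the
#' multiplicity of each reiterated one. Across populations: a symmetric
#' matrix counting haplotypes observed in both members of each pair.
#'
#' @param table A normalized [haplotype_table()].
#' @return List with \code{per_population} (data frame: population,
#'   n_complete, n_distinct, and reiterated haplotype counts as a nested
#'   list) and \code{sharing} (populations x populations integer matrix;
#'   diagonal = number of distinct haplotypes in that population).
#' @export
haplotype_sharing_summary <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  if (!table$normalized) stop("requires a normalized table")
  tab <- suppressWarnings(filter_complete(table))
  key <- apply(tab$repeats, 1L, paste, collapse = "-")
  pops <- sort(unique(tab$populations))
  per <- lapply(pops, function(p) {
    k <- key[tab$populations == p]
    cnt <- table(k)
    list(population = p, n_complete = length(k),
         n_distinct = length(cnt),
         reiterated = cnt[cnt >= 2L])
  })
  per_df <- data.frame(
    population = pops,
    n_complete = vapply(per, `[[`, integer(1), "n_complete"),
    n_distinct = vapply(per, `[[`, integer(1), "n_distinct"),
    n_reiterated = vapply(per, function(x) length(x$reiterated), integer(1)),
    stringsAsFactors = FALSE)
  sharing <- matrix(0L, length(pops), length(pops),
                    dimnames = list(pops, pops))
  by_pop <- lapply(pops, function(p) unique(key[tab$populations == p]))
  names(by_pop) <- pops
  for (i in seq_along(pops)) {
    sharing[i, i] <- length(by_pop[[i]])
    if (i < length(pops)) for (j in seq((i + 1L), length(pops))) {
      shared <- length(intersect(by_pop[[i]], by_pop[[j]]))
      sharing[i, j] <- sharing[j, i] <- shared
    }
  }
  list(per_population = per_df, reiterated = lapply(per, `[[`, "reiterated"),
       sharing = sharing)
}

#' Per-population diversity summary table
#'
#' One row per population: sample size, number of distinct haplotypes,
#' modal-haplotype share, Nei average gene diversity (with SD across loci)
#' and Vp. Populations with fewer than two complete haplotypes get NA
#' diversities.
#'
#' @param table A normalized [haplotype_table()].
#' @param frequencies Optional named vector of haplogroup carrier
#'   proportions per population (from survey totals, which the haplotype
#'   table alone cannot supply).
#' @return A data frame, one row per population.
#' @export
diversity_summary <- function(table, frequencies = NULL) {
  stopifnot(inherits(table, "haplotype_table"))
  if (!table$normalized) stop("requires a normalized table")
  pops <- sort(unique(table$populations))
  rows <- lapply(pops, function(p) {
    sub <- subset_table(table, population = p)
    comp <- suppressWarnings(filter_complete(sub))
    nc <- n_samples(comp)
    key <- if (nc) apply(comp$repeats, 1L, paste, collapse = "-") else character(0)
    gd <- sdl <- vp <- NA_real_
    if (n_samples(sub) >= 2L) {
      g <- nei_average_gene_diversity(sub)
      gd <- g$gd; sdl <- g$sd
    }
    if (nc >= 2L) vp <- vp_mean_variance(sub)$vp
    data.frame(
      population = p, n = n_samples(sub), n_complete = nc,
      frequency = if (!is.null(frequencies) && p %in% names(frequencies))
        unname(frequencies[p]) else NA_real_,
      nei_gd = gd, nei_gd_sd = sdl, vp = vp,
      n_distinct_haplotypes = length(unique(key)),
      modal_share = if (nc) max(table(key)) / nc else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a diversity summary as TSV
#'
#' @param summary Data frame from [diversity_summary()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_diversity_summary <- function(summary, path) {
  utf8_write_tsv(summary, path)
  invisible(path)
}
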