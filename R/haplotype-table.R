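#' The 17-locus Yfiler Y-STR panel
#'
#' Locus names of the AmpFlSTR Yfiler kit in canonical order. DYS385a/b are
#' the two copies of the multicopy DYS385 locus; DYS389II is reported by the
#' kit as a compound count that includes the DYS389I stretch.
#'
#' @return Character vector of 17 locus names.
#' @export
yfiler_panel <- function() {
  c("DYS19", "DYS385a", "DYS385b", "DYS389I", "DYS389II", "DYS390",
    "DYS391", "DYS392", "DYS393", "DYS437", "DYS438", "DYS439",
    "DYS448", "DYS456", "DYS458", "DYS635", "GATAH4")
}

#' The 15-locus panel used for diversity and dating
#'
#' The Yfiler panel after normalization: DYS385a/b removed (the kit cannot
#' assign alleles to the a and b copies) and DYS389II re-expressed as the
#' repeat count of its own stretch only.
#'
#' @return Character vector of 15 locus names.
#' @export
normalized_panel <- function() {
  setdiff(yfiler_panel(), c("DYS385a", "DYS385b"))
}

# Repeat counts outside this range are biologically implausible for Y-STRs.
.REPEAT_MIN <- 5L
.REPEAT_MAX <- 50L

#' Construct a haplotype table
#'
#' The central container: one row per sampled individual, one column per
#' Y-STR locus, integer repeat counts with \code{NA} for missing calls.
#'
#' @param samples Character vector of unique sample identifiers.
#' @param populations Character vector of population labels, recycled if
#'   length 1.
#' @param repeats Integer matrix (individuals x loci) of repeat counts;
#'   column names are locus names. \code{NA} marks a missing call.
#' @param normalized Logical; \code{TRUE} once DYS389II has been adjusted and
#'   DYS385a/b dropped (see [normalize_panel()]).
#' @return An object of class \code{haplotype_table}.
#' @export
haplotype_table <- function(samples, populations, repeats, normalized = FALSE) {
  repeats <- as.matrix(repeats)
  if (is.null(colnames(repeats)) || any(!nzchar(colnames(repeats)))) {
    stop("`repeats` must have locus names as column names")
  }
  if (anyDuplicated(colnames(repeats))) {
    stop("duplicate locus names in panel: ",
         paste(unique(colnames(repeats)[duplicated(colnames(repeats))]),
               collapse = ", "))
  }
  storage.mode(repeats) <- "integer"
  samples <- as.character(samples)
  if (length(samples) != nrow(repeats)) {
    stop("length(samples) must equal nrow(repeats)")
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample_id: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (length(populations) == 1L) {
    populations <- rep(as.character(populations), length(samples))
  }
  populations <- as.character(populations)
  if (length(populations) != length(samples)) {
    stop("length(populations) must equal length(samples)")
  }
  bad <- which(!is.na(repeats) &
                 (repeats < .REPEAT_MIN | repeats > .REPEAT_MAX))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(repeats))
    stop(sprintf("repeat count %d out of range [%d, %d] for sample '%s' at %s",
                 repeats[bad[1L]], .REPEAT_MIN, .REPEAT_MAX,
                 samples[idx[1L]], colnames(repeats)[idx[2L]]))
  }
  rownames(repeats) <- samples
  structure(
    list(samples = samples, populations = populations,
         repeats = repeats, normalized = isTRUE(normalized)),
    class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d individuals x %d loci (%s)\n",
              nrow(x$repeats), ncol(x$repeats),
              if (x$normalized) "normalized" else "raw panel"))
  pops <- table(x$populations)
  cat("populations:",
      paste(sprintf("%s (%d)", names(pops), as.integer(pops)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.haplotype_table <- function(x) dim(x$repeats)

#' Number of individuals in a haplotype table
#' @param table A [haplotype_table()].
#' @return Integer count.
#' @export
n_samples <- function(table) nrow(table$repeats)

#' Locus names of a haplotype table
#' @param table A [haplotype_table()].
#' @return Character vector.
#' @export
panel_loci <- function(table) colnames(table$repeats)

#' Subset a haplotype table by population or row index
#'
#' @param table A [haplotype_table()].
#' @param population Population label(s) to keep, or \code{NULL}.
#' @param rows Integer/logical row selector, or \code{NULL}.
#' @return A [haplotype_table()] with the selected records.
#' @export
subset_table <- function(table, population = NULL, rows = NULL) {
  stopifnot(inherits(table, "haplotype_table"))
  keep <- rep(TRUE, n_samples(table))
  if (!is.null(population)) keep <- keep & table$populations %in% population
  if (!is.null(rows)) {
    sel <- rep(FALSE, n_samples(table))
    sel[rows] <- TRUE
    keep <- keep & sel
  }
  haplotype_table(table$samples[keep], table$populations[keep],
                  table$repeats[keep, , drop = FALSE],
                  normalized = table$normalized)
}

#' Combine haplotype tables over a shared panel
#'
#' @param ... Tables with identical panels and normalization state.
#' @return A single [haplotype_table()].
#' @export
bind_tables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1L)
  panel <- panel_loci(tabs[[1L]])
  norm <- tabs[[1L]]$normalized
  for (t in tabs[-1L]) {
    if (!identical(panel_loci(t), panel)) stop("panel mismatch in bind_tables")
    if (!identical(t$normalized, norm)) {
      stop("cannot bind normalized and un-normalized tables")
    }
  }
  haplotype_table(
    unlist(lapply(tabs, `[[`, "samples")),
    unlist(lapply(tabs, `[[`, "populations")),
    do.call(rbind, lapply(tabs, `[[`, "repeats")),
    normalized = norm)
}
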