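#' Read a Y-STR haplotype table from TSV/CSV
#'
#' Expects a header-first delimited file with one row per individual: a
#' sample-identifier column, a population column, and one column per locus
#' holding integer repeat counts. Missing calls are empty cells or "NA" —
#' never 0, which is not a possible repeat count. Intermediate
#' (non-integer) alleles such as "13.2" are rejected by default because the
#' stepwise statistics downstream are defined on integer repeat scores.
#'
#' @param path Path to the file.
#' @param delim Field delimiter; \code{NULL} (default) auto-detects tab
#'   versus comma from the header line.
#' @param sample_col,population_col Column names holding the sample id and
#'   population label; \code{NULL} matches the first header named like
#'   "sample"/"id" and "population"/"pop" (case-insensitive).
#' @param intermediate How to treat non-integer repeat values: \code{"error"}
#'   (default) aborts naming the row and column; \code{"drop"} removes the
#'   affected records with a warning.
#' @param normalized Mark the table as already normalized (DYS389II
#'   adjusted, DYS385 dropped); the file format itself does not record this.
#' @return A [haplotype_table()] (un-normalized unless stated).
#' @export
read_haplotype_table <- function(path, delim = NULL,
                                 sample_col = NULL, population_col = NULL,
                                 intermediate = c("error", "drop"),
                                 normalized = FALSE) {
  intermediate <- match.arg(intermediate)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty file (no header): ", path)
  if (is.null(delim)) {
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("", "NA"), quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  cn <- names(df)
  pick <- function(given, patterns, what) {
    if (!is.null(given)) {
      if (!given %in% cn) stop("column '", given, "' not found in ", path)
      return(given)
    }
    hit <- cn[grepl(patterns, cn, ignore.case = TRUE)]
    if (!length(hit)) stop("no ", what, " column found in header of ", path)
    hit[1L]
  }
  sample_col <- pick(sample_col, "^(sample|sampleid|sample_id|id)$", "sample id")
  population_col <- pick(population_col, "^(population|pop|group)$", "population")
  locus_cols <- setdiff(cn, c(sample_col, population_col))
  if (!length(locus_cols)) stop("no locus columns found in ", path)

  if (nrow(df) == 0L) {
    mat <- matrix(integer(0), nrow = 0, ncol = length(locus_cols),
                  dimnames = list(NULL, locus_cols))
    return(haplotype_table(character(0), character(0), mat,
                           normalized = normalized))
  }

  raw <- as.matrix(df[locus_cols])
  num <- suppressWarnings(as.numeric(raw))
  bad_parse <- !is.na(raw) & is.na(num)
  non_int <- !is.na(num) & (num != floor(num))
  offending <- bad_parse | matrix(non_int, nrow = nrow(raw))
  if (any(offending)) {
    idx <- which(offending, arr.ind = TRUE)
    if (intermediate == "error" || any(bad_parse)) {
      i <- idx[1L, ]
      stop(sprintf(
        "non-integer repeat value '%s' at row %d (sample '%s'), locus %s",
        raw[i[1L], i[2L]], i[1L], df[[sample_col]][i[1L]],
        locus_cols[i[2L]]))
    }
    drop_rows <- unique(idx[, 1L])
    warning(sprintf("dropping %d record(s) with intermediate alleles",
                    length(drop_rows)))
    df <- df[-drop_rows, , drop = FALSE]
    raw <- as.matrix(df[locus_cols])
    num <- suppressWarnings(as.numeric(raw))
  }
  mat <- matrix(as.integer(num), nrow = nrow(df),
                dimnames = list(NULL, locus_cols))
  haplotype_table(df[[sample_col]], df[[population_col]], mat,
                  normalized = normalized)
}

#' Write a haplotype table as tab-delimited text
#'
#' Emits UTF-8, header-first TSV with columns
#' \code{SampleID, Population, <locus...>}; missing calls as empty cells.
#'
#' @param table A [haplotype_table()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_haplotype_table <- function(table, path) {
  stopifnot(inherits(table, "haplotype_table"))
  df <- data.frame(SampleID = table$samples, Population = table$populations,
                   table$repeats, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utf8_write_tsv(df, path)
  invisible(path)
}

# shared TSV writer: tab, header first, no quoting, NA as empty cell
utf8_write_tsv <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
}

#' Normalize a Yfiler haplotype table to the 15-locus panel
#'
#' Applies the two panel conventions used for Y-STR diversity work:
#' DYS389II is re-expressed as its own repeat stretch by subtracting
#' DYS389I (the kit's DYS389II amplicon spans both), and the multicopy
#' DYS385a/b columns are removed because a/b copies cannot be assigned.
#' Normalizing an already-normalized table is an error, which guards
#' against double subtraction.
#'
#' @param table An un-normalized [haplotype_table()] containing DYS389I,
#'   DYS389II, and (optionally) DYS385a/b columns.
#' @return A normalized [haplotype_table()] on the 15-locus panel.
#' @export
normalize_panel <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  if (table$normalized) stop("table is already normalized")
  loci <- panel_loci(table)
  if (!all(c("DYS389I", "DYS389II") %in% loci)) {
    stop("normalization requires DYS389I and DYS389II columns")
  }
  rep2 <- table$repeats
  i1 <- rep2[, "DYS389I"]
  i2 <- rep2[, "DYS389II"]
  bad <- which(!is.na(i1) & !is.na(i2) & i2 <= i1)
  if (length(bad)) {
    stop(sprintf(
      "DYS389II (%d) <= DYS389I (%d) for sample '%s': biologically impossible",
      i2[bad[1L]], i1[bad[1L]], table$samples[bad[1L]]))
  }
  rep2[, "DYS389II"] <- i2 - i1
  drop <- intersect(c("DYS385a", "DYS385b", "DYS385"), loci)
  rep2 <- rep2[, setdiff(loci, drop), drop = FALSE]
  haplotype_table(table$samples, table$populations, rep2, normalized = TRUE)
}

#' Keep only complete haplotypes
#'
#' Records with a missing call at any locus are removed; diversity measures
#' such as the mean microsatellite variance are defined on complete
#' haplotypes only.
#'
#' @param table A normalized [haplotype_table()].
#' @return A [haplotype_table()] with complete records only. Warns if no
#'   record survives.
#' @export
filter_complete <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  if (!table$normalized) stop("filter_complete requires a normalized table")
  keep <- stats::complete.cases(table$repeats)
  if (!any(keep) && n_samples(table) > 0L) {
    warning("no complete haplotypes remain after filtering")
  }
  subset_table(table, rows = which(keep))
}

#' Read a per-locus mutation-rate table
#'
#' Two-column, header-first delimited file: locus name and per-generation
#' mutation rate (mutations/locus/generation). Rates must be strictly
#' positive; rates at or above 0.05 per generation are implausible for
#' Y-STRs and trigger a warning.
#'
#' @param path Path to the file.
#' @param source_label Free-text provenance (database, retrieval date).
#'   Defaults to the file name.
#' @return A \code{mutation_rate_table}: list with \code{rates} (named
#'   numeric vector) and \code{source_label}.
#' @export
read_mutation_rates <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("mutation-rate table needs two columns (locus, rate)")
  mutation_rate_table(stats::setNames(as.numeric(df[[2L]]),
                                      as.character(df[[1L]])),
                      source_label = source_label)
}

#' Construct a mutation-rate table from a named vector
#'
#' @param rates Named numeric vector, locus -> rate per generation.
#' @param source_label Free-text provenance string.
#' @return A \code{mutation_rate_table}.
#' @export
mutation_rate_table <- function(rates, source_label = "user-supplied") {
  if (is.null(names(rates)) || any(!nzchar(names(rates)))) {
    stop("rates must be a named vector (locus names)")
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    bad <- names(rates)[!is.finite(rates) | rates <= 0][1L]
    stop("non-positive mutation rate for locus ", bad)
  }
  if (any(rates >= 0.05)) {
    warning("mutation rate >= 0.05/generation at ",
            paste(names(rates)[rates >= 0.05], collapse = ", "),
            ": implausibly fast for a Y-STR")
  }
  structure(list(rates = rates, source_label = source_label),
            class = "mutation_rate_table")
}

#' @export
print.mutation_rate_table <- function(x, ...) {
  cat(sprintf("mutation_rate_table: %d loci, mean rate %.4g (%s)\n",
              length(x$rates), mean(x$rates), x$source_label))
  invisible(x)
}

# Look up rates for a panel, erroring on any locus without a rate.
rates_for_panel <- function(rates, loci) {
  stopifnot(inherits(rates, "mutation_rate_table"))
  missing <- setdiff(loci, names(rates$rates))
  if (length(missing)) {
    stop("no mutation rate for locus: ", paste(missing, collapse = ", "))
  }
  rates$rates[loci]
}

#' Bundled synthetic per-locus mutation rates
#'
#' A plausible 15-locus rate table for the normalized Yfiler panel, for
#' simulation and examples. The values are synthetic (order-of-magnitude
#' realistic, around 0.002/generation); real dating runs should supply a
#' provenance-labelled table from a mutation-rate database.
#'
#' @return A \code{mutation_rate_table} labelled synthetic.
#' @export
synthetic_locus_rates <- function() {
  path <- system.file("extdata", "synthetic_locus_rates.tsv",
                      package = "ystrtrace", mustWork = TRUE)
  read_mutation_rates(path, source_label = "synthetic (bundled)")
}
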