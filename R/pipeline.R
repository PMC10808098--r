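#' Pipeline configuration
#'
#' Collects the inputs and tuning parameters for [run_pipeline()]. Can also
#' be read from a flat YAML file with the same field names via
#' [read_pipeline_config()].
#'
#' @param haplotypes Path to the haplotype TSV (or a [haplotype_table()]).
#' @param rates Path to the mutation-rate TSV (or a
#'   \code{mutation_rate_table}).
#' @param output_dir Directory for all outputs (created if absent).
#' @param permutations Permutations per Rst pair (default 10000).
#' @param seed Integer seed recorded in the manifest and used by every
#'   stochastic stage.
#' @param generation_times Years/generation vector (default c(25, 30)).
#' @param mds_dimensions MDS target dimensionality (default 2).
#' @param epsilon Median-joining relaxation (default 0).
#' @param alpha Family-wise significance level (default 0.05).
#' @param already_normalized Set TRUE if the input table is already on the
#'   15-locus adjusted panel.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(haplotypes, rates, output_dir,
                            permutations = 10000L, seed = 1L,
                            generation_times = c(25, 30),
                            mds_dimensions = 2L, epsilon = 0,
                            alpha = 0.05, already_normalized = FALSE) {
  structure(list(haplotypes = haplotypes, rates = rates,
                 output_dir = output_dir,
                 permutations = as.integer(permutations),
                 seed = as.integer(seed),
                 generation_times = generation_times,
                 mds_dimensions = as.integer(mds_dimensions),
                 epsilon = epsilon, alpha = alpha,
                 already_normalized = isTRUE(already_normalized)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Flat key-value YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full Y-STR analysis pipeline
#'
#' Executes, in order: panel normalization, per-population diversity
#' summaries and haplotype sharing, the pairwise Rst matrix with
#' permutation p-values and Bonferroni flagging, classical MDS of the
#' distance matrix, the median-joining network (GraphML export), and the
#' per-population TMRCA report. With a single population the Rst and MDS
#' stages are skipped with a logged reason. A JSON manifest records
#' inputs, parameters, seed and package version; a plain-text log records
#' stage progress. Outputs are a pure function of (inputs, config, seed).
#'
#' @param config A \code{pipeline_config}.
#' @return Invisibly, a list of the in-memory stage results plus
#'   \code{files} (named vector of written paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "pipeline.log")
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    note("stage ", name, ": start")
    res <- tryCatch(expr, error = function(e) {
      note("stage ", name, ": FAILED — ", conditionMessage(e))
      writeLines(log_lines, log_path)
      stop("pipeline aborted at stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
    note("stage ", name, ": done")
    res
  }

  tab <- stage("read", {
    if (inherits(config$haplotypes, "haplotype_table")) config$haplotypes
    else read_haplotype_table(config$haplotypes,
                              normalized = config$already_normalized)
  })
  rates <- if (inherits(config$rates, "mutation_rate_table")) config$rates
           else stage("rates", read_mutation_rates(config$rates))
  norm <- stage("normalize", {
    if (tab$normalized) tab else normalize_panel(tab)
  })
  files <- c()
  out <- function(name) file.path(config$output_dir, name)

  div <- stage("diversity", diversity_summary(norm))
  write_diversity_summary(div, out("diversity_summary.tsv"))
  files["diversity"] <- out("diversity_summary.tsv")

  sharing <- stage("sharing", haplotype_sharing_summary(norm))
  utf8_write_tsv(data.frame(Population = rownames(sharing$sharing),
                            sharing$sharing, check.names = FALSE),
                 out("haplotype_sharing.tsv"))
  files["sharing"] <- out("haplotype_sharing.tsv")

  n_pops <- length(unique(norm$populations))
  rst <- mds <- NULL
  if (n_pops >= 2L) {
    rst <- stage("rst", rst_matrix(norm, n_permutations = config$permutations,
                                   seed = config$seed, alpha = config$alpha))
    write_distance_matrix(rst, out("rst_matrix.tsv"))
    files["rst"] <- out("rst_matrix.tsv")
    if (n_pops >= 3L) {
      mds <- stage("mds", classical_mds(rst, k = config$mds_dimensions))
      write_mds_embedding(mds, out("mds_coordinates.tsv"))
      files["mds"] <- out("mds_coordinates.tsv")
    } else {
      note("stage mds: skipped — need >= 3 populations for a 2-D embedding")
    }
  } else {
    note("stage rst: skipped — single population, no pairwise distances")
    note("stage mds: skipped — single population")
  }

  net <- stage("network", median_joining(norm, epsilon = config$epsilon))
  write_network(net, out("network.graphml"), format = "graphml")
  files["network"] <- out("network.graphml")

  tmrca <- stage("tmrca", tmrca_report(
    norm, rates, generation_times = config$generation_times,
    seed = config$seed))
  utf8_write_tsv(tmrca, out("tmrca_report.tsv"))
  files["tmrca"] <- out("tmrca_report.tsv")

  manifest <- list(
    package = "ystrtrace",
    version = as.character(utils::packageVersion("ystrtrace")),
    seed = config$seed,
    permutations = config$permutations,
    generation_times = config$generation_times,
    mds_dimensions = config$mds_dimensions,
    epsilon = config$epsilon,
    alpha = config$alpha,
    inputs = list(
      haplotypes = if (is.character(config$haplotypes)) config$haplotypes
                   else "in-memory haplotype_table",
      rates = if (is.character(config$rates)) config$rates
              else rates$source_label),
    n_individuals = n_samples(norm),
    n_populations = n_pops,
    outputs = as.list(files))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files["manifest"] <- out("manifest.json")
  writeLines(log_lines, log_path)
  files["log"] <- log_path

  invisible(list(table = norm, diversity = div, sharing = sharing,
                 rst = rst, mds = mds, network = net, tmrca = tmrca,
                 files = files))
}
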