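#' Locus weights inversely proportional to repeat variance
#'
#' Network construction down-weights fast, highly variable loci: each locus
#' gets weight proportional to 1/variance of its repeat counts, rescaled so
#' the most variable locus has weight 1, capped, and rounded to an integer
#' scale. Monomorphic loci (zero variance) receive the cap.
#'
#' @param table A normalized [haplotype_table()] with n >= 2.
#' @param cap Maximum weight (default 10).
#' @return An object of class \code{locus_weights}: list with
#'   \code{weights} (named positive numeric) and \code{cap}.
#' @export
locus_weights_inverse_variance <- function(table, cap = 10) {
  stopifnot(inherits(table, "haplotype_table"))
  if (!table$normalized) stop("requires a normalized table")
  if (n_samples(table) < 2L) stop("weights need n >= 2")
  v <- apply(table$repeats, 2L, stats::var, na.rm = TRUE)
  w <- rep(as.numeric(cap), length(v))
  names(w) <- names(v)
  poly <- !is.na(v) & v > 0
  if (any(poly)) {
    raw <- 1 / v[poly]
    w[poly] <- pmin(cap, pmax(1, round(raw / min(raw))))
  }
  structure(list(weights = w, cap = cap), class = "locus_weights")
}

#' Equal locus weights
#'
#' @param loci Character vector of locus names.
#' @return A \code{locus_weights} with every weight 1.
#' @export
equal_locus_weights <- function(loci) {
  structure(list(weights = stats::setNames(rep(1, length(loci)), loci),
                 cap = 1),
            class = "locus_weights")
}

#' Per-locus and total mutational steps between two haplotypes
#'
#' Under the single-step mutation model the number of mutations separating
#' two alleles is the absolute repeat difference; haplotype distance is the
#' sum across loci.
#'
#' @param h1,h2 Named integer vectors of repeat counts on the same panel.
#' @return List with \code{per_locus} (named integer) and \code{total}.
#' @export
pairwise_steps <- function(h1, h2) {
  if (is.null(names(h1)) || is.null(names(h2)) ||
      !identical(names(h1), names(h2))) {
    stop("panel mismatch: haplotypes must share identical locus names")
  }
  if (anyNA(h1) || anyNA(h2)) stop("haplotypes must be complete")
  d <- abs(as.integer(h1) - as.integer(h2))
  names(d) <- names(h1)
  list(per_locus = d, total = sum(d))
}

# --- internal geometry on haplotype matrices ---------------------------------

# weighted L1 distance matrix between rows of H (integer because weights are)
.wdist <- function(H, w) {
  n <- nrow(H)
  D <- matrix(0, n, n)
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) {
    di <- abs(sweep(H[(i + 1L):n, , drop = FALSE], 2L, H[i, ])) %*% w
    D[i, (i + 1L):n] <- D[(i + 1L):n, i] <- as.numeric(di)
  }
  D
}

# Prim MST on a dense distance matrix; deterministic (lowest index wins ties).
# Returns edge list matrix (from, to) and the minimax matrix M where
# M[i,j] = min over paths of the maximum step distance (equal for all MSTs).
.mst_minimax <- function(D) {
  n <- nrow(D)
  if (n == 1L) {
    return(list(edges = matrix(integer(0), 0, 2), minimax = matrix(0, 1, 1),
                cost = 0))
  }
  in_tree <- rep(FALSE, n)
  best <- rep(Inf, n); parent <- rep(NA_integer_, n)
  in_tree[1L] <- TRUE
  best <- D[1L, ]; parent[] <- 1L
  edges <- matrix(integer(0), 0, 2)
  cost <- 0
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    in_tree[v] <- TRUE
    edges <- rbind(edges, c(parent[v], v))
    cost <- cost + best[v]
    upd <- !in_tree & D[v, ] < best
    best[upd] <- D[v, upd]
    parent[upd] <- v
  }
  # minimax distances: max edge along the unique MST path, by BFS per node
  adj <- vector("list", n)
  wts <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    adj[[a]] <- c(adj[[a]], b); wts[[a]] <- c(wts[[a]], D[a, b])
    adj[[b]] <- c(adj[[b]], a); wts[[b]] <- c(wts[[b]], D[a, b])
  }
  M <- matrix(0, n, n)
  for (s in seq_len(n)) {
    seen <- rep(FALSE, n); seen[s] <- TRUE
    queue <- s
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[u]]
      for (idx in seq_along(nb)) {
        v <- nb[idx]
        if (!seen[v]) {
          seen[v] <- TRUE
          M[s, v] <- max(M[s, u], wts[[u]][idx])
          queue <- c(queue, v)
        }
      }
    }
  }
  list(edges = edges, minimax = M, cost = cost)
}

# epsilon-relaxed minimum spanning network: link (i,j) iff
# d(i,j) <= minimax(i,j) + epsilon. With epsilon = 0 this is the union of
# all minimum spanning trees.
.msn_edges <- function(D, epsilon) {
  mm <- .mst_minimax(D)
  n <- nrow(D)
  keep <- which(upper.tri(D) & D <= mm$minimax + epsilon + 1e-9, arr.ind = TRUE)
  list(edges = keep, mst_cost = mm$cost)
}

.hap_key <- function(H) apply(H, 1L, paste, collapse = "-")

# lexicographic row order for deterministic processing
.lex_order <- function(H) do.call(order, as.data.frame(H))

#' Median-joining haplotype network
#'
#' Reconstructs a haplotype network by the median-joining algorithm:
#' iteratively (i) build the epsilon-relaxed minimum spanning network over
#' the current haplotype set under weighted single-step distances, (ii) for
#' every linked pair plus a third haplotype, add the per-locus median
#' (the middle repeat value of the three) as an inferred "median vector" if
#' it is not already present, (iii) repeat to convergence, then (iv) prune
#' median vectors whose removal does not increase the minimum spanning cost
#' of the remaining set (maximum-parsimony heuristic) or that end up with
#' degree < 2. All processing follows lexicographic haplotype order, so the
#' result is independent of input record order.
#'
#' @param table A normalized [haplotype_table()] with at least one complete
#'   haplotype.
#' @param weights A \code{locus_weights} (default: inverse repeat variance
#'   when n >= 2, equal weights otherwise).
#' @param epsilon Non-negative relaxation parameter in weighted-distance
#'   units (default 0, the usual software default).
#' @param max_iterations Safety cap on median-addition rounds.
#' @return An object of class \code{haplotype_network}: list with
#'   \code{graph} (igraph, undirected), \code{haplotypes} (node x locus
#'   matrix), \code{nodes} (data frame: name, multiplicity,
#'   is_median_vector), \code{populations} (per-node named count vectors),
#'   \code{weights}, \code{epsilon}.
#' @export
median_joining <- function(table, weights = NULL, epsilon = 0,
                           max_iterations = 25L) {
  stopifnot(inherits(table, "haplotype_table"))
  if (!table$normalized) stop("requires a normalized table")
  if (epsilon < 0) stop("epsilon must be >= 0")
  tab <- suppressWarnings(filter_complete(table))
  if (n_samples(tab) < 1L) stop("median_joining needs >= 1 complete haplotype")
  if (is.null(weights)) {
    weights <- if (n_samples(tab) >= 2L)
      locus_weights_inverse_variance(tab) else
      equal_locus_weights(panel_loci(tab))
  }
  stopifnot(inherits(weights, "locus_weights"))
  loci <- panel_loci(tab)
  w <- weights$weights[loci]
  if (anyNA(w)) stop("weights missing for some panel loci")

  # collapse to unique observed haplotypes with multiplicity and composition
  key_all <- .hap_key(tab$repeats)
  uniq <- !duplicated(key_all)
  H <- tab$repeats[uniq, , drop = FALSE]
  storage.mode(H) <- "integer"
  ord <- .lex_order(H)
  H <- H[ord, , drop = FALSE]
  obs_keys <- .hap_key(H)
  mult <- as.integer(table(factor(key_all, levels = obs_keys)))
  pop_comp <- lapply(obs_keys, function(kk) {
    tt <- table(tab$populations[key_all == kk])
    stats::setNames(as.integer(tt), names(tt))
  })
  n_obs <- nrow(H)
  is_median <- rep(FALSE, n_obs)
  node_names <- paste0("H", seq_len(n_obs))
  mv_counter <- 0L

  # median-addition loop: per round, generate the componentwise medians of
  # (linked pair, third sequence) triples and add the new ones with minimal
  # connection cost (d(u,v)+d(u,w)+d(v,w))/2, as in the published algorithm
  for (iter in seq_len(max_iterations)) {
    D <- .wdist(H, w)
    msn <- .msn_edges(D, epsilon)
    E <- msn$edges
    if (!nrow(E)) break
    have <- .hap_key(H)
    cand_key <- character(0)
    cand_rows <- list()
    cand_cost <- numeric(0)
    n_cur <- nrow(H)
    for (e in seq_len(nrow(E))) {
      u <- E[e, 1L]; v <- E[e, 2L]
      lo <- pmin(H[u, ], H[v, ])
      hi <- pmax(H[u, ], H[v, ])
      # median of (u, v, t) per locus = t clamped into [lo, hi]
      med <- pmin(pmax(H, rep(lo, each = n_cur)), rep(hi, each = n_cur))
      keys <- .hap_key(med)
      costs <- (D[u, v] + D[u, ] + D[v, ]) / 2
      fresh <- which(!(keys %in% have) & !duplicated(keys))
      for (t in fresh) {
        k <- keys[t]
        at <- match(k, cand_key)
        if (is.na(at)) {
          cand_key <- c(cand_key, k)
          cand_rows[[length(cand_rows) + 1L]] <- med[t, ]
          cand_cost <- c(cand_cost, costs[t])
        } else if (costs[t] < cand_cost[at]) {
          cand_cost[at] <- costs[t]
        }
      }
    }
    if (!length(cand_key)) break
    pickable <- which(cand_cost <= min(cand_cost) + 1e-9)
    new_H <- do.call(rbind, cand_rows[pickable])
    new_H <- new_H[order(cand_key[pickable]), , drop = FALSE]
    storage.mode(new_H) <- "integer"
    colnames(new_H) <- loci
    for (r in seq_len(nrow(new_H))) {
      mv_counter <- mv_counter + 1L
      node_names <- c(node_names, paste0("mv", mv_counter))
    }
    H <- rbind(H, new_H)
    mult <- c(mult, rep(0L, nrow(new_H)))
    is_median <- c(is_median, rep(TRUE, nrow(new_H)))
    pop_comp <- c(pop_comp, rep(list(stats::setNames(integer(0), character(0))),
                                nrow(new_H)))
  }

  # prune obsolete median vectors: iteratively drop those with degree < 2
  # in the current spanning network, or lying on no shortest connection
  # between observed haplotypes (parsimony heuristic)
  repeat {
    D <- .wdist(H, w)
    E <- .msn_edges(D, epsilon)$edges
    n_cur <- nrow(H)
    deg <- tabulate(c(E[, 1L], E[, 2L]), nbins = n_cur)
    drop <- which(is_median & deg < 2L)
    if (!length(drop)) {
      # all-pairs shortest paths over the spanning network's weighted edges
      sp <- matrix(Inf, n_cur, n_cur)
      diag(sp) <- 0
      for (e in seq_len(nrow(E))) {
        sp[E[e, 1L], E[e, 2L]] <- sp[E[e, 2L], E[e, 1L]] <- D[E[e, 1L], E[e, 2L]]
      }
      for (k in seq_len(n_cur)) {
        sp <- pmin(sp, outer(sp[, k], sp[k, ], `+`))
      }
      obs <- which(!is_median)
      mv <- which(is_median)
      if (length(mv)) {
        on_geodesic <- vapply(mv, function(i) {
          thru <- outer(sp[obs, i], sp[i, obs], `+`)
          any(thru <= sp[obs, obs] + 1e-9 & sp[obs, obs] > 0)
        }, logical(1))
        drop <- mv[!on_geodesic]
      }
    }
    if (!length(drop)) break
    H <- H[-drop, , drop = FALSE]
    mult <- mult[-drop]; is_median <- is_median[-drop]
    pop_comp <- pop_comp[-drop]; node_names <- node_names[-drop]
  }

  D <- .wdist(H, w)
  E <- .msn_edges(D, epsilon)$edges
  steps <- integer(nrow(E))
  wlen <- numeric(nrow(E))
  for (e in seq_len(nrow(E))) {
    d <- abs(H[E[e, 1L], ] - H[E[e, 2L], ])
    steps[e] <- sum(d)
    wlen[e] <- sum(d * w)
  }
  g <- igraph::make_empty_graph(n = nrow(H), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = node_names)
  g <- igraph::set_vertex_attr(g, "multiplicity", value = mult)
  g <- igraph::set_vertex_attr(g, "is_median_vector", value = is_median)
  g <- igraph::set_vertex_attr(g, "haplotype", value = .hap_key(H))
  g <- igraph::set_vertex_attr(
    g, "populations",
    value = vapply(pop_comp, function(p)
      paste(sprintf("%s:%d", names(p), p), collapse = ";"), character(1)))
  if (nrow(E)) {
    g <- igraph::add_edges(g, t(E))
    g <- igraph::set_edge_attr(g, "steps", value = steps)
    g <- igraph::set_edge_attr(g, "weighted_length", value = wlen)
  }
  nodes <- data.frame(name = node_names, multiplicity = mult,
                      is_median_vector = is_median,
                      stringsAsFactors = FALSE)
  rownames(H) <- node_names
  structure(list(graph = g, haplotypes = H, nodes = nodes,
                 populations = stats::setNames(pop_comp, node_names),
                 weights = weights, epsilon = epsilon),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf(
    "haplotype_network: %d nodes (%d observed, %d median vectors), %d edges; epsilon = %g\n",
    nrow(x$nodes), sum(!x$nodes$is_median_vector),
    sum(x$nodes$is_median_vector), igraph::ecount(x$graph), x$epsilon))
  invisible(x)
}

#' Minimum mutational separation between two population groups
#'
#' Minimum over node pairs (one bearing samples from group A, the other
#' from group B) of the shortest-path length through the network, path
#' length being the sum of unweighted mutational steps along edges. Zero
#' when the groups share a haplotype node.
#'
#' @param network A \code{haplotype_network}.
#' @param groupA,groupB Character vectors of population labels.
#' @return Numeric minimum step count.
#' @export
group_separation <- function(network, groupA, groupB) {
  stopifnot(inherits(network, "haplotype_network"))
  bears <- function(grp) which(vapply(network$populations, function(p)
    any(names(p) %in% grp), logical(1)))
  a <- bears(groupA); b <- bears(groupB)
  if (!length(a)) stop("no node bears a population from groupA")
  if (!length(b)) stop("no node bears a population from groupB")
  d <- igraph::distances(network$graph, v = a, to = b,
                         weights = igraph::E(network$graph)$steps)
  min(d)
}

#' Export a haplotype network as GraphML or DOT
#'
#' Node attributes: \code{name}, \code{multiplicity},
#' \code{is_median_vector}, \code{populations} (as "Pop:count;..." string),
#' \code{haplotype}; edge attributes: \code{steps}, \code{weighted_length}.
#'
#' @param network A \code{haplotype_network}.
#' @param path Output path.
#' @param format \code{"graphml"} (default) or \code{"dot"}.
#' @return Invisibly, \code{path}.
#' @export
write_network <- function(network, path, format = c("graphml", "dot")) {
  stopifnot(inherits(network, "haplotype_network"))
  format <- match.arg(format)
  g <- network$graph
  # igraph's graphml writer needs plain types; booleans as 0/1
  g <- igraph::set_vertex_attr(
    g, "is_median_vector",
    value = as.integer(igraph::V(g)$is_median_vector))
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Read a network previously exported as GraphML
#'
#' @param path GraphML file written by [write_network()].
#' @return An igraph object with the exported attributes.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
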