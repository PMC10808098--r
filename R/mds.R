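#' Classical (Torgerson) multidimensional scaling of a distance matrix
#'
#' Double-centers the squared distances and takes the top-k positive
#' eigenvalue axes (metric MDS). Negative input entries — which pairwise
#' Rst can produce by sampling — are floored at 0 before embedding.
#' Goodness of fit is reported as Kruskal stress-1,
#' \eqn{\sqrt{\sum (d - \hat d)^2 / \sum d^2}}, and as the squared Pearson
#' correlation between input and embedded distances.
#'
#' @param dist An \code{rst_matrix}, \code{dist} object, or square symmetric
#'   numeric matrix with zero diagonal.
#' @param k Target number of dimensions (default 2). If fewer positive
#'   eigenvalues exist, fewer axes are returned with a warning.
#' @return An object of class \code{mds_embedding}: list with
#'   \code{coordinates} (populations x k, centered at the origin),
#'   \code{stress}, \code{r_squared}, and \code{eigenvalues}.
#' @export
classical_mds <- function(dist, k = 2L) {
  if (inherits(dist, "rst_matrix")) {
    m <- dist$values
  } else if (inherits(dist, "dist")) {
    m <- as.matrix(dist)
  } else {
    m <- as.matrix(dist)
  }
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-9)) {
    stop("distance matrix must be square and symmetric")
  }
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal must be 0")
  if (k < 1L) stop("k must be >= 1")
  m[m < 0] <- 0
  n <- nrow(m)
  if (all(m == 0)) {
    coords <- matrix(0, n, k, dimnames = list(rownames(m), NULL))
    return(structure(list(coordinates = coords, stress = 0, r_squared = NA_real_,
                          eigenvalues = rep(0, n)),
                     class = "mds_embedding"))
  }
  fit <- stats::cmdscale(stats::as.dist(m), k = min(k, n - 1L), eig = TRUE)
  n_pos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  coords <- as.matrix(fit$points)
  if (ncol(coords) > n_pos) coords <- coords[, seq_len(n_pos), drop = FALSE]
  if (ncol(coords) < k) {
    warning(sprintf("only %d positive eigenvalue axis/axes available (k = %d requested)",
                    ncol(coords), k))
  }
  coords <- sweep(coords, 2L, colMeans(coords))
  rownames(coords) <- rownames(m)
  dhat <- as.matrix(stats::dist(coords))
  lower <- lower.tri(m)
  d <- m[lower]; e <- dhat[lower]
  stress <- sqrt(sum((d - e)^2) / sum(d^2))
  r2 <- if (stats::sd(d) == 0 || stats::sd(e) == 0) NA_real_ else
    stats::cor(d, e)^2
  structure(list(coordinates = coords, stress = stress, r_squared = r2,
                 eigenvalues = fit$eig),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("mds_embedding: %d points in %d dimension(s); stress-1 = %.5f, R^2 = %.5f\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              if (is.na(x$r_squared)) NA else x$r_squared))
  invisible(x)
}

#' Write MDS coordinates as TSV
#'
#' @param embedding An \code{mds_embedding}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_mds_embedding <- function(embedding, path) {
  stopifnot(inherits(embedding, "mds_embedding"))
  co <- embedding$coordinates
  df <- data.frame(Population = rownames(co), co,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1L] <- paste0("Dim", seq_len(ncol(co)))
  utf8_write_tsv(df, path)
  invisible(path)
}
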