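#' Standardized three-variable PCA
#'
#' Principal component analysis of (elevation, LST, RZSM) observations:
#' variables are standardized to zero mean and unit variance, the
#' decomposition comes from the singular values of the standardized matrix,
#' and each component's sign is fixed so that its largest-magnitude loading
#' is positive (deterministic orientation). Biplot arrow coordinates are
#' `loading * sqrt(eigenvalue)`.
#'
#' @param x matrix or data.frame with 3 numeric columns; rows with any
#'   missing value are dropped; at least 3 complete rows are required and
#'   every variable must have positive variance.
#' @param var_names column names used in the output (defaults to the input
#'   column names, or elevation/lst/rzsm).
#' @return object of class `pca3`: `loadings` (3x3 orthonormal, variables x
#'   components), `explained` (variance fractions, non-increasing, summing
#'   to 1), `scores` (observations x components; `scores %*% t(loadings)`
#'   reproduces the standardized data), `arrows` (biplot arrow coordinates),
#'   `sdev`, `n`.
#' @export
pca_3var <- function(x, var_names = NULL) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("exactly 3 variables are required")
  if (is.null(var_names))
    var_names <- colnames(x) %||% c("elevation", "lst", "rzsm")
  colnames(x) <- var_names
  complete <- stats::complete.cases(x)
  x <- x[complete, , drop = FALSE]
  n <- nrow(x)
  if (n < 3) stop("need at least 3 complete rows, got ", n)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero variance in variable(s): ",
         paste(var_names[sds == 0], collapse = ", "))
  z <- scale(x)
  s <- svd(z)
  loadings <- s$v
  scores <- s$u %*% diag(s$d)
  for (j in 1:3) {  # orient: largest-|loading| entry positive
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  eigenvalues <- s$d^2 / (n - 1)
  dimnames(loadings) <- list(var_names, paste0("PC", 1:3))
  colnames(scores) <- paste0("PC", 1:3)
  arrows <- loadings %*% diag(sqrt(eigenvalues))
  dimnames(arrows) <- dimnames(loadings)
  structure(list(loadings = loadings,
                 explained = s$d^2 / sum(s$d^2),
                 scores = scores, arrows = arrows,
                 sdev = sqrt(eigenvalues), n = n),
            class = "pca3")
}

#' @export
print.pca3 <- function(x, ...) {
  cat(sprintf("pca3: n = %d; explained = %s\n", x$n,
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  print(round(x$loadings, 3))
  invisible(x)
}
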