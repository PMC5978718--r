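## PCAenv: correlation PCA of climate variables over coastal background plus
## occurrence sites, defining the 2-D environmental niche space.

#' Fit the environmental ordination (PCAenv)
#'
#' Centers and unit-scales each retained climate variable over the combined
#' background + occurrence rows and performs a principal component analysis,
#' so that the leading axes span the climate space available along the
#' coastlines and occupied by the species. Loading signs follow a fixed
#' convention: each component's largest-magnitude loading is made positive.
#'
#' @param background Numeric matrix/data frame of background-site
#'   environmental vectors (columns = retained variables).
#' @param occurrences Matrix of occurrence-site vectors with the same
#'   columns.
#' @return Object of class `pcaenv`: `center`, `scale`, `loadings`
#'   (variables x components, orthonormal columns), `eigenvalues`,
#'   `var_frac`, `scores_background`, `scores_occurrences`.
#' @export
fit_pcaenv <- function(background, occurrences) {
  background <- as.matrix(background)
  occurrences <- as.matrix(occurrences)
  stopifnot(identical(colnames(background), colnames(occurrences)))
  x <- rbind(background, occurrences)
  if (nrow(x) < 2) stop("need at least 2 rows to fit a PCA")
  if (nrow(x) < ncol(x)) stop("need at least as many rows as variables")
  if (any(!is.finite(x))) stop("non-finite environmental values")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # fixed sign convention: largest |loading| per component positive
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  ev <- pc$sdev^2
  nb <- nrow(background)
  structure(list(center = pc$center, scale = pc$scale,
                 loadings = pc$rotation, eigenvalues = ev,
                 var_frac = ev / sum(ev),
                 scores_background = pc$x[seq_len(nb), , drop = FALSE],
                 scores_occurrences = pc$x[nb + seq_len(nrow(occurrences)), ,
                                           drop = FALSE]),
            class = "pcaenv")
}

#' Project new environmental vectors into an existing PCAenv
#'
#' @param object A [fit_pcaenv()] model.
#' @param newdata Matrix with the model's variables as columns.
#' @param ... Unused.
#' @return Score matrix (rows x components).
#' @export
predict.pcaenv <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, names(object$center), drop = FALSE]
  scale(newdata, center = object$center, scale = object$scale) %*%
    object$loadings
}

#' @export
print.pcaenv <- function(x, ...) {
  cat("<pcaenv> correlation PCA,", length(x$eigenvalues), "components\n")
  vf <- round(100 * x$var_frac[1:min(5, length(x$var_frac))], 1)
  cat("variance explained (%):", paste(vf, collapse = ", "), "...\n")
  invisible(x)
}
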