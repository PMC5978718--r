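## Greedy correlation filter: keep a subset of climate variables whose
## pairwise |Pearson r| all fall below a threshold before ordination.

#' Drop highly correlated environmental variables
#'
#' Repeatedly finds the pair with the largest pairwise `|r|` at or above
#' `threshold` and drops, from that pair, the variable with the larger mean
#' `|r|` against all remaining variables (ties broken by variable-name
#' order), until every retained pair satisfies `|r| < threshold`.
#'
#' @param env Numeric matrix or data frame (rows = sites, columns = named
#'   variables); at least 2 variables and 3 rows.
#' @param threshold Correlation threshold (default 0.9).
#' @return Character vector of retained variable names (original column
#'   order).
#' @export
filter_correlated <- function(env, threshold = 0.9) {
  env <- as.matrix(env)
  stopifnot(ncol(env) >= 2, nrow(env) >= 3, !is.null(colnames(env)))
  sds <- apply(env, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(env)[sds == 0],
                                       collapse = ", "),
         " (correlation undefined)")
  }
  keep <- colnames(env)
  r <- abs(stats::cor(env))
  repeat {
    sub <- r[keep, keep, drop = FALSE]
    diag(sub) <- 0
    if (max(sub) < threshold) break
    worst <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- sort(c(keep[worst[1]], keep[worst[2]]))
    # mean |r| of each pair member against the other retained variables
    mean_r <- vapply(pair, function(v) {
      others <- setdiff(keep, v)
      mean(r[v, others])
    }, numeric(1))
    drop <- if (mean_r[1] > mean_r[2]) pair[1] else
      if (mean_r[2] > mean_r[1]) pair[2] else pair[1] # tie: name order
    keep <- setdiff(keep, drop)
    if (length(keep) == 1) break
  }
  colnames(env)[colnames(env) %in% keep]
}
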