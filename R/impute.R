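#' k-nearest-neighbour imputation of an abundance matrix
#'
#' Each missing cell is replaced by the mean of that column over the `k`
#' nearest rows, using Euclidean distance on z-scored, mutually observed
#' columns (column means and SDs from the observed cells). Only rows with
#' the target column observed are eligible neighbours; ties in distance are
#' broken by row order. Observed cells are never touched. `k = 3` is the
#' pipeline default.
#'
#' @param x Samples x proteins numeric matrix with `NA` for missing cells.
#' @param k Number of neighbours (default 3).
#' @return The matrix with all missing cells imputed.
#' @examples
#' m <- matrix(rlnorm(50), 10, 5,
#'             dimnames = list(paste0("s", 1:10), paste0("p", 1:5)))
#' m[2, 3] <- NA
#' knn_impute(m)[2, 3]
#' @export
knn_impute <- function(x, k = 3) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  stopifnot(k >= 1)
  if (!anyNA(x)) return(x)
  if (any(colSums(!is.na(x)) == 0)) stop("a column is entirely missing")
  if (any(colSums(!is.na(x)) < k))
    stop("every column needs at least k observed rows")
  if (any(rowSums(!is.na(x)) == 0)) stop("a row is entirely missing")

  mu <- colMeans(x, na.rm = TRUE)
  s <- apply(x, 2, sd, na.rm = TRUE)
  s[s == 0 | is.na(s)] <- 1
  z <- sweep(sweep(x, 2, mu), 2, s, `/`)

  out <- x
  for (i in which(rowSums(is.na(x)) > 0)) {
    for (j in which(is.na(x[i, ]))) {
      donors <- which(!is.na(x[, j]))
      d <- vapply(donors, function(r) {
        shared <- which(!is.na(z[i, ]) & !is.na(z[r, ]))
        if (!length(shared)) return(Inf)
        sqrt(sum((z[i, shared] - z[r, shared])^2))
      }, numeric(1))
      nn <- donors[order(d)[seq_len(k)]]
      out[i, j] <- mean(x[nn, j])
    }
  }
  out
}
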