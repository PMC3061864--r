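#' Singular value decomposition of a data matrix
#'
#' Decomposes the delay-by-channel matrix `D = U S V'` into orthonormal
#' time-domain traces (left singular vectors, columns of `U`), singular
#' values in non-increasing order, and orthonormal spectral-domain
#' vectors (columns of `V`). Because the sign of a singular-vector pair
#' carries no physical meaning, a deterministic convention is applied:
#' the largest-magnitude element of each right vector is made positive.
#'
#' @param data a [data_matrix()] or plain numeric matrix (rows = times).
#' @return object of class `svd_result` with elements `left_vectors`
#'   (`U`), `singular_values` (diagonal of `S`) and `right_vectors`
#'   (`V`).
#' @examples
#' d <- outer(exp(-(0:10) / 3), c(1, 2, 1))
#' svd_decompose(d)$singular_values
#' @export
svd_decompose <- function(data) {
  m <- if (inherits(data, "data_matrix")) data$values else as.matrix(data)
  if (any(!is.finite(m)))
    stop("data must be finite for SVD", call. = FALSE)
  dec <- svd(m)
  for (j in seq_along(dec$d)) {
    i <- which.max(abs(dec$v[, j]))
    if (dec$v[i, j] < 0) {
      dec$v[, j] <- -dec$v[, j]
      dec$u[, j] <- -dec$u[, j]
    }
  }
  structure(list(left_vectors = dec$u, singular_values = dec$d,
                 right_vectors = dec$v),
            class = "svd_result")
}

#' @export
print.svd_result <- function(x, ...) {
  cat("<svd_result> ", length(x$singular_values), " components\n",
      "  singular values: ",
      paste(signif(utils::head(x$singular_values, 6), 4), collapse = ", "),
      if (length(x$singular_values) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Singular-value-weighted time traces
#'
#' The first `n_keep` left singular vectors scaled column-wise by their
#' singular values, taking the singular-value amplitude as the measure
#' of dominance of each (wavelength-independent) time trace. The column
#' norm of trace `i` therefore equals `s_i`.
#'
#' @param svd an [svd_decompose()] result.
#' @param n_keep number of traces to keep (`1 <= n_keep <= rank`).
#' @return time x `n_keep` matrix of weighted traces.
#' @export
weight_left_vectors <- function(svd, n_keep) {
  stopifnot(inherits(svd, "svd_result"))
  r <- length(svd$singular_values)
  if (!is.numeric(n_keep) || n_keep < 1 || n_keep > r)
    stop("n_keep must lie in [1, ", r, "]", call. = FALSE)
  n_keep <- as.integer(n_keep)
  svd$left_vectors[, seq_len(n_keep), drop = FALSE] %*%
    diag(svd$singular_values[seq_len(n_keep)], n_keep)
}

#' Estimate the number of significant SVD components
#'
#' Heuristic gap criterion: the rank is the position of the last ratio
#' gap `s_r / s_(r+1) >= gap_factor`, so that the singular values beyond
#' it continue a flat/linear noise trend (no further gap of that size).
#' If no such gap exists anywhere (e.g. pure white noise), `0L` is
#' returned with attribute `no_gap = TRUE`. The scree should always also
#' be inspected by eye; [scree_table()] prints it.
#'
#' @param svd an [svd_decompose()] result.
#' @param gap_factor required ratio between consecutive singular values
#'   (> 1, default 10).
#' @return integer count of significant components.
#' @export
significant_rank <- function(svd, gap_factor = 10) {
  stopifnot(inherits(svd, "svd_result"))
  if (gap_factor <= 1) stop("gap_factor must be > 1", call. = FALSE)
  s <- svd$singular_values
  s <- s[s > 0]
  n <- length(s)
  if (n == 0L) return(structure(0L, no_gap = TRUE))
  if (n == 1L) return(1L)
  ratios <- s[-n] / s[-1]
  gaps <- which(ratios >= gap_factor)
  if (length(gaps) == 0L) return(structure(0L, no_gap = TRUE))
  as.integer(max(gaps))
}

#' Scree table of singular values
#'
#' @param svd an [svd_decompose()] result.
#' @param n number of leading values to tabulate (default all).
#' @return data frame with `component`, `singular_value` and the ratio
#'   to the next value; suitable for delimited export.
#' @export
scree_table <- function(svd, n = length(svd$singular_values)) {
  s <- svd$singular_values[seq_len(min(n, length(svd$singular_values)))]
  data.frame(component = seq_along(s),
             singular_value = s,
             ratio_to_next = c(s[-length(s)] / s[-1], NA))
}
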