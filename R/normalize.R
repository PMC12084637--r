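#' Normalize spectrum counts by ancestral target counts
#'
#' Divides each channel's counts by the occurrence count of its ancestral
#' context in the ancestral genome (the number of `ACG` 3-mers for channel
#' `A[C>T]G`, the canonical ancestral dinucleotide count for an SDM channel).
#' Converts raw counts into per-target mutation rates so channels and
#' genomes with different base compositions are comparable.
#'
#' @param mat samples x channels matrix of counts.
#' @param targets named target counts from [kmer_targets()] or
#'   [dinuc_targets()].
#' @return matrix of rates, same shape as `mat`.
#' @export
target_normalize <- function(mat, targets) {
  ctx <- channel_context(colnames(mat))
  t <- targets[ctx]
  bad <- is.na(t) | t <= 0
  if (any(bad))
    stop("channels with missing or zero ancestral target count: ",
         paste(colnames(mat)[bad], collapse = ", "))
  sweep(mat, 2, t, "/")
}

#' Zero-offset rule for matrices containing zeros
#'
#' The sample-wise median-of-ratios factor is undefined when a sample has
#' zeros in more than half its channels. When any entry of the matrix is 0, a
#' small constant is added to every entry: `1 x 10^N` where `N =
#' floor(log10(s))` and `s` is the smallest positive entry (smallest positive
#' entry 3.5e-9 gives offset 1e-9). Matrices without zeros are returned
#' unchanged with offset 0.
#'
#' @param mat numeric matrix with at least one positive entry.
#' @return list with `matrix` (offset applied) and `offset`.
#' @export
zero_offset <- function(mat) {
  if (!any(mat > 0)) stop("all-zero matrix: no positive entry to set the offset")
  if (any(mat < 0)) stop("negative entries are not meaningful spectrum rates")
  if (!any(mat == 0)) return(list(matrix = mat, offset = 0))
  offset <- 10^floor(log10(min(mat[mat > 0])))
  list(matrix = mat + offset, offset = offset)
}

#' Median-of-ratios sample normalization
#'
#' Computes per-sample size factors as the median, across channels, of the
#' ratio of the sample's rate to the channel's geometric mean across samples:
#' `s_j = median_i k_ij / (prod_v k_iv)^(1/m)`, then divides each sample's
#' row by its factor. Channels whose geometric mean is 0 are excluded from
#' the median (apply [zero_offset()] first when zeros are present). Because
#' the factors are only identified up to a common scale, they are by default
#' rescaled to geometric mean 1, which makes the operation exactly idempotent
#' and leaves all between-sample comparisons unchanged; `scale_factors =
#' FALSE` returns the raw medians.
#'
#' @param mat strictly positive samples x channels matrix.
#' @param scale_factors rescale factors to geometric mean 1 (default TRUE).
#' @return list with `matrix` (normalized), `factors` (named per-sample), and
#'   `m` (sample count).
#' @export
median_of_ratios <- function(mat, scale_factors = TRUE) {
  m <- nrow(mat)
  if (is.null(m) || m < 1) stop("need at least one sample")
  logmat <- suppressWarnings(log(mat))
  logmat[mat <= 0] <- -Inf
  g <- exp(colMeans(logmat))
  use <- g > 0
  if (!any(use)) stop("no channel has a positive geometric mean")
  ratios <- sweep(mat[, use, drop = FALSE], 2, g[use], "/")
  s <- apply(ratios, 1, median)
  if (any(!is.finite(s) | s <= 0))
    stop("non-positive or non-finite factor; apply zero_offset() first")
  if (scale_factors) s <- s / exp(mean(log(s)))
  names(s) <- rownames(mat)
  list(matrix = sweep(mat, 1, s, "/"), factors = s, m = m)
}

#' Combine target-normalized datasets onto one scale
#'
#' Row-concatenates several target-normalized spectrum matrices sharing one
#' channel set, applies the zero-offset rule to the joint matrix, and
#' normalizes it with a single median-of-ratios pass, placing all samples
#' (e.g. from different species) on a common scale.
#'
#' @param mats list of samples x channels matrices with identical channel
#'   labels in identical order.
#' @param scale_factors passed to [median_of_ratios()].
#' @return list with `matrix`, `factors`, `offset`, and `dataset` (factor
#'   mapping rows to their source matrix).
#' @export
combine_datasets <- function(mats, scale_factors = TRUE) {
  stopifnot(length(mats) >= 1)
  ref <- colnames(mats[[1]])
  for (i in seq_along(mats)) {
    if (!identical(colnames(mats[[i]]), ref)) {
      diff <- union(setdiff(colnames(mats[[i]]), ref),
                    setdiff(ref, colnames(mats[[i]])))
      stop("channel sets differ between datasets: ",
           paste(head(diff, 10), collapse = ", "))
    }
  }
  joint <- do.call(rbind, mats)
  dataset <- factor(rep(seq_along(mats), vapply(mats, nrow, integer(1))),
                    labels = if (!is.null(names(mats))) names(mats)
                    else as.character(seq_along(mats)))
  off <- zero_offset(joint)
  norm <- median_of_ratios(off$matrix, scale_factors = scale_factors)
  list(matrix = norm$matrix, factors = norm$factors, offset = off$offset,
       dataset = dataset)
}
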