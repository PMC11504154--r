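# Cohort-level normalisations applied before (zero-to-one per gene) and
# after (fractional ranking of the per-sample signature scores) signature
# scoring.

#' Zero-to-one normalisation per gene
#'
#' Rescales every gene row affinely to the unit interval across the
#' cohort: `y = (x - min) / (max - min)`. Genes that are constant across
#' samples carry no contrast and are set to all-zero; their identifiers
#' are recorded in the `constant_genes` attribute and reported via a
#' message so downstream scoring can exclude them.
#'
#' @param m validated expression matrix with at least 2 samples.
#' @return normalised matrix in `[0, 1]` with attribute `constant_genes`.
#' @export
zero_one_normalize <- function(m) {
  validate_expression_matrix(m)
  if (ncol(m) < 2L)
    stop("zero-to-one normalisation is undefined for a single-sample matrix")
  lo <- apply(m, 1L, min)
  hi <- apply(m, 1L, max)
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1  # avoid 0/0; constant rows forced to zero below
  out <- (m - lo) / rng
  out[const, ] <- 0
  attr(out, "constant_genes") <- rownames(m)[const]
  if (any(const))
    message(sprintf("zero_one_normalize: %d constant gene(s) flagged and set to zero",
                    sum(const)))
  out
}

#' Fractional ranking
#'
#' Tie-averaged ranks divided by the number of observations, giving
#' values in `(0, 1]`. Used to place signature scores from different
#' cohorts on a common scale.
#'
#' @param x numeric vector, all finite, length >= 1.
#' @return numeric vector of fractional ranks in `(0, 1]`.
#' @export
fractional_rank <- function(x) {
  if (length(x) < 1L) stop("fractional_rank needs at least one value")
  if (any(!is.finite(x))) stop("fractional_rank: non-finite values present")
  rank(x, ties.method = "average") / length(x)
}
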