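# Signature scoring: geometric-mean proliferation and migration indices,
# per-cohort fractional ranks, the Dichotomy Index (DI) and its high/low
# categorisation.

#' Geometric-mean signature score per sample
#'
#' For each sample the score is the geometric mean of the normalised
#' expression values of the signature genes present in the matrix, with a
#' small pseudocount to keep zeros (guaranteed by min-max normalisation)
#' from annihilating the product:
#' `score = (prod(y + eps))^(1/k) - eps`, clipped at 0.
#'
#' Gene matching is case-insensitive with built-in alias resolution
#' (SNAIL -> SNAI1, SLUG -> SNAI2). At least 50% of the set must be
#' present in the matrix; genes flagged as constant by
#' [zero_one_normalize()] are excluded from scoring.
#'
#' @param norm normalised matrix from [zero_one_normalize()].
#' @param set a [gene_set()].
#' @param pseudocount small non-negative real, default `1e-6`; zero is
#'   permitted when the matrix is known to be zero-free.
#' @return named numeric vector of per-sample scores (>= 0).
#' @export
geometric_mean_index <- function(norm, set, pseudocount = 1e-6) {
  stopifnot(inherits(set, "gene_set"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a single non-negative number")
  row_can <- canonical_gene_ids(rownames(norm))
  set_can <- canonical_gene_ids(set$genes)
  idx <- match(set_can, row_can)
  missing <- set$genes[is.na(idx)]
  if (length(missing) > 0.5 * length(set$genes))
    stop("gene set '", set$name, "': only ",
         length(set$genes) - length(missing), "/", length(set$genes),
         " genes present (<50%); missing: ", paste(missing, collapse = ", "))
  if (length(missing))
    message(sprintf("gene set '%s': %d gene(s) absent from matrix: %s",
                    set$name, length(missing), paste(missing, collapse = ", ")))
  idx <- idx[!is.na(idx)]
  const <- canonical_gene_ids(attr(norm, "constant_genes") %||% character(0))
  drop_const <- row_can[idx] %in% const
  if (any(drop_const))
    message(sprintf("gene set '%s': %d constant-flagged gene(s) excluded",
                    set$name, sum(drop_const)))
  idx <- idx[!drop_const]
  if (length(idx) == 0L)
    stop("gene set '", set$name, "': no scorable genes in matrix")
  sub <- norm[idx, , drop = FALSE]
  score <- exp(colMeans(log(sub + pseudocount))) - pseudocount
  pmax(score, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample signature table
#'
#' Computes the proliferation and migration geometric-mean indices for
#' every sample present in both the matrix and the clinical table, their
#' per-cohort fractional ranks, and the Dichotomy Index
#' `di = prolif_rank / migr_rank`. Samples missing from either input are
#' dropped with a logged count.
#'
#' @param norm normalised matrix from [zero_one_normalize()].
#' @param clinical clinical table (see [read_clinical_table()]).
#' @param prolif_set,migr_set [gene_set()] objects for the proliferation
#'   and migration programmes.
#' @param pseudocount passed to [geometric_mean_index()].
#' @return data.frame with columns sample_id, prolif_index, migr_index,
#'   prolif_rank, migr_rank, di.
#' @export
compute_signature_table <- function(norm, clinical, prolif_set, migr_set,
                                    pseudocount = 1e-6) {
  common <- intersect(colnames(norm), clinical$sample_id)
  if (length(common) == 0L)
    stop("no samples shared between expression matrix and clinical table")
  dropped <- (ncol(norm) - length(common)) +
    (nrow(clinical) - length(common))
  if (dropped > 0L)
    message(sprintf("compute_signature_table: %d sample(s) present in only one input dropped",
                    dropped))
  sub <- norm[, common, drop = FALSE]
  attr(sub, "constant_genes") <- attr(norm, "constant_genes")
  p <- geometric_mean_index(sub, prolif_set, pseudocount)
  m <- geometric_mean_index(sub, migr_set, pseudocount)
  pr <- fractional_rank(p)
  mr <- fractional_rank(m)
  data.frame(sample_id = common,
             prolif_index = unname(p),
             migr_index = unname(m),
             prolif_rank = unname(pr),
             migr_rank = unname(mr),
             di = unname(pr / mr),
             stringsAsFactors = FALSE)
}

#' Dichotomise the Dichotomy Index
#'
#' Splits the cohort at the median DI: `di > median` is proliferation
#' dominant (`high`), `di <= median` migration dominant (`low`). If every
#' DI is identical the split is degenerate: all samples are assigned
#' `low` with a warning. The threshold is recorded in the
#' `di_threshold` attribute.
#'
#' @param sig signature table from [compute_signature_table()], >= 2 rows.
#' @param method split rule; only `"median"` is implemented.
#' @return the table with an added `di_category` column.
#' @export
dichotomize_di <- function(sig, method = c("median")) {
  method <- match.arg(method)
  if (nrow(sig) < 2L) stop("dichotomize_di needs at least 2 samples")
  med <- median(sig$di)
  if (all(sig$di == sig$di[1L])) {
    warning("all DI values identical; every sample assigned 'low'")
    sig$di_category <- rep("low", nrow(sig))
  } else {
    sig$di_category <- ifelse(sig$di > med, "high", "low")
  }
  attr(sig, "di_threshold") <- med
  sig
}
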