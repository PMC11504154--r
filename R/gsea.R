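# Lightweight gene set enrichment: signal-to-noise ranking, the weighted
# Kolmogorov-Smirnov running-sum enrichment score, phenotype-permutation
# nominal p / NES / sign-stratified FDR, leading-edge ("core enrichment")
# extraction, and core-gene overlap comparison between contrasts.

.s2n_scores <- function(m, idx_a, idx_b, sd_floor = 0.2) {
  mu_a <- rowMeans(m[, idx_a, drop = FALSE])
  mu_b <- rowMeans(m[, idx_b, drop = FALSE])
  ss <- function(x, mu) sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  sd_a <- ss(m[, idx_a, drop = FALSE], mu_a)
  sd_b <- ss(m[, idx_b, drop = FALSE], mu_b)
  # each sd floored at max(sd_floor * |mean|, sd_floor)
  sd_a <- pmax(sd_a, pmax(sd_floor * abs(mu_a), sd_floor))
  sd_b <- pmax(sd_b, pmax(sd_floor * abs(mu_b), sd_floor))
  (mu_a - mu_b) / (sd_a + sd_b)
}

.as_two_class <- function(labels) {
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels, levels = unique(labels))
  if (nlevels(f) != 2L)
    stop("phenotype must have exactly 2 classes, got ", nlevels(f))
  if (any(table(f) < 3L))
    stop("each phenotype class needs >= 3 samples")
  f
}

#' Rank genes by signal-to-noise ratio
#'
#' For a binary phenotype, ranks every gene by
#' `(mu_A - mu_B) / (sd_A + sd_B)` with each class standard deviation
#' floored at `max(0.2 |mu|, 0.2)` (the reference GSEA convention). The
#' first level of `labels` is class A. Ties are broken lexicographically
#' by gene identifier for cross-platform determinism.
#'
#' @param m expression matrix (genes x samples).
#' @param labels binary phenotype, one label per column; >= 3 per class.
#' @return object of class `ranked_list`: list with `gene_ids` and
#'   `scores`, sorted by score descending.
#' @export
rank_by_signal_to_noise <- function(m, labels) {
  if (length(labels) != ncol(m))
    stop("labels must have one entry per sample column")
  f <- .as_two_class(labels)
  s <- .s2n_scores(m, which(f == levels(f)[1L]), which(f == levels(f)[2L]))
  ord <- order(-s, rownames(m))
  structure(list(gene_ids = rownames(m)[ord], scores = unname(s[ord])),
            class = "ranked_list")
}

.es_core <- function(scores, hit, weight) {
  n <- length(scores)
  nh <- sum(hit)
  w <- abs(scores[hit])^weight
  sw <- sum(w)
  inc <- if (sw > 0) w / sw else rep(1 / nh, nh)
  step <- rep(-1 / (n - nh), n)
  step[hit] <- inc
  running <- cumsum(step)
  # signed maximum deviation; an exact tie between the positive and
  # negative extremes (possible with rational step sizes) resolves to
  # the positive peak, with a tolerance so floating-point noise cannot
  # flip the choice
  mx <- max(running); mn <- min(running)
  tol <- 1e-12 * max(1, abs(mx), abs(mn))
  if (mx >= -mn - tol) {
    peak <- which.max(running)
  } else {
    peak <- which.min(running)
  }
  list(es = running[peak], running = running, peak = peak)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks down the ranked list; set members ("hits") increment the running
#' sum by `|score|^weight / sum(|score_hits|^weight)`, non-members
#' decrement it by `1 / (N - N_hits)`. The enrichment score is the signed
#' maximum deviation from zero; an exact tie between the positive and
#' negative extremes resolves to the positive peak (1e-12 tolerance, so
#' floating-point noise cannot flip the sign). The leading edge contains
#' the set genes
#' at or before the peak for a positive score (at or after, for a
#' negative one).
#'
#' @param ranked `ranked_list` from [rank_by_signal_to_noise()].
#' @param set a [gene_set()]; must overlap the list but not cover it.
#' @param weight exponent on the hit scores, >= 0, default 1.
#' @return list with `es`, `running_sum`, `peak_index`, `leading_edge`.
#' @export
enrichment_score <- function(ranked, set, weight = 1) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(set, "gene_set"))
  if (weight < 0) stop("weight must be >= 0")
  hit <- canonical_gene_ids(ranked$gene_ids) %in% canonical_gene_ids(set$genes)
  n <- length(hit)
  if (!any(hit)) stop("gene set '", set$name, "' does not overlap the ranked list")
  if (all(hit)) stop("gene set '", set$name, "' covers the entire ranked list")
  r <- .es_core(ranked$scores, hit, weight)
  le_idx <- if (r$es >= 0) which(hit & seq_len(n) <= r$peak)
            else which(hit & seq_len(n) >= r$peak)
  list(es = r$es, running_sum = r$running, peak_index = r$peak,
       leading_edge = ranked$gene_ids[le_idx])
}

#' Phenotype-permutation gene set enrichment
#'
#' For each gene set, computes the observed enrichment score on the
#' signal-to-noise ranking, then rebuilds the ranking under `n_perm`
#' seeded permutations of the phenotype labels. The nominal p is the
#' fraction of same-sign permuted scores at least as extreme as the
#' observed one; NES divides the observed score by the mean magnitude of
#' same-sign permuted scores; the FDR q compares the pooled permuted NES
#' distribution with the observed NES distribution, stratified by sign
#' (the reference GSEA procedure). Fully deterministic given `seed`.
#'
#' @param m expression matrix (genes x samples).
#' @param labels binary phenotype (first level = class A).
#' @param gene_sets list of [gene_set()] objects.
#' @param n_perm number of label permutations, >= 100 (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param weight KS weight, default 1.
#' @return list of per-set results: `set_name`, `es`, `nes`,
#'   `p_nominal`, `fdr_q`, `leading_edge`, `n_perm`.
#' @export
gsea_phenotype <- function(m, labels, gene_sets, n_perm = 1000, seed = 1,
                           weight = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100 for stable estimates")
  if (inherits(gene_sets, "gene_set")) gene_sets <- list(gene_sets)
  f <- .as_two_class(labels)
  if (length(f) != ncol(m)) stop("labels must match sample columns")
  n_sets <- length(gene_sets)
  row_can <- canonical_gene_ids(rownames(m))
  masks <- lapply(gene_sets, function(gs) row_can %in% canonical_gene_ids(gs$genes))
  for (j in seq_len(n_sets)) {
    if (!any(masks[[j]]))
      stop("gene set '", gene_sets[[j]]$name, "' does not overlap the matrix")
    if (all(masks[[j]]))
      stop("gene set '", gene_sets[[j]]$name, "' covers the entire matrix")
  }

  obs_ranked <- rank_by_signal_to_noise(m, f)
  obs <- lapply(gene_sets, function(gs) enrichment_score(obs_ranked, gs, weight))
  es_obs <- vapply(obs, `[[`, numeric(1), "es")

  set.seed(seed)
  es_perm <- matrix(NA_real_, n_perm, n_sets)
  a_lab <- levels(f)[1L]
  for (i in seq_len(n_perm)) {
    pf <- sample(f)
    s <- .s2n_scores(m, which(pf == a_lab), which(pf != a_lab))
    ord <- order(-s, rownames(m))
    sc <- s[ord]
    for (j in seq_len(n_sets))
      es_perm[i, j] <- .es_core(sc, masks[[j]][ord], weight)$es
  }

  # per-set same-sign normalisation of observed and permuted ES
  nes_obs <- rep(NA_real_, n_sets)
  nes_perm <- matrix(NA_real_, n_perm, n_sets)
  p_nom <- rep(NA_real_, n_sets)
  for (j in seq_len(n_sets)) {
    ep <- es_perm[, j]
    pos <- ep >= 0
    mean_pos <- if (any(pos)) mean(ep[pos]) else NA_real_
    mean_neg <- if (any(!pos)) mean(abs(ep[!pos])) else NA_real_
    nes_perm[pos, j] <- ep[pos] / mean_pos
    nes_perm[!pos, j] <- ep[!pos] / mean_neg
    if (es_obs[j] >= 0) {
      p_nom[j] <- if (any(pos)) mean(ep[pos] >= es_obs[j]) else 0
      nes_obs[j] <- if (is.finite(mean_pos) && mean_pos > 0) es_obs[j] / mean_pos else NA_real_
    } else {
      p_nom[j] <- if (any(!pos)) mean(ep[!pos] <= es_obs[j]) else 0
      nes_obs[j] <- if (is.finite(mean_neg) && mean_neg > 0) es_obs[j] / mean_neg else NA_real_
    }
  }

  all_perm_nes <- as.vector(nes_perm)
  fdr_q <- rep(NA_real_, n_sets)
  for (j in seq_len(n_sets)) {
    nj <- nes_obs[j]
    if (!is.finite(nj)) { fdr_q[j] <- 1; next }
    if (nj >= 0) {
      perm_pos <- all_perm_nes[is.finite(all_perm_nes) & all_perm_nes >= 0]
      obs_pos <- nes_obs[is.finite(nes_obs) & nes_obs >= 0]
      num <- if (length(perm_pos)) mean(perm_pos >= nj) else 0
      den <- mean(obs_pos >= nj)
    } else {
      perm_neg <- all_perm_nes[is.finite(all_perm_nes) & all_perm_nes < 0]
      obs_neg <- nes_obs[is.finite(nes_obs) & nes_obs < 0]
      num <- if (length(perm_neg)) mean(perm_neg <= nj) else 0
      den <- mean(obs_neg <= nj)
    }
    fdr_q[j] <- min(1, num / den)
  }

  lapply(seq_len(n_sets), function(j) {
    structure(list(set_name = gene_sets[[j]]$name,
                   es = es_obs[j], nes = nes_obs[j],
                   p_nominal = p_nom[j], fdr_q = fdr_q[j],
                   leading_edge = obs[[j]]$leading_edge,
                   n_perm = n_perm),
              class = "mpd_enrichment")
  })
}

#' Flatten enrichment results to a data.frame
#'
#' @param results list of results from [gsea_phenotype()].
#' @return data.frame with one row per set; leading-edge genes
#'   semicolon-joined.
#' @export
enrichment_table <- function(results) {
  data.frame(
    set_name = vapply(results, `[[`, character(1), "set_name"),
    es = vapply(results, `[[`, numeric(1), "es"),
    nes = vapply(results, `[[`, numeric(1), "nes"),
    p_nominal = vapply(results, `[[`, numeric(1), "p_nominal"),
    fdr_q = vapply(results, `[[`, numeric(1), "fdr_q"),
    n_leading_edge = vapply(results, function(r) length(r$leading_edge), integer(1)),
    leading_edge = vapply(results, function(r) paste(r$leading_edge, collapse = ";"),
                          character(1)),
    stringsAsFactors = FALSE
  )
}

#' Compile core enrichment genes
#'
#' Keeps the sets passing the significance thresholds (nominal p and FDR
#' q) and returns the unique union of their leading-edge genes.
#'
#' @param results list of results from [gsea_phenotype()].
#' @param p_thresh nominal p threshold (default 0.05).
#' @param q_thresh FDR q threshold (default 0.25).
#' @param sign optionally restrict to sets with positive (`"pos"`) or
#'   negative (`"neg"`) enrichment scores; default `"both"`.
#' @return list with `core_genes` (sorted unique character vector) and
#'   `total` (its size).
#' @export
core_gene_compilation <- function(results, p_thresh = 0.05, q_thresh = 0.25,
                                  sign = c("both", "pos", "neg")) {
  sign <- match.arg(sign)
  if (length(results) == 0L) stop("no enrichment results supplied")
  keep <- vapply(results, function(r) {
    ok <- is.finite(r$p_nominal) && is.finite(r$fdr_q) &&
      r$p_nominal < p_thresh && r$fdr_q < q_thresh
    if (sign == "pos") ok <- ok && r$es > 0
    if (sign == "neg") ok <- ok && r$es < 0
    ok
  }, logical(1))
  genes <- sort(unique(unlist(lapply(results[keep], `[[`, "leading_edge"))))
  list(core_genes = genes, total = length(genes))
}

#' Compare core-gene overlap shares between two pairings
#'
#' Given a reference category's core genes and two comparison categories,
#' computes the shared fraction of each pairing
#' (`|ref ∩ x| / |ref ∪ x|`) and contrasts the two fractions with the
#' pooled two-proportion z test. This is the comparison used to ask
#' whether, e.g., early-stage core enrichment resembles the low-DI or
#' the high-DI programme more.
#'
#' @param core_ref,core_b,core_c character vectors of core genes.
#' @return an `mpd_overlap_z` (see [two_proportion_z()]) with the counts
#'   `k1 = |ref ∩ b|, n1 = |ref ∪ b|, k2 = |ref ∩ c|, n2 = |ref ∪ c|`.
#' @export
core_overlap_comparison <- function(core_ref, core_b, core_c) {
  k1 <- length(intersect(core_ref, core_b))
  n1 <- length(union(core_ref, core_b))
  k2 <- length(intersect(core_ref, core_c))
  n2 <- length(union(core_ref, core_c))
  two_proportion_z(k1, n1, k2, n2)
}
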