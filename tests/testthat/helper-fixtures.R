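# Shared fixtures and independent oracles used across test files.

tiny_matrix <- function() {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("TP53", "ZEB1", "MKI67"), c("S1", "S2")))
  m
}

# Independent running-sum oracle for the weighted KS enrichment score:
# a literal step-by-step walk, sharing no code with the engine. Ties
# between the positive and negative extremes resolve to the positive
# peak within tolerance (the documented convention).
brute_force_es <- function(scores, hit, weight) {
  n <- length(scores)
  nh <- sum(hit)
  sw <- sum(abs(scores[hit])^weight)
  run <- 0
  runs <- numeric(n)
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) {
      if (sw > 0) abs(scores[i])^weight / sw else 1 / nh
    } else {
      -1 / (n - nh)
    }
    runs[i] <- run
  }
  mx <- max(runs); mn <- min(runs)
  tol <- 1e-12 * max(1, abs(mx), abs(mn))
  if (mx >= -mn - tol) mx else mn
}

random_ranked_instance <- function(n_max = 30) {
  n <- sample(5:n_max, 1)
  scores <- sort(rnorm(n), decreasing = TRUE)
  ids <- sprintf("G%03d", seq_len(n))
  k <- sample(seq_len(n - 1), 1)
  genes <- sample(ids, k)
  list(ranked = structure(list(gene_ids = ids, scores = scores),
                          class = "ranked_list"),
       set = gene_set("RANDSET", genes),
       hit = ids %in% genes)
}

# Quiet wrapper: the pipeline logs drops/flags via message()/warning();
# tests that are not about the logging silence it.
quiet <- function(expr) suppressWarnings(suppressMessages(expr))

run_preset_verdict <- function(preset_name, seed) {
  cfg <- preset(preset_name)
  cfg$seed <- as.integer(seed)
  coh <- generate_cohort(cfg)
  rep <- quiet(run_analysis(coh$matrix, coh$clinical, coh$prolif_set,
                            coh$migr_set, options = list(run_gsea = FALSE)))
  rep$verdict
}

fake_enrichment <- function(name, es, p, q, le) {
  structure(list(set_name = name, es = es, nes = sign(es) * 1.5,
                 p_nominal = p, fdr_q = q, leading_edge = le,
                 n_perm = 1000L), class = "mpd_enrichment")
}

fake_cor <- function(r, n, p, p_adj = NA_real_) {
  ci <- fisher_ci(r, n)
  structure(list(r = r, n = n, ci_low = ci[1], ci_high = ci[2],
                 p = p, p_adj = p_adj), class = "mpd_cor")
}
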