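# End-to-end analysis: normalise, score, stage-stratified correlations
# with BH adjustment, dominance-shift tests, GSEA for the DI and stage
# contrasts with core-gene overlap z statistics, and the model
# discrimination verdict.

#' Classify the migration-proliferation relationship
#'
#' Decision rule over the within-stage correlation results (adjusted
#' p-values): at least one significant and all significant negative ->
#' `MPD`; all significant positive -> `SMP`; none significant -> `PR`;
#' mixed signs among significant results -> `indeterminate`. The pooled
#' overall correlation is deliberately excluded: stage-dependent
#' composition can induce a pooled correlation that no stage exhibits.
#'
#' @param corrs list of `mpd_cor` results (one per stage group).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return one of `"MPD"`, `"SMP"`, `"PR"`, `"indeterminate"`.
#' @export
classify_model <- function(corrs, alpha = 0.05) {
  if (length(corrs) == 0L) stop("classify_model: no correlation results")
  p <- vapply(corrs, function(cr) {
    pa <- cr$p_adj
    if (is.na(pa)) cr$p else pa
  }, numeric(1))
  r <- vapply(corrs, `[[`, numeric(1), "r")
  sig <- p < alpha
  if (!any(sig)) return("PR")
  if (all(r[sig] < 0)) return("MPD")
  if (all(r[sig] > 0)) return("SMP")
  "indeterminate"
}

#' Dominance-shift tests between early and late stages
#'
#' Welch t test on the Dichotomy Index between early- and late-stage
#' samples, and the chi-square independence test on the high/low DI
#' category by stage. The direction is taken from the sign of the mean
#' DI difference when either test reaches p < 0.05: a higher early DI
#' means the late stage has shifted toward migration dominance.
#'
#' @param sig signature table with `di_category` (see [dichotomize_di()]).
#' @param clinical clinical table; stage groups early/late are used.
#' @return list with `t_test`, `chi_square` (both `mpd_test`),
#'   `mean_di_early`, `mean_di_late` and `direction` in
#'   `{"toward_migration", "toward_proliferation", "none"}`.
#' @export
dominance_shift <- function(sig, clinical) {
  stage <- clinical$stage_group[match(sig$sample_id, clinical$sample_id)]
  early <- sig$di[stage == "early"]
  late <- sig$di[stage == "late"]
  if (length(early) == 0L || length(late) == 0L)
    stop("dominance_shift: both early and late groups must be non-empty")
  tt <- independent_t(early, late)
  keep <- stage %in% c("early", "late")
  tab <- table(factor(sig$di_category[keep], levels = c("high", "low")),
               factor(stage[keep], levels = c("early", "late")))
  chi <- chi_square_independence(as.matrix(tab))
  dir <- "none"
  if (min(tt$p, chi$p) < 0.05)
    dir <- if (mean(early) > mean(late)) "toward_migration" else "toward_proliferation"
  list(t_test = tt, chi_square = chi,
       mean_di_early = mean(early), mean_di_late = mean(late),
       direction = dir)
}

.cor_for_group <- function(sig, idx, label, min_group) {
  if (sum(idx) < min_group) {
    warning(sprintf("stage group '%s' has %d sample(s) (< %d); skipped",
                    label, sum(idx), min_group))
    return(NULL)
  }
  tryCatch(pearson_r(sig$prolif_rank[idx], sig$migr_rank[idx]),
           error = function(e) {
             warning(sprintf("stage group '%s' skipped: %s", label,
                             conditionMessage(e)))
             NULL
           })
}

#' Run the full migration-proliferation dichotomy analysis
#'
#' Pipeline: zero-to-one normalisation -> signature scoring and DI ->
#' median dichotomisation -> Pearson correlation between the ranked
#' indices per stage group and overall, BH-adjusted within the cohort ->
#' dominance-shift t and chi-square tests -> optional phenotype-
#' permutation GSEA for the high-vs-low-DI and early-vs-late contrasts
#' with core-gene compilation and overlap z comparisons -> model verdict.
#'
#' @param m raw expression matrix (genes x samples).
#' @param clinical clinical table.
#' @param prolif_set,migr_set [gene_set()]s for the two programmes.
#' @param options list; recognised fields: `alpha` (0.05), `n_perm`
#'   (1000), `seed` (1), `run_gsea` (TRUE), `extra_sets` (additional
#'   gene sets for GSEA), `min_group` (3), `gsea_weight` (1),
#'   `p_thresh` (0.05) and `q_thresh` (0.25) for core compilation.
#' @return object of class `mpd_report`.
#' @export
run_analysis <- function(m, clinical, prolif_set, migr_set, options = list()) {
  opt <- modifyList(list(alpha = 0.05, n_perm = 1000, seed = 1,
                         run_gsea = TRUE, extra_sets = list(),
                         min_group = 3, gsea_weight = 1,
                         p_thresh = 0.05, q_thresh = 0.25), options)
  norm <- zero_one_normalize(m)
  sig <- compute_signature_table(norm, clinical, prolif_set, migr_set)
  sig <- dichotomize_di(sig)
  stage <- clinical$stage_group[match(sig$sample_id, clinical$sample_id)]

  corrs <- list()
  for (g in intersect(.STAGE_LEVELS, unique(stage))) {
    cr <- .cor_for_group(sig, stage == g, g, opt$min_group)
    if (!is.null(cr)) corrs[[g]] <- cr
  }
  overall <- .cor_for_group(sig, rep(TRUE, nrow(sig)), "overall", opt$min_group)
  # BH family: the within-stage rows of one cohort; the pooled overall
  # correlation is reported unadjusted (its p_adj stays NA).
  if (length(corrs)) {
    adj <- bh_adjust(vapply(corrs, `[[`, numeric(1), "p"))
    for (i in seq_along(corrs)) corrs[[i]]$p_adj <- adj[i]
  }

  verdict <- if (length(corrs)) classify_model(corrs, opt$alpha) else "indeterminate"
  dom <- if (all(c("early", "late") %in% stage))
    dominance_shift(sig, clinical) else NULL

  gsea <- NULL
  if (isTRUE(opt$run_gsea)) {
    sets <- c(list(prolif_set, migr_set), opt$extra_sets)
    keep <- stage %in% c("early", "late")
    sub <- norm[, sig$sample_id, drop = FALSE]
    di_lab <- factor(sig$di_category, levels = c("high", "low"))
    res_di <- tryCatch(
      gsea_phenotype(sub, di_lab, sets, n_perm = opt$n_perm,
                     seed = opt$seed, weight = opt$gsea_weight),
      error = function(e) { warning("DI-contrast GSEA skipped: ",
                                    conditionMessage(e)); NULL })
    res_stage <- tryCatch(
      gsea_phenotype(sub[, keep, drop = FALSE],
                     factor(stage[keep], levels = c("early", "late")),
                     sets, n_perm = opt$n_perm, seed = opt$seed + 1L,
                     weight = opt$gsea_weight),
      error = function(e) { warning("stage-contrast GSEA skipped: ",
                                    conditionMessage(e)); NULL })
    gsea <- list(di_contrast = res_di, stage_contrast = res_stage)
    if (!is.null(res_di) && !is.null(res_stage)) {
      cores <- list(
        high_di = core_gene_compilation(res_di, opt$p_thresh, opt$q_thresh, "pos"),
        low_di = core_gene_compilation(res_di, opt$p_thresh, opt$q_thresh, "neg"),
        early = core_gene_compilation(res_stage, opt$p_thresh, opt$q_thresh, "pos"),
        late = core_gene_compilation(res_stage, opt$p_thresh, opt$q_thresh, "neg")
      )
      gsea$cores <- cores
      gsea$overlap_early <- tryCatch(
        core_overlap_comparison(cores$early$core_genes,
                                cores$low_di$core_genes,
                                cores$high_di$core_genes),
        error = function(e) NULL)
      gsea$overlap_late <- tryCatch(
        core_overlap_comparison(cores$late$core_genes,
                                cores$low_di$core_genes,
                                cores$high_di$core_genes),
        error = function(e) NULL)
    }
  }

  structure(list(signature_table = sig,
                 di_threshold = attr(sig, "di_threshold"),
                 correlations = corrs,
                 overall = overall,
                 dominance = dom,
                 gsea = gsea,
                 verdict = verdict,
                 options = opt),
            class = "mpd_report")
}

#' Per-subgroup correlation analysis
#'
#' Computes the ranked-index Pearson correlation within each subgroup
#' (e.g. molecular subtype) with at least `min_n` samples; smaller
#' subgroups are reported as skipped, mirroring the treatment of
#' underpowered subtypes. BH adjustment is applied across the analysed
#' subgroups.
#'
#' @param m raw expression matrix.
#' @param clinical clinical table with a `subgroup` column.
#' @param prolif_set,migr_set [gene_set()]s.
#' @param min_n minimum subgroup size (default 10).
#' @return list with `results` (named list of `mpd_cor`) and `skipped`
#'   (named integer vector of subgroup sizes below the minimum).
#' @export
grouped_analysis <- function(m, clinical, prolif_set, migr_set, min_n = 10) {
  if (!"subgroup" %in% names(clinical) || all(is.na(clinical$subgroup)))
    stop("grouped_analysis: clinical table has no subgroup labels")
  norm <- zero_one_normalize(m)
  sig <- compute_signature_table(norm, clinical, prolif_set, migr_set)
  grp <- clinical$subgroup[match(sig$sample_id, clinical$sample_id)]
  results <- list()
  skipped <- integer(0)
  for (g in sort(unique(grp[!is.na(grp)]))) {
    idx <- !is.na(grp) & grp == g
    if (sum(idx) < min_n) {
      warning(sprintf("subgroup '%s' has %d sample(s) (< %d); skipped",
                      g, sum(idx), min_n))
      skipped[g] <- sum(idx)
      next
    }
    results[[g]] <- pearson_r(sig$prolif_rank[idx], sig$migr_rank[idx])
  }
  if (length(results) == 0L)
    warning("grouped_analysis: no subgroup met the minimum size")
  if (length(results)) {
    adj <- bh_adjust(vapply(results, `[[`, numeric(1), "p"))
    for (i in seq_along(results)) results[[i]]$p_adj <- adj[i]
  }
  list(results = results, skipped = skipped)
}

#' Stage-wise correlation table from a report
#'
#' @param report `mpd_report` from [run_analysis()].
#' @return data.frame with one row per stage group plus the overall row.
#' @export
correlation_table <- function(report) {
  rows <- c(report$correlations,
            if (!is.null(report$overall)) list(overall = report$overall))
  data.frame(group = names(rows),
             n = vapply(rows, `[[`, numeric(1), "n"),
             r = vapply(rows, `[[`, numeric(1), "r"),
             ci_low = vapply(rows, `[[`, numeric(1), "ci_low"),
             ci_high = vapply(rows, `[[`, numeric(1), "ci_high"),
             p = vapply(rows, `[[`, numeric(1), "p"),
             p_adj = vapply(rows, `[[`, numeric(1), "p_adj"),
             row.names = NULL, stringsAsFactors = FALSE)
}

.serializable_report <- function(report) {
  num <- function(x) if (is.null(x)) NULL else unclass(x)
  list(
    verdict = report$verdict,
    di_threshold = report$di_threshold,
    correlations = lapply(report$correlations, num),
    overall = num(report$overall),
    dominance = if (is.null(report$dominance)) NULL else list(
      t_test = num(report$dominance$t_test),
      chi_square = num(report$dominance$chi_square),
      mean_di_early = report$dominance$mean_di_early,
      mean_di_late = report$dominance$mean_di_late,
      direction = report$dominance$direction),
    gsea = if (is.null(report$gsea)) NULL else list(
      di_contrast = if (is.null(report$gsea$di_contrast)) NULL else
        enrichment_table(report$gsea$di_contrast),
      stage_contrast = if (is.null(report$gsea$stage_contrast)) NULL else
        enrichment_table(report$gsea$stage_contrast),
      cores = if (is.null(report$gsea$cores)) NULL else
        lapply(report$gsea$cores, function(x)
          list(total = x$total, core_genes = x$core_genes)),
      overlap_early = num(report$gsea$overlap_early),
      overlap_late = num(report$gsea$overlap_late)),
    signature_table = report$signature_table,
    options = report$options[c("alpha", "n_perm", "seed", "run_gsea",
                               "min_group", "gsea_weight",
                               "p_thresh", "q_thresh")]
  )
}

#' Serialise a report to JSON
#'
#' Deterministic given identical inputs and seed: re-running the
#' analysis and writer produces byte-identical files.
#'
#' @param report `mpd_report` from [run_analysis()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  json <- jsonlite::toJSON(.serializable_report(report), auto_unbox = TRUE,
                           digits = 12, pretty = TRUE, null = "null",
                           na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Write report tables as TSV
#'
#' Emits `correlations.tsv`, `signature_table.tsv` and, when GSEA ran,
#' `gsea_di_contrast.tsv` / `gsea_stage_contrast.tsv` into `dir`.
#'
#' @param report `mpd_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) write.table(df, file.path(dir, name), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  wt(correlation_table(report), "correlations.tsv")
  wt(report$signature_table, "signature_table.tsv")
  if (!is.null(report$gsea$di_contrast))
    wt(enrichment_table(report$gsea$di_contrast), "gsea_di_contrast.tsv")
  if (!is.null(report$gsea$stage_contrast))
    wt(enrichment_table(report$gsea$stage_contrast), "gsea_stage_contrast.tsv")
  invisible(dir)
}
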