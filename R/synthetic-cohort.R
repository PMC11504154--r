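# Latent-factor synthetic cohort generator. Each sample carries a latent
# proliferation activity P and migration activity M drawn from a
# bivariate normal whose correlation rho encodes the competing models
# (dichotomy: rho < 0; simultaneous: rho > 0; phenotype-refractory:
# rho = 0) and whose stage-dependent means encode the dominance shift
# (early: (+delta, -delta); late: (-delta, +delta)). Programme genes load
# linearly on their latent activity with uniform loadings plus Gaussian
# noise; background genes are pure noise.

#' Synthetic cohort configuration
#'
#' @param n_early,n_late samples per stage group, each >= 10.
#' @param rho latent migration-proliferation correlation, `|rho| < 1`.
#' @param delta stage dominance shift in latent SD units, >= 0.
#' @param n_prolif_genes,n_migr_genes programme gene counts, each >= 5;
#'   defaults mirror a 70-gene proliferation signature and the 9 EMT
#'   regulators.
#' @param n_background pure-noise genes, >= 0.
#' @param sigma gene-level noise SD, > 0.
#' @param seed integer RNG seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_early, n_late, rho, delta = 0,
                             n_prolif_genes = 70, n_migr_genes = 9,
                             n_background = 200, sigma = 0.3, seed = 1) {
  if (n_early < 10 || n_late < 10) stop("need >= 10 samples per stage group")
  if (!is.finite(rho) || abs(rho) >= 1) stop("|rho| must be < 1")
  if (delta < 0) stop("delta must be >= 0")
  if (n_prolif_genes < 5 || n_migr_genes < 5) stop("need >= 5 genes per programme")
  if (n_background < 0) stop("n_background must be >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  structure(list(n_early = as.integer(n_early), n_late = as.integer(n_late),
                 rho = rho, delta = delta,
                 n_prolif_genes = as.integer(n_prolif_genes),
                 n_migr_genes = as.integer(n_migr_genes),
                 n_background = as.integer(n_background),
                 sigma = sigma, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic expression cohort
#'
#' @param config a [synthetic_config()].
#' @return list with `matrix` (genes x samples, non-negative), `clinical`
#'   (sample_id / stage_group), `truth` (latent P and M per sample),
#'   `prolif_set` and `migr_set` ([gene_set()]s naming the programme
#'   genes), and the `config` echo. Fully determined by `config$seed`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  ne <- config$n_early; nl <- config$n_late; n <- ne + nl
  stage <- rep(c("early", "late"), c(ne, nl))
  sgn <- ifelse(stage == "early", 1, -1)
  lat <- MASS::mvrnorm(n, mu = c(0, 0),
                       Sigma = matrix(c(1, config$rho, config$rho, 1), 2))
  P <- lat[, 1L] + config$delta * sgn
  M <- lat[, 2L] - config$delta * sgn

  np <- config$n_prolif_genes; nm <- config$n_migr_genes; nb <- config$n_background
  a_p <- runif(np, 0.5, 1.5)
  a_m <- runif(nm, 0.5, 1.5)
  xp <- outer(a_p, P) + matrix(rnorm(np * n, sd = config$sigma), np)
  xm <- outer(a_m, M) + matrix(rnorm(nm * n, sd = config$sigma), nm)
  x <- rbind(xp, xm)
  if (nb > 0) x <- rbind(x, matrix(rnorm(nb * n), nb))
  x <- x - min(x)  # shift to non-negative; downstream min-max is shift-invariant

  pro_ids <- sprintf("PRO_%03d", seq_len(np))
  mig_ids <- sprintf("MIG_%03d", seq_len(nm))
  bg_ids <- if (nb > 0) sprintf("BG_%04d", seq_len(nb)) else character(0)
  rownames(x) <- c(pro_ids, mig_ids, bg_ids)
  colnames(x) <- sprintf("S%04d", seq_len(n))

  list(matrix = x,
       clinical = data.frame(sample_id = colnames(x), stage_group = stage,
                             raw_stage = NA_character_, subgroup = NA_character_,
                             stringsAsFactors = FALSE),
       truth = data.frame(sample_id = colnames(x), P = P, M = M,
                          stringsAsFactors = FALSE),
       prolif_set = gene_set("PROLIF_PROGRAM", pro_ids),
       migr_set = gene_set("MIGR_PROGRAM", mig_ids),
       config = config)
}

#' Named cohort presets
#'
#' Fixed configurations emulating the study conditions: `crc_like`
#' (333 early / 293 late, weak inverse correlation, weak dominance
#' shift), `gc_like` (59 / 382, strong inverse correlation and shift),
#' `null_model` (no correlation, no shift), `smp_like` (positive
#' correlation, simultaneous-programme alternative) and `pr_like`
#' (independent programmes with a composition shift,
#' phenotype-refractory alternative).
#'
#' @param name preset name.
#' @return a [synthetic_config()] with a fixed documented seed.
#' @export
preset <- function(name = c("crc_like", "gc_like", "null_model",
                            "smp_like", "pr_like")) {
  name <- match.arg(name)
  switch(name,
    crc_like = synthetic_config(333, 293, rho = -0.25, delta = 0.2, seed = 101L),
    gc_like = synthetic_config(59, 382, rho = -0.55, delta = 0.5, seed = 102L),
    null_model = synthetic_config(200, 200, rho = 0, delta = 0, seed = 103L),
    smp_like = synthetic_config(200, 200, rho = 0.5, delta = 0, seed = 104L),
    pr_like = synthetic_config(200, 200, rho = 0, delta = 0.5, seed = 105L)
  )
}
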