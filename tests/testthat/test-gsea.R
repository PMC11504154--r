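test_that("signal-to-noise ranking matches direct formula evaluation", {
  # 4 genes x 6 samples, class A = S1..S3
  m <- rbind(
    G1 = c(5, 6, 7, 1, 2, 3),
    G2 = c(1, 1.1, 0.9, 1, 1.05, 0.95),
    G3 = c(0, 0, 0, 4, 5, 6),
    G4 = c(2, 2, 2, 2, 2, 2)
  )
  colnames(m) <- paste0("S", 1:6)
  lab <- factor(rep(c("A", "B"), each = 3), levels = c("A", "B"))
  rk <- rank_by_signal_to_noise(m, lab)
  # independent evaluation of (muA - muB) / (sdA + sdB) with the 0.2 floor
  s2n_hand <- apply(m, 1, function(x) {
    a <- x[1:3]; b <- x[4:6]
    sa <- max(sd(a), 0.2 * abs(mean(a)), 0.2)
    sb <- max(sd(b), 0.2 * abs(mean(b)), 0.2)
    (mean(a) - mean(b)) / (sa + sb)
  })
  expect_identical(rk$gene_ids, names(sort(-s2n_hand)))
  expect_equal(rk$scores, unname(sort(s2n_hand, decreasing = TRUE)))
  # gene high in class A with low noise ranks first
  expect_identical(rk$gene_ids[1], "G1")
})

test_that("swapping phenotype labels negates and reverses the ranking", {
  set.seed(41)
  m <- matrix(abs(rnorm(200 * 10)), 200,
              dimnames = list(sprintf("G%03d", 1:200), paste0("S", 1:10)))
  lab <- rep(c("A", "B"), each = 5)
  r1 <- rank_by_signal_to_noise(m, factor(lab, c("A", "B")))
  r2 <- rank_by_signal_to_noise(m, factor(lab, c("B", "A")))
  s1 <- r1$scores[match(rownames(m), r1$gene_ids)]
  s2 <- r2$scores[match(rownames(m), r2$gene_ids)]
  expect_equal(s1, -s2)
  expect_error(rank_by_signal_to_noise(m[, 1:7], rep(c("A", "B"), c(5, 2))),
               ">= 3")
})

test_that("enrichment score handles the single-gene extremes", {
  ids <- paste0("G", 1:10)
  ranked <- structure(list(gene_ids = ids, scores = seq(5, -4)),
                      class = "ranked_list")
  first <- enrichment_score(ranked, gene_set("TOP", "G1"), weight = 0)
  expect_equal(first$es, 1)
  expect_identical(first$leading_edge, "G1")
  last <- enrichment_score(ranked, gene_set("BOT", "G10"), weight = 0)
  expect_true(last$es < 0)
  expect_equal(last$peak_index, 9)
  expect_identical(last$leading_edge, "G10")
  expect_error(enrichment_score(ranked, gene_set("NONE", "ZZZ")), "overlap")
  expect_error(enrichment_score(ranked, gene_set("ALL", ids)), "entire")
})

test_that("enrichment score equals the brute-force running-sum oracle and terminates at zero", {
  set.seed(42)
  for (i in 1:150) {
    inst <- random_ranked_instance()
    w <- sample(c(0, 1, 2), 1)
    e <- enrichment_score(inst$ranked, inst$set, weight = w)
    expect_equal(e$es, brute_force_es(inst$ranked$scores, inst$hit, w),
                 tolerance = 1e-9)
    expect_lt(abs(e$running_sum[length(e$running_sum)]), 1e-9)
  }
})

test_that("phenotype permutation is deterministic and detects a planted signal", {
  set.seed(43)
  n <- 30
  m <- matrix(abs(rnorm(100 * n)), 100,
              dimnames = list(sprintf("G%03d", 1:100), paste0("S", 1:n)))
  lab <- factor(rep(c("A", "B"), each = 15), c("A", "B"))
  planted <- sprintf("G%03d", 1:10)
  m[planted, lab == "A"] <- m[planted, lab == "A"] + 3
  decoy <- gene_set("DECOY", sprintf("G%03d", 51:60))
  res1 <- gsea_phenotype(m, lab, list(gene_set("PLANTED", planted), decoy),
                         n_perm = 200, seed = 7)
  res2 <- gsea_phenotype(m, lab, list(gene_set("PLANTED", planted), decoy),
                         n_perm = 200, seed = 7)
  expect_identical(res1, res2)
  pl <- res1[[1]]
  expect_lte(pl$p_nominal, 1 / 200)
  expect_gt(pl$nes, 0)
  expect_true(all(pl$leading_edge %in% planted))
  expect_error(gsea_phenotype(m, lab, decoy, n_perm = 50), "n_perm")
})

test_that("nominal p is uniform-calibrated under a label-permuted null", {
  set.seed(44)
  n <- 40
  m <- matrix(abs(rnorm(150 * n)), 150,
              dimnames = list(sprintf("G%03d", 1:150), paste0("S", 1:n)))
  lab <- sample(rep(c("A", "B"), each = 20))  # labels independent of expression
  sets <- lapply(1:50, function(j)
    gene_set(paste0("SET", j), sample(rownames(m), 12)))
  res <- gsea_phenotype(m, lab, sets, n_perm = 200, seed = 9)
  p <- vapply(res, `[[`, numeric(1), "p_nominal")
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("core gene compilation unions the leading edges of passing sets", {
  res <- list(
    fake_enrichment("A", 0.8, 0.001, 0.01, c("G1", "G2")),
    fake_enrichment("B", 0.7, 0.002, 0.05, c("G2", "G3")),
    fake_enrichment("C", 0.9, 0.200, 0.01, c("G9")),    # fails p
    fake_enrichment("D", -0.6, 0.001, 0.50, c("G8"))    # fails q
  )
  cc <- core_gene_compilation(res)
  expect_identical(cc$core_genes, c("G1", "G2", "G3"))
  expect_equal(cc$total, 3L)
  none <- core_gene_compilation(list(fake_enrichment("X", 0.5, 0.9, 0.9, "G1")))
  expect_equal(none$total, 0L)
  # sign restriction
  res2 <- list(fake_enrichment("UP", 0.8, 0.001, 0.01, "G1"),
               fake_enrichment("DN", -0.8, 0.001, 0.01, "G2"))
  expect_identical(core_gene_compilation(res2, sign = "pos")$core_genes, "G1")
  expect_identical(core_gene_compilation(res2, sign = "neg")$core_genes, "G2")
})

test_that("core overlap comparison contrasts shared fractions via the pooled z", {
  ref <- paste0("G", 1:50)
  b <- paste0("G", 26:75)    # |ref ∩ b| = 25, |ref ∪ b| = 75
  c_ <- paste0("G", 46:55)   # |ref ∩ c| = 5, |ref ∪ c| = 55
  z <- core_overlap_comparison(ref, b, c_)
  ind <- two_proportion_z(25, 75, 5, 55)
  expect_equal(z$z, ind$z)
  # identical pairings give z = 0
  z0 <- core_overlap_comparison(ref, b, b)
  expect_equal(z0$z, 0)
})
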