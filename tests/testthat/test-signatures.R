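test_that("geometric mean index matches direct evaluation of the formula", {
  # three genes, values 1/2/4 for one sample: cube root of 8 = 2 at eps = 0
  m <- matrix(c(1, 2, 4), 3, 1, dimnames = list(c("A", "B", "C"), "S1"))
  expect_equal(unname(geometric_mean_index(m, gene_set("GS", c("A", "B", "C")),
                                           pseudocount = 0)), 2)
  # equal values v: pseudocount cancels to within 1e-9
  v <- 0.37
  m2 <- matrix(v, 3, 2, dimnames = list(c("A", "B", "C"), c("S1", "S2")))
  s <- geometric_mean_index(m2, gene_set("GS", c("A", "B", "C")))
  expect_equal(unname(s), c(v, v), tolerance = 1e-9)
  # one zero among k = 2 genes: direct evaluation of the eps formula
  eps <- 1e-6
  m3 <- matrix(c(0, 1), 2, 1, dimnames = list(c("A", "B"), "S1"))
  expected <- sqrt(eps * (1 + eps)) - eps
  expect_equal(unname(geometric_mean_index(m3, gene_set("GS", c("A", "B")), eps)),
               expected)
  expect_equal(expected, 0.000999, tolerance = 1e-3)
})

test_that("signature gene matching enforces coverage, aliases and constant-gene exclusion", {
  m <- matrix(runif(8, 0.1, 1), 4, 2,
              dimnames = list(c("SNAI1", "SNAI2", "TWIST1", "OTHER"),
                              c("S1", "S2")))
  # aliases SNAIL/SLUG resolve; 3/4 genes present passes the 50% bar
  s <- quiet(geometric_mean_index(m, gene_set("EMT", c("SNAIL", "SLUG", "TWIST1", "GLI1"))))
  expect_length(s, 2L)
  # below 50% coverage errors and names the missing genes
  expect_error(geometric_mean_index(m, gene_set("X", c("A", "B", "C", "SNAI1"))),
               "<50%")
  # constant-flagged genes are excluded from scoring
  mm <- rbind(m, CONSTG = c(0.5, 0.5))
  nm <- quiet(zero_one_normalize(mm))
  s_with <- quiet(geometric_mean_index(nm, gene_set("GS", c("SNAI1", "CONSTG"))))
  s_only <- quiet(geometric_mean_index(nm, gene_set("GS2", "SNAI1")))
  expect_equal(unname(s_with), unname(s_only))
})

test_that("geometric mean index is monotone in any component gene", {
  set.seed(21)
  m <- matrix(runif(20), 5, 4,
              dimnames = list(paste0("G", 1:5), paste0("S", 1:4)))
  gs <- gene_set("GS", paste0("G", 1:5))
  base <- geometric_mean_index(m, gs)
  for (i in 1:5) {
    m2 <- m
    m2[i, 2] <- m2[i, 2] + 0.3
    expect_true(geometric_mean_index(m2, gs)[2] >= base[2])
  }
})

test_that("signature table computes ranked indices and DI over the sample intersection", {
  set.seed(22)
  n <- 6
  m <- matrix(runif(4 * n, 0.1, 1), 4, n,
              dimnames = list(c("P1", "P2", "M1", "M2"), paste0("S", 1:n)))
  clin <- data.frame(sample_id = c(paste0("S", 1:(n - 1)), "EXTRA"),
                     stage_group = "early", stringsAsFactors = FALSE)
  tab <- quiet(compute_signature_table(m, clin,
                                       gene_set("P", c("P1", "P2")),
                                       gene_set("M", c("M1", "M2"))))
  # row count equals |samples(matrix) ∩ samples(clinical)|
  expect_equal(nrow(tab), n - 1L)
  expect_equal(tab$di, tab$prolif_rank / tab$migr_rank)
  # hand-checked extremes: top prolif rank 1.0 and bottom migr rank 1/n give di = n
  k <- nrow(tab)
  i_hi <- which(tab$prolif_rank == 1)
  expect_equal(tab$prolif_rank[i_hi], 1)
  expect_equal(max(tab$di), max(tab$prolif_rank / tab$migr_rank))
})

test_that("di equals hand-ranked values on a 3-sample fixture", {
  # indices set by hand through a diagonal matrix construction
  m <- rbind(P1 = c(0.9, 0.5, 0.1), M1 = c(0.1, 0.5, 0.9))
  m <- rbind(m, P2 = m["P1", ], M2 = m["M1", ])
  colnames(m) <- c("S1", "S2", "S3")
  clin <- data.frame(sample_id = colnames(m), stage_group = "early",
                     stringsAsFactors = FALSE)
  tab <- quiet(compute_signature_table(m, clin,
                                       gene_set("P", c("P1", "P2")),
                                       gene_set("M", c("M1", "M2"))))
  # prolif ranks: S1 > S2 > S3 -> (1, 2/3, 1/3); migr reversed
  expect_equal(tab$prolif_rank, c(1, 2 / 3, 1 / 3))
  expect_equal(tab$migr_rank, c(1 / 3, 2 / 3, 1))
  expect_equal(tab$di, c(3, 1, 1 / 3))
})

test_that("di is invariant to rescaling all raw expression values", {
  coh <- generate_cohort(synthetic_config(10, 10, rho = -0.5, seed = 31,
                                          n_background = 10))
  t1 <- quiet(compute_signature_table(quiet(zero_one_normalize(coh$matrix)),
                                      coh$clinical, coh$prolif_set, coh$migr_set))
  t2 <- quiet(compute_signature_table(quiet(zero_one_normalize(coh$matrix * 7.3)),
                                      coh$clinical, coh$prolif_set, coh$migr_set))
  expect_equal(t1$prolif_rank, t2$prolif_rank)
  expect_equal(t1$migr_rank, t2$migr_rank)
  expect_equal(t1$di, t2$di)
})

test_that("median dichotomisation splits DI into high and low", {
  tab <- data.frame(sample_id = paste0("S", 1:4),
                    prolif_index = 1, migr_index = 1,
                    prolif_rank = 1, migr_rank = 1,
                    di = c(0.5, 1, 2, 4), stringsAsFactors = FALSE)
  out <- dichotomize_di(tab)
  expect_identical(out$di_category, c("low", "low", "high", "high"))
  expect_equal(attr(out, "di_threshold"), 1.5)
  out2 <- dichotomize_di(tab[2:3, ])
  expect_identical(out2$di_category, c("low", "high"))
  tab$di <- rep(1, 4)
  expect_warning(out3 <- dichotomize_di(tab), "identical")
  expect_identical(out3$di_category, rep("low", 4))
  expect_error(dichotomize_di(tab[1, ]), "at least 2")
})
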