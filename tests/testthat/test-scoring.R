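test_that("normalization matches a hand-computed median-scale/log1p/z pipeline", {
  counts <- matrix(c(1, 2, 3,
                     4, 5, 6), nrow = 3,
                   dimnames = list(c("a", "b", "c"), c("g1", "g2")))
  ct <- cell_table(c("a", "b", "c"), 1:3, 1:3, counts, c("g1", "g2"))
  z <- normalize_cells(ct)
  # independent arithmetic, gene by gene
  totals <- c(5, 7, 9)
  lg <- log1p(counts / totals * median(totals))
  expected <- apply(lg, 2, function(v) (v - mean(v)) / sd(v))
  expect_equal(z, expected, tolerance = 1e-12)
})

test_that("normalization conventions: constant genes and proportional cells", {
  # cells a and c have proportional counts: identical normalized profiles
  prop <- cell_table(c("a", "c"), 1:2, 1:2,
                     rbind(c(2, 3, 1), c(4, 6, 2)), c("g1", "g2", "g3"))
  zp <- normalize_cells(prop)
  expect_equal(unname(zp[1, ]), unname(zp[2, ]))
  # a truly constant gene after scaling maps to 0
  cg <- cell_table(c("a", "b"), 1:2, 1:2,
                   matrix(c(2, 4, 2, 4), 2), c("g1", "g2"))
  expect_equal(unname(normalize_cells(cg)[, 2]), c(0, 0))
  zero <- cell_table(c("a", "b"), 1:2, 1:2, matrix(c(1, 0, 1, 0), 2),
                     c("g1", "g2"))
  expect_error(normalize_cells(zero), "zero total")
})

test_that("mean-z scores reduce correctly and ignore absent or reordered genes", {
  z <- matrix(rnorm(20), 5, 4,
              dimnames = list(sprintf("c%d", 1:5), c("g1", "g2", "g3", "g4")))
  one <- score_signature(z, gene_signature("DZ", "g2", "DZ_up"))
  expect_equal(unname(one), unname(z[, "g2"]))
  s1 <- score_signature(z, gene_signature("DZ", c("g1", "g3"), "DZ_up"))
  s2 <- suppressMessages(
    score_signature(z, gene_signature("DZ", c("g3", "ABSENT", "g1"), "DZ_up")))
  expect_equal(s1, s2)
  expect_equal(unname(score_signature(matrix(0, 3, 2,
                                             dimnames = list(NULL, c("g1", "g2"))),
                                      gene_signature("DZ", "g1", "DZ_up"))),
               rep(0, 3))
  expect_error(score_signature(z, gene_signature("DZ", "nope", "DZ_up")),
               "no gene of signature")
})

test_that("control-bin scoring is seeded-deterministic and tracks mean-z", {
  sim <- generate_gc(synthetic_config(n_cells = 400, signature_effect = 1.5,
                                      seed = 21))
  z <- normalize_cells(sim$cells)
  s1 <- score_signature(z, sim$signatures$DZ, method = "ctrl_bins", seed = 9)
  s2 <- score_signature(z, sim$signatures$DZ, method = "ctrl_bins", seed = 9)
  expect_identical(s1, s2)
  mz <- score_signature(z, sim$signatures$DZ)
  expect_gt(cor(s1, mz), 0.9)
})

test_that("signature scores separate the true zones on synthetic tissue", {
  sim <- generate_gc(synthetic_config(n_cells = 1000, signature_effect = 1.5,
                                      seed = 23))
  z <- normalize_cells(sim$cells)
  dz_score <- score_signature(z, sim$signatures$DZ)
  dz_true <- sim$truth$true_zone == "DZ"
  tt <- t.test(dz_score[dz_true], dz_score[!dz_true], alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("combined-score classification follows the +/-0.3 thresholds", {
  ann <- classify_cells(dz_score = c(0.8, 0.1, 0.0),
                        lz_score = c(0.3, 0.1, 0.31))
  expect_equal(ann$dzlz_score, c(0.5, 0.0, -0.31))
  expect_equal(ann$phenotype, c("DZ", "INT", "LZ"))
  # boundary values are intermediate (strict inequalities)
  expect_equal(classify_cells(0.3, 0)$phenotype, "INT")
  expect_equal(classify_cells(0, 0.3)$phenotype, "INT")
  expect_error(classify_cells(1, 1, upper = -0.3, lower = 0.3),
               "upper threshold")
  expect_error(classify_cells(1:3, 1:2), "equal length")
  expect_error(classify_cells(NA_real_, 1), "finite")
})

test_that("classification partitions every cell", {
  set.seed(31)
  ann <- classify_cells(rnorm(500), rnorm(500))
  expect_equal(sum(table(factor(ann$phenotype, c("DZ", "LZ", "INT")))), 500)
})

test_that("tertile stratification orders samples and ignores column order", {
  # two genes spanning three samples: dzlz ascending by construction
  expr <- rbind(DZS001 = c(0, 1, 2), LZS001 = c(2, 1, 0))
  colnames(expr) <- c("s1", "s2", "s3")
  dz <- gene_signature("DZ", "DZS001", "DZ_up")
  lz <- gene_signature("LZ", "LZS001", "LZ_up")
  strat <- stratify_bulk(expr, dz, lz)
  expect_equal(strat$group, c("LZ-like", "intermediate", "DZ-like"))
  perm <- stratify_bulk(expr[, c(3, 1, 2)], dz, lz)
  expect_equal(perm$group[match(strat$sample, perm$sample)], strat$group)
  expect_error(stratify_bulk(expr[, 1:2], dz, lz), "at least 3 samples")
})

test_that("bulk stratification recovers latent DZ-like classes", {
  # class 1 sized to the tertile so full recovery is attainable
  cohort <- simulate_bulk_cohort(n_samples = 60, effect = 1,
                                 class_fraction = 1 / 3, seed = 17)
  strat <- stratify_bulk(cohort$expr, cohort$signatures$DZ,
                         cohort$signatures$LZ)
  expect_equal(table(strat$group)[["DZ-like"]], 20)
  expect_gte(mean(strat$group[cohort$class == 1] == "DZ-like"), 0.8)
  km <- stratify_bulk(cohort$expr, cohort$signatures$DZ,
                      cohort$signatures$LZ, rule = "kmeans")
  expect_setequal(unique(km$group),
                  c("DZ-like", "LZ-like", "intermediate"))
})
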