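test_that("median-of-ratios size factors match hand arithmetic", {
  counts <- rbind(g1 = c(2, 4), g2 = c(4, 8))
  colnames(counts) <- c("s1", "s2")
  sf <- size_factors(counts)
  # geometric means 2.83 and 5.66; each sample's ratios are constant
  expect_equal(unname(sf), c(2 / sqrt(8), 4 / sqrt(8)), tolerance = 1e-12)
  expect_equal(prod(sf), 1)   # geometric mean of the factors is 1 here
  same <- cbind(s1 = c(10, 20, 5), s2 = c(10, 20, 5))
  rownames(same) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(same)), c(1, 1))
  zeroy <- rbind(g1 = c(0, 5), g2 = c(5, 0))
  expect_error(size_factors(zeroy), "no gene has nonzero counts")
})

test_that("dispersion estimation recovers the simulated noise regime", {
  set.seed(61)
  n <- 2000
  mu <- rlnorm(n, log(200), 1)
  # Poisson data: method-of-moments dispersions collapse toward the floor
  pois <- two_group_counts(mu, mu, n = 4, alpha = 0, seed = 62)
  d_pois <- estimate_dispersion(pois$counts, pois$design)
  expect_lt(median(d_pois$alpha), 0.01)
  # NB alpha = 0.1: median estimate lands in a factor-2 band at 4 replicates
  nb <- two_group_counts(mu, mu, n = 4, alpha = 0.1, seed = 63)
  d_nb <- estimate_dispersion(nb$counts, nb$design)
  expect_gt(median(d_nb$alpha), 0.05)
  expect_lt(median(d_nb$alpha), 0.2)
  # under-dispersed genes are floored before shrinkage
  flat <- rbind(g1 = c(100, 100, 100, 100, 100, 100),
                g2 = c(80, 120, 100, 90, 110, 100))
  colnames(flat) <- c(paste0("A_r", 1:3), paste0("B_r", 1:3))
  design <- sample_design(colnames(flat), rep(c("A", "B"), each = 3), rep(1:3, 2))
  d_flat <- estimate_dispersion(flat, design)
  expect_equal(d_flat$alpha_mom[1], 1e-8)
  expect_error(estimate_dispersion(flat, sample_design(colnames(flat),
                                                       colnames(flat), rep(1, 6))),
               ">= 2 replicates")
})

test_that("the NB Wald test separates clear effects from noise", {
  counts <- rbind(null_g = c(100, 102, 98, 99, 101, 103),
                  de_g   = c(10, 12, 11, 400, 380, 420),
                  ref1   = c(50, 52, 48, 51, 49, 50),
                  ref2   = c(200, 205, 195, 202, 198, 201))
  colnames(counts) <- c(paste0("A_r", 1:3), paste0("B_r", 1:3))
  design <- sample_design(colnames(counts), rep(c("A", "B"), each = 3), rep(1:3, 2))
  de <- nb_wald_test(counts, design, "A", "B")
  null_row <- de[de$gene_id == "null_g", ]
  expect_lt(abs(null_row$log2_fold_change), 0.1)
  expect_gt(null_row$padj, 0.05)
  de_row <- de[de$gene_id == "de_g", ]
  expect_equal(de_row$log2_fold_change, 5.1, tolerance = 0.05)
  expect_lt(de_row$padj, 1e-6)
})

test_that("the Wald pipeline matches an independent scalar oracle", {
  # oracle: re-derive normalization, dispersion shrinkage inputs and the
  # delta-method statistic from first principles for one gene
  counts <- rbind(g_t = c(120, 95, 110, 60, 45, 55),
                  g_a = c(30, 28, 33, 31, 29, 30),
                  g_b = c(500, 480, 520, 505, 495, 500),
                  g_c = c(80, 85, 75, 82, 78, 80))
  colnames(counts) <- c(paste0("A_r", 1:3), paste0("B_r", 1:3))
  design <- sample_design(colnames(counts), rep(c("A", "B"), each = 3), rep(1:3, 2))
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, design, sf = sf)
  de <- nb_wald_test(counts, design, "A", "B", sf = sf, dispersions = disp)

  norm <- sweep(counts, 2, sf, "/")
  m1 <- mean(norm["g_t", 1:3]); m2 <- mean(norm["g_t", 4:6])
  alpha <- disp$alpha[disp$gene_id == "g_t"]
  v1 <- sum(m1 / sf[1:3] + alpha * m1^2 / sf[1:3]^2) / 9
  v2 <- sum(m2 / sf[4:6] + alpha * m2^2 / sf[4:6]^2) / 9
  se <- sqrt(v1 / m1^2 + v2 / m2^2) / log(2)
  stat <- log2(m2 / m1) / se
  row <- de[de$gene_id == "g_t", ]
  expect_equal(row$log2_fold_change, log2((m2 + 0.5) / (m1 + 0.5)), tolerance = 1e-12)
  expect_equal(row$se, se, tolerance = 1e-12)
  expect_equal(row$stat, stat, tolerance = 1e-12)
  expect_equal(row$p, 2 * pnorm(-abs(stat)), tolerance = 1e-12)
})

test_that("swapping the groups negates fold changes and keeps p-values", {
  fx <- two_group_counts(rlnorm(200, log(100), 1),
                         rlnorm(200, log(100), 1), n = 3, seed = 64)
  ab <- nb_wald_test(fx$counts, fx$design, "A", "B")
  ba <- nb_wald_test(fx$counts, fx$design, "B", "A")
  expect_equal(ba$log2_fold_change, -ab$log2_fold_change)
  expect_equal(ba$p, ab$p)
})

test_that("all-zero genes are untested; one-sided zeros stay finite", {
  counts <- rbind(allzero = rep(0, 6),
                  onesided = c(0, 0, 0, 50, 60, 55),
                  ref = c(100, 110, 90, 100, 105, 95),
                  ref2 = c(20, 22, 18, 21, 19, 20))
  colnames(counts) <- c(paste0("A_r", 1:3), paste0("B_r", 1:3))
  design <- sample_design(colnames(counts), rep(c("A", "B"), each = 3), rep(1:3, 2))
  de <- nb_wald_test(counts, design, "A", "B")
  expect_true(is.na(de$p[de$gene_id == "allzero"]))
  os <- de[de$gene_id == "onesided", ]
  expect_true(is.finite(os$stat))
  expect_lt(os$padj, 0.05)
  expect_gt(os$log2_fold_change, 0)
})

test_that("a monosomic simulation yields overwhelmingly negative on-chromosome DTGs", {
  cfg <- small_config(genes = 400, reps = 4, seed = 65,
                      responding_fraction = 1, triad_fraction = 0)
  ds <- simulate_dataset(cfg, wheat_karyotypes()[c("euploid", "M4B")])
  fpkm <- compute_fpkm(ds$counts, ds$annotation)
  genes <- filter_expressed(fpkm, ds$design)
  de <- nb_wald_test(ds$counts, ds$design, "euploid", "M4B", genes = genes)
  on4B <- de[de$gene_id %in%
               ds$annotation$gene_id[ds$annotation$chromosome == "4B"], ]
  hits <- on4B[on4B$dtg, ]
  expect_gt(nrow(hits), 50)
  expect_gte(mean(hits$log2_fold_change < 0), 0.95)
})

test_that("the DTG chromosome table splits Down and Up by contrast", {
  ann <- suppressWarnings(gene_annotation(paste0("g", 1:4),
                                          c("4B", "4B", "2A", "Un"),
                                          c(0, 1, 2, 3) * 1e6,
                                          c(0, 1, 2, 3) * 1e6 + 1e3))
  de <- tibble::tibble(gene_id = paste0("g", 1:4),
                       log2_fold_change = c(-2, 1.5, -1, 0.5),
                       padj = c(0.01, 0.01, 0.2, 0.01),
                       dtg = c(TRUE, TRUE, FALSE, TRUE))
  tab <- dtg_table(list(m_vs_e = de), ann)
  expect_equal(tab$`4B`[tab$regulation == "Down"], 1)
  expect_equal(tab$`4B`[tab$regulation == "Up"], 1)
  expect_equal(tab$Un[tab$regulation == "Up"], 1)
  expect_equal(tab$total, c(1, 2))
})
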