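dosage_fixture <- function(fpkm_rows, genos = c("M", "E", "T"),
                           doses = c(M = 1, E = 2, T = 3), reps = 3) {
  samples <- paste0(rep(genos, each = reps), "_r", rep(1:reps, length(genos)))
  fpkm <- do.call(rbind, fpkm_rows)
  colnames(fpkm) <- samples
  ann <- gene_annotation(rownames(fpkm), rep("4B", nrow(fpkm)),
                         seq(0, by = 1e6, length.out = nrow(fpkm)),
                         seq(1e4, by = 1e6, length.out = nrow(fpkm)))
  kts <- lapply(genos, function(g) {
    karyotype(g, overrides = data.frame(chromosome = "4B", start = NA,
                                        end = NA, copies = doses[[g]]))
  })
  names(kts) <- genos
  design <- sample_design(samples, rep(genos, each = reps), rep(1:reps, length(genos)))
  list(fpkm = fpkm, ann = ann, kts = kts, design = design)
}

test_that("the per-gene Pearson dosage test matches a brute-force oracle", {
  # one replicate per genotype, dosages 1/2/3, FPKM 10/19/32
  fx <- dosage_fixture(list(g1 = c(10, 19, 32)), reps = 1)
  rec <- dosage_correlation_test(fx$fpkm, fx$design, fx$ann, fx$kts,
                                 genes = "g1")
  x <- c(1, 2, 3); y <- c(10, 19, 32)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_oracle <- r_oracle * sqrt(1 / (1 - r_oracle^2))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 1)
  expect_equal(rec$r, r_oracle, tolerance = 1e-12)
  expect_equal(rec$p, p_oracle, tolerance = 1e-12)
  expect_equal(rec$n_units, 3)
  # and agrees with cor.test as an independent reference
  ct <- cor.test(x, y)
  expect_equal(rec$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(rec$p, ct$p.value, tolerance = 1e-12)
})

test_that("proportional abundance gives r = 1 and degenerate genes are untestable", {
  fx <- dosage_fixture(list(
    prop = rep(c(5, 10, 15), each = 3),     # exactly proportional to dosage
    flat = rep(7, 9)))                      # constant: zero variance
  rec <- dosage_correlation_test(fx$fpkm, fx$design, fx$ann, fx$kts,
                                 genes = c("prop", "flat"))
  expect_equal(rec$r[rec$gene_id == "prop"], 1)
  expect_lt(rec$p[rec$gene_id == "prop"], 0.05)
  expect_false(rec$testable[rec$gene_id == "flat"])
  expect_true(is.na(rec$padj[rec$gene_id == "flat"]))
  # genes on an unvaried chromosome have constant dosage -> untestable
  ann2 <- fx$ann; ann2$chromosome <- "5A"
  ann2 <- gene_annotation(ann2$gene_id, ann2$chromosome, ann2$start, ann2$end)
  rec2 <- dosage_correlation_test(fx$fpkm, fx$design, ann2, fx$kts,
                                  genes = c("prop", "flat"))
  expect_false(any(rec2$testable))
})

test_that("BH adjustment agrees with a brute-force step-up oracle", {
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p)
    crit <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(crit)))
    out <- numeric(m); out[o] <- pmin(adj, 1)
    out
  }
  set.seed(31)
  for (m in c(1, 10, 137, 1000)) {
    p <- runif(m)^2
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
    # step-up decision set: genes with adjusted p <= alpha are exactly the
    # largest k with p_(k) <= alpha * k / m
    alpha <- 0.05
    k <- max(c(0, which(sort(p) <= alpha * seq_len(m) / m)))
    expect_equal(sum(p.adjust(p, "BH") <= alpha), k)
  }
})

test_that("the positively-correlated fraction counts r > 0 at FDR", {
  rec <- tibble::tibble(gene_id = paste0("g", 1:5),
                        chromosome = c(rep("4B", 4), "2A"),
                        r = c(0.9, 0.8, 0.85, -0.9, 0.9),
                        p = c(0.005, 0.1, 0.015, 0.02, 0.001),
                        padj = c(0.01, 0.2, 0.03, 0.04, 0.002),
                        n_units = 9, testable = TRUE)
  fr <- dosage_correlated_fraction(rec, chromosome = "4B")
  expect_equal(fr$n_tested, 4)
  expect_equal(fr$n_correlated, 2)   # g4 significant but negative
  expect_equal(fr$fraction, 0.5)
  rec$r[4] <- 0.7
  expect_equal(dosage_correlated_fraction(rec, chromosome = "4B")$fraction,
               0.75)
  expect_error(dosage_correlated_fraction(rec, chromosome = "6D"), "no testable")
})

test_that("a null simulation keeps the FDR-positive fraction near or below the nominal level", {
  fracs <- sapply(1:20, function(s) {
    cfg <- simulation_config(chromosomes = c("4A", "4B", "4D"),
                             genes_per_chromosome = 120,
                             responding_fraction = 0, triad_fraction = 0,
                             replicates_per_genotype = 3, seed = 100 + s)
    ds <- simulate_dataset(cfg, wheat_karyotypes()[c("euploid", "M4B", "Tri4B")])
    fpkm <- compute_fpkm(ds$counts, ds$annotation)
    rec <- dosage_correlation_test(fpkm, ds$design, ds$annotation, ds$karyotypes)
    on4B <- rec[rec$chromosome == "4B" & rec$testable, ]
    mean(on4B$padj < 0.05 & on4B$r > 0)
  })
  expect_lte(mean(fracs), 0.05)
})

test_that("detection power grows with replicate number", {
  power_at <- function(reps) {
    cfg <- simulation_config(chromosomes = c("4A", "4B", "4D"),
                             genes_per_chromosome = 100,
                             responding_fraction = 1, triad_fraction = 0,
                             dispersion = 0.3, replicates_per_genotype = reps,
                             seed = 77)
    ds <- simulate_dataset(cfg, wheat_karyotypes()[c("euploid", "M4B", "Tri4B")])
    fpkm <- compute_fpkm(ds$counts, ds$annotation)
    rec <- dosage_correlation_test(fpkm, ds$design, ds$annotation, ds$karyotypes)
    dosage_correlated_fraction(rec, chromosome = "4B")$fraction
  }
  expect_gt(power_at(6), power_at(2))
})
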