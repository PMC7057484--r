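make_profile_fixture <- function() {
  ann <- gene_annotation(paste0("g", 1:3), rep("4B", 3),
                         c(0, 1e6, 2e6), c(1e4, 1.01e6, 2.01e6))
  fpkm <- rbind(g1 = c(15, 15, 10, 10),
                g2 = c(10, 10, 10, 10),
                g3 = c(20, 20, 10, 10))
  colnames(fpkm) <- c("T_r1", "T_r2", "E_r1", "E_r2")
  design <- sample_design(colnames(fpkm), rep(c("Tri", "eu"), each = 2),
                          rep(1:2, 2))
  list(ann = ann, fpkm = fpkm, design = design)
}

test_that("log2 ratios of genotype-averaged FPKM are computed per gene", {
  fx <- make_profile_fixture()
  prof <- log2_ratio_profile(fx$fpkm, fx$design, fx$ann, "Tri", "eu")
  expect_equal(prof$log2_ratio, c(log2(1.5), 0, 1), tolerance = 1e-12)
  expect_equal(prof$position, c(5e3, 1.005e6, 2.005e6))
  # antisymmetry: swapping the genotypes negates every ratio
  rev <- log2_ratio_profile(fx$fpkm, fx$design, fx$ann, "eu", "Tri")
  expect_equal(rev$log2_ratio, -prof$log2_ratio)
  expect_error(log2_ratio_profile(fx$fpkm, fx$design, fx$ann, "nope", "eu"),
               "unknown genotype")
})

test_that("zero-mean genes are excluded from the ratio and counted", {
  fx <- make_profile_fixture()
  fpkm <- fx$fpkm
  fpkm["g2", c("E_r1", "E_r2")] <- 0   # denominator zero
  prof <- log2_ratio_profile(fpkm, fx$design, fx$ann, "Tri", "eu")
  expect_equal(prof$gene_id, c("g1", "g3"))
  expect_equal(attr(prof, "dropped"), 1)
})

test_that("tri-cube local regression is exact on constants and lines", {
  set.seed(8)
  x <- sort(runif(60, 0, 1e6))
  prof_c <- tibble::tibble(chromosome = "4B", position = x,
                           log2_ratio = rep(0.7, 60))
  expect_equal(loess_smooth(prof_c, span = 0.3)$smoothed, rep(0.7, 60))
  prof_l <- tibble::tibble(chromosome = "4B", position = x,
                           log2_ratio = 2 + 3e-6 * x)
  sm <- loess_smooth(prof_l, span = 1)
  expect_equal(sm$smoothed, prof_l$log2_ratio, tolerance = 1e-8)
})

test_that("smoothed values match a brute-force tri-cube WLS oracle", {
  # independent oracle: per evaluation point, explicit normal-equations solve
  oracle <- function(x, y, span, degree) {
    n <- length(x); q <- max(degree + 1, min(n, floor(span * n)))
    sapply(seq_along(x), function(k) {
      d <- abs(x - x[k]); h <- sort(d)[q]
      if (h == 0) return(mean(y[d == 0]))
      w <- ifelse(d < h, (1 - (d / h)^3)^3, 0)
      use <- w > 0
      X <- outer(x[use] - x[k], 0:degree, `^`)
      beta <- solve(t(X) %*% (w[use] * X), t(X) %*% (w[use] * y[use]))
      beta[1]
    })
  }
  set.seed(13)
  x <- sort(runif(50, 0, 100))
  y <- sin(x / 12) + rnorm(50, 0, 0.25)
  prof <- tibble::tibble(chromosome = "2A", position = x, log2_ratio = y)
  for (span in c(0.1, 0.3, 0.8)) {
    for (degree in 1:2) {
      sm <- loess_smooth(prof, span = span, degree = degree)
      expect_equal(sm$smoothed, oracle(x, y, span, degree), tolerance = 1e-6)
    }
  }
})

test_that("at span 1 the fit agrees with stats::loess on its exact surface", {
  set.seed(14)
  x <- sort(runif(80, 0, 1))
  y <- cos(4 * x) + rnorm(80, 0, 0.2)
  prof <- tibble::tibble(chromosome = "1A", position = x, log2_ratio = y)
  ours <- loess_smooth(prof, span = 1, degree = 2)$smoothed
  ref <- fitted(stats::loess(y ~ x, span = 1, degree = 2,
                             surface = "direct", family = "gaussian"))
  expect_equal(ours, unname(ref), tolerance = 1e-6)
})

test_that("degree-1 smoothing of an interior-dense profile stays within the data range", {
  set.seed(15)
  x <- sort(runif(200, 0, 1e6))
  y <- rnorm(200, sin(x / 2e5), 0.3)
  prof <- tibble::tibble(chromosome = "7B", position = x, log2_ratio = y)
  sm <- loess_smooth(prof, span = 0.2, degree = 1)
  expect_true(all(sm$smoothed >= min(y) & sm$smoothed <= max(y)))
})

test_that("short chromosomes fall back to a global polynomial with a warning", {
  prof <- tibble::tibble(chromosome = "5D", position = c(1, 2, 3, 4),
                         log2_ratio = c(1, 2, 3, 4))
  expect_warning(sm <- loess_smooth(prof, span = 0.5), "falling back")
  expect_equal(sm$smoothed, prof$log2_ratio, tolerance = 1e-8)
})

test_that("region summaries report median and mean over member genes", {
  prof <- tibble::tibble(chromosome = "4B",
                         position = c(10, 20, 30),
                         log2_ratio = c(-1.1, -1.0, -0.9))
  rs <- region_summary(prof, "4B")
  expect_equal(rs$median_log2_ratio, -1)
  expect_equal(rs$n_genes, 3)
  expect_equal(region_summary(prof, "4B", start = 15, end = 35)$median_log2_ratio,
               -0.95)
  expect_equal(region_summary(prof, "4B", start = 15, end = 35,
                              invert = TRUE)$median_log2_ratio, -1.1)
  expect_error(region_summary(prof, "6A"), "no genes")
})
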