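triad_fixture <- function(a, b, d, genos = c("euploid", "M4B"), reps = 2,
                          jitter = 0) {
  # one triad whose member FPKM per genotype is given as named vectors
  samples <- paste0(rep(genos, each = reps), "_r", rep(1:reps, length(genos)))
  per_gene <- function(v) {
    vals <- rep(v[genos], each = reps)
    if (jitter > 0) vals <- vals * exp(rnorm(length(vals), 0, jitter))
    vals
  }
  fpkm <- rbind(gA = per_gene(a), gB = per_gene(b), gD = per_gene(d))
  colnames(fpkm) <- samples
  list(fpkm = fpkm,
       triads = triad_catalog("t1", "gA", "gB", "gD"),
       design = sample_design(samples, rep(genos, each = reps),
                              rep(1:reps, length(genos))))
}

test_that("triad totals and relative contributions are per-genotype", {
  fx <- triad_fixture(a = c(euploid = 2, M4B = 2),
                      b = c(euploid = 3, M4B = 1.5),
                      d = c(euploid = 5, M4B = 5))
  te <- triad_expression(fx$fpkm, fx$triads, fx$design)
  expect_equal(unname(te$genotype_totals["t1", ]), c(10, 8.5))
  eu <- te$contributions[te$contributions$genotype == "euploid", ]
  expect_equal(c(eu$a, eu$b, eu$d), c(0.2, 0.3, 0.5))
  expect_equal(eu$a + eu$b + eu$d, 1, tolerance = 1e-9)
  expect_true(te$expressed["t1"])
})

test_that("the expressed rule uses the euploid summed FPKM, strictly above threshold", {
  low <- triad_fixture(a = c(euploid = 0.2, M4B = 5),
                       b = c(euploid = 0.3, M4B = 5),
                       d = c(euploid = 0.4, M4B = 5))
  te <- triad_expression(low$fpkm, low$triads, low$design)
  expect_false(te$expressed["t1"])   # 0.9 <= 1 in the euploid reference
  # members missing from the matrix count as zero, with a warning
  fx <- triad_fixture(a = c(euploid = 2, M4B = 2),
                      b = c(euploid = 3, M4B = 3),
                      d = c(euploid = 5, M4B = 5))
  expect_warning(te2 <- triad_expression(fx$fpkm[c("gA", "gB"), ], fx$triads,
                                         fx$design), "absent")
  expect_equal(unname(te2$genotype_totals["t1", "euploid"]), 5)
})

test_that("passive buffering shrinks the triad total by the member's share", {
  # balanced triad, cis member halved: total x 5/6, log2 ~ -0.263
  fx <- triad_fixture(a = c(euploid = 10, M4B = 10),
                      b = c(euploid = 10, M4B = 5),
                      d = c(euploid = 10, M4B = 10))
  te <- triad_expression(fx$fpkm, fx$triads, fx$design)
  ratio <- te$genotype_totals["t1", "M4B"] / te$genotype_totals["t1", "euploid"]
  expect_equal(ratio, 2.5 / 3)
  expect_equal(log2(ratio), -0.263, tolerance = 0.002)
  # the total is always buffered relative to the member's own change
  for (dose in c(1, 3, 4)) {
    member_ratio <- dose / 2
    total_ratio <- (2 + member_ratio) / 3
    expect_lt(abs(log2(total_ratio)), abs(log2(member_ratio)))
  }
})

test_that("ternary classification assigns the nearest of seven centroids", {
  cl <- classify_bias(1 / 3, 1 / 3, 1 / 3)
  expect_equal(as.character(cl$category), "balanced")
  expect_equal(cl$dist_balanced, 0)
  expect_equal(as.character(classify_bias(0.9, 0.05, 0.05)$category),
               "A-dominant")
  # hand-computed: (0.1, 0.45, 0.45) is 0.122 from A-suppressed, 0.285 from balanced
  cl2 <- classify_bias(0.1, 0.45, 0.45)
  expect_equal(as.character(cl2$category), "A-suppressed")
  expect_equal(cl2$dist_A_suppressed, sqrt(0.1^2 + 2 * 0.05^2), tolerance = 1e-12)
  expect_equal(cl2$dist_balanced,
               sqrt((0.1 - 1/3)^2 + 2 * (0.45 - 1/3)^2), tolerance = 1e-12)
  expect_error(classify_bias(0.5, 0.4, 0.3), "sum to 1")
})

test_that("exact centroid ties resolve in the fixed category order", {
  # (3/4, 1/4, 0) is equidistant from A-dominant (1,0,0) and D-suppressed
  # (1/2,1/2,0); the fixed order picks A-dominant
  cl <- classify_bias(0.75, 0.25, 0)
  expect_equal(cl$dist_A_dominant, cl$dist_D_suppressed)
  expect_equal(as.character(cl$category), "A-dominant")
})

test_that("relabeling subgenomes permutes categories and preserves distances", {
  set.seed(91)
  raw <- matrix(rexp(300), ncol = 3)
  P <- raw / rowSums(raw)
  ab <- classify_bias(P[, 1], P[, 2], P[, 3])
  ba <- classify_bias(P[, 2], P[, 1], P[, 3])   # swap A and B
  swap <- c(balanced = "balanced",
            `A-dominant` = "B-dominant", `B-dominant` = "A-dominant",
            `D-dominant` = "D-dominant",
            `A-suppressed` = "B-suppressed", `B-suppressed` = "A-suppressed",
            `D-suppressed` = "D-suppressed")
  expect_equal(as.character(ba$category),
               unname(swap[as.character(ab$category)]))
  expect_equal(ba$dist_A_dominant, ab$dist_B_dominant)
  expect_equal(ba$dist_balanced, ab$dist_balanced)
  expect_equal(sort(as.matrix(ab[-1])), sort(as.matrix(ba[-1])))
})

test_that("the triad ANOVA matches a hand-computed F and stats::anova", {
  fx <- triad_fixture(a = c(E = 0.5, M = 1.5, T = 2.5),
                      b = c(E = 0.25, M = 0.75, T = 1.25),
                      d = c(E = 0.25, M = 0.75, T = 1.25),
                      genos = c("E", "M", "T"), reps = 2)
  # scale columns so the per-replicate totals become [1,2], [3,4], [5,6]
  fx$fpkm[, ] <- fx$fpkm * rep(c(1, 2, 1, 4/3, 1, 1.2), each = 3)
  te <- triad_expression(fx$fpkm, fx$triads, fx$design, euploid = "E")
  expect_equal(unname(te$totals["t1", ]), c(1, 2, 3, 4, 5, 6))
  res <- dtt_test(te, genotypes = c("E", "M", "T"))
  expect_equal(res$f, 16)
  expect_equal(res$p, pf(16, 2, 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$p, 0.0251, tolerance = 1e-3)
  # independent reference: anova on lm
  ref <- anova(lm(y ~ g, data = data.frame(y = c(1, 2, 3, 4, 5, 6),
                                           g = rep(c("E", "M", "T"), each = 2))))
  expect_equal(res$f, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("identical group means with residual noise give F near 0, p near 1", {
  fx <- triad_fixture(a = c(E = 1, M = 1), b = c(E = 1, M = 1),
                      d = c(E = 1, M = 1), genos = c("E", "M"), reps = 3)
  fx$fpkm <- fx$fpkm * rep(c(0.9, 1.0, 1.1, 0.9, 1.0, 1.1), each = 3)
  te <- triad_expression(fx$fpkm, fx$triads, fx$design, euploid = "E")
  res <- dtt_test(te, genotypes = c("E", "M"))
  expect_lt(res$f, 1e-10)
  expect_gt(res$p, 0.999)
  # zero within-group variance everywhere: untestable
  fx2 <- triad_fixture(a = c(E = 1, M = 1), b = c(E = 1, M = 1),
                       d = c(E = 1, M = 1), genos = c("E", "M"), reps = 3)
  te2 <- triad_expression(fx2$fpkm, fx2$triads, fx2$design, euploid = "E")
  res2 <- dtt_test(te2, genotypes = c("E", "M"))
  expect_true(is.na(res2$p))
})

test_that("the buffering report contrasts DTG-rich with DTT-poor regions", {
  cfg <- small_config(genes = 150, reps = 3, seed = 92,
                      responding_fraction = 1, triad_fraction = 1,
                      triad_member_sdlog = 0)
  ds <- simulate_dataset(cfg, wheat_karyotypes()[c("euploid", "M4B")])
  fpkm <- compute_fpkm(ds$counts, ds$annotation)
  genes <- filter_expressed(fpkm, ds$design)
  de <- nb_wald_test(ds$counts, ds$design, "euploid", "M4B", genes = genes)
  te <- triad_expression(fpkm, ds$triads, ds$design)
  dtt <- dtt_test(te, genotypes = c("euploid", "M4B"))
  rep_ <- buffering_report(te, de, dtt, ds$annotation, chromosome = "4B")
  expect_gt(rep_$summary$dtg_fraction, rep_$summary$dtt_fraction)
  expect_equal(rep_$summary$n_expressed_triads,
               sum(te$expressed[ds$triads$triad_id[
                 substr(ds$triads$B, 2, 3) == "4B"]]))
  expect_setequal(rep_$contrib_comparison$group, c("DTT", "non-DTT"))
})
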