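test_that("expected counts are proportional and conserved across regions", {
  expect_equal(expected_count(100, 50, 200), 25)
  expect_equal(expected_count(0, 50, 200), 0)
  # per-region gene counts printed for the stress-gene analysis
  expect_equal(expected_count(3031, 7554, 33801), 3031 * 7554 / 33801,
               tolerance = 1e-12)
  expect_error(expected_count(10, 5, 0), "zero")
  expect_error(expected_count(300, 50, 200), "obs")
  # conservation: regions partitioning TOT conserve OBS
  regs <- c(7554, 6466, 19781)
  expect_equal(sum(expected_count(3031, regs, sum(regs))), 3031,
               tolerance = 1e-9)
})

test_that("chi-square matches the 2x2 closed form and stats::chisq.test", {
  m <- rbind(c(20, 10), c(10, 20))
  closed <- function(m, correct) {
    n <- sum(m)
    d <- abs(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
    if (correct) d <- max(0, d - n / 2)
    n * d^2 / prod(rowSums(m), colSums(m))
  }
  expect_equal(chi_square_test(m, yates = FALSE)$statistic, closed(m, FALSE),
               tolerance = 1e-12)
  expect_equal(chi_square_test(m, yates = TRUE)$statistic, closed(m, TRUE),
               tolerance = 1e-12)
  expect_equal(chi_square_test(m, yates = FALSE)$statistic, 20 / 3,
               tolerance = 1e-9)
  expect_equal(chi_square_test(m, yates = TRUE)$statistic, 5.4,
               tolerance = 1e-9)
  # no deviation -> 0 / p = 1
  flat <- rbind(c(10, 10), c(10, 10))
  expect_equal(chi_square_test(flat)$statistic, 0)
  expect_equal(chi_square_test(flat)$p_value, 1)
  # randomized tables against the reference implementation
  withr::local_seed(4)
  for (i in 1:25) {
    m <- matrix(sample(5:60, 4), 2)
    ours <- chi_square_test(m)  # Yates by default for 2x2
    ref <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    m3 <- matrix(sample(5:60, 9), 3)
    ours <- chi_square_test(m3)
    ref <- suppressWarnings(stats::chisq.test(m3))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter))
    # goodness of fit
    o <- sample(5:50, 4); e <- sum(o) * c(0.1, 0.2, 0.3, 0.4)
    ours <- chi_square_test(o, e)
    ref <- suppressWarnings(stats::chisq.test(o, p = c(.1, .2, .3, .4)))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
  expect_error(chi_square_test(c(1, 2), c(0, 3)), "expected cell")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, m = 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, m = 10), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.9), m = 1), c(0.2, 0.9))
  expect_error(bonferroni_adjust(1.5), "\\[0, 1\\]")
})

test_that("Mann-Whitney U matches exact enumeration and wilcox.test", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2/20 rank splits as extreme
  # identical multisets: p = 1, and swapping a/b leaves p unchanged
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  withr::local_seed(6)
  a <- rnorm(10); b <- rnorm(12, 0.5)
  expect_equal(mann_whitney_u(a, b)$p_value, mann_whitney_u(b, a)$p_value)
  # against the reference continuity-corrected normal approximation (ties)
  x <- c(1, 2, 2, 3, 5, 5, 5, 8); y <- c(2, 3, 3, 4, 5, 9, 9)
  ours <- mann_whitney_u(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                             exact = FALSE))
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  # against exact enumeration without ties
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8, 0.8)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(mann_whitney_u(a, b)$p_value, ref$p.value,
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("compartment category enrichment: folds, pairwise tests, conservation", {
  withr::local_seed(10)
  labels <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:3000),
    compartment = sample(c("RR", "INT", "RP"), 3000, TRUE,
                         prob = c(0.2, 0.2, 0.6)))
  # a category present only in RP
  rp_only <- labels$gene_id[labels$compartment == "RP"][1:60]
  assignments <- dplyr::bind_rows(
    tibble::tibble(gene_id = rp_only, category = "rp_marker"),
    tibble::tibble(gene_id = sample(labels$gene_id, 600), category = "flat"))
  enr <- compartment_category_enrichment(labels, assignments)
  counts <- enr$counts
  rp_fold <- counts$fold[counts$category == "rp_marker" &
                           counts$compartment == "RP"]
  rr_fold <- counts$fold[counts$category == "rp_marker" &
                           counts$compartment == "RR"]
  expect_gt(rp_fold, 1)
  expect_equal(rr_fold, 0)
  # proportionally distributed category: folds ~ 1, no significant pair
  flat <- dplyr::filter(enr$tests, category == "flat")
  expect_true(all(flat$p_value > 0.05))
  # conservation of expected counts per category
  per_cat <- dplyr::summarise(
    dplyr::group_by(counts, category),
    tot_exp = sum(expected), tot_obs = sum(observed))
  expect_equal(per_cat$tot_exp, per_cat$tot_obs, tolerance = 1e-9)
  expect_s3_class(tidy(enr), "tbl_df")
  # te_gene and EXCLUDED rows are dropped before counting
  labels2 <- dplyr::mutate(labels, te_gene = FALSE)
  labels2$te_gene[1:10] <- TRUE
  enr2 <- compartment_category_enrichment(labels2, assignments)
  expect_equal(enr2$total_genes, 2990)
})

test_that("consensus/status table counts genes with upstream copies", {
  genes <- mk_genes(c(5000, 15000, 25000), c(6000, 16000, 26000),
                    id = c("up1", "st1", "st2"))
  reps <- mk_repeats(c(4500, 14500, 4000), c(4600, 14600, 4100),
                     id = c("ra", "rb", "rc"), consensus = "consX")
  de <- tibble::tibble(gene_id = c("up1", "st1", "st2"),
                       comparison = "dpa17_dpa52",
                       status = c("up", "stable", "stable"))
  tab <- consensus_status_table(genes, reps, de)
  # two copies upstream of up1 still count the gene once
  expect_equal(tab$observed[tab$status == "up"], 1)
  expect_equal(tab$observed[tab$status == "stable"], 1)
  # expression filter: n_expressed counts RPKM > 0 at the later stage
  expr <- tibble::tibble(gene_id = c("up1", "st1", "st2"), leaf = 1,
                         dpa17 = 1, dpa39 = 1, dpa42 = 1,
                         dpa52 = c(5, 0, 0))
  tab <- consensus_status_table(genes, reps, de, expr)
  expect_equal(tab$n_expressed[tab$status == "up"], 1)
  expect_equal(tab$n_expressed[tab$status == "stable"], 0)
})

test_that("THEO is the contingency expectation and filters apply jointly", {
  # 50-copy consensus against 100/100/800 status margins
  tab <- tibble::tibble(
    consensus_id = rep(c("A", "B"), each = 3),
    status = rep(c("up", "down", "stable"), 2),
    observed = c(20L, 5L, 25L, 80L, 95L, 775L),
    n_expressed = c(20L, 5L, 25L, 80L, 95L, 775L))
  out <- consensus_de_enrichment(tab)
  a_up <- out[out$consensus_id == "A" & out$status == "up", ]
  expect_equal(a_up$theo, 50 * 100 / 1000)
  expect_equal(a_up$fold, 4)
  expect_equal(a_up$fold_bin, factor("2.5-6", c("1-2.5", "2.5-6", "6-9")))
  # THEO conservation: sum of expected cells = grand total
  expect_equal(sum(out$theo), sum(tab$observed), tolerance = 1e-9)
  expect_true(a_up$passes_filters)
  # min_genes filter defeats a strong but sparse enrichment
  out <- consensus_de_enrichment(
    dplyr::mutate(tab, n_expressed = c(8L, 5L, 25L, 80L, 95L, 775L)))
  expect_false(out$passes_filters[out$consensus_id == "A" &
                                    out$status == "up"])
  # fold filter
  out <- consensus_de_enrichment(tab, filters = list(min_genes = 10,
                                                     min_fold = 5,
                                                     max_p = 0.001))
  expect_false(any(out$passes_filters))
  expect_error(consensus_de_enrichment(dplyr::mutate(tab, observed = 0L)),
               "empty")
})

test_that("random placement null converges to the analytic overlap probability", {
  kary <- karyotype("chr1", 100000)
  # footprint covering 50% of the chromosome
  fp <- tibble::tibble(chrom = "chr1", start = seq(0, 99000, by = 2000))
  fp$end <- fp$start + 1000
  q <- tibble::tibble(id = sprintf("q%d", 1:200), chrom = "chr1",
                      start = seq(10, 99000, length.out = 200))
  q$end <- q$start + 1
  ana <- random_placement_expectation(q, fp, kary, mode = "analytic")
  expect_equal(ana$expected_fraction, 0.5, tolerance = 0.01)
  mc <- random_placement_expectation(q, fp, kary, n_shuffles = 400, seed = 2)
  expect_equal(mc$expected_fraction, ana$expected_fraction,
               tolerance = 2 / sqrt(400))
  # determinism
  mc2 <- random_placement_expectation(q, fp, kary, n_shuffles = 400, seed = 2)
  expect_identical(mc, mc2)
  # degenerate cases
  whole <- tibble::tibble(chrom = "chr1", start = 0, end = 100000)
  expect_equal(random_placement_expectation(q, whole, kary,
                                            n_shuffles = 100,
                                            seed = 1)$expected_fraction, 1)
  long <- tibble::tibble(id = "x", chrom = "chr1", start = 0, end = 100000)
  expect_error(random_placement_expectation(
    dplyr::mutate(long, end = 2e5), fp, kary), "exceeds length")
})
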