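test_that("TE-gene flagging uses strict >50% CDS footprint coverage", {
  # 300 bp CDS, 200 bp covered -> 0.667, flagged
  g <- mk_genes(0, 1000, cds = list(tibble::tibble(start = 0, end = 300)))
  r <- mk_repeats(0, 200)
  out <- flag_te_genes(g, r)
  expect_equal(out$cds_te_coverage, 2 / 3, tolerance = 1e-12)
  expect_true(out$te_gene)
  # exactly 50% is NOT flagged
  out <- flag_te_genes(g, mk_repeats(0, 150))
  expect_false(out$te_gene)
  # two repeats over the same bases count once
  out <- flag_te_genes(g, mk_repeats(c(0, 0), c(100, 100), id = c("a", "b")))
  expect_equal(out$cds_te_coverage, 1 / 3, tolerance = 1e-12)
  # only high-confidence repeats count
  out <- flag_te_genes(g, mk_repeats(0, 300, hc = FALSE))
  expect_equal(out$cds_te_coverage, 0)
  # a gene without CDS is a contract violation
  g$cds <- list(tibble::tibble(start = numeric(0), end = numeric(0)))
  expect_error(flag_te_genes(g, r), "no CDS")
})

test_that("closest_repeat is strand-aware with gap distances and tie-breaks", {
  g <- mk_genes(1000, 2000)
  r <- mk_repeats(c(100, 2500), c(200, 2600), id = c("r1", "r2"))
  up <- closest_repeat(g, r, "upstream")
  expect_equal(c(up$repeat_id, up$distance), c("r1", "800"))
  down <- closest_repeat(g, r, "downstream")
  expect_equal(c(down$repeat_id, down$distance), c("r2", "500"))
  # minus strand flips the sides
  g$strand <- "-"
  expect_equal(closest_repeat(g, r, "upstream")$repeat_id, "r2")
  expect_equal(closest_repeat(g, r, "downstream")$repeat_id, "r1")
  # bookended repeat: distance 0, not overlapping
  g$strand <- "+"
  ab <- closest_repeat(g, mk_repeats(2000, 2100), "downstream")
  expect_equal(ab$distance, 0)
  # overlapping repeats are excluded by default, distance-0 partners otherwise
  ov <- mk_repeats(1500, 1600)
  expect_true(is.na(closest_repeat(g, ov, "upstream")$repeat_id))
  expect_equal(closest_repeat(g, ov, "upstream",
                              ignore_overlapping = FALSE)$distance, 0)
  # equidistant partners resolve to the smaller start coordinate
  tie <- mk_repeats(c(700, 700), c(900, 900), id = c("tb", "ta"))
  expect_equal(closest_repeat(g, tie, "upstream")$repeat_id, "tb")
})

test_that("gene configuration window is strict and classes are exclusive", {
  g <- mk_genes(5000, 8000,
                cds = list(tibble::tibble(start = c(5000, 6000),
                                          end = c(5500, 6500))))
  # repeat at exactly 1000 bp is outside the window
  expect_equal(classify_gene_configuration(
    g, mk_repeats(3800, 4000))$config, "no_repeat")
  expect_equal(classify_gene_configuration(
    g, mk_repeats(3801, 4001))$config, "upstream_only")
  # intron of this gene is [5500, 6000)
  expect_equal(classify_gene_configuration(
    g, mk_repeats(5600, 5700))$config, "intronic_only")
  # upstream AND intronic -> multiple
  expect_equal(classify_gene_configuration(
    g, mk_repeats(c(4500, 5600), c(4600, 5700), id = c("u", "i")))$config,
    "multiple")
  # exon-only overlap counts for no class
  expect_equal(classify_gene_configuration(
    g, mk_repeats(5100, 5200))$config, "no_repeat")
})

test_that("repeat methylation is per-context, half-open, thresholded", {
  r <- mk_repeats(100, 200)
  calls <- tibble::tibble(
    chrom = "chr1", position = c(150, 199, 200, 120),
    context = c("CG", "CHH", "CWG", "CWG"),
    methylated = c(TRUE, FALSE, TRUE, TRUE))
  out <- repeat_methylation_status(r, calls)
  expect_true(out$CG)         # methylated CG call inside
  expect_false(out$CHH)       # unmethylated call does not count
  expect_true(out$CWG)        # position 120 inside; 200 is the exclusive end
  expect_true(out$methylated)
  out <- repeat_methylation_status(r, calls, min_calls = 2)
  expect_false(any(out$CG, out$CHH, out$CWG))
  # only unmethylated calls -> unmethylated overall
  out <- repeat_methylation_status(r, dplyr::mutate(calls, methylated = FALSE))
  expect_false(out$methylated)
})

test_that("DMR-repeat links classify by the maximal-shared-bases partner", {
  r <- mk_repeats(c(100, 120, 150), c(200, 140, 400), id = c("R1", "R2", "R3"))
  d <- mk_dmrs(c(150, 100, 100, 90), c(180, 200, 130, 410),
               id = c("inside", "span", "small", "contains"))
  L <- link_dmrs_to_repeats(d, r)
  lk <- L$links
  expect_equal(lk$link_class[lk$dmr_id == "inside"], "dmr_inside_repeat")
  # [100,200) shares 100 with R1 and 50 with R3 -> R1, fully contains R2
  expect_equal(lk$repeat_id[lk$dmr_id == "span"], "R1")
  expect_equal(lk$link_class[lk$dmr_id == "span"], "dmr_inside_repeat")
  expect_equal(lk$link_class[lk$dmr_id == "contains"], "repeat_inside_dmr")
  # identical spans classify as dmr_inside_repeat
  d2 <- mk_dmrs(120, 140, id = "same")
  expect_equal(link_dmrs_to_repeats(d2, r)$links$link_class,
               "dmr_inside_repeat")
  # class fractions partition the linked DMRs
  expect_equal(sum(L$summary$n[L$summary$link_class != "any"]),
               L$summary$n[L$summary$link_class == "any"])
  expect_equal(L$summary$fraction[L$summary$link_class == "any"],
               nrow(lk) / nrow(d))
  expect_equal(nrow(tidy(L)), nrow(lk))
})

test_that("repeat-linked DMRs join genes on all qualifying sides", {
  genes <- mk_genes(c(5000, 9000), c(8000, 9500), id = c("g1", "g2"),
                    cds = list(tibble::tibble(start = c(5000, 6000),
                                              end = c(5500, 6500)),
                               tibble::tibble(start = 9000, end = 9500)))
  dmrs <- mk_dmrs(c(4500, 5600, 8600), c(4700, 5800, 8800),
                  id = c("dup", "dintr", "dmid"))
  reps <- mk_repeats(c(4500, 5600, 8600), c(4700, 5800, 8800))
  links <- link_dmrs_to_repeats(dmrs, reps)
  out <- sort_assoc(associate_dmrs_with_genes(links, dmrs, genes))
  # dup upstream of g1; dintr intronic in g1; dmid downstream of g1 AND
  # upstream of g2
  expect_equal(nrow(out), 4)
  expect_equal(out$relation[out$partner_id == "dmid"],
               c("downstream", "upstream"))
  expect_equal(out$distance[out$gene_id == "g1" & out$partner_id == "dup"],
               300)
  # only repeat-linked DMRs participate
  out2 <- associate_dmrs_with_genes(links$links[0, ], dmrs, genes)
  expect_equal(nrow(out2), 0)
  # exactly 1 kb away is excluded (strict <)
  d1k <- mk_dmrs(3800, 4000, id = "at1k")
  l1k <- link_dmrs_to_repeats(d1k, mk_repeats(3800, 4000))
  expect_equal(nrow(associate_dmrs_with_genes(l1k, d1k, genes)), 0)
})

test_that("RIN-DMR association honours the +/-10 and +/-500 bp extensions", {
  pk <- tibble::tibble(peak_id = "p1", chrom = "chr1", start = 1000,
                       end = 1001)
  d <- mk_dmrs(c(1005, 1300, 2000), c(1100, 1400, 2100),
               id = c("dA", "dB", "dC"))
  out <- associate_rin_with_dmrs(pk, d, NULL)
  expect_equal(nrow(out), 2)  # dC is beyond 500 bp
  expect_equal(out$mode[out$dmr_id == "dA"], "overlap")
  expect_equal(out$mode[out$dmr_id == "dB"], "adjacent")
  # every overlap-mode association is also within the adjacent extension
  expect_true(all(out$dmr_id[out$overlap] %in% out$dmr_id))
  # gap of exactly 500 bases does not qualify
  d500 <- mk_dmrs(1501, 1600, id = "d500")
  expect_equal(nrow(associate_rin_with_dmrs(pk, d500, NULL)), 0)
  d499 <- mk_dmrs(1500, 1600, id = "d499")
  expect_equal(nrow(associate_rin_with_dmrs(pk, d499, NULL)), 1)
  # repeat support flows through the DMR-repeat links
  links <- link_dmrs_to_repeats(mk_dmrs(1005, 1100, id = "dA"),
                                mk_repeats(1000, 1200))
  out <- associate_rin_with_dmrs(pk, d, links)
  expect_true(out$repeat_supported[out$dmr_id == "dA"])
  expect_false(out$repeat_supported[out$dmr_id == "dB"])
})

test_that("distance bins partition the upstream-only genes", {
  genes <- mk_genes(c(2000, 6000, 10000), c(3000, 7000, 11000),
                    id = c("a", "b", "c"))
  reps <- mk_repeats(c(1900, 4990, 8990), c(1950, 5001, 9001))
  cfg <- classify_gene_configuration(genes, reps)
  up <- closest_repeat(genes, reps, "upstream")
  expr <- tibble::tibble(gene_id = c("a", "b", "c"), leaf = c(1, 2, 3),
                         dpa17 = 0, dpa39 = 0, dpa42 = 0, dpa52 = 0)
  out <- distance_binned_expression(cfg, up, expr)
  expect_equal(nrow(out), sum(cfg$config == "upstream_only"))
  expect_equal(out$bin[out$gene_id == "a"], 0)    # distance 50
  expect_equal(out$bin[out$gene_id == "b"], 9)    # distance 999
  expect_equal(out$rpkm, c(1, 2, 3)[match(out$gene_id, c("a", "b", "c"))])
})
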