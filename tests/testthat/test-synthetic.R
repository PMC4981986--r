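# The generator is first-class code: these tests check its distributional
# contracts on reduced genomes (1 x 5 Mb unless the contract needs more) to
# keep the default run fast.

test_that("layout tiles chromosomes with RP tips and a central RR block", {
  spec <- synthetic_spec(seed = 1, chromosomes = karyotype("chr1", 5e6))
  lay <- generate_layout(spec)
  expect_equal(lay$label, c("RP", "INT", "RR", "INT", "RP"))
  expect_equal(lay$start[1], 0)
  expect_equal(lay$end[nrow(lay)], 5e6)
  expect_true(all(lay$start[-1] == lay$end[-nrow(lay)])) # exact tiling
  # single-label layout: one segment spanning the chromosome
  spec1 <- synthetic_spec(seed = 1, chromosomes = karyotype("chr1", 2e6),
                          layout_template = "RR", layout_fractions = 1)
  lay1 <- generate_layout(spec1)
  expect_equal(nrow(lay1), 1)
  expect_equal(lay1$end - lay1$start, 2e6)
  # determinism
  expect_identical(generate_layout(spec), generate_layout(spec))
  # segments below two window lengths are rejected
  expect_error(generate_layout(
    synthetic_spec(seed = 1, chromosomes = karyotype("chr1", 2e6))),
    "segment shorter")
})

test_that("realized repeat coverage and gene counts honour the spec targets", {
  spec <- synthetic_spec(seed = 5, chromosomes = karyotype("chr1", 5e6))
  ds <- generate_genome(spec, sequence = FALSE)
  lay <- ds$truth$layout
  for (i in seq_len(nrow(lay))) {
    seg <- tibble::tibble(chrom = lay$chrom[i], start = lay$start[i],
                          end = lay$end[i])
    cov <- repeatscape:::iv_intersect_bp(seg, ds$repeats) /
      (lay$end[i] - lay$start[i])
    target <- spec$repeat_cov_targets[[lay$label[i]]]
    expect_lt(abs(cov - target), 0.05)
  }
  counts <- table(ds$genes$compartment_truth)
  mb <- tapply(lay$end - lay$start, lay$label, sum) / 1e6
  for (lab in names(counts)) {
    lambda <- spec$genes_per_mb[[lab]] * mb[[lab]]
    expect_lt(abs(counts[[lab]] - lambda), 4 * sqrt(lambda) + 3)
  }
  # all emitted features pass the package validators
  expect_silent(repeatscape:::validate_features(ds$repeats, "repeat_",
                                                ds$karyotype))
  expect_silent(repeatscape:::validate_features(ds$genes, "gene",
                                                ds$karyotype))
  expect_silent(repeatscape:::validate_features(ds$dmrs, "dmr",
                                                ds$karyotype))
  # coverage > 1 is infeasible
  expect_error(generate_genome(
    synthetic_spec(seed = 1, repeat_cov_targets = c(RR = 1.2, INT = .5,
                                                    RP = .1))),
    "coverage")
})

test_that("same seed reproduces a byte-identical emitted dataset", {
  spec <- synthetic_spec(seed = 33, chromosomes = karyotype("chr1", 5e6))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_synthetic_dataset(generate_genome(spec), d1)
  write_synthetic_dataset(generate_genome(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e7),
                     readBin(file.path(d2, f), "raw", 5e7),
                     label = paste("bytes of", f))
  }
  # and a different seed does not
  d3 <- withr::local_tempdir()
  spec2 <- synthetic_spec(seed = 34, chromosomes = karyotype("chr1", 5e6))
  write_synthetic_dataset(generate_genome(spec2), d3)
  expect_false(identical(readBin(file.path(d1, "repeats.gff3"), "raw", 5e7),
                         readBin(file.path(d3, "repeats.gff3"), "raw", 5e7)))
})

test_that("expression model orders compartment medians and honours DE labels", {
  spec <- synthetic_spec(seed = 8)
  genes <- tibble::tibble(gene_id = sprintf("g%05d", 1:9000),
                          compartment_truth = rep(c("RR", "INT", "RP"),
                                                  each = 3000))
  ex <- assign_expression_and_de(spec, genes)
  med <- tapply(ex$expression$leaf, genes$compartment_truth, median)
  expect_lt(med[["RR"]], med[["INT"]])
  expect_lt(med[["INT"]], med[["RP"]])
  expect_equal(med[["RR"]], 0)
  # up genes rise between the stage pair, down genes fall
  joined <- dplyr::left_join(ex$de_status, ex$expression, by = "gene_id")
  expect_true(all(joined$dpa52[joined$status == "up"] >
                    joined$dpa17[joined$status == "up"]))
  expect_true(all(joined$dpa17[joined$status == "down"] >
                    joined$dpa52[joined$status == "down"]))
  fr <- table(ex$de_status$status) / 9000
  expect_lt(abs(fr[["up"]] - 0.05), 0.01)
  expect_lt(abs(fr[["down"]] - 0.05), 0.01)
  # degenerate: everything stable
  spec0 <- synthetic_spec(seed = 8, de_fractions = c(up = 0, down = 0))
  ex0 <- assign_expression_and_de(spec0, genes)
  expect_true(all(ex0$de_status$status == "stable"))
})

test_that("methylome/DMR/RIN placement matches its ground truth exactly", {
  spec <- synthetic_spec(seed = 21, chromosomes = karyotype("chr1", 5e6))
  ds <- generate_genome(spec, sequence = FALSE)
  # DMR association fraction within +/-5 points of target
  L <- link_dmrs_to_repeats(ds$dmrs, ds$repeats)
  frac <- L$summary$fraction[L$summary$link_class == "any"]
  expect_lt(abs(frac - spec$dmr_fraction_associated), 0.05)
  # generator truth and association engine agree DMR by DMR
  expect_equal(ds$dmrs$dmr_id %in% L$links$dmr_id,
               ds$truth$dmr_truth$associated)
  # methylation is denser and more methylated on repeats
  meth <- repeat_methylation_status(ds$repeats, ds$methylation)
  expect_gt(mean(meth$methylated), 0.5)
  # RIN peaks: near/far truth is recovered by the association engine
  rin <- associate_rin_with_dmrs(ds$rin_peaks, ds$dmrs, L,
                                 karyotype = ds$karyotype)
  expect_setequal(unique(rin$peak_id),
                  ds$truth$rin_truth$peak_id[ds$truth$rin_truth$near_dmr])
  near_frac <- mean(ds$truth$rin_truth$near_dmr)
  expect_lt(abs(near_frac - spec$rin_fraction_near), 0.06)
})

test_that("degenerate placement parameters behave as stated", {
  spec <- synthetic_spec(seed = 3, chromosomes = karyotype("chr1", 5e6),
                         dmr_fraction_associated = 0, rin_fraction_near = 0,
                         meth_p_bg = 0)
  ds <- generate_genome(spec, sequence = FALSE)
  L <- link_dmrs_to_repeats(ds$dmrs, ds$repeats)
  expect_equal(nrow(L$links), 0)  # no DMR touches any repeat
  rin <- associate_rin_with_dmrs(ds$rin_peaks, ds$dmrs, L,
                                 karyotype = ds$karyotype)
  expect_equal(nrow(rin), 0)      # no peak within 500 bp of a DMR
  # background methylation probability 0: methylated calls only on repeats
  m <- dplyr::filter(ds$methylation, methylated)
  ov <- repeatscape:::iv_overlap_bp_per_row(
    tibble::tibble(chrom = m$chrom, start = m$position,
                   end = m$position + 1), ds$repeats)
  expect_true(all(ov > 0))
})

test_that("repeat sequence carries family-specific G+C above background", {
  spec <- synthetic_spec(seed = 12, chromosomes = karyotype("chr1", 2e6),
                         layout_template = c("RR", "RP"),
                         layout_fractions = c(0.5, 0.5))
  ds <- generate_genome(spec)
  gyp <- dplyr::filter(ds$repeats, family == "Gypsy")
  gc_gyp <- gc_content(ds$sequences, gyp[, c("chrom", "start", "end")])
  free <- repeatscape:::iv_footprint(ds$repeats)
  expect_gt(gc_gyp, 0.40)             # Gypsy target 0.42
  gc_all <- gc_content(ds$sequences)
  expect_lt(gc_all, gc_gyp)           # background 0.35 dilutes
})
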