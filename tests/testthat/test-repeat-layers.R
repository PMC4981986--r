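test_that("find_kmer_repeats matches the brute-force count oracle on planted cases", {
  p <- kmer_params()
  # 100 consecutive A: every 16-mer occurs 85 >= 10 times
  r <- find_kmer_repeats(c(chr1 = strrep("A", 100)), p)
  expect_equal(as.data.frame(r),
               data.frame(chrom = "chr1", start = 0L, end = 100L))
  # random 10 kb: no 16-mer repeats 10 times
  withr::local_seed(1)
  expect_equal(nrow(find_kmer_repeats(c(chr1 = random_dna(10000)), p)), 0)
  # 40 bp motif embedded 10x behind unique 100 bp spacers: 10 exact fragments
  motif <- random_dna(40)
  emb <- paste(vapply(1:10, function(i) paste0(random_dna(100), motif),
                      ""), collapse = "")
  r <- find_kmer_repeats(c(chr1 = emb), p)
  expect_equal(nrow(r), 10)
  expect_true(all(r$end - r$start == 40))
  expect_equal(as.data.frame(r), as.data.frame(
    oracle_kmer(c(chr1 = emb), 16, 10, 30)))
})

test_that("find_kmer_repeats equals the oracle on randomized sequences", {
  withr::local_seed(42)
  p <- kmer_params(k = 5, min_occurrences = 3, min_fragment = 8)
  for (i in 1:60) {
    # low-complexity alphabet + Ns force frequent k-mers and ambiguity runs
    seqs <- c(s1 = random_dna(400, c("A", "C", "G", "T", "A", "C", "N")),
              s2 = random_dna(300, c("A", "C", "A", "G")))
    expect_equal(as.data.frame(find_kmer_repeats(seqs, p)),
                 as.data.frame(oracle_kmer(seqs, 5, 3, 8)))
  }
})

test_that("canonical counting pools a k-mer with its reverse complement", {
  revcomp <- function(x) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(x, "")[[1]]),
                                      collapse = ""))
  withr::local_seed(19)
  # motif twice forward + once as reverse complement: only canonical
  # counting reaches 3 occurrences
  motif <- random_dna(12)
  s <- c(chr1 = paste0(random_dna(60), motif, random_dna(60), motif,
                       random_dna(60), revcomp(motif), random_dna(60)))
  p_fwd <- kmer_params(k = 12, min_occurrences = 3, min_fragment = 12)
  p_can <- kmer_params(k = 12, min_occurrences = 3, min_fragment = 12,
                       canonical = TRUE)
  expect_equal(nrow(find_kmer_repeats(s, p_fwd)), 0)
  r <- find_kmer_repeats(s, p_can)
  expect_equal(nrow(r), 3)
  expect_true(all(r$end - r$start == 12))
})

test_that("layer merge applies the novel-span and non-overlap rules", {
  pol <- merge_policy()
  prim <- mk_repeats(c(50, 150), c(200, 400), id = c("p1", "p2"))
  # fully included secondary dropped; partially novel one clipped to [100,150)
  sec <- mk_repeats(c(100, 100), c(160, 200), id = c("s1", "s2"),
                    layer = "secondary_denovo")
  out <- merge_annotation_layers(prim[2, ], sec[2, ], NULL, pol)
  novel <- out[out$layer == "secondary_denovo", ]
  expect_equal(c(novel$start, novel$end), c(100, 150))
  out <- merge_annotation_layers(prim[1, ], sec[1, ], NULL, pol)
  expect_equal(nrow(out[out$layer == "secondary_denovo", ]), 0)
  # clipped-to-49bp secondary is re-filtered by span
  sec49 <- mk_repeats(101, 200, id = "s3", layer = "secondary_denovo")
  out <- merge_annotation_layers(prim[2, ], sec49, NULL, pol)
  expect_equal(nrow(out[out$layer == "secondary_denovo", ]), 0)
  # k-mer fragments: 29 bp dropped, any overlap with the de novo footprint drops
  km <- tibble::tibble(chrom = "chr1", start = c(500, 600, 390),
                       end = c(529, 700, 450))
  out <- merge_annotation_layers(prim[2, ], NULL, km, pol)
  kept <- out[out$layer == "kmer_strict", ]
  expect_equal(c(kept$start, kept$end), c(600, 700))
})

test_that("merged footprint equals the union of the retained layers", {
  withr::local_seed(11)
  for (i in 1:20) {
    ps <- sample(0:5000, 5)
    prim <- mk_repeats(ps, ps + sample(60:400, 5), id = sprintf("p%d", 1:5))
    ss <- sample(0:5000, 5)
    sec <- mk_repeats(ss, ss + sample(60:400, 5), id = sprintf("s%d", 1:5),
                      layer = "secondary_denovo")
    ks <- sample(0:5000, 5)
    km <- tibble::tibble(chrom = "chr1", start = ks,
                         end = ks + sample(35:200, 5))
    out <- merge_annotation_layers(prim, sec, km)
    # no retained secondary/kmer interval may violate its layer rule
    pf <- repeatscape:::iv_footprint(prim)
    for (lay in c("secondary_denovo", "kmer_strict")) {
      kept <- out[out$layer == lay, ]
      if (nrow(kept) == 0) next
      ov <- repeatscape:::iv_overlap_bp_per_row(kept, pf)
      if (lay == "secondary_denovo") {
        expect_true(all(ov == 0) && all(kept$end - kept$start >= 50))
      } else {
        denovo <- out[out$layer != "kmer_strict", ]
        ov2 <- repeatscape:::iv_overlap_bp_per_row(kept,
                                                   repeatscape:::iv_footprint(denovo))
        expect_true(all(ov2 == 0) && all(kept$end - kept$start >= 30))
      }
    }
  }
})

test_that("gc_content excludes ambiguous bases and weights by length", {
  expect_equal(gc_content(c(s = "GGCC")), 1)
  expect_equal(gc_content(c(s = "ATAT")), 0)
  expect_equal(gc_content(c(s = "ATGCN")), 0.5)
  expect_error(gc_content(c(s = "NNNN")), "undefined")
  # concatenation = length-weighted mean of the parts
  s1 <- "GGGGGGGGAT"  # 0.8 over 10
  s2 <- "ATATA"       # 0.0 over 5
  expect_equal(gc_content(c(s = paste0(s1, s2))),
               (0.8 * 10 + 0 * 5) / 15)
  # interval extraction
  expect_equal(gc_content(c(chr1 = paste0(s1, s2)),
                          tibble::tibble(chrom = "chr1", start = 10, end = 15)),
               0)
})
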