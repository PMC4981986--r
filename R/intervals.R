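# Internal interval arithmetic. All package coordinates are 0-based half-open
# [start, end); conversion to the 1-based closed convention of
# IRanges/GenomicRanges happens only inside these helpers.

# Half-open tibble -> GRanges (1-based closed).
iv_granges <- function(df, karyotype = NULL) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  if (!is.null(karyotype)) {
    GenomeInfoDb::seqlevels(gr) <- karyotype$chrom
    GenomeInfoDb::seqlengths(gr) <- karyotype$length
  }
  gr
}

# GRanges -> half-open tibble.
iv_tibble <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

# Deduplicated union of a feature set's bases, as a half-open tibble sorted by
# (chrom, start).
iv_footprint <- function(df) {
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  red <- GenomicRanges::reduce(iv_granges(df), ignore.strand = TRUE)
  out <- iv_tibble(red)
  out$strand <- NULL
  arrange(out, .data$chrom, .data$start)
}

iv_footprint_bp <- function(df) {
  fp <- iv_footprint(df)
  sum(as.numeric(fp$end - fp$start))
}

# Total bases shared between the footprints of two interval sets.
iv_intersect_bp <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  ia <- GenomicRanges::reduce(iv_granges(a), ignore.strand = TRUE)
  ib <- GenomicRanges::reduce(iv_granges(b), ignore.strand = TRUE)
  sum(as.numeric(GenomicRanges::width(GenomicRanges::intersect(ia, ib, ignore.strand = TRUE))))
}

# Per-row overlap in bases between each interval of `a` and the footprint of
# `b` (same order as `a`).
iv_overlap_bp_per_row <- function(a, b) {
  if (nrow(a) == 0) return(numeric(0))
  if (nrow(b) == 0) return(rep(0, nrow(a)))
  ga <- iv_granges(a)
  gb <- GenomicRanges::reduce(iv_granges(b), ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(ga, gb, ignore.strand = TRUE)
  shared <- GenomicRanges::width(IRanges::pintersect(
    ga[S4Vectors::queryHits(hits)], gb[S4Vectors::subjectHits(hits)]
  ))
  out <- rep(0, nrow(a))
  agg <- tapply(shared, S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

# Validate a feature tibble against the karyotype and the half-open contract.
iv_validate <- function(df, karyotype = NULL, what = "feature") {
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad) > 0) {
    abort(sprintf("%s row %d: invalid interval [%s, %s) (need 0 <= start < end)",
                  what, bad[1], df$start[bad[1]], df$end[bad[1]]))
  }
  if (!is.null(karyotype)) {
    miss <- setdiff(unique(df$chrom), karyotype$chrom)
    if (length(miss) > 0) {
      abort(sprintf("%s on chromosome(s) absent from karyotype: %s",
                    what, paste(miss, collapse = ", ")))
    }
    len <- karyotype$length[match(df$chrom, karyotype$chrom)]
    over <- which(df$end > len)
    if (length(over) > 0) {
      abort(sprintf("%s row %d: end %s exceeds length of %s (%s)",
                    what, over[1], df$end[over[1]], df$chrom[over[1]], len[over[1]]))
    }
  }
  invisible(df)
}

# Gap (bases strictly between two half-open intervals on the same chromosome);
# 0 for abutting intervals, NA when they overlap.
iv_gap <- function(start1, end1, start2, end2) {
  g <- pmax(start1, start2) - pmin(end1, end2)
  ifelse(g < 0, NA_real_, g)
}
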