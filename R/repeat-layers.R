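# Strict k-mer repeat detection, annotation-layer merge rules and G+C content.

#' K-mer detection parameters
#'
#' Defaults reproduce the strict-mapping setting used for the tomato assembly:
#' 16-mers occurring at least 10 times genome-wide, keeping fragments of at
#' least 30 bp.
#'
#' @param k K-mer size (>= 2).
#' @param min_occurrences Minimum genome-wide exact-match count (>= 2).
#' @param min_fragment Minimum retained fragment length in bp (>= k).
#' @param canonical Count each k-mer together with its reverse complement
#'   (`FALSE` by default: forward-strand exact counting).
#' @return A list of class `kmer_params`.
#' @export
kmer_params <- function(k = 16, min_occurrences = 10, min_fragment = 30,
                        canonical = FALSE) {
  if (k < 2) abort("k must be >= 2")
  if (min_occurrences < 2) abort("min_occurrences must be >= 2")
  if (min_fragment < k) abort("min_fragment must be >= k")
  structure(list(k = as.integer(k), min_occurrences = as.integer(min_occurrences),
                 min_fragment = as.integer(min_fragment), canonical = canonical),
            class = "kmer_params")
}

# 2-bit-encode one sequence; N and other ambiguity codes become NA.
encode_bases <- function(seq_chr) {
  x <- utf8ToInt(toupper(seq_chr))
  code <- rep(NA_real_, length(x))
  code[x == utf8ToInt("A")] <- 0
  code[x == utf8ToInt("C")] <- 1
  code[x == utf8ToInt("G")] <- 2
  code[x == utf8ToInt("T")] <- 3
  code
}

# Rolling base-4 codes of all k-mers of one sequence (NA where any base is
# ambiguous). Codes fit exactly in a double for k <= 26.
kmer_codes <- function(base_codes, k) {
  n <- length(base_codes) - k + 1
  if (n < 1) return(numeric(0))
  acc <- base_codes[seq_len(n)]
  for (j in seq_len(k - 1)) {
    acc <- acc * 4 + base_codes[seq_len(n) + j]
  }
  acc
}

# Reverse-complement code of each k-mer, computed positionally.
kmer_codes_rc <- function(base_codes, k) {
  n <- length(base_codes) - k + 1
  if (n < 1) return(numeric(0))
  acc <- 3 - base_codes[seq_len(n) + (k - 1)]
  for (j in rev(seq_len(k - 1) - 1)) {
    acc <- acc * 4 + (3 - base_codes[seq_len(n) + j])
  }
  acc
}

#' Detect repeats as runs of frequent k-mers
#'
#' Counts every exact k-mer across the whole sequence set, keeps the positions
#' of k-mers whose genome-wide count reaches `min_occurrences`, merges them
#' into maximal intervals and drops fragments shorter than `min_fragment`.
#' Ambiguous bases (N) never match any k-mer.
#'
#' @param sequences A named character vector, a `Biostrings::DNAStringSet`, or
#'   a path to a FASTA file.
#' @param params A [kmer_params()] object.
#' @return A tibble of disjoint sorted intervals (`chrom`, `start`, `end`),
#'   0-based half-open.
#' @export
find_kmer_repeats <- function(sequences, params = kmer_params()) {
  seqs <- as_sequence_set(sequences)
  if (length(seqs) == 0) abort("empty sequence set")
  k <- params$k
  if (max(nchar(seqs)) < k) {
    warn("k exceeds the longest sequence; no k-mer repeats detectable")
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  enc <- lapply(seqs, encode_bases)
  fwd <- lapply(enc, kmer_codes, k = k)
  key <- if (params$canonical) {
    rc <- lapply(enc, kmer_codes_rc, k = k)
    purrr::map2(fwd, rc, pmin)
  } else {
    fwd
  }
  all_codes <- unlist(key, use.names = FALSE)
  keep_na <- !is.na(all_codes)
  idx <- match(all_codes, all_codes)         # first-occurrence index as hash
  counts <- tabulate(idx[keep_na], nbins = length(all_codes))
  per_pos_count <- ifelse(keep_na, counts[idx], 0L)
  offsets <- cumsum(c(0, vapply(key, length, numeric(1))))
  out <- purrr::map(seq_along(seqs), function(i) {
    nm <- names(seqs)[i]
    if (offsets[i + 1] == offsets[i]) {
      return(tibble(chrom = character(), start = integer(), end = integer()))
    }
    cnt <- per_pos_count[(offsets[i] + 1):offsets[i + 1]]
    hit <- which(cnt >= params$min_occurrences)
    if (length(hit) == 0) {
      return(tibble(chrom = character(), start = integer(), end = integer()))
    }
    ir <- IRanges::reduce(IRanges::IRanges(start = hit, width = k))
    tibble(chrom = nm, start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
  out <- bind_rows(out)
  out <- out[out$end - out$start >= params$min_fragment, , drop = FALSE]
  arrange(out, .data$chrom, .data$start)
}

as_sequence_set <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) {
    setNames(as.character(sequences), names(sequences))
  } else if (is.character(sequences) && length(sequences) == 1 &&
             file.exists(sequences)) {
    x <- Biostrings::readDNAStringSet(sequences)
    names(x) <- sub("\\s.*$", "", names(x))
    setNames(as.character(x), names(x))
  } else if (is.character(sequences)) {
    if (is.null(names(sequences))) {
      names(sequences) <- sprintf("seq%d", seq_along(sequences))
    }
    sequences
  } else {
    abort("sequences must be a DNAStringSet, named character vector or FASTA path")
  }
}

#' Layer-merge policy
#'
#' @param secondary_min_span Minimum novel span (bp) for a secondary de novo
#'   annotation to be retained (default 50).
#' @param kmer_min_span Minimum span (bp) for a k-mer fragment (default 30).
#' @param inclusion_rule `"not_included"`: secondary candidates are clipped to
#'   their bases novel over the primary footprint and re-filtered by span;
#'   `"not_overlapping"`: candidates sharing any base with the footprint are
#'   dropped whole.
#' @return A list of class `merge_policy`.
#' @export
merge_policy <- function(secondary_min_span = 50, kmer_min_span = 30,
                         inclusion_rule = c("not_included", "not_overlapping")) {
  if (secondary_min_span < 1 || kmer_min_span < 1) abort("spans must be >= 1")
  structure(list(secondary_min_span = secondary_min_span,
                 kmer_min_span = kmer_min_span,
                 inclusion_rule = match.arg(inclusion_rule)),
            class = "merge_policy")
}

# Subtract a footprint from candidate intervals, returning the novel pieces
# tagged with their originating row.
subtract_footprint <- function(candidates, footprint) {
  if (nrow(candidates) == 0) return(candidates[0, c("chrom", "start", "end")])
  if (nrow(footprint) == 0) {
    out <- candidates[, c("chrom", "start", "end")]
    out$src <- seq_len(nrow(candidates))
    return(out)
  }
  gc_ <- iv_granges(candidates)
  gf <- GenomicRanges::reduce(iv_granges(footprint), ignore.strand = TRUE)
  pieces <- lapply(seq_len(nrow(candidates)), function(i) {
    d <- GenomicRanges::setdiff(gc_[i], gf, ignore.strand = TRUE)
    if (length(d) == 0) return(NULL)
    out <- iv_tibble(d)[, c("chrom", "start", "end")]
    out$src <- i
    out
  })
  pieces <- bind_rows(pieces)
  if (nrow(pieces) == 0) {
    pieces <- tibble(chrom = character(), start = integer(),
                     end = integer(), src = integer())
  }
  pieces
}

#' Merge repeat annotation layers
#'
#' Combines a primary de novo annotation with a secondary de novo layer and a
#' strict k-mer layer. Secondary candidates contribute only their bases not
#' already in the primary footprint (minimum novel span 50 bp); k-mer
#' fragments are kept only when they share no base with the primary+secondary
#' footprint and span at least 30 bp.
#'
#' @param primary Repeat tibble (layer `primary_denovo`).
#' @param secondary Repeat tibble or `NULL`.
#' @param kmer Interval tibble (`chrom`,`start`,`end`) from
#'   [find_kmer_repeats()], or `NULL`.
#' @param policy A [merge_policy()].
#' @return A unified repeat tibble with a `layer` column.
#' @export
merge_annotation_layers <- function(primary, secondary = NULL, kmer = NULL,
                                    policy = merge_policy()) {
  primary <- mutate(primary, layer = "primary_denovo")
  out <- primary
  prim_fp <- iv_footprint(primary)
  if (!is.null(secondary) && nrow(secondary) > 0) {
    if (policy$inclusion_rule == "not_included") {
      novel <- subtract_footprint(secondary, prim_fp)
      novel <- novel[novel$end - novel$start >= policy$secondary_min_span, ,
                     drop = FALSE]
      if (nrow(novel) > 0) {
        kept <- secondary[novel$src, , drop = FALSE]
        kept$start <- novel$start
        kept$end <- novel$end
        kept$repeat_id <- sprintf("%s_n%d", kept$repeat_id,
                                  stats::ave(novel$src, novel$src, FUN = seq_along))
        kept$layer <- "secondary_denovo"
        out <- bind_rows(out, kept)
      }
    } else {
      ov <- iv_overlap_bp_per_row(secondary, prim_fp)
      span <- secondary$end - secondary$start
      kept <- secondary[ov == 0 & span >= policy$secondary_min_span, , drop = FALSE]
      if (nrow(kept) > 0) {
        kept$layer <- "secondary_denovo"
        out <- bind_rows(out, kept)
      }
    }
  }
  if (!is.null(kmer) && nrow(kmer) > 0) {
    denovo_fp <- iv_footprint(out)
    ov <- iv_overlap_bp_per_row(kmer, denovo_fp)
    span <- kmer$end - kmer$start
    kept <- kmer[ov == 0 & span >= policy$kmer_min_span, , drop = FALSE]
    if (nrow(kept) > 0) {
      kept <- tibble(
        repeat_id = sprintf("kmer%06d", seq_len(nrow(kept))),
        chrom = kept$chrom, start = kept$start, end = kept$end,
        strand = "*", family = "Unclassified", consensus_id = NA_character_,
        layer = "kmer_strict", high_confidence = FALSE
      )
      out <- bind_rows(out, kept)
    }
  }
  arrange(out, .data$chrom, .data$start)
}

#' G+C content
#'
#' Fraction (#G + #C) / (#A + #C + #G + #T); ambiguous bases are excluded from
#' both numerator and denominator.
#'
#' @param sequences Named character vector, `DNAStringSet` or FASTA path.
#' @param intervals Optional interval tibble; when given, content is computed
#'   over the bases these intervals cover.
#' @return A single fraction in \[0, 1\].
#' @export
gc_content <- function(sequences, intervals = NULL) {
  seqs <- as_sequence_set(sequences)
  if (!is.null(intervals)) {
    seqs <- vapply(seq_len(nrow(intervals)), function(i) {
      substr(seqs[[intervals$chrom[i]]], intervals$start[i] + 1, intervals$end[i])
    }, character(1))
  }
  tab <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(toupper(seqs))
  ))
  acgt <- tab[c("A", "C", "G", "T")]
  if (sum(acgt) == 0) abort("no unambiguous bases; G+C content undefined")
  unname((acgt["G"] + acgt["C"]) / sum(acgt))
}
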