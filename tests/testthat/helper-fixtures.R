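# Fixture builders and independent brute-force oracles used across the suite.

mk_karyotype <- function(n = 1, len = 10000) {
  karyotype(paste0("chr", seq_len(n)), rep(len, n))
}

mk_repeats <- function(start, end, chrom = "chr1", id = NULL,
                       family = "Gypsy", consensus = "consA",
                       layer = "primary_denovo", hc = TRUE, strand = "*") {
  n <- length(start)
  tibble::tibble(
    repeat_id = id %||% sprintf("r%03d", seq_len(n)),
    chrom = rep_len(chrom, n), start = start, end = end,
    strand = rep_len(strand, n), family = rep_len(family, n),
    consensus_id = rep_len(consensus, n), layer = rep_len(layer, n),
    high_confidence = rep_len(hc, n)
  )
}

mk_genes <- function(start, end, chrom = "chr1", strand = "+", id = NULL,
                     cds = NULL) {
  n <- length(start)
  if (is.null(cds)) {
    cds <- lapply(seq_len(n), function(i) {
      tibble::tibble(start = start[i], end = end[i])
    })
  }
  tibble::tibble(
    gene_id = id %||% sprintf("g%03d", seq_len(n)),
    chrom = rep_len(chrom, n), start = start, end = end,
    strand = rep_len(strand, n), cds = cds
  )
}

mk_dmrs <- function(start, end, chrom = "chr1", id = NULL) {
  n <- length(start)
  tibble::tibble(
    dmr_id = id %||% sprintf("d%03d", seq_len(n)),
    chrom = rep_len(chrom, n), start = start, end = end,
    comparison = "dpa17_dpa52", direction = "hypo"
  )
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force k-mer repeat oracle: dictionary count of every k-mer, union of
# the positions of frequent ones, minimum fragment filter.
oracle_kmer <- function(seqs, k, min_occ, min_frag) {
  words <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    w <- substring(s, 1:(n - k + 1), k:n)
    w[grepl("[^ACGT]", w)] <- NA
    w
  })
  counts <- table(unlist(words, use.names = FALSE))
  out <- lapply(names(seqs), function(nm) {
    w <- words[[nm]]
    if (length(w) == 0) return(NULL)
    keep <- !is.na(w) & counts[w] >= min_occ
    keep[is.na(keep)] <- FALSE
    covered <- logical(nchar(seqs[[nm]]))
    for (i in which(keep)) covered[i:(i + k - 1)] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep_runs <- r$values & r$lengths >= min_frag
    if (!any(keep_runs)) return(NULL)
    tibble::tibble(chrom = nm, start = starts[keep_runs] - 1L,
                   end = ends[keep_runs])
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer())
  }
  dplyr::arrange(out, chrom, start)
}

# All-pairs closest-repeat oracle for a single gene row.
oracle_closest <- function(gene, repeats, side, ignore_overlapping = TRUE) {
  best_id <- NA_character_
  best_d <- Inf
  best_start <- Inf
  left_is_up <- gene$strand != "-"
  want_left <- (side == "upstream") == left_is_up
  for (i in seq_len(nrow(repeats))) {
    r <- repeats[i, ]
    if (r$chrom != gene$chrom) next
    overlapping <- r$start < gene$end & r$end > gene$start
    if (overlapping) {
      if (ignore_overlapping) next
      d <- 0
    } else if (want_left && r$end <= gene$start) {
      d <- gene$start - r$end
    } else if (!want_left && r$start >= gene$end) {
      d <- r$start - gene$end
    } else {
      next
    }
    if (d < best_d || (d == best_d && r$start < best_start)) {
      best_d <- d
      best_id <- r$repeat_id
      best_start <- r$start
    }
  }
  if (is.infinite(best_d)) {
    tibble::tibble(gene_id = gene$gene_id, repeat_id = NA_character_,
                   distance = NA_real_)
  } else {
    tibble::tibble(gene_id = gene$gene_id, repeat_id = best_id,
                   distance = best_d)
  }
}

# All-pairs DMR-repeat link oracle.
oracle_dmr_links <- function(dmrs, repeats) {
  out <- list()
  for (i in seq_len(nrow(dmrs))) {
    d <- dmrs[i, ]
    best <- NULL
    for (j in seq_len(nrow(repeats))) {
      r <- repeats[j, ]
      if (r$chrom != d$chrom) next
      shared <- min(d$end, r$end) - max(d$start, r$start)
      if (shared <= 0) next
      cls <- if (d$start >= r$start && d$end <= r$end) "dmr_inside_repeat"
             else if (r$start >= d$start && r$end <= d$end) "repeat_inside_dmr"
             else "partial_overlap"
      cand <- list(repeat_id = r$repeat_id, shared = shared, cls = cls,
                   r_start = r$start)
      if (is.null(best) || cand$shared > best$shared ||
          (cand$shared == best$shared &&
             (cand$r_start < best$r_start ||
                (cand$r_start == best$r_start &&
                   cand$repeat_id < best$repeat_id)))) {
        best <- cand
      }
    }
    if (!is.null(best)) {
      out[[length(out) + 1]] <- tibble::tibble(
        dmr_id = d$dmr_id, repeat_id = best$repeat_id,
        link_class = best$cls, shared_bp = best$shared)
    }
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble::tibble(dmr_id = character(), repeat_id = character(),
                          link_class = character(), shared_bp = numeric())
  }
  out
}

# Pairwise DMR/gene association oracle (upstream/downstream strand-aware,
# intronic by intron overlap), strict < window.
oracle_dmr_genes <- function(dmrs, genes, window = 1000) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    introns <- if ("introns" %in% names(genes)) g$introns[[1]] else {
      cds <- g$cds[[1]][order(g$cds[[1]]$start), ]
      if (nrow(cds) < 2) tibble::tibble(start = integer(), end = integer())
      else tibble::tibble(start = cds$end[-nrow(cds)], end = cds$start[-1])
    }
    for (j in seq_len(nrow(dmrs))) {
      d <- dmrs[j, ]
      if (d$chrom != g$chrom) next
      overlapping <- d$start < g$end & d$end > g$start
      left_is_up <- g$strand != "-"
      if (!overlapping && d$end <= g$start && (g$start - d$end) < window) {
        rel <- if (left_is_up) "upstream" else "downstream"
        out[[length(out) + 1]] <- tibble::tibble(
          gene_id = g$gene_id, partner_id = d$dmr_id, relation = rel,
          distance = g$start - d$end)
      }
      if (!overlapping && d$start >= g$end && (d$start - g$end) < window) {
        rel <- if (left_is_up) "downstream" else "upstream"
        out[[length(out) + 1]] <- tibble::tibble(
          gene_id = g$gene_id, partner_id = d$dmr_id, relation = rel,
          distance = d$start - g$end)
      }
      if (nrow(introns) > 0 &&
          any(d$start < introns$end & d$end > introns$start)) {
        out[[length(out) + 1]] <- tibble::tibble(
          gene_id = g$gene_id, partner_id = d$dmr_id, relation = "intronic",
          distance = 0)
      }
    }
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble::tibble(gene_id = character(), partner_id = character(),
                          relation = character(), distance = numeric())
  }
  out
}

sort_assoc <- function(x) {
  if (nrow(x) == 0) return(x)
  dplyr::arrange(x, gene_id, partner_id, relation)
}

`%||%` <- rlang::`%||%`
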