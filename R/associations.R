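# The interval-relation engine: TE-gene filtering, gene/repeat configurations,
# repeat methylation status, DMR/repeat links, repeat-associated-DMR/gene
# links and RIN-peak/DMR links.
#
# Distance semantics everywhere: the number of bases strictly between two
# half-open intervals; abutting intervals are at distance 0 and are distinct
# from overlapping ones. "Within 1 kb" is strict (< 1000). Upstream is the
# 5' side of the gene (strand-aware; genes without strand are read as '+').

#' Flag putative TE-genes by CDS coverage
#'
#' A gene whose CDS footprint is covered more than `threshold` (strictly) by
#' the footprint of high-confidence repeats is flagged as a putative TE-gene
#' (an artefact of gene prediction over protein-coding transposons) and should
#' be excluded from downstream gene analyses.
#'
#' @param genes Gene tibble with a `cds` list-column.
#' @param repeats Repeat tibble; only rows with `high_confidence == TRUE` are
#'   used (pass `high_confidence_only = FALSE` to use all).
#' @param threshold Coverage fraction above which a gene is flagged
#'   (default 0.5, strict `>`).
#' @param high_confidence_only Filter repeats to the high-confidence subset.
#' @return `genes` with `cds_te_coverage` and logical `te_gene` columns.
#' @export
flag_te_genes <- function(genes, repeats, threshold = 0.5,
                          high_confidence_only = TRUE) {
  no_cds <- vapply(genes$cds, nrow, integer(1)) == 0
  if (any(no_cds)) {
    abort(sprintf("gene %s has no CDS; cannot compute TE coverage",
                  genes$gene_id[no_cds][1]))
  }
  reps <- if (high_confidence_only) filter(repeats, .data$high_confidence)
          else repeats
  cds <- genes_cds_table(genes)
  ov <- iv_overlap_bp_per_row(cds, reps)
  per_gene <- tibble(gene_id = cds$gene_id,
                     bp = cds$end - cds$start, ov = ov) %>%
    group_by(.data$gene_id) %>%
    summarise(cov = sum(.data$ov) / sum(.data$bp), .groups = "drop")
  cov <- per_gene$cov[match(genes$gene_id, per_gene$gene_id)]
  mutate(genes, cds_te_coverage = cov, te_gene = cov > threshold)
}

# Strand-aware side resolution: which genomic side is "upstream"?
upstream_is_left <- function(strand) strand != "-"

#' Closest repeat on one side of each gene
#'
#' For every gene, finds the nearest repeat on the requested side of its
#' 5'/3' orientation. Distance is the count of bases strictly between the
#' gene span and the repeat span; bookended features are at distance 0.
#' Repeats overlapping the gene are excluded when `ignore_overlapping` (the
#' default) and otherwise reported with distance 0. Ties are broken by the
#' smaller repeat start coordinate.
#'
#' @param genes Gene tibble.
#' @param repeats Repeat tibble.
#' @param side `"upstream"` or `"downstream"` (relative to gene strand).
#' @param ignore_overlapping Drop repeats that share bases with the gene span.
#' @return A tibble `gene_id`, `repeat_id`, `distance` (`NA` when no repeat
#'   exists on that side).
#' @export
closest_repeat <- function(genes, repeats, side = c("upstream", "downstream"),
                           ignore_overlapping = TRUE) {
  side <- match.arg(side)
  reps_by_chrom <- split(repeats, repeats$chrom)
  res <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    r <- reps_by_chrom[[g$chrom]]
    if (is.null(r) || nrow(r) == 0) {
      return(tibble(gene_id = g$gene_id, repeat_id = NA_character_,
                    distance = NA_real_))
    }
    left_is_up <- upstream_is_left(g$strand)
    want_left <- (side == "upstream") == left_is_up
    overlapping <- r$start < g$end & r$end > g$start
    cand <- if (want_left) !overlapping & r$end <= g$start
            else !overlapping & r$start >= g$end
    dist <- if (want_left) g$start - r$end else r$start - g$end
    if (!ignore_overlapping && any(overlapping)) {
      cand <- cand | overlapping
      dist[overlapping] <- 0
    }
    idx <- which(cand)
    if (length(idx) == 0) {
      return(tibble(gene_id = g$gene_id, repeat_id = NA_character_,
                    distance = NA_real_))
    }
    d <- dist[idx]
    best <- idx[d == min(d)]
    best <- best[which.min(r$start[best])]
    tibble(gene_id = g$gene_id, repeat_id = r$repeat_id[best],
           distance = min(d))
  })
  bind_rows(res)
}

# All repeats on one genomic side of a gene row within `window` bp (strict).
count_side_repeats <- function(g, r, want_left, window) {
  overlapping <- r$start < g$end & r$end > g$start
  if (want_left) {
    sum(!overlapping & r$end <= g$start & (g$start - r$end) < window)
  } else {
    sum(!overlapping & r$start >= g$end & (r$start - g$end) < window)
  }
}

#' Classify each gene's repeat configuration
#'
#' Counts repeats strictly within `window` bp upstream, within `window` bp
#' downstream, and overlapping any intron. A gene with exactly one non-zero
#' count gets the corresponding exclusive class (`upstream_only`,
#' `downstream_only`, `intronic_only`); all-zero genes are `no_repeat`; the
#' rest are `multiple` and are excluded from expression comparisons that
#' require an exclusive configuration.
#'
#' @param genes Gene tibble.
#' @param repeats Repeat tibble.
#' @param window Association window in bp (default 1000, strict `<`).
#' @return A tibble `gene_id`, `config`, `n_upstream`, `n_downstream`,
#'   `n_intronic`.
#' @export
classify_gene_configuration <- function(genes, repeats, window = 1000) {
  reps_by_chrom <- split(repeats, repeats$chrom)
  introns <- genes_intron_table(genes)
  intr_by_gene <- split(introns, introns$gene_id)
  res <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    r <- reps_by_chrom[[g$chrom]]
    if (is.null(r)) r <- genes[0, c("chrom", "start", "end")]
    left_is_up <- upstream_is_left(g$strand)
    n_up <- count_side_repeats(g, r, want_left = left_is_up, window = window)
    n_down <- count_side_repeats(g, r, want_left = !left_is_up, window = window)
    intr <- intr_by_gene[[g$gene_id]]
    n_intr <- if (is.null(intr) || nrow(intr) == 0) 0L else {
      sum(vapply(seq_len(nrow(r)), function(j) {
        any(r$start[j] < intr$end & r$end[j] > intr$start)
      }, logical(1)))
    }
    tibble(gene_id = g$gene_id, n_upstream = n_up, n_downstream = n_down,
           n_intronic = n_intr)
  })
  res <- bind_rows(res)
  nz <- (res$n_upstream > 0) + (res$n_downstream > 0) + (res$n_intronic > 0)
  res$config <- case_when(
    nz == 0 ~ "no_repeat",
    nz > 1 ~ "multiple",
    res$n_upstream > 0 ~ "upstream_only",
    res$n_downstream > 0 ~ "downstream_only",
    TRUE ~ "intronic_only"
  )
  select(res, "gene_id", "config", "n_upstream", "n_downstream", "n_intronic")
}

#' Methylation status of each repeat
#'
#' A context is methylated for a repeat when at least `min_calls` methylated
#' cytosine calls of that context fall within the repeat span (half-open: a
#' call at the exclusive end position does not count). `methylated` is TRUE
#' when any context is.
#'
#' @param repeats Repeat tibble.
#' @param methylation Methylation call tibble (`chrom`, `position`, `context`,
#'   `methylated`).
#' @param min_calls Minimum methylated call count per context (default 1).
#' @return `repeats` plus logical columns `CG`, `CHH`, `CWG`, `methylated`.
#' @export
repeat_methylation_status <- function(repeats, methylation, min_calls = 1) {
  out <- repeats
  meth <- filter(methylation, .data$methylated)
  for (ctx in methylation_contexts) out[[ctx]] <- FALSE
  if (nrow(meth) > 0 && nrow(repeats) > 0) {
    gr_rep <- iv_granges(repeats)
    for (ctx in methylation_contexts) {
      calls <- filter(meth, .data$context == ctx)
      if (nrow(calls) == 0) next
      gr_calls <- GenomicRanges::GRanges(
        calls$chrom, IRanges::IRanges(calls$position + 1L, width = 1L)
      )
      hits <- GenomicRanges::countOverlaps(gr_rep, gr_calls,
                                           ignore.strand = TRUE)
      out[[ctx]] <- hits >= min_calls
    }
  }
  mutate(out, methylated = .data$CG | .data$CHH | .data$CWG)
}

#' Link DMRs to repeats
#'
#' For each DMR sharing bases with at least one repeat, the partner with the
#' most shared bases defines the link, classified as `dmr_inside_repeat` (DMR
#' span contained in the repeat span, including identical spans),
#' `repeat_inside_dmr` (repeat strictly contained in the DMR) or
#' `partial_overlap`. DMRs sharing no base with any repeat are unlinked.
#'
#' @param dmrs DMR tibble.
#' @param repeats Repeat tibble.
#' @return A list of class `dmr_repeat_links` with `links` (one row per linked
#'   DMR), `pairs` (every overlapping DMR-repeat pair) and `summary`
#'   (class fractions over all DMRs and their total).
#' @export
link_dmrs_to_repeats <- function(dmrs, repeats) {
  empty <- tibble(dmr_id = character(), repeat_id = character(),
                  link_class = character(), shared_bp = numeric())
  if (nrow(dmrs) == 0 || nrow(repeats) == 0) {
    return(new_dmr_links(empty, empty, n_dmrs = nrow(dmrs)))
  }
  gd <- iv_granges(dmrs)
  gr <- iv_granges(repeats)
  hits <- GenomicRanges::findOverlaps(gd, gr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  shared <- GenomicRanges::width(IRanges::pintersect(gd[qi], gr[si]))
  pairs <- tibble(
    dmr_id = dmrs$dmr_id[qi], repeat_id = repeats$repeat_id[si],
    shared_bp = as.numeric(shared),
    d_start = dmrs$start[qi], d_end = dmrs$end[qi],
    r_start = repeats$start[si], r_end = repeats$end[si]
  )
  pairs$link_class <- case_when(
    pairs$d_start >= pairs$r_start & pairs$d_end <= pairs$r_end ~
      "dmr_inside_repeat",
    pairs$r_start >= pairs$d_start & pairs$r_end <= pairs$d_end ~
      "repeat_inside_dmr",
    TRUE ~ "partial_overlap"
  )
  links <- pairs %>%
    group_by(.data$dmr_id) %>%
    arrange(desc(.data$shared_bp), .data$r_start, .data$repeat_id,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  keep <- c("dmr_id", "repeat_id", "link_class", "shared_bp")
  new_dmr_links(select(links, dplyr::all_of(keep)),
                select(pairs, dplyr::all_of(keep)),
                n_dmrs = nrow(dmrs))
}

new_dmr_links <- function(links, pairs, n_dmrs) {
  classes <- c("partial_overlap", "dmr_inside_repeat", "repeat_inside_dmr")
  frac <- vapply(classes, function(cl) {
    if (n_dmrs == 0) 0 else sum(links$link_class == cl) / n_dmrs
  }, numeric(1))
  summary <- tibble(link_class = c(classes, "any"),
                    n = unname(c(vapply(classes, function(cl)
                      sum(links$link_class == cl), numeric(1)), nrow(links))),
                    fraction = unname(c(frac, sum(frac))))
  structure(list(links = links, pairs = pairs, summary = summary,
                 n_dmrs = n_dmrs),
            class = "dmr_repeat_links")
}

#' @export
print.dmr_repeat_links <- function(x, ...) {
  cat(sprintf("%d of %d DMRs linked to repeats (%.2f%%)\n",
              nrow(x$links), x$n_dmrs,
              100 * x$summary$fraction[x$summary$link_class == "any"]))
  print(x$summary)
  invisible(x)
}

#' @rdname link_dmrs_to_repeats
#' @param x A `dmr_repeat_links` object.
#' @param ... Unused.
#' @method tidy dmr_repeat_links
#' @export
tidy.dmr_repeat_links <- function(x, ...) x$links

#' Associate repeat-linked DMRs with genes
#'
#' A repeat-associated DMR joins a gene as `upstream`/`downstream` when its
#' span lies strictly within `window` bp of the gene on that (strand-aware)
#' side without overlapping the gene, and as `intronic` when it overlaps an
#' intron. All qualifying (gene, DMR) pairs are kept; one gene may be
#' associated with several DMRs and vice versa.
#'
#' @param links A `dmr_repeat_links` object or its `links` tibble.
#' @param dmrs DMR tibble.
#' @param genes Gene tibble.
#' @param window Association window in bp (default 1000, strict `<`).
#' @return A tibble of association records: `gene_id`, `partner_id`,
#'   `relation`, `distance` (0 for intronic).
#' @export
associate_dmrs_with_genes <- function(links, dmrs, genes, window = 1000) {
  link_tbl <- if (inherits(links, "dmr_repeat_links")) links$links else links
  d <- filter(dmrs, .data$dmr_id %in% link_tbl$dmr_id)
  empty <- tibble(gene_id = character(), partner_id = character(),
                  relation = character(), distance = numeric())
  if (nrow(d) == 0 || nrow(genes) == 0) return(empty)
  d_by_chrom <- split(d, d$chrom)
  introns <- genes_intron_table(genes)
  intr_by_gene <- split(introns, introns$gene_id)
  res <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    dd <- d_by_chrom[[g$chrom]]
    if (is.null(dd) || nrow(dd) == 0) return(empty)
    left_is_up <- upstream_is_left(g$strand)
    overlapping <- dd$start < g$end & dd$end > g$start
    left <- !overlapping & dd$end <= g$start & (g$start - dd$end) < window
    right <- !overlapping & dd$start >= g$end & (dd$start - g$end) < window
    up <- if (left_is_up) left else right
    down <- if (left_is_up) right else left
    dist_left <- g$start - dd$end
    dist_right <- dd$start - g$end
    recs <- list(
      tibble(gene_id = g$gene_id, partner_id = dd$dmr_id[up],
             relation = "upstream",
             distance = if (left_is_up) dist_left[up] else dist_right[up]),
      tibble(gene_id = g$gene_id, partner_id = dd$dmr_id[down],
             relation = "downstream",
             distance = if (left_is_up) dist_right[down] else dist_left[down])
    )
    intr <- intr_by_gene[[g$gene_id]]
    if (!is.null(intr) && nrow(intr) > 0) {
      in_intron <- vapply(seq_len(nrow(dd)), function(j) {
        any(dd$start[j] < intr$end & dd$end[j] > intr$start)
      }, logical(1))
      recs <- c(recs, list(tibble(gene_id = g$gene_id,
                                  partner_id = dd$dmr_id[in_intron],
                                  relation = "intronic", distance = 0)))
    }
    bind_rows(recs)
  })
  bind_rows(res)
}

#' Associate RIN binding peaks with DMRs
#'
#' A peak is in `overlap` mode with a DMR when the peak extended by +/- 10 bp
#' shares at least one base with it, and in `adjacent` mode when the +/- 500
#' bp extension does; every overlap-mode pair is also adjacent. Extensions are
#' clamped at chromosome bounds. A pair is `repeat_supported` when the DMR is
#' linked to a repeat.
#'
#' @param peaks RIN peak tibble.
#' @param dmrs DMR tibble.
#' @param links A `dmr_repeat_links` object (or links tibble), used for
#'   `repeat_supported`; `NULL` for all-FALSE.
#' @param overlap_ext,adjacent_ext Extensions in bp (defaults 10 and 500).
#' @param karyotype Optional karyotype for clamping.
#' @return A tibble of adjacent-mode pairs: `peak_id`, `dmr_id`, logical
#'   `overlap`, `mode`, `repeat_supported`.
#' @export
associate_rin_with_dmrs <- function(peaks, dmrs, links = NULL,
                                    overlap_ext = 10, adjacent_ext = 500,
                                    karyotype = NULL) {
  empty <- tibble(peak_id = character(), dmr_id = character(),
                  overlap = logical(), mode = character(),
                  repeat_supported = logical())
  if (nrow(peaks) == 0 || nrow(dmrs) == 0) return(empty)
  ext <- peaks
  ext$start <- pmax(0, peaks$start - adjacent_ext)
  ext$end <- peaks$end + adjacent_ext
  if (!is.null(karyotype)) {
    ext$end <- pmin(ext$end, karyotype$length[match(ext$chrom, karyotype$chrom)])
  }
  gp <- iv_granges(ext)
  gd <- iv_granges(dmrs)
  hits <- GenomicRanges::findOverlaps(gp, gd, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  # gap between the unextended peak and the DMR (negative => overlap)
  raw_gap <- pmax(peaks$start[qi], dmrs$start[si]) -
    pmin(peaks$end[qi], dmrs$end[si])
  is_overlap <- raw_gap < overlap_ext
  linked <- if (is.null(links)) character(0) else {
    lt <- if (inherits(links, "dmr_repeat_links")) links$links else links
    lt$dmr_id
  }
  tibble(
    peak_id = peaks$peak_id[qi], dmr_id = dmrs$dmr_id[si],
    overlap = is_overlap,
    mode = if_else(is_overlap, "overlap", "adjacent"),
    repeat_supported = dmrs$dmr_id[si] %in% linked
  )
}

#' Bin upstream-only genes by repeat distance
#'
#' Genes in exclusive upstream configuration are assigned to 100 bp distance
#' bins of the 1 kb association window; each gene contributes its RPKM to
#' exactly one bin.
#'
#' @param configs Output of [classify_gene_configuration()].
#' @param upstream Output of `closest_repeat(genes, repeats, "upstream")`.
#' @param expression Expression tibble (`gene_id` + condition columns).
#' @param condition Which condition's RPKM to attach (default `"leaf"`).
#' @param bin Bin width in bp (default 100).
#' @param window Association window in bp (default 1000).
#' @return A tibble `gene_id`, `distance`, `bin` (0-based bin index), `rpkm`.
#' @export
distance_binned_expression <- function(configs, upstream, expression,
                                       condition = "leaf", bin = 100,
                                       window = 1000) {
  genes_up <- filter(configs, .data$config == "upstream_only")
  d <- upstream$distance[match(genes_up$gene_id, upstream$gene_id)]
  out <- tibble(gene_id = genes_up$gene_id, distance = d,
                bin = floor(d / bin))
  out <- filter(out, !is.na(.data$distance), .data$distance < window)
  out$rpkm <- expression[[condition]][match(out$gene_id, expression$gene_id)]
  out
}
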