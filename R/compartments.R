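# Windowed coverage, k-means partition into RR/INT/RP, segment construction,
# feature assignment and standardized per-family coverage profiles.

#' Sliding-window parameters
#'
#' Defaults are the 500 kb windows with 50 kb overlap used for the coverage
#' profile, i.e. a step of 450 kb.
#'
#' @param window Window width in bp.
#' @param overlap Overlap between consecutive windows in bp
#'   (`0 <= overlap < window`).
#' @return A list of class `window_params` with `window`, `overlap`, `step`.
#' @export
window_params <- function(window = 500000, overlap = 50000) {
  if (overlap < 0 || overlap >= window) abort("need 0 <= overlap < window")
  structure(list(window = window, overlap = overlap, step = window - overlap),
            class = "window_params")
}

# Extract the CDS parts of a gene set as one interval tibble.
genes_cds_table <- function(genes) {
  if (nrow(genes) == 0 || !"cds" %in% names(genes)) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  cds <- tidyr::unnest(select(genes, "gene_id", "chrom", "cds"), "cds")
  select(cds, "chrom", "start", "end", "gene_id")
}

# Extract intron intervals; derives them from cds when no introns column.
genes_intron_table <- function(genes) {
  g <- genes
  if (!"introns" %in% names(g)) g$introns <- lapply(g$cds, cds_introns)
  tab <- tidyr::unnest(select(g, "gene_id", "chrom", "introns"), "introns")
  if (nrow(tab) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  select(tab, "gene_id", "chrom", "start", "end")
}

#' Windowed gene and repeat coverage
#'
#' Computes, for sliding windows along every chromosome, the fraction of
#' window bases covered by the repeat footprint and by the CDS footprint
#' (overlapping copies are flattened before counting; gene coverage uses CDS
#' parts, not whole gene spans). The final window of a chromosome is truncated
#' at the chromosome end and its coverage divided by its true width.
#'
#' @param genes Gene tibble with a `cds` list-column.
#' @param repeats Repeat tibble.
#' @param karyotype Karyotype tibble.
#' @param params A [window_params()].
#' @param families Repeat family names for which per-family coverage columns
#'   (`cov_<family>`) are added; `NULL` for none, `TRUE` for all present.
#' @return A tibble with one row per window: `chrom`, `start`, `end`,
#'   `repeat_cov`, `gene_cov` and optional per-family columns.
#' @export
compute_window_coverage <- function(genes, repeats, karyotype,
                                    params = window_params(),
                                    families = NULL) {
  iv_validate(repeats, karyotype, "repeat")
  windows <- purrr::map2(karyotype$chrom, karyotype$length, function(ch, L) {
    starts <- seq(0, max(0, L - 1), by = params$step)
    starts <- starts[starts < L]
    tibble(chrom = ch, start = starts, end = pmin(starts + params$window, L))
  })
  windows <- bind_rows(windows)
  cds <- genes_cds_table(genes)
  cov_frac <- function(feature_tbl) {
    bp <- window_overlap_bp(windows, feature_tbl)
    bp / (windows$end - windows$start)
  }
  windows$repeat_cov <- cov_frac(repeats)
  windows$gene_cov <- cov_frac(cds)
  if (isTRUE(families)) families <- intersect(repeat_families,
                                              unique(repeats$family))
  for (fam in families) {
    windows[[paste0("cov_", fam)]] <-
      cov_frac(filter(repeats, .data$family == fam))
  }
  windows
}

# Bases of the footprint of `features` inside each window row.
window_overlap_bp <- function(windows, features) {
  if (nrow(features) == 0) return(rep(0, nrow(windows)))
  iv_overlap_bp_per_row(windows, features)
}

#' Cluster coverage windows by k-means
#'
#' Runs k-means on the (gene coverage, repeat coverage) pairs with Euclidean
#' distance, keeping the best of `n_restarts` random starts by total
#' within-cluster sum of squares. Deterministic given `seed`.
#'
#' @param windows Output of [compute_window_coverage()].
#' @param k Number of clusters (default 3).
#' @param seed Integer seed.
#' @param n_restarts Random restarts (default 25).
#' @return `windows` with an integer `cluster` column; the `kmeans` fit is
#'   attached as attribute `"fit"`.
#' @export
cluster_windows <- function(windows, k = 3, seed = 1, n_restarts = 25) {
  m <- cbind(gene_cov = windows$gene_cov, repeat_cov = windows$repeat_cov)
  if (nrow(unique(m)) < k) {
    abort(sprintf("fewer than k = %d distinct coverage points; cannot cluster", k))
  }
  fit <- withr::with_seed(seed, kmeans(m, centers = k, nstart = n_restarts,
                                       iter.max = 100))
  out <- mutate(windows, cluster = fit$cluster)
  attr(out, "fit") <- fit
  out
}

#' Label clusters and build compartment segments
#'
#' The cluster with the highest mean repeat coverage becomes RR, the lowest
#' RP, the remaining one(s) INT. Consecutive same-label windows merge into
#' segments; where two differently labelled windows overlap, the boundary is
#' the midpoint of the overlap zone, so segments tile each chromosome exactly.
#'
#' @param windows Output of [cluster_windows()] (`cluster` column required).
#' @return A tibble of segments: `chrom`, `start`, `end`, `label`.
#' @export
label_and_segment <- function(windows) {
  means <- windows %>%
    group_by(.data$cluster) %>%
    summarise(mean_rep = mean(.data$repeat_cov), .groups = "drop") %>%
    arrange(desc(.data$mean_rep))
  if (anyDuplicated(means$mean_rep)) {
    tied <- means$cluster[duplicated(means$mean_rep) |
                            duplicated(means$mean_rep, fromLast = TRUE)]
    abort(sprintf("clusters %s tie on mean repeat coverage; cannot order RR/INT/RP",
                  paste(tied, collapse = ", ")))
  }
  lab <- rep("INT", nrow(means))
  lab[1] <- "RR"
  lab[nrow(means)] <- "RP"
  label_of <- setNames(lab, means$cluster)
  w <- mutate(windows, label = unname(label_of[as.character(.data$cluster)]))
  segs <- w %>%
    group_by(.data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    group_map(function(d, key) {
      n <- nrow(d)
      # boundary between window i and i+1: midpoint of their overlap zone
      cuts <- if (n > 1) floor((d$start[-1] + d$end[-n]) / 2) else numeric(0)
      starts <- c(d$start[1], cuts)
      ends <- c(cuts, d$end[n])
      seg <- tibble(chrom = key$chrom, start = starts, end = ends,
                    label = d$label)
      # merge consecutive same-label pieces
      run <- cumsum(c(1, as.integer(seg$label[-1] != seg$label[-n])))
      seg %>%
        group_by(run = run) %>%
        summarise(chrom = first(.data$chrom), start = min(.data$start),
                  end = max(.data$end), label = first(.data$label),
                  .groups = "drop") %>%
        select("chrom", "start", "end", "label")
    }) %>%
    bind_rows()
  arrange(segs, .data$chrom, .data$start)
}

#' Assign features to compartments
#'
#' A feature wholly inside one segment receives that segment's label; a
#' feature intersecting two or more segments is `"EXCLUDED"` (the
#' straddle-exclusion rule). Under half-open coordinates a feature ending
#' exactly at a boundary belongs to the left segment only.
#'
#' @param features Any interval tibble with an id column first.
#' @param segments Output of [label_and_segment()].
#' @return `features` with a `compartment` column.
#' @export
assign_features_to_compartments <- function(features, segments) {
  if (nrow(features) == 0) return(mutate(features, compartment = character(0)))
  gf <- iv_granges(features)
  gs <- iv_granges(segments)
  hits <- GenomicRanges::findOverlaps(gf, gs, ignore.strand = TRUE)
  nhit <- tabulate(S4Vectors::queryHits(hits), nbins = nrow(features))
  if (any(nhit == 0)) {
    abort(sprintf("feature outside all segments on %s (segments do not tile the chromosome)",
                  features$chrom[which(nhit == 0)[1]]))
  }
  lab <- rep(NA_character_, nrow(features))
  single <- which(nhit == 1)
  first_hit <- S4Vectors::selectHits(hits, select = "first")
  lab[single] <- segments$label[first_hit[single]]
  lab[nhit > 1] <- "EXCLUDED"
  mutate(features, compartment = lab)
}

#' Standardized per-family coverage profile
#'
#' Z-scores one coverage column across all windows genome-wide using the
#' population standard deviation; positive values mark enrichment, negative
#' depletion.
#'
#' @param windows Output of [compute_window_coverage()] with a
#'   `cov_<family>` column.
#' @param family Repeat family name.
#' @return `windows` with a `z` column.
#' @export
standardized_family_coverage <- function(windows, family) {
  col <- paste0("cov_", family)
  if (!col %in% names(windows)) {
    abort(sprintf("windows lack a %s column; recompute coverage with families = \"%s\"",
                  col, family))
  }
  if (nrow(windows) < 2) abort("need at least two windows")
  x <- windows[[col]]
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  if (sd_pop == 0) {
    warn(sprintf("constant %s coverage; all z-scores set to 0", family))
    return(mutate(windows, z = 0))
  }
  mutate(windows, z = (x - mu) / sd_pop)
}

#' Partition a genome into repeat-defined compartments
#'
#' One-call wrapper: windowed coverage, k-means clustering and segment
#' labelling. Returns a fit object with [generics::tidy()] and
#' [generics::glance()] methods and a [ggplot2::autoplot()] ideogram.
#'
#' @inheritParams compute_window_coverage
#' @inheritParams cluster_windows
#' @return An object of class `compartment_fit` with elements `windows`
#'   (per-window coverage, cluster and label), `segments`, `centers` and
#'   `karyotype`.
#' @export
partition_genome <- function(genes, repeats, karyotype,
                             params = window_params(), k = 3, seed = 1,
                             n_restarts = 25, families = NULL) {
  win <- compute_window_coverage(genes, repeats, karyotype, params, families)
  win <- cluster_windows(win, k = k, seed = seed, n_restarts = n_restarts)
  fit <- attr(win, "fit")
  segments <- label_and_segment(win)
  win$label <- assign_cluster_labels(win)[as.character(win$cluster)]
  structure(list(windows = win, segments = segments,
                 centers = fit$centers, tot_withinss = fit$tot.withinss,
                 karyotype = karyotype, params = params),
            class = "compartment_fit")
}

assign_cluster_labels <- function(windows) {
  means <- windows %>%
    group_by(.data$cluster) %>%
    summarise(mean_rep = mean(.data$repeat_cov), .groups = "drop") %>%
    arrange(desc(.data$mean_rep))
  lab <- rep("INT", nrow(means))
  lab[1] <- "RR"
  lab[nrow(means)] <- "RP"
  setNames(lab, means$cluster)
}

#' @export
print.compartment_fit <- function(x, ...) {
  sizes <- x$segments %>%
    group_by(.data$label) %>%
    summarise(mb = sum(.data$end - .data$start) / 1e6, .groups = "drop")
  cat("Genome partition into", nrow(sizes), "compartment classes\n")
  for (i in seq_len(nrow(sizes))) {
    cat(sprintf("  %-4s %8.2f Mb\n", sizes$label[i], sizes$mb[i]))
  }
  cat(sprintf("  (%d windows, k-means tot within-SS %.4f)\n",
              nrow(x$windows), x$tot_withinss))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a compartment fit
#'
#' @param x A `compartment_fit`.
#' @param ... Unused.
#' @return One row per window with coverage, cluster and compartment label.
#' @method tidy compartment_fit
#' @export
tidy.compartment_fit <- function(x, ...) {
  x$windows
}

#' @rdname tidy.compartment_fit
#' @return For `glance()`: a one-row tibble with window/segment counts, total
#'   within-cluster sum of squares and per-label megabases.
#' @method glance compartment_fit
#' @export
glance.compartment_fit <- function(x, ...) {
  mb <- x$segments %>%
    group_by(.data$label) %>%
    summarise(mb = sum(.data$end - .data$start) / 1e6, .groups = "drop")
  out <- tibble(n_windows = nrow(x$windows), n_segments = nrow(x$segments),
                k = nrow(x$centers), tot_withinss = x$tot_withinss)
  for (l in compartment_labels) {
    out[[paste0("mb_", l)]] <- sum(mb$mb[mb$label == l])
  }
  out
}
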