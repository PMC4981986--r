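# Seeded generator of a fully annotated synthetic genome: sequence, genes,
# repeats, expression, methylome, DMRs, RIN peaks and category labels, with
# the compartment structure and feature co-locations the analysis assumes,
# plus ground-truth tables for parameter-recovery tests.

#' Specification of a synthetic annotated genome
#'
#' Defaults state the emulated world once: compartment repeat-coverage targets
#' 0.85/0.50/0.15 and gene densities 15/57/122 per Mb for RR/INT/RP, a
#' RP-INT-RR-INT-RP chromosome layout (repeat-rich pericentromere, repeat-poor
#' tips), family mixes biased by compartment (Gypsy-heavy RR, Copia-enriched
#' INT, Class-II/SSR-enriched RP), family-specific G+C above a 0.35
#' background, compartment-dependent leaf expression (RR median 0, INT ~1.3,
#' RP ~4.9 RPKM), 5%/5%/90% up/down/stable genes between 17 and 52 d.p.a.,
#' 68 DMRs per Mb with 72.29% placed on repeats, and 5.4 RIN peaks per Mb
#' with 12.4% placed within 500 bp of a DMR.
#'
#' @param seed Single integer seed; every sub-generator derives from it.
#' @param chromosomes Karyotype tibble (default three 5 Mb chromosomes).
#' @param layout_template,layout_fractions Ordered segment labels and length
#'   fractions tiling each chromosome.
#' @param repeat_cov_targets,genes_per_mb Named per-label targets.
#' @param family_mix Named list (per label) of probability vectors over
#'   repeat families.
#' @param family_gc,background_gc Mean G+C of repeat sequence per family and
#'   of the genomic background.
#' @param expression_zero_frac,expression_meanlog,expression_sdlog Per-label
#'   zero-inflated log-normal RPKM model.
#' @param de_fractions Named fractions of up/down genes (rest stable).
#' @param de_pair Stage pair carrying the differential-expression labels.
#' @param n_proximal_consensus,base_upstream_rate,base_downstream_rate
#'   Gene-proximal repeat model: per-gene per-consensus placement probability
#'   within 1 kb upstream/downstream.
#' @param planted_enrichment Tibble (`consensus_id`, `status`, `fold`) of
#'   upstream placement biases, or `NULL`.
#' @param te_gene_prob Per-label probability that a gene is a planted TE-gene
#'   (its CDS fully covered by a high-confidence repeat).
#' @param dmrs_per_mb,dmr_fraction_associated,dmr_class_mix DMR model; the
#'   class mix splits associated DMRs into partially overlapping, contained
#'   in a repeat, and containing a repeat.
#' @param rin_per_mb,rin_fraction_near RIN peak model (fraction placed within
#'   500 bp of a DMR).
#' @param meth_calls_per_kb_repeat,meth_calls_per_kb_bg,meth_p_repeat,
#'   meth_p_bg Methylation call density and per-context methylation
#'   probabilities on repeats vs background.
#' @param meth_spreading_bp Methylation spreading distance into flanks
#'   (default 0: no spreading model).
#' @param min_segment_bp Minimum layout segment length (two window lengths).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(
    seed = 1,
    chromosomes = karyotype(paste0("chr", 1:3), rep(5e6, 3)),
    layout_template = c("RP", "INT", "RR", "INT", "RP"),
    layout_fractions = rep(0.2, 5),
    repeat_cov_targets = c(RR = 0.85, INT = 0.50, RP = 0.15),
    genes_per_mb = c(RR = 15, INT = 57, RP = 122),
    family_mix = default_family_mix(),
    family_gc = c(Gypsy = 0.42, Copia = 0.39, DNA = 0.36, NA_DNA = 0.35,
                  LINE = 0.37, SINE = 0.36, SSR = 0.30, EVE = 0.38,
                  Unclassified = 0.35),
    background_gc = 0.35,
    expression_zero_frac = c(RR = 0.60, INT = 0.10, RP = 0.05),
    expression_meanlog = c(RR = log(0.9), INT = log(1.59), RP = log(5.27)),
    expression_sdlog = 1.2,
    de_fractions = c(up = 0.05, down = 0.05),
    de_pair = "dpa17_dpa52",
    n_proximal_consensus = 20,
    base_upstream_rate = 0.15,
    base_downstream_rate = 0.05,
    planted_enrichment = NULL,
    te_gene_prob = c(RR = 0.30, INT = 0.12, RP = 0.02),
    dmrs_per_mb = 68,
    dmr_fraction_associated = 0.7229,
    dmr_class_mix = c(partial_overlap = 0.1865, dmr_inside_repeat = 0.5457,
                      repeat_inside_dmr = 0.0080),
    rin_per_mb = 5.4,
    rin_fraction_near = 0.124,
    meth_calls_per_kb_repeat = 1,
    meth_calls_per_kb_bg = 0.3,
    meth_p_repeat = c(CG = 0.9, CWG = 0.7, CHH = 0.4),
    meth_p_bg = 0.05,
    meth_spreading_bp = 0,
    min_segment_bp = 1e6) {
  if (length(layout_template) != length(layout_fractions) ||
      abs(sum(layout_fractions) - 1) > 1e-9) {
    abort("layout fractions must match the template and sum to 1")
  }
  if (any(repeat_cov_targets > 1) || any(repeat_cov_targets < 0)) {
    abort("repeat coverage targets must lie in [0, 1]")
  }
  if (sum(de_fractions) > 1) abort("de fractions must sum to <= 1")
  for (mix in family_mix) {
    if (abs(sum(mix) - 1) > 1e-9) abort("family mix must sum to 1")
  }
  spec <- list(
    seed = as.integer(seed), chromosomes = chromosomes,
    layout_template = layout_template, layout_fractions = layout_fractions,
    repeat_cov_targets = repeat_cov_targets, genes_per_mb = genes_per_mb,
    family_mix = family_mix, family_gc = family_gc,
    background_gc = background_gc,
    expression_zero_frac = expression_zero_frac,
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog,
    de_fractions = de_fractions, de_pair = de_pair,
    n_proximal_consensus = n_proximal_consensus,
    base_upstream_rate = base_upstream_rate,
    base_downstream_rate = base_downstream_rate,
    planted_enrichment = planted_enrichment,
    te_gene_prob = te_gene_prob,
    dmrs_per_mb = dmrs_per_mb,
    dmr_fraction_associated = dmr_fraction_associated,
    dmr_class_mix = dmr_class_mix / sum(dmr_class_mix),
    rin_per_mb = rin_per_mb, rin_fraction_near = rin_fraction_near,
    meth_calls_per_kb_repeat = meth_calls_per_kb_repeat,
    meth_calls_per_kb_bg = meth_calls_per_kb_bg,
    meth_p_repeat = meth_p_repeat, meth_p_bg = meth_p_bg,
    meth_spreading_bp = meth_spreading_bp,
    min_segment_bp = min_segment_bp
  )
  structure(spec, class = "synthetic_spec")
}

default_family_mix <- function() {
  list(
    RR = c(Gypsy = 0.55, Copia = 0.15, DNA = 0.04, NA_DNA = 0.04,
           LINE = 0.03, SINE = 0.02, SSR = 0.05, EVE = 0.02,
           Unclassified = 0.10),
    INT = c(Gypsy = 0.25, Copia = 0.30, DNA = 0.12, NA_DNA = 0.08,
            LINE = 0.04, SINE = 0.03, SSR = 0.06, EVE = 0.02,
            Unclassified = 0.10),
    RP = c(Gypsy = 0.10, Copia = 0.15, DNA = 0.20, NA_DNA = 0.15,
           LINE = 0.05, SINE = 0.05, SSR = 0.15, EVE = 0.02,
           Unclassified = 0.13)
  )
}

family_mean_len <- c(Gypsy = 3000, Copia = 2500, DNA = 800, NA_DNA = 400,
                     LINE = 1500, SINE = 300, SSR = 150, EVE = 1000,
                     Unclassified = 500)

family_hc_prob <- c(Gypsy = 0.8, Copia = 0.8, DNA = 0.8, NA_DNA = 0.8,
                    LINE = 0.8, SINE = 0.8, SSR = 0, EVE = 0.5,
                    Unclassified = 0)

#' Ground-truth compartment layout
#'
#' Tiles each chromosome with the spec's ordered segment template (by default
#' RP at the tips, RR centrally, INT in the transition zones).
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble `chrom`, `start`, `end`, `label` tiling every chromosome.
#' @export
generate_layout <- function(spec) {
  segs <- purrr::map2(spec$chromosomes$chrom, spec$chromosomes$length,
                      function(ch, L) {
    bounds <- round(cumsum(c(0, spec$layout_fractions)) * L)
    bounds[length(bounds)] <- L
    out <- tibble(chrom = ch, start = bounds[-length(bounds)],
                  end = bounds[-1], label = spec$layout_template)
    if (any(out$end - out$start < spec$min_segment_bp)) {
      abort(sprintf("layout segment shorter than %d bp on %s; enlarge the chromosome or change the template",
                    spec$min_segment_bp, ch))
    }
    out
  })
  layout <- bind_rows(segs)
  bad <- layout %>%
    group_by(.data$chrom) %>%
    summarise(tot = sum(.data$end - .data$start), .groups = "drop") %>%
    left_join(spec$chromosomes, by = "chrom") %>%
    filter(.data$tot != .data$length)
  if (nrow(bad) > 0) abort("layout does not tile the chromosome")
  layout
}

# Majority-label ground truth for the analysis windows.
truth_window_labels <- function(layout, karyotype, params = window_params()) {
  windows <- bind_rows(purrr::map2(karyotype$chrom, karyotype$length,
                                   function(ch, L) {
    starts <- seq(0, max(0, L - 1), by = params$step)
    starts <- starts[starts < L]
    tibble(chrom = ch, start = starts, end = pmin(starts + params$window, L))
  }))
  windows$label <- vapply(seq_len(nrow(windows)), function(i) {
    seg <- layout[layout$chrom == windows$chrom[i], , drop = FALSE]
    ov <- pmin(seg$end, windows$end[i]) - pmax(seg$start, windows$start[i])
    seg$label[which.max(ov)]
  }, character(1))
  windows
}

# --- gene placement ----------------------------------------------------------

sample_gene_structure <- function(span) {
  k <- sample(1:4, 1)
  exons <- round(runif(k, 120, 450))
  intr <- if (k > 1) round(runif(k - 1, 80, 600)) else numeric(0)
  while (sum(exons) + sum(intr) > span && k > 1) {
    k <- k - 1
    exons <- exons[seq_len(k)]
    intr <- intr[seq_len(max(0, k - 1))]
  }
  if (sum(exons) > span) exons <- min(span, 300)
  list(exons = exons, introns = intr)
}

place_genes <- function(spec, layout) {
  gene_rows <- list()
  gi <- 0
  for (s in seq_len(nrow(layout))) {
    seg <- layout[s, ]
    S <- seg$end - seg$start
    n <- rbinom(1, size = round(4 * spec$genes_per_mb[[seg$label]] * S / 1e6),
                prob = 0.25) # Poisson-like count with bounded support
    if (n == 0) next
    occ <- logical(S)
    placed <- 0
    attempts <- 0
    while (placed < n && attempts < 300 * n) {
      attempts <- attempts + 1
      span <- round(min(10000, max(600, rlnorm(1, log(2500), 0.4))))
      if (span >= S) next
      a <- sample.int(S - span, 1)      # 1-based offset within segment
      if (any(occ[a:(a + span - 1)])) next
      occ[a:(a + span - 1)] <- TRUE
      placed <- placed + 1
      gi <- gi + 1
      gstart <- seg$start + a - 1
      str <- sample_gene_structure(span)
      cds_total <- sum(str$exons) + sum(str$introns)
      off <- if (span > cds_total) sample.int(span - cds_total, 1) - 1 else 0
      cds_starts <- gstart + off +
        cumsum(c(0, head(str$exons, -1) + str$introns))
      cds <- tibble(start = cds_starts, end = cds_starts + str$exons)
      gene_rows[[gi]] <- tibble(
        gene_id = "", chrom = seg$chrom, start = gstart, end = gstart + span,
        strand = sample(c("+", "-"), 1), compartment_truth = seg$label,
        cds = list(cds)
      )
    }
  }
  genes <- bind_rows(gene_rows)
  genes <- arrange(genes, .data$chrom, .data$start)
  genes$gene_id <- sprintf("gene%05d", seq_len(nrow(genes)))
  genes$introns <- lapply(genes$cds, cds_introns)
  genes
}

# Read-only per-chromosome occupancy bitmaps for an interval set.
build_bitmap <- function(features, karyotype, pad = 0) {
  maps <- lapply(seq_len(nrow(karyotype)), function(i) {
    x <- logical(karyotype$length[i])
    f <- features[features$chrom == karyotype$chrom[i], , drop = FALSE]
    for (j in seq_len(nrow(f))) {
      a <- max(1, f$start[j] + 1 - pad)
      b <- min(length(x), f$end[j] + pad)
      if (a <= b) x[a:b] <- TRUE
    }
    x
  })
  setNames(maps, karyotype$chrom)
}

# --- repeat placement --------------------------------------------------------

place_te_gene_repeats <- function(spec, genes) {
  p <- spec$te_gene_prob[genes$compartment_truth]
  is_te <- runif(nrow(genes)) < p
  idx <- which(is_te)
  if (length(idx) == 0) {
    return(list(repeats = empty_repeats(), te_genes = character(0)))
  }
  fam <- sample(c("Gypsy", "Copia", "DNA", "LINE"), length(idx),
                replace = TRUE)
  reps <- tibble(
    repeat_id = sprintf("teg%05d", seq_along(idx)),
    chrom = genes$chrom[idx], start = genes$start[idx], end = genes$end[idx],
    strand = genes$strand[idx], family = fam,
    consensus_id = paste0("teg_", fam), layer = "primary_denovo",
    high_confidence = TRUE
  )
  list(repeats = reps, te_genes = genes$gene_id[idx])
}

empty_repeats <- function() {
  tibble(repeat_id = character(), chrom = character(), start = numeric(),
         end = numeric(), strand = character(), family = character(),
         consensus_id = character(), layer = character(),
         high_confidence = logical())
}

place_proximal_repeats <- function(spec, genes, cds_bitmap) {
  n_cons <- spec$n_proximal_consensus
  cons_ids <- sprintf("cons%02d", seq_len(n_cons))
  cons_fam <- rep(c("DNA", "NA_DNA", "SSR", "LINE", "SINE", "Unclassified",
                    "Copia", "Gypsy"), length.out = n_cons)
  planted <- spec$planted_enrichment
  status <- genes$de_status_truth %||% rep("stable", nrow(genes))
  chrom_len <- setNames(spec$chromosomes$length, spec$chromosomes$chrom)
  out <- list()
  truth <- list()
  k <- 0
  for (j in seq_len(n_cons)) {
    for (side in c("up", "down")) {
      rate <- if (side == "up") spec$base_upstream_rate
              else spec$base_downstream_rate
      p <- rep(rate, nrow(genes))
      if (side == "up" && !is.null(planted)) {
        pl <- planted[planted$consensus_id == cons_ids[j], , drop = FALSE]
        for (q in seq_len(nrow(pl))) {
          p[status == pl$status[q]] <- pmin(1, rate * pl$fold[q])
        }
      }
      hit <- which(runif(nrow(genes)) < p)
      if (length(hit) == 0) next
      len <- sample(80:300, length(hit), replace = TRUE)
      gap <- sample(0:700, length(hit), replace = TRUE)
      left <- if (side == "up") genes$strand[hit] != "-"
              else genes$strand[hit] == "-"
      start <- ifelse(left, genes$start[hit] - gap - len,
                      genes$end[hit] + gap)
      end <- start + len
      ok <- start >= 0 & end <= chrom_len[genes$chrom[hit]]
      # drop placements that would touch any CDS base (keeps TE-gene truth exact)
      for (i in which(ok)) {
        bm <- cds_bitmap[[genes$chrom[hit[i]]]]
        if (any(bm[(start[i] + 1):end[i]])) ok[i] <- FALSE
      }
      if (!any(ok)) next
      k <- k + 1
      out[[k]] <- tibble(
        repeat_id = sprintf("prox_%s_%s_%s", cons_ids[j], side,
                            genes$gene_id[hit[ok]]),
        chrom = genes$chrom[hit[ok]], start = start[ok], end = end[ok],
        strand = "*", family = cons_fam[j], consensus_id = cons_ids[j],
        layer = "primary_denovo", high_confidence = FALSE
      )
      if (side == "up") {
        truth[[k]] <- tibble(
          gene_id = genes$gene_id[hit[ok]], consensus_id = cons_ids[j],
          repeat_id = out[[k]]$repeat_id, distance = gap[ok],
          status = status[hit[ok]]
        )
      }
    }
  }
  list(repeats = bind_rows(out), planted_upstream = bind_rows(truth),
       consensus_ids = cons_ids)
}

# Fill each segment with background repeats up to the per-label coverage
# target. New copies are placed into free gaps (random sequential placement
# alone jams well below the 0.85 repeat-rich target), then a configurable
# fraction of nested copies is added inside existing elements to emulate
# nested insertions. High-confidence copies overlapping the CDS of a
# non-TE-gene are demoted to low confidence so planted TE-gene truth stays
# exact.
place_background_repeats <- function(spec, layout, existing, cds_bitmap,
                                     nested_fraction = 0.1) {
  out <- list()
  k <- 0
  for (s in seq_len(nrow(layout))) {
    seg <- layout[s, ]
    S <- seg$end - seg$start
    target <- spec$repeat_cov_targets[[seg$label]]
    mix <- spec$family_mix[[seg$label]]
    occ <- logical(S)
    ex <- existing[existing$chrom == seg$chrom &
                     existing$end > seg$start & existing$start < seg$end, ,
                   drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      a <- max(1, ex$start[j] - seg$start + 1)
      b <- min(S, ex$end[j] - seg$start)
      if (a <= b) occ[a:b] <- TRUE
    }
    covered <- sum(occ)
    cbm <- cds_bitmap[[seg$chrom]]
    seg_rows <- list()
    kk <- 0
    iter <- 0
    while (covered / S < target && iter < 200) {
      iter <- iter + 1
      gaps <- rle_gaps(occ)
      gaps <- gaps[gaps$width >= 50, , drop = FALSE]
      if (nrow(gaps) == 0) break
      m <- min(nrow(gaps), max(5, ceiling((target * S - covered) / 1200)))
      pick <- sample.int(nrow(gaps), m, prob = gaps$width)
      pick <- unique(pick)
      fam <- sample(names(mix), length(pick), replace = TRUE, prob = mix)
      want <- pmin(10000, pmax(50, round(rlnorm(length(pick),
                                                log(family_mean_len[fam]),
                                                0.5))))
      hc <- runif(length(pick)) < family_hc_prob[fam]
      for (i in seq_along(pick)) {
        if (covered / S >= target) break
        gw <- gaps$width[pick[i]]
        len <- min(want[i], gw)
        a <- gaps$start[pick[i]] + sample.int(gw - len + 1, 1) - 1
        sl <- a:(a + len - 1)
        if (hc[i] && any(cbm[seg$start + sl])) hc[i] <- FALSE
        covered <- covered + sum(!occ[sl])
        occ[sl] <- TRUE
        kk <- kk + 1
        seg_rows[[kk]] <- list(chrom = seg$chrom, start = seg$start + a - 1,
                               end = seg$start + a - 1 + len,
                               family = fam[i], hc = hc[i])
      }
    }
    # nested copies inside already-placed background elements
    n_nested <- floor(nested_fraction * kk)
    if (n_nested > 0) {
      hosts <- sample.int(kk, n_nested, replace = TRUE)
      for (h in hosts) {
        host <- seg_rows[[h]]
        hw <- host$end - host$start
        if (hw < 120) next
        len <- sample(50:min(hw, 2000), 1)
        a0 <- host$start + sample.int(hw - len + 1, 1) - 1
        fam <- sample(names(mix), 1, prob = mix)
        hc <- runif(1) < family_hc_prob[fam]
        if (hc && any(cbm[(a0 + 1):(a0 + len)])) hc <- FALSE
        kk <- kk + 1
        seg_rows[[kk]] <- list(chrom = seg$chrom, start = a0, end = a0 + len,
                               family = fam, hc = hc)
      }
    }
    out <- c(out, seg_rows)
    k <- k + kk
  }
  if (k == 0) return(empty_repeats())
  df <- bind_rows(lapply(out, as_tibble))
  tibble(
    repeat_id = sprintf("bg%06d", seq_len(nrow(df))),
    chrom = df$chrom, start = df$start, end = df$end, strand = "*",
    family = df$family,
    consensus_id = paste0(df$family, "_fam",
                          1 + (seq_len(nrow(df)) %% 5)),
    layer = if_else(runif(nrow(df)) < 0.1, "secondary_denovo",
                    "primary_denovo"),
    high_confidence = df$hc
  )
}

# Free runs of a logical occupancy vector as 1-based (start, width) rows.
rle_gaps <- function(occ) {
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble(start = starts[!r$values], width = r$lengths[!r$values])
}

# --- expression and differential regulation ----------------------------------

#' Assign expression and differential-expression status
#'
#' Draws zero-inflated log-normal RPKM per condition with
#' compartment-dependent parameters (RR genes mostly silent, RP most
#' expressed) and samples up/down/stable labels for the spec's stage pair;
#' up genes are forced to have higher RPKM at the later stage than at the
#' earlier one, down genes the reverse.
#'
#' @param spec A [synthetic_spec()].
#' @param genes Gene tibble with a `compartment_truth` column.
#' @return A list with `expression` (gene_id + five condition columns) and
#'   `de_status` (`gene_id`, `comparison`, `status`).
#' @export
assign_expression_and_de <- function(spec, genes) {
  n <- nrow(genes)
  lab <- genes$compartment_truth
  draw <- function() {
    x <- rlnorm(n, spec$expression_meanlog[lab], spec$expression_sdlog)
    zero <- runif(n) < spec$expression_zero_frac[lab]
    round(ifelse(zero, 0, x), 3)
  }
  expr <- tibble(gene_id = genes$gene_id, leaf = draw(), dpa17 = draw(),
                 dpa39 = draw(), dpa42 = draw(), dpa52 = draw())
  fr <- spec$de_fractions
  status <- sample(c("up", "down", "stable"), n, replace = TRUE,
                   prob = c(fr[["up"]], fr[["down"]], 1 - sum(fr)))
  stages <- stringr::str_split(spec$de_pair, "_")[[1]]
  early <- stages[1]; late <- stages[2]
  up <- status == "up"; down <- status == "down"
  base_up <- pmax(expr[[early]][up], 0.5)
  expr[[late]][up] <- round(base_up * runif(sum(up), 2, 8), 3)
  base_down <- pmax(expr[[late]][down], 0.5)
  expr[[early]][down] <- round(base_down * runif(sum(down), 2, 8), 3)
  expr[[late]][down] <- base_down
  list(expression = expr,
       de_status = tibble(gene_id = genes$gene_id,
                          comparison = spec$de_pair, status = status))
}

# --- categories --------------------------------------------------------------

go_pool <- c("GO:0005515", "GO:0047714", "GO:0009611", "GO:0016020",
             "GO:0008152", "GO:0019199", "GO:0030599", "GO:0042936",
             "GO:0080054", "GO:0016168")

assign_categories <- function(genes) {
  lab <- genes$compartment_truth
  n <- nrow(genes)
  origin_probs <- list(
    RR = c(ANC2 = 0.30, ANC1 = 0.30, NEW = 0.35, unknown = 0.05),
    INT = c(ANC2 = 0.45, ANC1 = 0.30, NEW = 0.20, unknown = 0.05),
    RP = c(ANC2 = 0.55, ANC1 = 0.25, NEW = 0.15, unknown = 0.05)
  )
  origin <- vapply(lab, function(l) {
    sample(names(origin_probs[[l]]), 1, prob = origin_probs[[l]])
  }, character(1))
  stress_p <- c(RR = 0.04, INT = 0.08, RP = 0.08)
  stress <- runif(n) < stress_p[lab]
  n_go <- sample(0:3, n, replace = TRUE, prob = c(0.35, 0.35, 0.2, 0.1))
  go <- vapply(n_go, function(k) {
    if (k == 0) "" else paste(sample(go_pool, k), collapse = ",")
  }, character(1))
  tibble(gene_id = genes$gene_id, go_terms = go, origin = unname(origin),
         stress = unname(stress))
}

# --- methylome, DMRs, RIN peaks ----------------------------------------------

#' Generate methylation calls, DMRs and RIN peaks
#'
#' Methylation calls are dense and mostly methylated on repeats and sparse
#' and mostly unmethylated elsewhere. DMRs are placed non-overlapping, a
#' target fraction of them on repeats (inside, partially overlapping or
#' containing a repeat); the rest are rejection-sampled into repeat-free
#' space so the realized association fraction matches the target exactly up
#' to placement feasibility. RIN peaks are likewise split into a
#' within-500-bp-of-a-DMR set and a far set.
#'
#' @param spec A [synthetic_spec()].
#' @param repeats Placed repeat tibble.
#' @return A list with `methylation`, `dmrs`, `rin_peaks`, `dmr_truth`,
#'   `rin_truth`.
#' @export
generate_methylome_and_dmrs <- function(spec, repeats) {
  kary <- spec$chromosomes
  meth <- simulate_methylation(spec, repeats)
  rep_bitmap <- build_bitmap(repeats, kary)
  reps_by_chrom <- split(repeats, repeats$chrom)
  genome_mb <- sum(kary$length) / 1e6
  n_dmrs <- round(spec$dmrs_per_mb * genome_mb)
  per_chrom <- round(n_dmrs * kary$length / sum(kary$length))
  stage_pairs <- apply(combn(ripening_stages, 2), 2, paste, collapse = "_")
  dmr_rows <- list()
  truth_rows <- list()
  di <- 0
  for (ci in seq_len(nrow(kary))) {
    ch <- kary$chrom[ci]; L <- kary$length[ci]
    rb <- rep_bitmap[[ch]]
    r <- reps_by_chrom[[ch]]
    occ <- logical(L)
    n_here <- per_chrom[ci]
    # exact associated count (shuffled), so the realized fraction matches the
    # stated target up to rounding rather than binomial noise
    n_assoc <- round(spec$dmr_fraction_associated * n_here)
    assoc <- sample(c(rep(TRUE, n_assoc), rep(FALSE, n_here - n_assoc)))
    cls <- sample(names(spec$dmr_class_mix), n_here, replace = TRUE,
                  prob = spec$dmr_class_mix)
    rw <- if (is.null(r)) numeric(0) else r$end - r$start
    for (q in seq_len(n_here)) {
      len <- round(min(2000, max(50, rlnorm(1, log(250), 0.6))))
      placed <- FALSE
      for (try in seq_len(300)) {
        if (assoc[q] && !is.null(r) && nrow(r) > 0) {
          pos <- place_dmr_on_repeat(cls[q], r, rw, len, L)
        } else {
          s0 <- sample.int(L - len, 1) - 1
          pos <- c(s0, s0 + len)
          if (any(rb[(pos[1] + 1):pos[2]])) next  # must stay repeat-free
        }
        if (is.null(pos)) break
        if (any(occ[(pos[1] + 1):pos[2]])) next   # DMRs must not overlap
        occ[(pos[1] + 1):pos[2]] <- TRUE
        placed <- TRUE
        break
      }
      if (!placed) {
        if (assoc[q]) next  # no suitable repeat; drop silently
        abort("more DMRs requested than placeable without overlap")
      }
      di <- di + 1
      dmr_rows[[di]] <- tibble(
        dmr_id = "", chrom = ch, start = pos[1], end = pos[2],
        comparison = sample(stage_pairs, 1, prob = c(2, 1, 1, 1, 1, 2)[
          seq_along(stage_pairs)]),
        direction = sample(c("hypo", "hyper"), 1, prob = c(0.8, 0.2))
      )
      truth_rows[[di]] <- tibble(dmr_id = "", associated = assoc[q],
                                 planted_class = if (assoc[q]) cls[q]
                                                 else NA_character_)
    }
  }
  dmrs <- bind_rows(dmr_rows)
  dmr_truth <- bind_rows(truth_rows)
  dmrs$dmr_id <- sprintf("dmr%05d", seq_len(nrow(dmrs)))
  dmr_truth$dmr_id <- dmrs$dmr_id
  rin <- simulate_rin_peaks(spec, dmrs)
  list(methylation = meth, dmrs = dmrs, rin_peaks = rin$peaks,
       dmr_truth = dmr_truth, rin_truth = rin$truth)
}

place_dmr_on_repeat <- function(cls, r, rw, len, L) {
  if (cls == "dmr_inside_repeat") {
    cand <- which(rw >= len)
    if (length(cand) == 0) return(NULL)
    i <- cand[sample.int(length(cand), 1)]
    s0 <- r$start[i] + sample.int(rw[i] - len + 1, 1) - 1
    c(s0, s0 + len)
  } else if (cls == "repeat_inside_dmr") {
    cand <- which(rw < len)
    if (length(cand) == 0) return(NULL)
    i <- cand[sample.int(length(cand), 1)]
    a <- sample.int(len - rw[i] + 1, 1) - 1
    s0 <- max(0, r$start[i] - a)
    if (s0 + len > L) s0 <- L - len
    if (s0 > r$start[i] || s0 + len < r$end[i]) return(NULL)
    c(s0, s0 + len)
  } else {
    i <- sample.int(nrow(r), 1)
    o <- sample.int(max(1, min(len, rw[i]) - 1), 1)
    if (runif(1) < 0.5) {
      s0 <- r$end[i] - o        # crosses the right edge
    } else {
      s0 <- r$start[i] - (len - o)  # crosses the left edge
    }
    if (s0 < 0 || s0 + len > L) return(NULL)
    if (s0 <= r$start[i] && s0 + len >= r$end[i]) return(NULL)
    if (s0 >= r$start[i] && s0 + len <= r$end[i]) return(NULL)
    c(s0, s0 + len)
  }
}

simulate_methylation <- function(spec, repeats) {
  kary <- spec$chromosomes
  ctx_prob <- c(CG = 0.4, CHH = 0.4, CWG = 0.2)
  rep_w <- repeats$end - repeats$start
  n_rep_calls <- pmax(1, round(rep_w * spec$meth_calls_per_kb_repeat / 1000))
  rep_idx <- rep(seq_len(nrow(repeats)), n_rep_calls)
  pos <- repeats$start[rep_idx] +
    floor(runif(length(rep_idx)) * rep_w[rep_idx])
  ctx <- sample(names(ctx_prob), length(rep_idx), replace = TRUE,
                prob = ctx_prob)
  on_rep <- tibble(
    chrom = repeats$chrom[rep_idx], position = pos, context = ctx,
    methylated = runif(length(rep_idx)) < spec$meth_p_repeat[ctx]
  )
  n_bg <- round(sum(kary$length) * spec$meth_calls_per_kb_bg / 1000)
  bg_chrom <- sample(kary$chrom, n_bg, replace = TRUE,
                     prob = kary$length / sum(kary$length))
  bg_pos <- floor(runif(n_bg) * kary$length[match(bg_chrom, kary$chrom)])
  bg_ctx <- sample(names(ctx_prob), n_bg, replace = TRUE, prob = ctx_prob)
  bg <- tibble(chrom = bg_chrom, position = bg_pos, context = bg_ctx,
               methylated = runif(n_bg) < spec$meth_p_bg)
  arrange(bind_rows(on_rep, bg), .data$chrom, .data$position) %>%
    distinct(.data$chrom, .data$position, .data$context, .keep_all = TRUE)
}

simulate_rin_peaks <- function(spec, dmrs) {
  kary <- spec$chromosomes
  n <- round(spec$rin_per_mb * sum(kary$length) / 1e6)
  n_near <- round(spec$rin_fraction_near * n)
  near <- sample(c(rep(TRUE, n_near), rep(FALSE, n - n_near)))
  dmr_ext_bitmap <- build_bitmap(dmrs, kary, pad = 500)
  dmrs_by_chrom <- split(dmrs, dmrs$chrom)
  chrom <- sample(kary$chrom, n, replace = TRUE,
                  prob = kary$length / sum(kary$length))
  rows <- list()
  truth <- list()
  for (i in seq_len(n)) {
    L <- kary$length[match(chrom[i], kary$chrom)]
    len <- sample(150:400, 1)
    if (near[i]) {
      dd <- dmrs_by_chrom[[chrom[i]]]
      if (is.null(dd) || nrow(dd) == 0) { near[i] <- FALSE } else {
        j <- sample.int(nrow(dd), 1)
        gap <- sample(0:480, 1)
        s0 <- if (runif(1) < 0.5) dd$end[j] + gap else dd$start[j] - gap - len
        if (s0 < 0 || s0 + len > L) {
          s0 <- max(0, min(L - len, s0))
        }
        rows[[i]] <- tibble(peak_id = "", chrom = chrom[i], start = s0,
                            end = s0 + len)
        truth[[i]] <- tibble(peak_id = "", near_dmr = TRUE,
                             dmr_id = dd$dmr_id[j])
        next
      }
    }
    bm <- dmr_ext_bitmap[[chrom[i]]]
    for (try in seq_len(1000)) {
      s0 <- sample.int(L - len, 1) - 1
      if (!any(bm[(s0 + 1):(s0 + len)])) break
      s0 <- NA
    }
    if (is.na(s0)) abort("could not place a RIN peak away from all DMRs")
    rows[[i]] <- tibble(peak_id = "", chrom = chrom[i], start = s0,
                        end = s0 + len)
    truth[[i]] <- tibble(peak_id = "", near_dmr = FALSE,
                         dmr_id = NA_character_)
  }
  peaks <- bind_rows(rows)
  tr <- bind_rows(truth)
  peaks$peak_id <- sprintf("rin%04d", seq_len(nrow(peaks)))
  tr$peak_id <- peaks$peak_id
  list(peaks = peaks, truth = tr)
}

# --- sequence ----------------------------------------------------------------

simulate_sequences <- function(spec, repeats) {
  bases <- c("A", "C", "G", "T")
  gc_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  out <- lapply(seq_len(nrow(spec$chromosomes)), function(i) {
    L <- spec$chromosomes$length[i]
    x <- sample(bases, L, replace = TRUE, prob = gc_probs(spec$background_gc))
    r <- repeats[repeats$chrom == spec$chromosomes$chrom[i], , drop = FALSE]
    for (j in seq_len(nrow(r))) {
      w <- r$end[j] - r$start[j]
      x[(r$start[j] + 1):r$end[j]] <-
        sample(bases, w, replace = TRUE,
               prob = gc_probs(spec$family_gc[[r$family[j]]]))
    }
    paste(x, collapse = "")
  })
  setNames(unlist(out), spec$chromosomes$chrom)
}

# --- top-level generator -----------------------------------------------------

#' Generate a synthetic annotated genome
#'
#' Runs every sub-generator under the spec's single seed: layout, genes,
#' TE-genes, gene-proximal repeats (with optional planted consensus
#' enrichment), background repeats up to the per-compartment coverage
#' targets, expression and differential regulation, category labels,
#' methylome, DMRs and RIN peaks, and (optionally) chromosome sequences with
#' family-specific G+C. The same seed yields a byte-identical dataset.
#'
#' @param spec A [synthetic_spec()].
#' @param sequence Generate chromosome sequences (disable to speed up
#'   simulations that do not need them).
#' @return A list of class `synthetic_dataset` with elements `karyotype`,
#'   `sequences`, `genes`, `repeats`, `expression`, `de_status`,
#'   `categories`, `methylation`, `dmrs`, `rin_peaks` and `truth` (layout,
#'   per-window labels, TE-genes, planted upstream placements, DMR and RIN
#'   placement truth).
#' @export
generate_genome <- function(spec, sequence = TRUE) {
  if (any(spec$repeat_cov_targets > 1)) abort("requested coverage > 1")
  withr::with_seed(spec$seed, {
    layout <- generate_layout(spec)
    genes <- place_genes(spec, layout)
    ex <- assign_expression_and_de(spec, genes)
    genes$de_status_truth <- ex$de_status$status
    teg <- place_te_gene_repeats(spec, genes)
    # only the CDS of non-TE-genes must stay clear of high-confidence repeats
    non_te_cds <- genes_cds_table(filter(genes,
                                         !genes$gene_id %in% teg$te_genes))
    cds_bitmap <- build_bitmap(non_te_cds, spec$chromosomes)
    prox <- place_proximal_repeats(spec, genes, cds_bitmap)
    existing <- bind_rows(teg$repeats, prox$repeats)
    bg <- place_background_repeats(spec, layout, existing, cds_bitmap)
    repeats <- arrange(bind_rows(teg$repeats, prox$repeats, bg),
                       .data$chrom, .data$start)
    categories <- assign_categories(genes)
    md <- generate_methylome_and_dmrs(spec, repeats)
    seqs <- if (sequence) simulate_sequences(spec, repeats) else NULL
    truth <- list(
      layout = layout,
      windows = truth_window_labels(layout, spec$chromosomes),
      te_genes = teg$te_genes,
      planted_upstream = prox$planted_upstream,
      consensus_ids = prox$consensus_ids,
      dmr_truth = md$dmr_truth,
      rin_truth = md$rin_truth
    )
    structure(list(
      karyotype = spec$chromosomes, sequences = seqs,
      genes = select(genes, -"de_status_truth"),
      repeats = repeats,
      expression = ex$expression, de_status = ex$de_status,
      categories = categories, methylation = md$methylation,
      dmrs = md$dmrs, rin_peaks = md$rin_peaks,
      truth = truth, spec = spec
    ), class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic annotated genome: %d chromosomes (%.1f Mb), %d genes, %d repeats,\n  %d methylation calls, %d DMRs, %d RIN peaks (seed %d)\n",
    nrow(x$karyotype), sum(x$karyotype$length) / 1e6, nrow(x$genes),
    nrow(x$repeats), nrow(x$methylation), nrow(x$dmrs), nrow(x$rin_peaks),
    x$spec$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits exactly the formats the readers consume: FASTA sequences, GFF3 genes
#' and repeats, BED DMRs and RIN peaks, TSV expression/methylation/categories
#' /de-status tables, a karyotype TSV and a ground-truth JSON.
#'
#' @param dataset A `synthetic_dataset`.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_karyotype(dataset$karyotype, p("karyotype.tsv"))
  if (!is.null(dataset$sequences)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(dataset$sequences), p("genome.fa"))
  }
  write_features(dataset$genes, p("genes.gff3"), "gff3", "gene")
  write_features(dataset$repeats, p("repeats.gff3"), "gff3", "repeat")
  write_features(dataset$dmrs, p("dmrs.bed"), "bed", "dmr")
  write_features(dataset$rin_peaks, p("rin_peaks.bed"), "bed", "rin")
  write_quant_table(dataset$expression, p("expression.tsv"))
  write_quant_table(dataset$methylation, p("methylation.tsv"))
  write_quant_table(dataset$categories, p("categories.tsv"))
  write_quant_table(dataset$de_status, p("de_status.tsv"))
  truth <- dataset$truth
  jsonlite::write_json(truth, p("truth.json"), digits = NA, pretty = TRUE)
  invisible(outdir)
}
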