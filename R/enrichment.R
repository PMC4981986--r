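# Categorical and rank statistics: expected counts, chi-square with
# Bonferroni, compartment category enrichment, consensus-vs-DE enrichment
# with the 10-gene / 2-fold / 0.001 filters, Mann-Whitney comparisons and
# Monte-Carlo placement nulls.

#' Expected category count in a region
#'
#' `EXP = OBS * REG / TOT`: the genome-wide count of a category (`OBS`)
#' scaled by the region's share of genes (`REG` of `TOT`). Summed over
#' regions whose `REG` partition `TOT`, the expected counts conserve `OBS`.
#'
#' @param obs Genome-wide count of the category.
#' @param reg Gene count of the region of interest.
#' @param tot Total gene count.
#' @return The real-valued expected count.
#' @examples
#' expected_count(100, 50, 200) # 25
#' @export
expected_count <- function(obs, reg, tot) {
  if (any(tot == 0)) abort("total gene count is zero")
  if (any(obs < 0) || any(obs > tot)) abort("need 0 <= obs <= tot")
  if (any(reg <= 0) || any(reg > tot)) abort("need 0 < reg <= tot")
  obs * reg / tot
}

#' Pearson chi-square test
#'
#' For an r x c contingency table the expected cells are the product of the
#' margins over the grand total and df = (r-1)(c-1); for a goodness-of-fit
#' comparison against given expected cells, df = cells - 1. The Yates
#' continuity correction (|O-E| reduced by 0.5 before squaring) applies to
#' 2 x 2 contingency tables and defaults to on for those, off otherwise.
#'
#' @param observed Matrix (contingency) or numeric vector (goodness of fit).
#' @param expected Expected cells for goodness of fit; `NULL` for a
#'   contingency table.
#' @param yates Logical; `NULL` picks the 2 x 2 default.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(observed, expected = NULL, yates = NULL) {
  if (is.null(expected)) {
    m <- as.matrix(observed)
    if (nrow(m) < 2 || ncol(m) < 2) {
      abort("contingency mode needs a matrix with >= 2 rows and columns")
    }
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    df <- (nrow(m) - 1) * (ncol(m) - 1)
    if (is.null(yates)) yates <- nrow(m) == 2 && ncol(m) == 2
    o <- as.numeric(m)
    e <- as.numeric(e)
  } else {
    o <- as.numeric(observed)
    e <- as.numeric(expected)
    if (length(o) != length(e)) abort("observed and expected lengths differ")
    df <- length(o) - 1
    if (is.null(yates)) yates <- FALSE
  }
  if (any(e <= 0)) abort("expected cell <= 0; chi-square undefined")
  dev <- abs(o - e)
  if (yates) dev <- pmax(0, dev - 0.5)
  x2 <- sum(dev^2 / e)
  tibble(statistic = x2, df = df,
         p_value = pchisq(x2, df = df, lower.tail = FALSE))
}

#' Bonferroni adjustment
#'
#' @param p P-values in \[0, 1\].
#' @param m Number of comparisons (default `length(p)`).
#' @return `pmin(1, p * m)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  pmin(1, p * m)
}

#' Mann-Whitney U test
#'
#' Rank-sum U with average ranks for ties. The two-sided p-value uses exact
#' enumeration when both samples have at most `exact_max` observations and
#' there are no ties, and otherwise the normal approximation with
#' tie-corrected variance and a 0.5 continuity correction (the behaviour of a
#' continuity-corrected rank-sum test).
#'
#' @param a,b Numeric samples (both nonempty).
#' @param exact_max Largest per-sample size for exact enumeration (default 8).
#' @return A one-row tibble: `statistic` (U of sample `a`), `p_value`,
#'   `method`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 8) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be nonempty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && na <= exact_max && nb <= exact_max) {
    # enumerate all rank splits; U is determined by which ranks go to sample a
    splits <- combn(n, na)
    us <- colSums(matrix(splits, nrow = na)) - na * (na + 1) / 2
    p <- 2 * min(mean(us <= u), mean(us >= u))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tt <- table(c(a, b))
    tie_term <- sum(tt^3 - tt) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 == 0) {
      return(tibble(statistic = u, p_value = 1, method = "normal"))
    }
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  tibble(statistic = u, p_value = min(1, p), method = method)
}

#' Category enrichment across genome compartments
#'
#' For every category, computes per-region observed counts, the expected
#' count `EXP = OBS * REG / TOT`, and the fold observed/expected; then
#' compares each pair of regions (RR vs INT, RR vs RP, INT vs RP) with a
#' 2 x 2 chi-square (category vs not, region A vs region B, Yates-corrected)
#' and applies a Bonferroni correction over all categories tested.
#'
#' TE-gene-flagged genes and genes excluded by the straddle rule must be
#' removed before calling (rows with `te_gene == TRUE` or
#' `compartment == "EXCLUDED"` are dropped if those columns are present).
#'
#' @param gene_labels Tibble with `gene_id` and `compartment` (RR/INT/RP).
#' @param assignments Tibble with `gene_id` and `category`, one row per
#'   assignment (a gene may carry several categories, e.g. GO terms).
#' @return A list of class `compartment_enrichment` with `counts` (category x
#'   region observed/expected/fold) and `tests` (category x region-pair
#'   chi-square with `p_bonferroni`).
#' @export
compartment_category_enrichment <- function(gene_labels, assignments) {
  g <- gene_labels
  if ("te_gene" %in% names(g)) g <- filter(g, !.data$te_gene)
  g <- filter(g, .data$compartment %in% compartment_labels)
  if (nrow(g) == 0) abort("no genes with RR/INT/RP labels")
  reg <- count(g, .data$compartment, name = "reg")
  if (!all(compartment_labels %in% reg$compartment)) {
    abort(sprintf("region with zero genes: %s",
                  setdiff(compartment_labels, reg$compartment)[1]))
  }
  tot <- nrow(g)
  a <- inner_join(assignments, g, by = "gene_id")
  obs_genome <- count(a, .data$category, name = "obs_genome")
  counts <- a %>%
    count(.data$category, .data$compartment, name = "observed") %>%
    tidyr::complete(.data$category,
                    compartment = compartment_labels,
                    fill = list(observed = 0L)) %>%
    left_join(obs_genome, by = "category") %>%
    left_join(reg, by = "compartment") %>%
    mutate(expected = expected_count(.data$obs_genome, .data$reg, tot),
           fold = .data$observed / .data$expected)
  pair_list <- list(c("RR", "INT"), c("RR", "RP"), c("INT", "RP"))
  cats <- unique(counts$category)
  tests <- purrr::map(cats, function(cat) {
    purrr::map(pair_list, function(pr) {
      ga <- filter(g, .data$compartment == pr[1])
      gb <- filter(g, .data$compartment == pr[2])
      in_a <- sum(a$category == cat & a$compartment == pr[1])
      in_b <- sum(a$category == cat & a$compartment == pr[2])
      m <- rbind(c(in_a, nrow(ga) - in_a), c(in_b, nrow(gb) - in_b))
      res <- if (any(colSums(m) == 0)) {
        tibble(statistic = NA_real_, df = 1, p_value = NA_real_)
      } else {
        chi_square_test(m)
      }
      tibble(category = cat, region_a = pr[1], region_b = pr[2],
             observed_a = in_a, observed_b = in_b,
             statistic = res$statistic, df = res$df, p_value = res$p_value)
    }) %>% bind_rows()
  }) %>% bind_rows()
  tests <- tests %>%
    group_by(.data$region_a, .data$region_b) %>%
    mutate(p_bonferroni = bonferroni_adjust(.data$p_value, m = length(cats))) %>%
    ungroup()
  structure(list(counts = select(counts, "category", "compartment",
                                 "observed", "expected", "fold"),
                 tests = tests, n_categories = length(cats), total_genes = tot),
            class = "compartment_enrichment")
}

#' @export
print.compartment_enrichment <- function(x, ...) {
  cat(sprintf("Compartment enrichment over %d categories (%d genes)\n",
              x$n_categories, x$total_genes))
  sig <- filter(x$tests, .data$p_bonferroni < 0.001)
  cat(sprintf("%d of %d pairwise comparisons with Bonferroni p < 0.001\n",
              nrow(sig), nrow(x$tests)))
  invisible(x)
}

#' @rdname compartment_category_enrichment
#' @param x A `compartment_enrichment` object.
#' @param ... Unused.
#' @method tidy compartment_enrichment
#' @export
tidy.compartment_enrichment <- function(x, ...) x$tests

#' Build the consensus-by-regulation-status count table
#'
#' Counts, for every repeat consensus, the genes with at least one copy of
#' that consensus strictly within `window` bp upstream, split by the gene's
#' regulation status for one stage pair. `n_expressed` counts, per cell, the
#' genes with RPKM > 0 at the later stage of the pair (used by the
#' "at least 10 genes expressed" filter).
#'
#' @param genes Gene tibble.
#' @param repeats Repeat tibble with `consensus_id`.
#' @param de_status Tibble `gene_id`, `comparison`, `status`.
#' @param expression Expression tibble, or `NULL` (then `n_expressed =
#'   observed`).
#' @param stage_pair Stage pair, e.g. `"dpa17_dpa52"`.
#' @param window Upstream window in bp (default 1000, strict `<`).
#' @return A tibble `consensus_id`, `status`, `observed`, `n_expressed`.
#' @export
consensus_status_table <- function(genes, repeats, de_status,
                                   expression = NULL,
                                   stage_pair = "dpa17_dpa52",
                                   window = 1000) {
  st <- filter(de_status, .data$comparison == stage_pair)
  status <- setNames(st$status, st$gene_id)
  reps <- filter(repeats, !is.na(.data$consensus_id))
  reps_by_chrom <- split(reps, reps$chrom)
  later <- stringr::str_split(stage_pair, "_")[[1]][2]
  expressed <- if (is.null(expression)) NULL else
    setNames(expression[[later]] > 0, expression$gene_id)
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    r <- reps_by_chrom[[g$chrom]]
    if (is.null(r) || nrow(r) == 0) return(NULL)
    left_is_up <- upstream_is_left(g$strand)
    overlapping <- r$start < g$end & r$end > g$start
    near <- if (left_is_up) {
      !overlapping & r$end <= g$start & (g$start - r$end) < window
    } else {
      !overlapping & r$start >= g$end & (r$start - g$end) < window
    }
    if (!any(near)) return(NULL)
    tibble(gene_id = g$gene_id, consensus_id = unique(r$consensus_id[near]))
  })
  rows <- bind_rows(rows)
  if (nrow(rows) == 0) {
    return(tibble(consensus_id = character(), status = character(),
                  observed = integer(), n_expressed = integer()))
  }
  rows$status <- unname(status[rows$gene_id])
  rows$status[is.na(rows$status)] <- "stable"
  rows$expressed <- if (is.null(expressed)) TRUE else
    unname(expressed[rows$gene_id]) %in% TRUE
  rows %>%
    group_by(.data$consensus_id, .data$status) %>%
    summarise(observed = n(), n_expressed = sum(.data$expressed),
              .groups = "drop") %>%
    tidyr::complete(.data$consensus_id, status = de_statuses,
                    fill = list(observed = 0L, n_expressed = 0L))
}

#' Consensus enrichment near differentially regulated genes
#'
#' For each consensus (row) and regulation status (column) the expected cell
#' THEO is the standard contingency expectation row_total x column_total /
#' grand_total; fold = observed / THEO. Each consensus row is tested by
#' goodness-of-fit chi-square against its THEO row, Bonferroni-corrected over
#' the number of consensus tested. A (consensus, status) result passes the
#' filters when at least `min_genes` of its observed genes are expressed,
#' fold >= `min_fold` and the Bonferroni p-value is below `max_p`.
#' `fold_vs_stable` reports the per-gene rate ratio against the stable class,
#' the direct estimate of a planted placement bias.
#'
#' @param table Output of [consensus_status_table()].
#' @param filters List with `min_genes` (default 10), `min_fold` (2) and
#'   `max_p` (0.001).
#' @param n_genes_by_status Optional named vector of gene counts per status
#'   (needed for `fold_vs_stable`); `NULL` leaves it `NA`.
#' @return A tibble with one row per (consensus, status): observed, expected
#'   (`theo`), `fold`, `fold_vs_stable`, `fold_bin` (1-2.5 / 2.5-6 / 6-9),
#'   `statistic`, `p_value`, `p_bonferroni`, `passes_filters`.
#' @export
consensus_de_enrichment <- function(table,
                                    filters = list(min_genes = 10,
                                                   min_fold = 2,
                                                   max_p = 0.001),
                                    n_genes_by_status = NULL) {
  grand <- sum(table$observed)
  if (grand == 0) abort("empty consensus/status table")
  tab <- table %>%
    group_by(.data$consensus_id) %>%
    mutate(row_total = sum(.data$observed)) %>%
    ungroup() %>%
    group_by(.data$status) %>%
    mutate(col_total = sum(.data$observed)) %>%
    ungroup() %>%
    mutate(theo = .data$row_total * .data$col_total / grand,
           fold = if_else(.data$theo > 0, .data$observed / .data$theo,
                          NA_real_))
  # per-consensus goodness-of-fit test of the observed row vs its THEO row
  tests <- tab %>%
    group_by(.data$consensus_id) %>%
    summarise(res = list(if (all(.data$theo > 0))
      chi_square_test(.data$observed, .data$theo)
      else tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_)),
      .groups = "drop") %>%
    tidyr::unnest("res")
  m <- nrow(tests)
  tests$p_bonferroni <- bonferroni_adjust(tests$p_value, m = m)
  out <- left_join(tab, tests, by = "consensus_id")
  if (!is.null(n_genes_by_status)) {
    stable_rate <- out %>%
      filter(.data$status == "stable") %>%
      mutate(rate = .data$observed / n_genes_by_status[["stable"]]) %>%
      select("consensus_id", "rate")
    out <- out %>%
      left_join(stable_rate, by = "consensus_id") %>%
      mutate(fold_vs_stable = (.data$observed /
                                 unname(n_genes_by_status[.data$status])) /
               .data$rate) %>%
      select(-"rate")
  } else {
    out$fold_vs_stable <- NA_real_
  }
  out %>%
    mutate(
      fold_bin = cut(.data$fold, breaks = c(1, 2.5, 6, 9),
                     labels = c("1-2.5", "2.5-6", "6-9"), right = FALSE),
      passes_filters = .data$status != "stable" &
        .data$n_expressed >= filters$min_genes &
        !is.na(.data$fold) & .data$fold >= filters$min_fold &
        !is.na(.data$p_bonferroni) & .data$p_bonferroni < filters$max_p
    ) %>%
    select("consensus_id", "status", "observed", "n_expressed", "row_total",
           "col_total", "theo", "fold", "fold_vs_stable", "fold_bin",
           "statistic", "p_value", "p_bonferroni", "passes_filters")
}

#' Random-placement expectation for feature/footprint association
#'
#' Estimates how often query features (e.g. DMRs or RIN peaks) would overlap
#' a target footprint if placed uniformly at random, each on its own
#' chromosome with its length preserved, and compares the observed associated
#' count to that expectation by a 2-cell goodness-of-fit chi-square. The
#' analytic mode returns the exact coverage-based overlap probability for
#' cross-validation of the Monte-Carlo estimate.
#'
#' @param query Interval tibble of query features.
#' @param target Interval tibble whose footprint defines association.
#' @param karyotype Karyotype tibble.
#' @param n_shuffles Number of shuffles (>= 100 for the Monte-Carlo mode).
#' @param seed Integer seed.
#' @param mode `"shuffle"` (Monte Carlo) or `"analytic"` (closed form).
#' @return A one-row tibble: `observed_fraction`, `expected_fraction`,
#'   `statistic`, `df`, `p_value`, `n`, `n_shuffles`.
#' @export
random_placement_expectation <- function(query, target, karyotype,
                                         n_shuffles = 1000, seed = 1,
                                         mode = c("shuffle", "analytic")) {
  mode <- match.arg(mode)
  iv_validate(query, karyotype, "query")
  n <- nrow(query)
  lens <- query$end - query$start
  chrom_len <- setNames(karyotype$length, karyotype$chrom)
  if (any(lens > chrom_len[query$chrom])) {
    abort("query feature longer than its chromosome")
  }
  fp <- iv_footprint(target)
  observed <- sum(iv_overlap_bp_per_row(query, fp) > 0)
  if (mode == "shuffle") {
    if (n_shuffles < 100) abort("need n_shuffles >= 100")
    fp_by_chrom <- lapply(split(fp, fp$chrom), function(f) {
      IRanges::IRanges(start = f$start + 1L, end = f$end)
    })
    expected_fraction <- withr::with_seed(seed, {
      mean(vapply(seq_len(n_shuffles), function(s) {
        starts <- floor(runif(n, min = 0,
                              max = chrom_len[query$chrom] - lens + 1))
        hit <- logical(n)
        for (ch in unique(query$chrom)) {
          i <- query$chrom == ch
          f <- fp_by_chrom[[ch]]
          if (is.null(f)) next
          ir <- IRanges::IRanges(start = starts[i] + 1L,
                                 width = lens[i])
          hit[i] <- IRanges::countOverlaps(ir, f) > 0
        }
        mean(hit)
      }, numeric(1)))
    })
  } else {
    # exact per-feature probability that a uniform placement overlaps fp
    probs <- vapply(seq_len(n), function(i) {
      L <- chrom_len[[query$chrom[i]]]
      l <- lens[i]
      f <- fp[fp$chrom == query$chrom[i], , drop = FALSE]
      if (nrow(f) == 0) return(0)
      # starts s in [0, L-l] with s < f$end and s + l > f$start
      lo <- pmax(0, f$start - l + 1)
      hi <- pmin(L - l, f$end - 1)
      keep <- hi >= lo
      if (!any(keep)) return(0)
      ir <- IRanges::reduce(IRanges::IRanges(start = lo[keep] + 1,
                                             end = hi[keep] + 1))
      sum(IRanges::width(ir)) / (L - l + 1)
    }, numeric(1))
    expected_fraction <- mean(probs)
    n_shuffles <- NA_integer_
  }
  exp_counts <- c(expected_fraction, 1 - expected_fraction) * n
  res <- if (all(exp_counts > 0)) {
    chi_square_test(c(observed, n - observed), exp_counts)
  } else {
    tibble(statistic = NA_real_, df = 1, p_value = NA_real_)
  }
  tibble(observed_fraction = observed / n,
         expected_fraction = expected_fraction,
         statistic = res$statistic, df = res$df, p_value = res$p_value,
         n = n, n_shuffles = n_shuffles)
}
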