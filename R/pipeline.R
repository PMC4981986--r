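# Orchestration: one config drives simulate -> repeat layers -> compartments
# -> associations -> enrichment, with a run manifest for reproducibility.

#' Build a run configuration
#'
#' Every parameter defaults to the analysis' published setting: 500 kb
#' windows with 50 kb overlap, 16-mers at 10 occurrences keeping 30 bp
#' fragments, 50 bp minimum novel span for the secondary layer, 1 kb
#' association windows, the >50% CDS TE-gene rule, RIN extensions of +/-10
#' and +/-500 bp, and the 10-gene/2-fold/0.001 enrichment filters.
#'
#' @param ... Overrides of the default fields (see Details in the vignette).
#' @param file Optional YAML file of overrides, applied before `...`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- list(
    seed = 1,
    simulate = TRUE,
    synthetic = list(),       # overrides forwarded to synthetic_spec()
    input_dir = NULL,         # read inputs from here when simulate = FALSE
    window = 500000, overlap = 50000,
    kmer_k = 16, kmer_min_occurrences = 10, kmer_min_fragment = 30,
    secondary_min_span = 50,
    association_window = 1000,
    te_gene_threshold = 0.5,
    rin_overlap_ext = 10, rin_adjacent_ext = 500,
    filters = list(min_genes = 10, min_fold = 2, max_p = 0.001),
    stage_pair = "dpa17_dpa52",
    n_shuffles = 200,
    kmeans_restarts = 25,
    run_kmer_layer = TRUE
  )
  if (!is.null(file)) {
    over <- yaml::read_yaml(file)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (cfg$overlap >= cfg$window) {
    abort("config error: overlap must be smaller than window")
  }
  if (!cfg$simulate && is.null(cfg$input_dir)) {
    abort("config error: input_dir required when simulate = FALSE")
  }
  structure(cfg, class = "run_config")
}

read_pipeline_inputs <- function(dir) {
  kary <- read_karyotype(file.path(dir, "karyotype.tsv"))
  list(
    karyotype = kary,
    sequences = if (file.exists(file.path(dir, "genome.fa")))
      file.path(dir, "genome.fa") else NULL,
    genes = read_features(file.path(dir, "genes.gff3"), "gff3", "gene", kary),
    repeats = read_features(file.path(dir, "repeats.gff3"), "gff3", "repeat",
                            kary),
    dmrs = read_features(file.path(dir, "dmrs.bed"), "bed", "dmr", kary),
    rin_peaks = read_features(file.path(dir, "rin_peaks.bed"), "bed", "rin",
                              kary),
    expression = read_quant_table(file.path(dir, "expression.tsv"),
                                  "expression"),
    methylation = read_quant_table(file.path(dir, "methylation.tsv"),
                                   "methylation"),
    categories = read_quant_table(file.path(dir, "categories.tsv"),
                                  "categories"),
    de_status = read_quant_table(file.path(dir, "de_status.tsv"), "de_status")
  )
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order: (0) simulate or load inputs, (1) k-mer
#' repeat layer and annotation merge, (2) windowed coverage + k-means
#' compartments, (3) TE-gene filtering and feature-to-compartment
#' assignment, (4) gene/repeat/DMR/RIN associations and repeat methylation,
#' (5) enrichment statistics and the DMR random-placement null. Any stage
#' failure aborts with a stage-named error. All outputs are written under
#' `outdir` (tables as TSV, segments as BED, manifest as JSON); wall-clock
#' timings go to `timings.log`, which is the only non-deterministic file.
#'
#' @param config A [run_config()].
#' @param outdir Output directory.
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  data <- stage("inputs", {
    if (isTRUE(config$simulate)) {
      spec <- do.call(synthetic_spec,
                      c(list(seed = config$seed), config$synthetic))
      ds <- generate_genome(spec)
      write_synthetic_dataset(ds, file.path(outdir, "inputs"))
      ds
    } else {
      read_pipeline_inputs(config$input_dir)
    }
  })

  repeats <- stage("repeat_layers", {
    if (isTRUE(config$run_kmer_layer) && !is.null(data$sequences)) {
      km <- find_kmer_repeats(data$sequences,
                              kmer_params(config$kmer_k,
                                          config$kmer_min_occurrences,
                                          config$kmer_min_fragment))
      merge_annotation_layers(
        data$repeats, secondary = NULL, kmer = km,
        policy = merge_policy(config$secondary_min_span,
                              config$kmer_min_fragment))
    } else {
      data$repeats
    }
  })

  fit <- stage("compartments", {
    partition_genome(data$genes, repeats, data$karyotype,
                     window_params(config$window, config$overlap),
                     seed = config$seed, n_restarts = config$kmeans_restarts,
                     families = TRUE)
  })

  genes <- stage("te_gene_filter", {
    g <- flag_te_genes(data$genes, repeats,
                       threshold = config$te_gene_threshold)
    assign_features_to_compartments(g, fit$segments)
  })
  genes_kept <- filter(genes, !.data$te_gene,
                       .data$compartment != "EXCLUDED")

  assoc <- stage("associations", {
    w <- config$association_window
    links <- link_dmrs_to_repeats(data$dmrs, repeats)
    list(
      upstream = closest_repeat(genes_kept, repeats, "upstream"),
      downstream = closest_repeat(genes_kept, repeats, "downstream"),
      configs = classify_gene_configuration(genes_kept, repeats, window = w),
      methylation = repeat_methylation_status(repeats, data$methylation),
      dmr_links = links,
      dmr_genes = associate_dmrs_with_genes(links, data$dmrs, genes_kept,
                                            window = w),
      rin = associate_rin_with_dmrs(data$rin_peaks, data$dmrs, links,
                                    config$rin_overlap_ext,
                                    config$rin_adjacent_ext,
                                    data$karyotype)
    )
  })

  enr <- stage("enrichment", {
    labels <- select(genes_kept, "gene_id", "compartment")
    origin <- compartment_category_enrichment(
      labels, rename(select(data$categories, "gene_id", "origin"),
                     category = "origin"))
    stress <- compartment_category_enrichment(
      labels, mutate(select(data$categories, "gene_id", "stress"),
                     category = if_else(.data$stress, "stress", "non_stress"),
                     stress = NULL))
    cons_tab <- consensus_status_table(genes_kept, repeats, data$de_status,
                                       data$expression,
                                       stage_pair = config$stage_pair,
                                       window = config$association_window)
    st <- filter(data$de_status, .data$comparison == config$stage_pair)
    n_by_status <- table(factor(st$status[st$gene_id %in% genes_kept$gene_id],
                                levels = de_statuses))
    consensus <- consensus_de_enrichment(cons_tab, config$filters,
                                         n_genes_by_status =
                                           setNames(as.numeric(n_by_status),
                                                    names(n_by_status)))
    dmr_null <- random_placement_expectation(
      data$dmrs, repeats, data$karyotype,
      n_shuffles = config$n_shuffles, seed = config$seed)
    list(origin = origin, stress = stress, consensus = consensus,
         dmr_null = dmr_null)
  })

  stage("write_outputs", {
    seg <- fit$segments
    readr::write_tsv(seg, file.path(outdir, "segments.bed"),
                     col_names = FALSE)
    readr::write_tsv(tidy(fit), file.path(outdir, "windows.tsv"))
    readr::write_tsv(select(genes, -"cds", -"introns"),
                     file.path(outdir, "genes_annotated.tsv"))
    readr::write_tsv(assoc$configs, file.path(outdir, "gene_configs.tsv"))
    readr::write_tsv(assoc$dmr_links$links,
                     file.path(outdir, "dmr_repeat_links.tsv"))
    readr::write_tsv(assoc$dmr_links$summary,
                     file.path(outdir, "dmr_link_summary.tsv"))
    readr::write_tsv(assoc$dmr_genes, file.path(outdir, "dmr_gene_associations.tsv"))
    readr::write_tsv(assoc$rin, file.path(outdir, "rin_associations.tsv"))
    readr::write_tsv(assoc$methylation %>% select(-dplyr::any_of(c("cds"))),
                     file.path(outdir, "repeat_methylation.tsv"))
    readr::write_tsv(enr$origin$tests, file.path(outdir, "origin_enrichment.tsv"))
    readr::write_tsv(enr$stress$tests, file.path(outdir, "stress_enrichment.tsv"))
    readr::write_tsv(enr$consensus, file.path(outdir, "consensus_enrichment.tsv"))
    readr::write_tsv(enr$dmr_null, file.path(outdir, "dmr_random_null.tsv"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("repeatscape")),
      config = unclass(config),
      seed = config$seed,
      outputs = sort(setdiff(list.files(outdir, recursive = TRUE),
                             c("manifest.json", "timings.log"))),
      checksums = as.list(tools::md5sum(
        file.path(outdir, sort(setdiff(list.files(outdir, recursive = TRUE),
                                       c("manifest.json", "timings.log"))))))
    )
    names(manifest$checksums) <- basename(names(manifest$checksums))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(sprintf("%s\t%.3f", names(timings), unlist(timings)),
               file.path(outdir, "timings.log"))
  })

  invisible(list(data = data, repeats = repeats, fit = fit, genes = genes,
                 associations = assoc, enrichment = enr, outdir = outdir))
}

#' Summarise a pipeline run
#'
#' Produces the headline counts of a run: compartment sizes, per-compartment
#' gene and repeat counts and median leaf expression, DMR link-class
#' fractions, RIN association counts and the consensus passing the
#' enrichment filters.
#'
#' @param result The list returned by [run_pipeline()], or an output
#'   directory containing its TSV files.
#' @return A tibble with `section`, `item`, `value` rows; printed compactly.
#' @export
report_summary <- function(result) {
  if (is.character(result)) {
    needed <- c("segments.bed", "windows.tsv", "genes_annotated.tsv",
                "dmr_link_summary.tsv", "rin_associations.tsv",
                "consensus_enrichment.tsv")
    missing <- needed[!file.exists(file.path(result, needed))]
    if (length(missing) > 0) {
      abort(sprintf("incomplete pipeline outputs; missing: %s",
                    paste(missing, collapse = ", ")))
    }
    seg <- readr::read_tsv(file.path(result, "segments.bed"),
                           col_names = c("chrom", "start", "end", "label"),
                           col_types = "cddc", progress = FALSE)
    genes <- readr::read_tsv(file.path(result, "genes_annotated.tsv"),
                             col_types = readr::cols(), progress = FALSE)
    link_summary <- readr::read_tsv(file.path(result, "dmr_link_summary.tsv"),
                                    col_types = readr::cols(), progress = FALSE)
    rin <- readr::read_tsv(file.path(result, "rin_associations.tsv"),
                           col_types = readr::cols(), progress = FALSE)
    consensus <- readr::read_tsv(file.path(result, "consensus_enrichment.tsv"),
                                 col_types = readr::cols(), progress = FALSE)
    expr <- NULL
  } else {
    seg <- result$fit$segments
    genes <- result$genes
    link_summary <- result$associations$dmr_links$summary
    rin <- result$associations$rin
    consensus <- result$enrichment$consensus
    expr <- result$data$expression
  }
  rows <- list()
  sizes <- seg %>%
    group_by(.data$label) %>%
    summarise(mb = sum(.data$end - .data$start) / 1e6, .groups = "drop")
  rows$compartment_mb <- tibble(section = "compartments",
                                item = sizes$label,
                                value = round(sizes$mb, 3))
  gc <- genes %>%
    filter(.data$compartment %in% compartment_labels) %>%
    count(.data$compartment)
  rows$gene_counts <- tibble(section = "genes_per_compartment",
                             item = gc$compartment, value = as.numeric(gc$n))
  if (!is.null(expr)) {
    med <- genes %>%
      filter(.data$compartment %in% compartment_labels, !.data$te_gene) %>%
      left_join(expr, by = "gene_id") %>%
      group_by(.data$compartment) %>%
      summarise(value = median(.data$leaf), .groups = "drop")
    rows$medians <- tibble(section = "median_leaf_rpkm",
                           item = med$compartment, value = med$value)
  }
  rows$dmr <- tibble(section = "dmr_repeat_fraction",
                     item = link_summary$link_class,
                     value = round(link_summary$fraction, 4))
  rows$rin <- tibble(
    section = "rin_associations",
    item = c("adjacent_pairs", "overlap_pairs", "repeat_supported_pairs"),
    value = c(nrow(rin), sum(rin$overlap), sum(rin$repeat_supported))
  )
  hits <- filter(consensus, .data$passes_filters)
  rows$consensus <- tibble(
    section = "enriched_consensus",
    item = if (nrow(hits) == 0) "none" else
      paste(hits$consensus_id, hits$status, sep = "/"),
    value = if (nrow(hits) == 0) 0 else round(hits$fold, 3)
  )
  bind_rows(rows)
}
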