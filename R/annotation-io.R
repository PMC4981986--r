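# Readers/writers for the genomic feature formats the pipeline touches.
# Internal coordinates are 0-based half-open everywhere; GFF3 (1-based closed)
# and BED (0-based half-open) are converted at the boundary only.

#' Build or read a karyotype
#'
#' A karyotype is the ordered table of chromosome identifiers and lengths that
#' anchors every interval in the package.
#'
#' @param chrom Character vector of unique chromosome identifiers.
#' @param length Positive chromosome lengths in base pairs.
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' karyotype(c("chr1", "chr2"), c(5e6, 4e6))
#' @export
karyotype <- function(chrom, length) {
  if (anyDuplicated(chrom)) abort("karyotype chromosome ids must be unique")
  if (any(length <= 0)) abort("karyotype lengths must be > 0")
  tibble(chrom = as.character(chrom), length = as.numeric(length))
}

#' @rdname karyotype
#' @param path Path to a 2-column TSV (`chrom`, `length`), no header required
#'   if the first field is not numeric.
#' @export
read_karyotype <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "length"),
                        col_types = "cd", comment = "#", progress = FALSE)
  if (nrow(df) > 0 && is.na(df$length[1])) df <- df[-1, ] # header line
  karyotype(df$chrom, as.numeric(df$length))
}

#' @rdname karyotype
#' @param x A karyotype tibble.
#' @export
write_karyotype <- function(x, path) {
  readr::write_tsv(x, path, col_names = FALSE)
  invisible(path)
}

feature_id_col <- c(gene = "gene_id", repeat_ = "repeat_id",
                    dmr = "dmr_id", rin = "peak_id")

normalize_kind <- function(feature_kind) {
  feature_kind <- match.arg(feature_kind, c("gene", "repeat", "dmr", "rin"))
  if (feature_kind == "repeat") "repeat_" else feature_kind
}

#' Read genomic features from GFF3 or BED
#'
#' Parses gene models (with CDS children), repeat annotations, DMR intervals or
#' RIN binding peaks into the package's typed tibbles. GFF3 coordinates
#' (1-based inclusive) and BED coordinates (0-based half-open) are both
#' converted to the internal 0-based half-open convention.
#'
#' @param path File to read.
#' @param format `"gff3"` or `"bed"`.
#' @param feature_kind One of `"gene"`, `"repeat"`, `"dmr"`, `"rin"`.
#' @param karyotype Optional karyotype tibble; when given, features on unknown
#'   chromosomes or exceeding chromosome bounds raise an error.
#' @return A typed feature tibble. Genes carry a `cds` list-column of
#'   half-open exonic CDS parts and an `introns` list-column derived from the
#'   gaps between them. Unknown repeat family strings are mapped to
#'   `"Unclassified"` with a warning.
#' @seealso [write_features()]
#' @export
read_features <- function(path, format = c("gff3", "bed"),
                          feature_kind = c("gene", "repeat", "dmr", "rin"),
                          karyotype = NULL) {
  format <- match.arg(format)
  kind <- normalize_kind(feature_kind)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- if (format == "gff3") read_features_gff3(path, kind)
         else read_features_bed(path, kind)
  validate_features(out, kind, karyotype)
}

read_features_gff3 <- function(path, kind) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- iv_tibble(gr)
  mc <- as.data.frame(S4Vectors::mcols(gr), stringsAsFactors = FALSE)
  df$type <- as.character(mc$type)
  df$ID <- if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_
  if (any(df$end < df$start)) {
    abort("GFF3 feature with end < start after coordinate conversion")
  }
  if (kind == "gene") {
    genes <- df[df$type == "gene", , drop = FALSE]
    cds <- df[df$type == "CDS", , drop = FALSE]
    parent <- if ("Parent" %in% names(mc)) mc$Parent else NULL
    cds$parent <- if (is.null(parent)) NA_character_ else
      vapply(parent[df$type == "CDS"], function(p) as.character(p)[1], character(1))
    cds_by_gene <- split(cds[, c("start", "end")], cds$parent)
    cds_list <- lapply(genes$ID, function(id) {
      parts <- cds_by_gene[[id]]
      if (is.null(parts)) return(tibble(start = integer(), end = integer()))
      as_tibble(parts[order(parts$start), , drop = FALSE])
    })
    out <- tibble(
      gene_id = genes$ID, chrom = genes$chrom, start = genes$start,
      end = genes$end, strand = genes$strand, cds = cds_list
    )
    out$introns <- lapply(out$cds, cds_introns)
    out
  } else if (kind == "repeat_") {
    reps <- df[df$type != "CDS", , drop = FALSE]
    fam <- if ("family" %in% names(mc)) as.character(mc$family)[df$type != "CDS"]
           else rep(NA_character_, nrow(reps))
    cons <- if ("consensus_id" %in% names(mc)) as.character(mc$consensus_id)[df$type != "CDS"]
            else rep(NA_character_, nrow(reps))
    layer <- if ("layer" %in% names(mc)) as.character(mc$layer)[df$type != "CDS"]
             else rep("primary_denovo", nrow(reps))
    hc <- if ("high_confidence" %in% names(mc))
      as.logical(as.character(mc$high_confidence))[df$type != "CDS"]
      else rep(TRUE, nrow(reps))
    tibble(
      repeat_id = reps$ID, chrom = reps$chrom, start = reps$start,
      end = reps$end, strand = reps$strand,
      family = coerce_family(fam), consensus_id = cons,
      layer = layer, high_confidence = hc
    )
  } else {
    abort(sprintf("GFF3 input is supported for genes and repeats, not '%s'",
                  sub("_$", "", kind)))
  }
}

bed_extra_cols <- list(
  repeat_ = c(family = "character", consensus_id = "character",
              layer = "character", high_confidence = "character"),
  dmr = c(comparison = "character", direction = "character"),
  rin = character(0),
  gene = character(0)
)

read_features_bed <- function(path, kind) {
  extras <- bed_extra_cols[[kind]]
  gr <- rtracklayer::import(path, format = "bed", extraCols = extras)
  df <- iv_tibble(gr)
  mc <- as.data.frame(S4Vectors::mcols(gr), stringsAsFactors = FALSE)
  ids <- if ("name" %in% names(mc)) as.character(mc$name)
         else sprintf("feat%06d", seq_len(nrow(df)))
  switch(kind,
    repeat_ = tibble(
      repeat_id = ids, chrom = df$chrom, start = df$start, end = df$end,
      strand = df$strand,
      family = coerce_family(mc$family),
      consensus_id = as.character(mc$consensus_id),
      layer = as.character(mc$layer),
      high_confidence = as.logical(as.character(mc$high_confidence))
    ),
    dmr = tibble(
      dmr_id = ids, chrom = df$chrom, start = df$start, end = df$end,
      comparison = as.character(mc$comparison),
      direction = as.character(mc$direction)
    ),
    rin = tibble(peak_id = ids, chrom = df$chrom, start = df$start,
                 end = df$end),
    abort("BED input is supported for repeats, DMRs and RIN peaks")
  )
}

coerce_family <- function(fam) {
  fam[is.na(fam)] <- "Unclassified"
  unknown <- setdiff(unique(fam), repeat_families)
  if (length(unknown) > 0) {
    warn(sprintf("unknown repeat family label(s) mapped to Unclassified: %s",
                 paste(unknown, collapse = ", ")))
    fam[fam %in% unknown] <- "Unclassified"
  }
  fam
}

# Introns are the gaps between consecutive sorted CDS parts.
cds_introns <- function(cds) {
  if (nrow(cds) < 2) return(tibble(start = integer(), end = integer()))
  cds <- cds[order(cds$start), , drop = FALSE]
  tibble(start = cds$end[-nrow(cds)], end = cds$start[-1])
}

validate_features <- function(df, kind, karyotype = NULL) {
  what <- sub("_$", "", kind)
  iv_validate(df, karyotype, what)
  idc <- feature_id_col[[kind]]
  if (anyDuplicated(df[[idc]])) {
    abort(sprintf("duplicated %s: %s", idc,
                  df[[idc]][duplicated(df[[idc]])][1]))
  }
  if (kind == "gene" && nrow(df) > 0) {
    ok <- purrr::map2_lgl(df$cds, seq_len(nrow(df)), function(cds, i) {
      if (nrow(cds) == 0) return(TRUE)
      cds <- cds[order(cds$start), , drop = FALSE]
      all(cds$start >= df$start[i]) && all(cds$end <= df$end[i]) &&
        all(cds$start < cds$end) &&
        (nrow(cds) < 2 || all(cds$start[-1] >= cds$end[-nrow(cds)]))
    })
    if (!all(ok)) {
      abort(sprintf("gene %s: CDS parts must be disjoint, sorted and within the gene span",
                    df$gene_id[!ok][1]))
    }
  }
  if (kind == "repeat_" && nrow(df) > 0) {
    df$family <- coerce_family(df$family)
    bad <- !(df$layer %in% annotation_layers)
    if (any(bad)) abort(sprintf("unknown annotation layer: %s", df$layer[bad][1]))
    nocons <- df$layer != "kmer_strict" &
      (is.na(df$consensus_id) | df$consensus_id == "")
    if (any(nocons)) {
      abort(sprintf("repeat %s: consensus_id required for layer %s",
                    df$repeat_id[nocons][1], df$layer[nocons][1]))
    }
  }
  if (kind == "dmr" && nrow(df) > 0) {
    parts <- stringr::str_split(df$comparison, "_", simplify = TRUE)
    if (ncol(parts) != 2 || any(parts[, 1] == parts[, 2]))
      abort("DMR comparison must be an ordered pair of distinct stages, e.g. 'dpa17_dpa52'")
    if (!all(df$direction %in% c("hypo", "hyper")))
      abort("DMR direction must be 'hypo' or 'hyper'")
  }
  df
}

#' Write genomic features to GFF3 or BED
#'
#' The inverse of [read_features()]: features are written in the external
#' convention of the chosen format (GFF3 1-based inclusive, BED half-open) and
#' round-trip through `read_features()` up to column ordering.
#'
#' @param features A typed feature tibble as produced by [read_features()] or
#'   the synthetic generator.
#' @param path Output file.
#' @param format `"gff3"` or `"bed"`.
#' @param feature_kind One of `"gene"`, `"repeat"`, `"dmr"`, `"rin"`.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, format = c("gff3", "bed"),
                           feature_kind = c("gene", "repeat", "dmr", "rin")) {
  format <- match.arg(format)
  kind <- normalize_kind(feature_kind)
  if (format == "gff3") write_features_gff3(features, path, kind)
  else write_features_bed(features, path, kind)
  invisible(path)
}

write_features_gff3 <- function(features, path, kind) {
  if (kind == "gene") {
    genes <- features
    gr_gene <- iv_granges(genes)
    S4Vectors::mcols(gr_gene) <- S4Vectors::DataFrame(
      type = "gene", ID = genes$gene_id
    )
    cds_tbl <- tidyr::unnest(
      select(genes, "gene_id", "chrom", "strand", "cds"), "cds"
    )
    if (nrow(cds_tbl) > 0) {
      gr_cds <- iv_granges(cds_tbl)
      S4Vectors::mcols(gr_cds) <- S4Vectors::DataFrame(
        type = "CDS", ID = NA_character_, phase = 0L
      )
      gr_cds$Parent <- as.character(cds_tbl$gene_id)
      gr_gene$Parent <- NA_character_
      gr <- c(gr_gene, gr_cds)
    } else {
      gr <- gr_gene
    }
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    rtracklayer::export(gr, path, format = "gff3")
  } else if (kind == "repeat_") {
    gr <- iv_granges(features)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      type = "dispersed_repeat",
      ID = features$repeat_id,
      family = features$family,
      consensus_id = features$consensus_id,
      layer = features$layer,
      high_confidence = ifelse(features$high_confidence, "TRUE", "FALSE")
    )
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    abort("GFF3 output is supported for genes and repeats")
  }
}

write_features_bed <- function(features, path, kind) {
  idc <- feature_id_col[[kind]]
  base <- tibble(
    chrom = features$chrom,
    start = format(features$start, scientific = FALSE, trim = TRUE),
    end = format(features$end, scientific = FALSE, trim = TRUE),
    name = features[[idc]],
    score = 0L,
    strand = if ("strand" %in% names(features)) {
      ifelse(features$strand == "*", ".", features$strand)
    } else "."
  )
  extras <- names(bed_extra_cols[[kind]])
  for (col in extras) {
    v <- features[[col]]
    base[[col]] <- if (is.logical(v)) ifelse(v, "TRUE", "FALSE") else as.character(v)
  }
  readr::write_tsv(base, path, col_names = FALSE)
}

#' Read quantitative gene/cytosine tables
#'
#' @param path TSV file with a header.
#' @param kind `"expression"` (gene_id + RPKM for the five conditions leaf and
#'   17/39/42/52 d.p.a.), `"methylation"` (chrom, position, context,
#'   methylated), `"categories"` (gene_id, go_terms, origin, stress and
#'   optional `de_<pair>` columns), or `"de_status"` (gene_id, comparison,
#'   status).
#' @return A validated typed tibble.
#' @export
read_quant_table <- function(path, kind = c("expression", "methylation",
                                            "categories", "de_status")) {
  kind <- match.arg(kind)
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  validate_quant_table(df, kind)
}

validate_quant_table <- function(df, kind) {
  if (kind == "expression") {
    need <- c("gene_id", expression_conditions)
    miss <- setdiff(need, names(df))
    if (length(miss) > 0)
      abort(sprintf("expression table missing column(s): %s",
                    paste(miss, collapse = ", ")))
    if (anyDuplicated(df$gene_id))
      abort(sprintf("duplicated gene_id in expression table: %s",
                    df$gene_id[duplicated(df$gene_id)][1]))
    vals <- as.matrix(df[, expression_conditions])
    if (anyNA(vals)) abort("missing expression value (NA) is not allowed")
    if (any(vals < 0)) abort("negative RPKM value")
    as_tibble(df[, need])
  } else if (kind == "methylation") {
    need <- c("chrom", "position", "context", "methylated")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0)
      abort(sprintf("methylation table missing column(s): %s",
                    paste(miss, collapse = ", ")))
    bad <- setdiff(unique(df$context), methylation_contexts)
    if (length(bad) > 0)
      abort(sprintf("unknown methylation context: %s", bad[1]))
    tibble(chrom = as.character(df$chrom),
           position = as.numeric(df$position),
           context = as.character(df$context),
           methylated = as.logical(as.numeric(df$methylated)))
  } else if (kind == "categories") {
    need <- c("gene_id", "go_terms", "origin", "stress")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0)
      abort(sprintf("categories table missing column(s): %s",
                    paste(miss, collapse = ", ")))
    if (anyDuplicated(df$gene_id))
      abort("duplicated gene_id in categories table")
    if (!all(df$origin %in% gene_origins))
      abort(sprintf("unknown origin label: %s",
                    setdiff(unique(df$origin), gene_origins)[1]))
    df$go_terms[is.na(df$go_terms)] <- ""
    df$stress <- as.logical(as.numeric(df$stress))
    as_tibble(df)
  } else {
    need <- c("gene_id", "comparison", "status")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0)
      abort(sprintf("de_status table missing column(s): %s",
                    paste(miss, collapse = ", ")))
    if (!all(df$status %in% de_statuses))
      abort("de status must be one of up/down/stable")
    as_tibble(df[, need])
  }
}

#' @rdname read_quant_table
#' @param x Table to write.
#' @export
write_quant_table <- function(x, path) {
  df <- x
  if ("methylated" %in% names(df)) df$methylated <- as.integer(df$methylated)
  if ("stress" %in% names(df)) df$stress <- as.integer(df$stress)
  readr::write_tsv(df, path)
  invisible(path)
}
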