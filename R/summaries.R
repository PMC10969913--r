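#' Genomic region classes
#'
#' The ANNOVAR-style region vocabulary used for variant-type accounting, in
#' canonical reporting order.
#'
#' @return Character vector of region class labels.
#' @export
region_vocabulary <- function() {
  c("downstream", "exonic", "exonic;splicing", "intergenic", "intronic",
    "ncRNA_exonic", "ncRNA_intronic", "ncRNA_splicing", "splicing",
    "upstream", "upstream;downstream", "UTR3", "UTR5", "UTR5;UTR3")
}

#' Map consequence categories to region classes
#'
#' Annotation tables mix Sequence-Ontology consequence terms with
#' ANNOVAR-style exonic labels; region accounting uses the ANNOVAR region
#' vocabulary. This fixed bridge maps every accepted category to one region
#' class: coding consequences to `exonic`, UTR terms to `UTR5`/`UTR3`
#' (including the 5'-UTR premature-start-codon gain, which lies in the
#' 5' UTR), splice-region terms to `splicing`, and the uninformative
#' `sequence_feature` to `exonic`. Terms that are already region classes
#' map to themselves.
#'
#' @param category Character vector of terms from [category_vocabulary()].
#' @return Character vector of region classes.
#' @export
category_to_region <- function(category) {
  map <- c(
    "intron_variant" = "intronic",
    "missense_variant" = "exonic",
    "nonsynonymous SNV" = "exonic",
    "non-synonymous SNV" = "exonic",
    "synonymous_variant" = "exonic",
    "synonymous SNV" = "exonic",
    "sequence_feature" = "exonic",
    "upstream_gene_variant" = "upstream",
    "downstream_gene_variant" = "downstream",
    "3_prime_UTR_variant" = "UTR3",
    "5_prime_UTR_variant" = "UTR5",
    "5_prime_UTR_premature_start_codon_gain_variant" = "UTR5",
    "splice_region_variant" = "splicing",
    "splice_region_variantand intron_variant" = "splicing"
  )
  map <- c(map, stats::setNames(region_vocabulary(), region_vocabulary()))
  unknown <- setdiff(unique(category), names(map))
  if (length(unknown) > 0L) {
    stop("no region mapping for category term(s): ",
         paste(unknown, collapse = "; "), call. = FALSE)
  }
  unname(map[category])
}

# Table-style percent printing: integers, one decimal below 1%, bare 0 when
# the one-decimal value rounds to 0.0.
format_region_percent <- function(x) {
  lab <- ifelse(round(x) >= 1, sprintf("%d", round(x)), sprintf("%.1f", x))
  ifelse(lab == "0.0", "0", lab)
}

#' Summarize variant types by genomic region class
#'
#' Counts SNVs and InDels per region class and reports each class's share
#' of its variant-type column. Percentages are kept at full precision in
#' `snv_percent`/`indel_percent` and printed at table precision (integers;
#' one decimal below 1%) in the `*_percent_label` columns. An `All` row
#' carries the column totals.
#'
#' @param variants A tibble with columns `ref`, `alt` and `region_class`
#'   (one row per variant), or precomputed counts via
#'   [summarize_region_counts()].
#' @return A region-summary tibble with one row per region class plus
#'   `All`.
#' @export
summarize_regions <- function(variants) {
  stopifnot(all(c("ref", "alt", "region_class") %in% names(variants)))
  bad <- setdiff(unique(variants$region_class), region_vocabulary())
  if (length(bad) > 0L) {
    stop("unknown region class(es): ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  type <- if (nrow(variants) > 0L) {
    classify_variant_type(variants$ref, variants$alt)
  } else {
    character()
  }
  cls <- factor(variants$region_class, levels = region_vocabulary())
  counts <- tibble(
    region_class = region_vocabulary(),
    snv_count = as.integer(table(cls[type == "SNV"])),
    indel_count = as.integer(table(cls[type == "InDel"]))
  )
  summarize_region_counts(counts)
}

#' Region summary from a precomputed count grid
#'
#' @param counts Tibble with columns `region_class`, `snv_count`,
#'   `indel_count` (one row per region class; classes absent from the grid
#'   count as zero).
#' @return A region-summary tibble as in [summarize_regions()].
#' @export
summarize_region_counts <- function(counts) {
  stopifnot(all(c("region_class", "snv_count", "indel_count") %in%
                  names(counts)))
  bad <- setdiff(unique(counts$region_class), region_vocabulary())
  if (length(bad) > 0L) {
    stop("unknown region class(es): ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  idx <- match(region_vocabulary(), counts$region_class)
  snv <- ifelse(is.na(idx), 0L, counts$snv_count[idx])
  indel <- ifelse(is.na(idx), 0L, counts$indel_count[idx])
  snv_tot <- sum(snv)
  indel_tot <- sum(indel)
  pct <- function(x, tot) if (tot > 0L) 100 * x / tot else rep(0, length(x))
  out <- tibble(
    region_class = c(region_vocabulary(), "All"),
    snv_count = c(snv, snv_tot),
    snv_percent = c(pct(snv, snv_tot), if (snv_tot > 0L) 100 else 0),
    indel_count = c(indel, indel_tot),
    indel_percent = c(pct(indel, indel_tot), if (indel_tot > 0L) 100 else 0)
  )
  out$snv_percent_label <- format_region_percent(out$snv_percent)
  out$indel_percent_label <- format_region_percent(out$indel_percent)
  out
}

#' Published exome-wide region-class count grid
#'
#' The bundled SNV/InDel count grid per region class from the reference
#' eight-patient MASH cohort study (134,961 SNVs, 13,925 InDels), used for
#' arithmetic checks and as the simulator's default region distribution.
#'
#' @return Tibble with columns `region_class`, `snv_count`, `indel_count`.
#' @export
region_class_counts <- function() {
  path <- system.file("extdata", "region_class_counts.tsv",
                      package = "sexvar", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cii", progress = FALSE)
}

#' Join exclusivity results to a variant annotation table
#'
#' Left join on the full variant key; unannotated rows keep `NA`
#' annotation columns.
#'
#' @param results Output of [filter_sex_specific()].
#' @param annotation Output of [read_annotation_table()].
#' @return `results` with annotation columns appended.
#' @export
annotate_results <- function(results, annotation) {
  dplyr::left_join(results, annotation,
                   by = c("chrom", "pos", "ref", "alt"))
}

#' Tally significant variants per gene
#'
#' Aggregates annotated significant exclusivity results into one row per
#' (gene, cohort): the number of variant records and the multiset of their
#' consequence categories. Results lacking a gene name are tallied under
#' `"NA"` with a warning.
#'
#' @param annotated Significant rows of [annotate_results()] output (must
#'   carry `pattern`, `gene_name`, `category`).
#' @return Tibble with columns `gene_name`, `cohort`, `n_variants`,
#'   `categories` (collapsed, comma-separated), sorted by descending
#'   `n_variants` then gene name.
#' @export
tally_genes <- function(annotated) {
  stopifnot(all(c("pattern", "gene_name", "category") %in% names(annotated)))
  if (nrow(annotated) == 0L) {
    return(tibble(gene_name = character(), cohort = character(),
                  n_variants = integer(), categories = character()))
  }
  if (any(is.na(annotated$gene_name))) {
    warning(sum(is.na(annotated$gene_name)),
            " significant variant(s) lack annotation; tallied under gene 'NA'",
            call. = FALSE)
    annotated$gene_name[is.na(annotated$gene_name)] <- "NA"
    annotated$category[is.na(annotated$category)] <- "unannotated"
  }
  out <- annotated |>
    dplyr::group_by(.data$gene_name, cohort = .data$pattern) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      categories = paste(sort(.data$category), collapse = ", "),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_variants), .data$gene_name)
  out
}
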