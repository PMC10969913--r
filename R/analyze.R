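#' Run the end-to-end sex-exclusive variant analysis
#'
#' Orchestrates the full pipeline: read the sample sheet and each patient's
#' VCF call set, build the cohort presence matrix, run the exact-test
#' exclusivity filter, join annotations, and produce the region summary and
#' per-gene tallies. With `out_dir` set, writes `results.tsv`,
#' `presence_matrix.tsv`, `region_summary.tsv`, `gene_tally.tsv` and a
#' `run_log.txt` recording the package version, a configuration hash,
#' input checksums and the cohort's minimum achievable p-value. Outputs
#' contain no timestamps, so re-running on identical inputs yields
#' byte-identical files.
#'
#' @param sample_sheet Path to a sample-sheet CSV (see
#'   [read_sample_sheet()]; must include a `vcf_path` column) or an
#'   equivalent tibble.
#' @param vcf_dir Directory against which relative `vcf_path` entries are
#'   resolved; defaults to the sample sheet's directory.
#' @param annotation Optional annotation TSV path or tibble
#'   ([read_annotation_table()] schema).
#' @param out_dir Optional output directory.
#' @param alpha Significance threshold; `NULL` uses the cohort's
#'   [min_achievable_p()].
#' @param keep_filtered Keep VCF records failing FILTER.
#' @param require_perfect_split,one_sided Passed to
#'   [significance_criterion()].
#' @param quiet Suppress progress messages.
#' @return A list: `results` (the full per-variant table, annotated when an
#'   annotation was supplied), `matrix` (the `presence_matrix`),
#'   `region_summary`, `gene_tally`, `alpha`, and `counts` with
#'   `n_female_exclusive`/`n_male_exclusive` significant totals.
#' @export
analyze_cohort <- function(sample_sheet, vcf_dir = NULL, annotation = NULL,
                           out_dir = NULL, alpha = NULL,
                           keep_filtered = FALSE,
                           require_perfect_split = TRUE, one_sided = FALSE,
                           quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  input_files <- character()

  if (is.character(sample_sheet)) {
    if (is.null(vcf_dir)) vcf_dir <- dirname(sample_sheet)
    input_files <- c(input_files, sample_sheet)
    sheet <- read_sample_sheet(sample_sheet)
  } else {
    sheet <- sample_sheet
    validate_patients(sheet)
  }
  if (!"vcf_path" %in% names(sheet)) {
    stop("sample sheet must carry a vcf_path column", call. = FALSE)
  }
  vcf_paths <- sheet$vcf_path
  if (!is.null(vcf_dir)) {
    rel <- !grepl("^(/|[A-Za-z]:)", vcf_paths)
    vcf_paths[rel] <- file.path(vcf_dir, vcf_paths[rel])
  }
  absent <- !file.exists(vcf_paths)
  if (any(absent)) {
    stop("missing VCF for patient(s): ",
         paste(sheet$patient_id[absent], collapse = ", "), call. = FALSE)
  }
  input_files <- c(input_files, vcf_paths)

  say("Reading ", nrow(sheet), " patient call sets")
  call_sets <- lapply(vcf_paths, read_patient_calls,
                      keep_filtered = keep_filtered)
  names(call_sets) <- sheet$patient_id
  pm <- build_presence_matrix(call_sets, sheet)
  say(sprintf("Presence matrix: %d variants x %d patients",
              nrow(pm$variants), nrow(pm$patients)))

  n_f <- sum(sheet$sex == "F")
  n_m <- sum(sheet$sex == "M")
  design_p <- min_achievable_p(n_f, n_m)
  if (design_p >= 1) {
    warning(sprintf(
      "cohort design %d F vs %d M has min achievable p = 1; nothing can be significant",
      n_f, n_m), call. = FALSE)
  }
  criterion <- significance_criterion(
    alpha = alpha, require_perfect_split = require_perfect_split,
    one_sided = one_sided
  )
  results <- filter_sex_specific(pm, criterion)

  ann <- NULL
  if (!is.null(annotation)) {
    if (is.character(annotation)) {
      input_files <- c(input_files, annotation)
      ann <- read_annotation_table(annotation)
    } else {
      ann <- annotation
    }
    results <- annotate_results(results, ann)
  }

  region_summary <- NULL
  gene_tally <- NULL
  if (!is.null(ann)) {
    annotated <- results[!is.na(results$category), , drop = FALSE]
    region_summary <- summarize_regions(tibble(
      ref = annotated$ref, alt = annotated$alt,
      region_class = category_to_region(annotated$category)
    ))
    gene_tally <- tally_genes(
      annotated[annotated$significant, , drop = FALSE]
    )
  }

  counts <- list(
    n_female_exclusive = sum(results$significant &
                               results$pattern == "female_exclusive"),
    n_male_exclusive = sum(results$significant &
                             results$pattern == "male_exclusive")
  )
  say(sprintf("Significant sex-exclusive variants: %d female, %d male",
              counts$n_female_exclusive, counts$n_male_exclusive))

  out <- list(results = results, matrix = pm,
              region_summary = region_summary, gene_tally = gene_tally,
              alpha = criterion$alpha %||% design_p,
              min_achievable_p = design_p, counts = counts)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_tsv(results, file.path(out_dir, "results.tsv"))
    write_presence_matrix(pm, file.path(out_dir, "presence_matrix.tsv"))
    if (!is.null(region_summary)) {
      readr::write_tsv(region_summary,
                       file.path(out_dir, "region_summary.tsv"),
                       progress = FALSE)
    }
    if (!is.null(gene_tally)) {
      readr::write_tsv(gene_tally, file.path(out_dir, "gene_tally.tsv"),
                       progress = FALSE)
    }
    write_run_log(file.path(out_dir, "run_log.txt"), input_files,
                  criterion, design_p, counts, nrow(pm$variants))
    out$out_dir <- out_dir
  }
  out
}

# Results interchange layout: test columns first, annotation columns (when
# joined) appended, p printed at 4 decimals as in published tables.
write_results_tsv <- function(results, path) {
  out <- tibble(
    `#CHROM` = results$chrom, POS = results$pos,
    REF = results$ref, ALT = results$alt,
    n_present_F = results$n_present_f, n_present_M = results$n_present_m,
    pattern = results$pattern, p_two_sided = results$p_two_sided,
    significant = results$significant, n_missing = results$n_missing
  )
  if ("gene_name" %in% names(results)) {
    out$Gene_ID <- results$gene_id
    out$Gene_Name <- results$gene_name
    out$CytoBand <- results$cytoband
    out$Avsnp150 <- results$rsid
    out$Category <- results$category
    out$Gene_Full_Name <- results$gene_full_name
    out$`p-Value` <- sprintf("%.4f", results$p_two_sided)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

write_run_log <- function(path, input_files, criterion, design_p, counts,
                          n_variants) {
  cfg <- paste(
    "alpha=", criterion$alpha %||% "min_achievable",
    " perfect_split=", criterion$require_perfect_split,
    " one_sided=", criterion$one_sided, sep = ""
  )
  cfg_file <- tempfile()
  writeLines(cfg, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  sums <- tools::md5sum(input_files)
  writeLines(c(
    paste0("sexvar version: ",
           as.character(utils::packageVersion("sexvar"))),
    paste0("config: ", cfg),
    paste0("config_md5: ", cfg_hash),
    paste0("min_achievable_p: ", format(design_p, digits = 15)),
    paste0("n_variants: ", n_variants),
    paste0("n_female_exclusive: ", counts$n_female_exclusive),
    paste0("n_male_exclusive: ", counts$n_male_exclusive),
    "inputs:",
    paste0("  ", basename(names(sums)), " md5=", unname(sums))
  ), path)
  invisible(path)
}
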