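#' Read one patient's variant calls from a VCF file
#'
#' Consumes an already-called per-patient VCF (e.g. a tumor-normal style
#' MASH-vs-normal call set) and returns the patient's carried variant keys.
#' A record is *present* when its genotype carries at least one alternate
#' allele and its FILTER is `PASS` or `.`; a `./.` genotype is returned as a
#' *missing* (no-call) state so downstream filtering can track completeness.
#' Multiallelic records keep the full comma-joined ALT string as one key.
#'
#' @param vcf_path Path to a VCF v4.x file (plain or bgzipped).
#' @param keep_filtered If `TRUE`, records failing FILTER are kept. The
#'   conservative default accepts only `PASS` and `.`.
#' @param sample Sample column to use; defaults to the first.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `state`
#'   (`"present"` or `"missing"`); absent records are never materialized.
#' @export
read_patient_calls <- function(vcf_path, keep_filtered = FALSE, sample = NULL) {
  if (!file.exists(vcf_path)) {
    stop("VCF file not found: ", vcf_path, call. = FALSE)
  }
  prescan_vcf(vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (nrow(vcf@fix) == 0L) {
    return(tibble(chrom = character(), pos = integer(),
                  ref = character(), alt = character(), state = character()))
  }
  # vcf@fix keeps matrix shape even for a single record (getFIX drops dims)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) {
    stop("no genotype (GT) column in ", vcf_path, call. = FALSE)
  }
  col <- if (is.null(sample)) 1L else {
    if (!sample %in% colnames(gt)) {
      stop("sample '", sample, "' not found in ", vcf_path, call. = FALSE)
    }
    sample
  }
  g <- gt[, col]

  filt <- fix$FILTER
  keep <- keep_filtered | is.na(filt) | filt %in% c("PASS", ".")
  # genotype carries an alternate allele index >= 1 (handles 0/1, 1/2, 1|1, 2)
  has_alt <- !is.na(g) & grepl("[1-9]", g)
  no_call <- is.na(g) | g %in% c("./.", ".|.", ".")

  state <- rep(NA_character_, nrow(fix))
  state[keep & has_alt] <- "present"
  state[keep & no_call] <- "missing"
  idx <- which(!is.na(state))
  if (length(idx) == 0L) {
    return(tibble(chrom = character(), pos = integer(),
                  ref = character(), alt = character(), state = character()))
  }
  keys <- variant_key(fix$CHROM[idx], as.integer(fix$POS[idx]),
                      fix$REF[idx], fix$ALT[idx])
  dplyr::bind_cols(keys, tibble(state = state[idx]))
}

# Light syntactic scan so parse errors carry a line number, which vcfR's
# reader does not report.
prescan_vcf <- function(vcf_path) {
  con <- if (grepl("\\.gz$", vcf_path)) gzfile(vcf_path) else file(vcf_path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  if (length(lines) == 0L || !startsWith(lines[[1]], "##fileformat=VCF")) {
    stop("not a VCF file (missing ##fileformat header): ", vcf_path,
         call. = FALSE)
  }
  header <- which(startsWith(lines, "#CHROM"))
  if (length(header) != 1L) {
    stop("VCF column header line (#CHROM) missing in ", vcf_path,
         call. = FALSE)
  }
  n_cols <- length(strsplit(lines[[header]], "\t", fixed = TRUE)[[1]])
  if (n_cols < 10L) {
    stop("VCF has no FORMAT/genotype columns: ", vcf_path, call. = FALSE)
  }
  body <- seq_along(lines) > header
  n_fields <- vapply(strsplit(lines[body], "\t", fixed = TRUE),
                     length, integer(1))
  bad <- which(n_fields != n_cols & n_fields > 0L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed VCF line %d in %s (%d fields, expected %d)",
                 which(body)[bad[1]], vcf_path, n_fields[bad[1]], n_cols),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a cohort sample sheet
#'
#' The sheet is a CSV with header
#' `patient_id,sex,phenotype,pair_id,vcf_path` mapping each patient to sex
#' (`F`/`M`), phenotype (`MASH`/`normal`), the identifier linking a
#' patient's matched MASH and normal samples, and (optionally) that
#' patient's call-set VCF.
#'
#' @param path CSV file path.
#' @return A tibble, one row per patient.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  required <- c("patient_id", "sex", "phenotype", "pair_id")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0L) {
    stop("sample sheet lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_patients(sheet)
  sheet
}

validate_patients <- function(patients) {
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in sample sheet", call. = FALSE)
  }
  if (!all(patients$sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'", call. = FALSE)
  }
  if (!all(patients$phenotype %in% c("MASH", "normal"))) {
    stop("phenotype must be 'MASH' or 'normal'", call. = FALSE)
  }
  if (any(is.na(patients$pair_id) | !nzchar(patients$pair_id))) {
    stop("pair_id must be non-empty", call. = FALSE)
  }
  invisible(patients)
}

#' Controlled vocabulary of variant consequence categories
#'
#' The union of Sequence-Ontology-style terms and ANNOVAR-style exonic
#' function labels accepted in annotation tables (ANNOVAR region classes
#' from [region_vocabulary()] are additionally accepted by
#' [read_annotation_table()]). The concatenated
#' `splice_region_variantand intron_variant` spelling appears verbatim in
#' published annotation exports and is accepted as-is.
#'
#' @return Character vector of accepted category terms.
#' @export
category_vocabulary <- function() {
  c(
    "intron_variant",
    "missense_variant", "nonsynonymous SNV", "non-synonymous SNV",
    "synonymous_variant", "synonymous SNV",
    "upstream_gene_variant", "downstream_gene_variant",
    "3_prime_UTR_variant", "5_prime_UTR_variant",
    "5_prime_UTR_premature_start_codon_gain_variant",
    "splice_region_variant", "splice_region_variantand intron_variant",
    "sequence_feature"
  )
}

#' Read a variant annotation table
#'
#' Tab-separated, with the column schema
#' `#CHROM POS Gene_ID Gene_Name CytoBand Avsnp150 Category REF ALT
#' Gene_Full_Name` and an optional trailing `p-Value` column. Categories
#' must come from [category_vocabulary()]; rsIDs must match `rs\\d+` when
#' present.
#'
#' @param path TSV file path.
#' @return A tibble with columns `chrom`, `pos`, `gene_id`, `gene_name`,
#'   `cytoband`, `rsid`, `category`, `ref`, `alt`, `gene_full_name`.
#' @export
read_annotation_table <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "", progress = FALSE,
                         locale = readr::locale(encoding = "UTF-8"))
  schema <- c("#CHROM", "POS", "Gene_ID", "Gene_Name", "CytoBand",
              "Avsnp150", "Category", "REF", "ALT", "Gene_Full_Name")
  if (!all(schema %in% names(ann))) {
    stop("annotation table lacks column(s): ",
         paste(setdiff(schema, names(ann)), collapse = ", "), call. = FALSE)
  }
  out <- tibble(
    chrom = normalize_chrom(ann[["#CHROM"]]),
    pos = as.integer(ann[["POS"]]),
    gene_id = ann[["Gene_ID"]],
    gene_name = ann[["Gene_Name"]],
    cytoband = ann[["CytoBand"]],
    rsid = ann[["Avsnp150"]],
    category = ann[["Category"]],
    ref = ann[["REF"]],
    alt = ann[["ALT"]],
    gene_full_name = ann[["Gene_Full_Name"]]
  )
  has_rs <- !is.na(out$rsid) & nzchar(out$rsid)
  if (!all(grepl("^rs[0-9]+$", out$rsid[has_rs]))) {
    stop("malformed rsID(s) in annotation table", call. = FALSE)
  }
  accepted <- c(category_vocabulary(), region_vocabulary())
  bad_cat <- setdiff(unique(out$category), accepted)
  if (length(bad_cat) > 0L) {
    stop("unknown consequence category term(s): ",
         paste(bad_cat, collapse = "; "), call. = FALSE)
  }
  validate_variant_keys(out)
  out
}
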