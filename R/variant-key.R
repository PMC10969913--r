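#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Chromosome dialect: hg19-style "chr" prefix, autosomes 1-22 then X, Y, M.
chrom_levels <- function() {
  c(paste0("chr", 1:22), "chrX", "chrY", "chrM")
}

#' Normalize chromosome labels to the "chr"-prefixed dialect
#'
#' Labels without the `chr` prefix (e.g. `"18"`, `"X"`) are prefixed, with a
#' warning, so that cohorts mixing dialects merge on a single key space.
#' `"MT"` is mapped to `"chrM"`.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @export
normalize_chrom <- function(chrom) {
  stopifnot(is.character(chrom))
  bare <- !startsWith(chrom, "chr")
  if (any(bare)) {
    warning(sprintf(
      "%d chromosome label(s) lacked the 'chr' prefix and were normalized",
      sum(bare)
    ), call. = FALSE)
    chrom[bare] <- paste0("chr", sub("^MT$", "M", chrom[bare]))
  }
  bad <- !chrom %in% chrom_levels()
  if (any(bad)) {
    stop("unknown chromosome label(s): ",
         paste(unique(chrom[bad]), collapse = ", "), call. = FALSE)
  }
  chrom
}

allele_ok <- function(x, allow_comma = FALSE) {
  pat <- if (allow_comma) "^[ACGTN]+(,[ACGTN]+)*$" else "^[ACGTN]+$"
  nzchar(x) & grepl(pat, x)
}

#' Construct a table of variant keys
#'
#' A variant's identity is the full `(chrom, pos, ref, alt)` tuple.
#' Multiallelic ALT strings are kept comma-joined as a single key (e.g.
#' `"T,CTT"`), never split: the unit of analysis is one call-set record.
#'
#' @param chrom Chromosome labels (normalized via [normalize_chrom()]).
#' @param pos 1-based reference positions.
#' @param ref Reference allele strings over `{A,C,G,T,N}`.
#' @param alt Alternate allele strings; comma-joined when multiallelic.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' variant_key("chr18", 56202768, "C", "A")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  chrom <- normalize_chrom(as.character(chrom))
  pos <- as.integer(pos)
  ref <- as.character(ref)
  alt <- as.character(alt)
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  keys <- tibble(
    chrom = rep_len(chrom, n), pos = rep_len(pos, n),
    ref = rep_len(ref, n), alt = rep_len(alt, n)
  )
  validate_variant_keys(keys)
  keys
}

validate_variant_keys <- function(keys) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(keys)))
  if (any(is.na(keys$pos)) || any(keys$pos < 1L)) {
    stop("variant positions must be integers >= 1", call. = FALSE)
  }
  if (!all(allele_ok(keys$ref))) {
    stop("invalid REF allele(s): ",
         paste(utils::head(unique(keys$ref[!allele_ok(keys$ref)]), 5),
               collapse = ", "), call. = FALSE)
  }
  if (!all(allele_ok(keys$alt, allow_comma = TRUE))) {
    stop("invalid ALT allele(s): ",
         paste(utils::head(unique(keys$alt[!allele_ok(keys$alt, TRUE)]), 5),
               collapse = ", "), call. = FALSE)
  }
  if (any(keys$ref == keys$alt)) {
    stop("REF and ALT must differ", call. = FALSE)
  }
  invisible(keys)
}

#' Canonical string form of a variant key
#'
#' @param keys A tibble with `chrom`, `pos`, `ref`, `alt` columns.
#' @return Character vector `"chrom:pos:ref:alt"` (ALT may contain commas).
#' @export
variant_id <- function(keys) {
  paste(keys$chrom, keys$pos, keys$ref, keys$alt, sep = ":")
}

#' Parse canonical variant-key strings back into a key table
#'
#' @param id Character vector produced by [variant_id()].
#' @return A variant-key tibble.
#' @export
parse_variant_id <- function(id) {
  parts <- strsplit(id, ":", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    stop("malformed variant id(s); expected 'chrom:pos:ref:alt'", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  variant_key(m[, 1], as.integer(m[, 2]), m[, 3], m[, 4])
}

# Order keys by (chrom in karyotype order, pos, ref, alt).
sort_variant_keys <- function(keys) {
  ord <- order(
    factor(keys$chrom, levels = chrom_levels()),
    keys$pos, keys$ref, keys$alt
  )
  keys[ord, , drop = FALSE]
}

#' Classify a variant as SNV or InDel
#'
#' A record is an SNV only when REF and every comma-separated ALT allele have
#' length 1; any longer allele (insertion, deletion, or a mixed multiallelic
#' record such as `C -> "T,CTT"`) makes it an InDel.
#'
#' @param ref,alt Allele strings (vectorized; `alt` may be comma-joined).
#' @return Character vector of `"SNV"` or `"InDel"`.
#' @examples
#' classify_variant_type("G", "A")            # SNV
#' classify_variant_type("AGCGCTG", "A")      # InDel (deletion)
#' classify_variant_type("C", "T,CTT")        # InDel (mixed multiallelic)
#' @export
classify_variant_type <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt))) {
    stop("empty allele string", call. = FALSE)
  }
  alt_max <- vapply(
    strsplit(alt, ",", fixed = TRUE),
    function(a) max(nchar(a)), integer(1)
  )
  ifelse(nchar(ref) == 1L & alt_max == 1L, "SNV", "InDel")
}
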