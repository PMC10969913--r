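#' Build the cohort presence matrix
#'
#' Merges per-patient call sets into a variant-by-patient grid. The variant
#' list is the union of all patients' present calls, sorted by chromosome
#' (chr1..chr22, chrX, chrY), position, REF, ALT. Each cell is `"P"`
#' (present), `"A"` (absent) or `"M"` (an explicitly flagged no-call).
#' Variants present in no patient are never materialized.
#'
#' @param call_sets Named list (names = patient ids) of tibbles as returned
#'   by [read_patient_calls()]: columns `chrom`, `pos`, `ref`, `alt` and an
#'   optional `state` column (`"present"`/`"missing"`; rows without a
#'   `state` column are all taken as present).
#' @param patients Patient metadata tibble with columns `patient_id`,
#'   `sex`, `phenotype`, `pair_id` covering every call set.
#' @return A `presence_matrix` object: a list with `variants` (key tibble),
#'   `patients`, and `cells` (character matrix, rows = variant ids,
#'   columns = patient ids).
#' @export
build_presence_matrix <- function(call_sets, patients) {
  if (length(call_sets) < 2L) {
    stop("need at least two patients to build a presence matrix",
         call. = FALSE)
  }
  if (is.null(names(call_sets)) || any(!nzchar(names(call_sets)))) {
    stop("call_sets must be a named list keyed by patient_id", call. = FALSE)
  }
  if (anyDuplicated(names(call_sets))) {
    stop("duplicate patient id in call_sets", call. = FALSE)
  }
  validate_patients(patients)
  missing_meta <- setdiff(names(call_sets), patients$patient_id)
  if (length(missing_meta) > 0L) {
    stop("patients missing from metadata: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  patients <- patients[match(names(call_sets), patients$patient_id), ]

  sets <- lapply(call_sets, function(cs) {
    cs <- as_tibble(cs)
    if (!"state" %in% names(cs)) cs$state <- "present"
    cs
  })
  all_rows <- dplyr::bind_rows(sets, .id = "patient_id")
  present <- all_rows[all_rows$state == "present", , drop = FALSE]
  variants <- sort_variant_keys(dplyr::distinct(
    present[, c("chrom", "pos", "ref", "alt")]
  ))
  ids <- variant_id(variants)

  cells <- matrix("A", nrow = nrow(variants), ncol = length(sets),
                  dimnames = list(ids, names(sets)))
  if (nrow(all_rows) > 0L) {
    row_idx <- match(variant_id(all_rows), ids)
    col_idx <- match(all_rows$patient_id, names(sets))
    on_grid <- !is.na(row_idx) # missing-only keys are not materialized
    cells[cbind(row_idx[on_grid], col_idx[on_grid])] <-
      ifelse(all_rows$state[on_grid] == "present", "P", "M")
  }

  structure(
    list(variants = variants, patients = patients, cells = cells),
    class = "presence_matrix"
  )
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf(
    "presence_matrix: %d variants x %d patients (%d F / %d M; %d missing cells)\n",
    nrow(x$variants), nrow(x$patients),
    sum(x$patients$sex == "F"), sum(x$patients$sex == "M"),
    sum(x$cells == "M")
  ))
  invisible(x)
}

#' @export
dim.presence_matrix <- function(x) dim(x$cells)

#' Write a presence matrix to its tabular interchange format
#'
#' A TSV with one `variant_key` column plus one `P`/`A`/`M` column per
#' patient; patient metadata is carried in `##patient` header lines so the
#' file round-trips through [read_presence_matrix()] losslessly.
#'
#' @param pm A `presence_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "presence_matrix"))
  meta <- sprintf("##patient\t%s\t%s\t%s\t%s",
                  pm$patients$patient_id, pm$patients$sex,
                  pm$patients$phenotype, pm$patients$pair_id)
  header <- paste(c("variant_key", colnames(pm$cells)), collapse = "\t")
  body <- paste(rownames(pm$cells),
                apply(pm$cells, 1L, paste, collapse = "\t"), sep = "\t")
  if (nrow(pm$cells) == 0L) body <- character()
  writeLines(c(meta, header, body), path)
  invisible(path)
}

#' Read a presence matrix from its tabular interchange format
#'
#' @param path File written by [write_presence_matrix()].
#' @return A `presence_matrix`.
#' @export
read_presence_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- lines[startsWith(lines, "##patient\t")]
  if (length(meta_lines) == 0L) {
    stop("no ##patient metadata lines in ", path, call. = FALSE)
  }
  meta <- do.call(rbind, strsplit(meta_lines, "\t", fixed = TRUE))
  patients <- tibble(patient_id = meta[, 2], sex = meta[, 3],
                     phenotype = meta[, 4], pair_id = meta[, 5])
  tab <- lines[!startsWith(lines, "##")]
  fields <- strsplit(tab, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (header[1] != "variant_key") {
    stop("expected a 'variant_key' header column in ", path, call. = FALSE)
  }
  body <- fields[-1]
  ids <- vapply(body, `[[`, character(1), 1L)
  cells <- matrix("A", nrow = length(body), ncol = length(header) - 1L,
                  dimnames = list(ids, header[-1]))
  for (i in seq_along(body)) cells[i, ] <- body[[i]][-1]
  if (!all(cells %in% c("P", "A", "M"))) {
    stop("presence cells must be P, A or M", call. = FALSE)
  }
  variants <- parse_variant_id(ids)
  structure(
    list(variants = variants, patients = patients, cells = cells),
    class = "presence_matrix"
  )
}
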