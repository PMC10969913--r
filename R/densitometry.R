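#' Read immunoblot densitometry measurements
#'
#' CSV with header `sample_id,sex,phenotype,target,loading` and an optional
#' `target_name` column: one row per band, giving the target protein's and
#' the loading control's (e.g. GAPDH) densitometry intensities from the
#' same lane.
#'
#' @param path CSV file path.
#' @return A tibble of blot measurements.
#' @export
read_blot_csv <- function(path) {
  m <- readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = "c", sex = "c", phenotype = "c",
      target = "d", loading = "d", .default = "c"
    ),
    progress = FALSE
  )
  required <- c("sample_id", "sex", "phenotype", "target", "loading")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0L) {
    stop("blot CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m
}

#' Loading-control normalization and fold change versus the normal group
#'
#' For each band the target intensity is divided by the loading-control
#' intensity from the same lane; each ratio is then divided by the mean
#' ratio of that sex's normal group, so the normal group's mean fold is 1
#' by construction. Group means are reported with SEM (sd/sqrt(n)) and a
#' two-sided two-sample t-test of the MASH folds against the normal folds
#' (equal-variance Student's form by default; Welch via `welch = TRUE`).
#' The t-test is run on folds; since folds are ratios scaled by a
#' group-level constant, the t statistic equals the one computed on raw
#' ratios.
#'
#' @param measurements Tibble as from [read_blot_csv()]: columns
#'   `sample_id`, `sex` (`F`/`M`), `phenotype` (`MASH`/`normal`),
#'   `target`, `loading`; intensities must be strictly positive.
#' @param by_sex Normalize and test within each sex separately (default),
#'   matching a design with per-sex blots.
#' @param welch Use Welch's unequal-variance t-test.
#' @return A tibble with one row per (sex, phenotype) group: `n`,
#'   `mean_fold`, `sem_fold` and `p_value` (MASH vs normal; `NA` on the
#'   normal rows and when either group has fewer than 2 samples).
#' @export
compute_folds <- function(measurements, by_sex = TRUE, welch = FALSE) {
  required <- c("sample_id", "sex", "phenotype", "target", "loading")
  stopifnot(all(required %in% names(measurements)))
  if (any(measurements$target <= 0) || any(measurements$loading <= 0)) {
    stop("band intensities must be strictly positive", call. = FALSE)
  }
  if (!all(measurements$phenotype %in% c("MASH", "normal"))) {
    stop("phenotype must be 'MASH' or 'normal'", call. = FALSE)
  }
  groups <- if (by_sex) split(measurements, measurements$sex)
            else list(all = measurements)

  res <- lapply(names(groups), function(g) {
    m <- groups[[g]]
    if (!any(m$phenotype == "normal")) {
      stop("no normal-group measurement to normalize against",
           if (by_sex) paste0(" (sex ", g, ")"), call. = FALSE)
    }
    ratio <- m$target / m$loading
    norm_mean <- mean(ratio[m$phenotype == "normal"])
    fold <- ratio / norm_mean
    per_group <- function(phen) {
      f <- fold[m$phenotype == phen]
      tibble(
        sex = if (by_sex) g else NA_character_,
        phenotype = phen,
        n = length(f),
        # mean(group ratios)/norm_mean: identically 1 for the normal group
        mean_fold = mean(ratio[m$phenotype == phen]) / norm_mean,
        sem_fold = if (length(f) > 1L) {
          stats::sd(f) / sqrt(length(f))
        } else {
          NA_real_
        }
      )
    }
    phens <- intersect(c("normal", "MASH"), unique(m$phenotype))
    out <- dplyr::bind_rows(lapply(phens, per_group))
    f_mash <- fold[m$phenotype == "MASH"]
    f_norm <- fold[m$phenotype == "normal"]
    out$p_value <- NA_real_
    if (length(f_mash) >= 2L && length(f_norm) >= 2L) {
      # zero within-group variance (e.g. identical replicate ratios) has no
      # defined t; report NA rather than an infinite statistic
      out$p_value[out$phenotype == "MASH"] <- tryCatch(
        stats::t.test(f_mash, f_norm, var.equal = !welch)$p.value,
        error = function(e) NA_real_
      )
    }
    out
  })
  dplyr::bind_rows(res)
}
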