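#' Hypergeometric probability mass
#'
#' Exact probability of drawing `k` females among `n` carriers when `K` of
#' the `N` patients are female, computed in log-space to avoid factorial
#' overflow: `C(K,k) C(N-K,n-k) / C(N,n)`. This is the conditional kernel
#' behind the exact sex-exclusivity test.
#'
#' @param N Population (cohort) size.
#' @param K Number of females in the cohort.
#' @param n Number of carriers of the variant.
#' @param k Number of female carriers.
#' @return The exact probability.
#' @examples
#' hypergeom_pmf(8, 4, 4, 4)  # 1/70: all four carriers female
#' @export
hypergeom_pmf <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, K <= N, n >= 0, n <= N)
  if (k < max(0, n - (N - K)) || k > min(n, K)) {
    stop("k = ", k, " outside the hypergeometric support", call. = FALSE)
  }
  exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n))
}

# Relative tolerance when comparing table probabilities, as in the classic
# two-sided Fisher convention: tables whose probability exceeds the observed
# one by less than one part in 1e7 still count as "at most as probable".
.fisher_rel_tol <- 1 + 1e-07

#' Two-sided Fisher exact test for a sex-by-carrier 2x2 table
#'
#' Conditions on the margins (rows = sex, columns = carrier status) and sums
#' the hypergeometric probabilities of all tables at most as probable as the
#' observed one. For the 4-vs-4 perfect split (4 female carriers, 0 male)
#' this yields 2/70 = 0.0286, the design p-value of an equal 4+4 cohort.
#'
#' @param n_present_f,n_present_m Carrier counts by sex.
#' @param n_f,n_m Cohort sizes by sex.
#' @param alternative `"two.sided"` (default) or `"one.sided"`; one-sided
#'   sums the tail at least as extreme in the observed direction.
#' @return The exact p-value; 1 when the carrier margin is empty or full.
#' @examples
#' fisher_two_sided(4, 4, 0, 4)  # 0.02857... = 2/70
#' @export
fisher_two_sided <- function(n_present_f, n_f, n_present_m, n_m,
                             alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n_present_f >= 0, n_present_m >= 0, n_f >= 1, n_m >= 1,
            n_present_f <= n_f, n_present_m <= n_m)
  N <- n_f + n_m
  n <- n_present_f + n_present_m
  if (n == 0L || n == N) {
    return(1)
  }
  support <- max(0, n - n_m):min(n, n_f)
  pmf <- vapply(support, function(k) hypergeom_pmf(N, n_f, n, k), numeric(1))
  p_obs <- pmf[match(n_present_f, support)]
  if (alternative == "one.sided") {
    expected_f <- n * n_f / N
    tail <- if (n_present_f >= expected_f) support >= n_present_f
            else support <= n_present_f
    return(min(1, sum(pmf[tail])))
  }
  min(1, sum(pmf[pmf <= p_obs * .fisher_rel_tol]))
}

#' Smallest p-value attainable by a cohort design
#'
#' The two-sided exact p of the perfect-split table: every patient of one
#' sex carries the variant and none of the other sex does (the more extreme
#' of the two orientations when cohort sizes differ). For equal cohorts
#' this is `2 / C(n_f + n_m, n_f)`: 0.0286 for 4 vs 4. It is the natural
#' significance threshold for the perfect-split criterion, and quantifies
#' what a given cohort size can ever detect (a 1-vs-1 design bottoms out
#' at p = 1).
#'
#' @param n_f,n_m Cohort sizes by sex.
#' @return The minimum achievable two-sided p-value.
#' @examples
#' min_achievable_p(4, 4)  # 2/70
#' min_achievable_p(1, 1)  # 1: such a design can never be significant
#' @export
min_achievable_p <- function(n_f, n_m) {
  stopifnot(n_f >= 1, n_m >= 1)
  min(
    fisher_two_sided(n_f, n_f, 0, n_m),
    fisher_two_sided(0, n_f, n_m, n_m)
  )
}

#' Default significance criterion for sex-exclusive filtering
#'
#' @param alpha Significance threshold in (0, 1]; defaults (when `NULL` in
#'   [filter_sex_specific()]) to the cohort's [min_achievable_p()], so that
#'   perfect splits pass in any design where they are the most extreme
#'   outcome.
#' @param require_perfect_split If `TRUE` (default), only perfect-split
#'   patterns can be significant; if `FALSE`, any pattern with p <= alpha
#'   qualifies, generalizing the filter to near-exclusive patterns.
#' @param one_sided Use the one-sided tail instead of the two-sided sum.
#' @return A `significance_criterion` list.
#' @export
significance_criterion <- function(alpha = NULL,
                                   require_perfect_split = TRUE,
                                   one_sided = FALSE) {
  if (!is.null(alpha)) {
    stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  }
  structure(
    list(alpha = alpha, require_perfect_split = require_perfect_split,
         one_sided = one_sided),
    class = "significance_criterion"
  )
}

classify_pattern <- function(k_f, k_m, n_f, n_m) {
  dplyr::case_when(
    k_f == n_f & k_m == 0L ~ "female_exclusive",
    k_m == n_m & k_f == 0L ~ "male_exclusive",
    k_f > 0L & k_m > 0L ~ "shared",
    k_f + k_m == 0L ~ "absent",
    TRUE ~ "partial"
  )
}

#' Filter a cohort for sex-exclusive variants
#'
#' Computes, for every variant in the presence matrix, carrier counts by
#' sex, the presence pattern, and the exact two-sided Fisher p-value, then
#' flags the significant subset: perfect-split patterns (present in all
#' patients of one sex, absent in all of the other) with p <= alpha.
#' Missing (`"M"`) cells count as absent for the test but are reported in
#' `n_missing` so incomplete variants can be audited or re-filtered.
#'
#' @param pm A `presence_matrix` with at least one female and one male.
#' @param criterion A [significance_criterion()]; `alpha = NULL` uses the
#'   cohort's [min_achievable_p()].
#' @return A tibble sorted by (chrom, pos), one row per variant: the key
#'   columns plus `n_present_f`, `n_present_m`, `n_f`, `n_m`, `n_missing`,
#'   `pattern`, `p_two_sided`, `p_bonferroni` (exome-wide Bonferroni,
#'   reported but never used for filtering), and `significant`.
#' @export
filter_sex_specific <- function(pm, criterion = significance_criterion()) {
  stopifnot(inherits(pm, "presence_matrix"))
  is_f <- pm$patients$sex == "F"
  n_f <- sum(is_f)
  n_m <- sum(!is_f)
  if (n_f == 0L || n_m == 0L) {
    stop("exclusivity filtering needs both sexes in the cohort",
         call. = FALSE)
  }
  alpha <- criterion$alpha %||% min_achievable_p(n_f, n_m)

  pres <- pm$cells == "P"
  k_f <- as.integer(rowSums(pres[, is_f, drop = FALSE]))
  k_m <- as.integer(rowSums(pres[, !is_f, drop = FALSE]))
  n_missing <- as.integer(rowSums(pm$cells == "M"))

  # p depends only on (k_f, k_m); compute each distinct table once
  tab_id <- paste(k_f, k_m)
  uniq <- !duplicated(tab_id)
  alt <- if (criterion$one_sided) "one.sided" else "two.sided"
  p_uniq <- mapply(function(a, b) fisher_two_sided(a, n_f, b, n_m, alt),
                   k_f[uniq], k_m[uniq])
  p <- unname(p_uniq[match(tab_id, tab_id[uniq])])

  pattern <- classify_pattern(k_f, k_m, n_f, n_m)
  exclusive <- pattern %in% c("female_exclusive", "male_exclusive")
  # p = 1 carries no evidence (e.g. a 1-vs-1 design, where alpha defaults
  # to 1); such rows are never flagged significant
  significant <- if (criterion$require_perfect_split) {
    exclusive & p <= alpha & p < 1
  } else {
    p <= alpha & p < 1
  }

  out <- dplyr::bind_cols(
    pm$variants,
    tibble(
      n_present_f = k_f, n_present_m = k_m,
      n_f = n_f, n_m = n_m, n_missing = n_missing,
      pattern = pattern, p_two_sided = p,
      p_bonferroni = pmin(1, p * nrow(pm$variants)),
      significant = significant
    )
  )
  ord <- order(factor(out$chrom, levels = chrom_levels()), out$pos,
               out$ref, out$alt)
  out[ord, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
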