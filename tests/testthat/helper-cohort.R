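# Shared builders: tiny VCFs written in code, small cohorts, and the
# brute-force exact-test oracle used to validate the analytic kernel.

write_test_vcf <- function(path, chrom, pos, ref, alt,
                           filter = "PASS", gt = "0/1",
                           sample = "S1", n_info_only = FALSE) {
  n <- length(pos)
  filter <- rep_len(filter, n)
  gt <- rep_len(gt, n)
  chrom <- rep_len(chrom, n)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  body <- if (n > 0) {
    paste(chrom, pos, ".", ref, alt, ".", filter, ".", "GT", gt, sep = "\t")
  } else {
    character()
  }
  writeLines(c(header, body), path)
  path
}

patients_tbl <- function(ids, sexes, phenotype = "MASH") {
  tibble::tibble(
    patient_id = ids, sex = sexes, phenotype = phenotype,
    pair_id = paste0("pair_", ids)
  )
}

key_tbl <- function(chrom, pos, ref, alt, state = "present") {
  k <- sexvar::variant_key(chrom, pos, ref, alt)
  k$state <- rep_len(state, nrow(k))
  k
}

# Independent oracle: two-sided exact p by enumerating every way to place
# the n carriers among the N = n_f + n_m patients; each placement is
# equally likely under the null, and the two-sided p is the fraction of
# placements whose female-carrier count is at most as probable as the
# observed one.
brute_force_fisher <- function(k_f, n_f, k_m, n_m) {
  N <- n_f + n_m
  n <- k_f + k_m
  if (n == 0 || n == N) {
    return(1)
  }
  assignments <- utils::combn(N, n)
  kf_all <- apply(assignments, 2, function(ix) sum(ix <= n_f))
  pmf_tab <- table(kf_all) / ncol(assignments)
  pmf_of <- function(k) as.numeric(pmf_tab[as.character(k)])
  p_obs <- pmf_of(k_f)
  probs <- vapply(kf_all, pmf_of, numeric(1))
  mean(probs <= p_obs * (1 + 1e-07))
}

# Closed-form equal-variance two-sample t (the densitometry oracle).
student_t_oracle <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * stats::pt(-abs(t), df = nx + ny - 2))
}
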