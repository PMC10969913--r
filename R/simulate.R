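#' Configure a synthetic matched-cohort simulation
#'
#' Defaults emulate the reference eight-patient study design: 4 female and
#' 4 male patients, a 10,000-variant background shared across patients with
#' no sex structure (a scaled-down exome null), 63 planted female-exclusive
#' and 54 planted male-exclusive variants, region classes drawn from the
#' published exome-wide SNV distribution, and an InDel fraction of
#' 13,925/148,881.
#'
#' @param n_f,n_m Cohort sizes by sex.
#' @param n_background Number of background (non-sex-structured) variants.
#' @param carrier_prob Per-patient independent probability that a
#'   background variant is called in a patient.
#' @param n_planted_f,n_planted_m Numbers of planted sex-exclusive
#'   variants (present in every patient of that sex, absent in the other).
#' @param region_dist Named probability vector over [region_vocabulary()];
#'   defaults to the bundled exome-wide SNV region proportions.
#' @param indel_frac Probability that a simulated variant is an InDel.
#' @param seed Integer RNG seed; the simulation is fully reproducible for
#'   a fixed seed, and per-patient background draws use deterministically
#'   derived substreams so changing the cohort size does not reshuffle
#'   unrelated draws.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_f = 4, n_m = 4,
                              n_background = 10000,
                              carrier_prob = 0.5,
                              n_planted_f = 63, n_planted_m = 54,
                              region_dist = NULL,
                              indel_frac = 13925 / 148881,
                              seed = 1) {
  if (is.null(region_dist)) {
    grid <- region_class_counts()
    region_dist <- stats::setNames(grid$snv_count / sum(grid$snv_count),
                                   grid$region_class)
  }
  stopifnot(
    n_f >= 1, n_m >= 1, n_background >= 0,
    n_planted_f >= 0, n_planted_m >= 0,
    carrier_prob >= 0, carrier_prob <= 1,
    indel_frac >= 0, indel_frac <= 1,
    abs(sum(region_dist) - 1) < 1e-08,
    all(names(region_dist) %in% region_vocabulary())
  )
  structure(
    list(n_f = n_f, n_m = n_m, n_background = n_background,
         carrier_prob = carrier_prob,
         n_planted_f = n_planted_f, n_planted_m = n_planted_m,
         region_dist = region_dist, indel_frac = indel_frac,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Derived substream seeds stay below 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 104729) %% 2147483647)
}

.sim_chroms <- function() paste0("chr", c(1:22, "X"))
.sim_pos_space <- 2.4e8  # per-chromosome address space for unique positions

random_alleles <- function(type) {
  bases <- c("A", "C", "G", "T")
  n <- length(type)
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(seq_len(n), function(i) {
    if (type[i] == "SNV") {
      sample(setdiff(bases, ref[i]), 1)
    } else if (stats::runif(1) < 0.5) { # insertion
      paste0(c(ref[i], sample(bases, sample(1:6, 1), replace = TRUE)),
             collapse = "")
    } else {
      "" # deletion: handled below (long REF, single-base ALT)
    }
  }, character(1))
  del <- type == "InDel" & alt == ""
  if (any(del)) {
    long_ref <- vapply(which(del), function(i) {
      paste0(c(ref[i], sample(bases, sample(1:6, 1), replace = TRUE)),
             collapse = "")
    }, character(1))
    alt[del] <- ref[del]
    ref[del] <- long_ref
  }
  list(ref = ref, alt = alt)
}

# SO-style category compatible with a region class, for simulated
# annotation tables; classes with no SO term keep the region class itself.
region_to_category <- function(region_class) {
  map <- c(
    intronic = "intron_variant", exonic = "synonymous_variant",
    upstream = "upstream_gene_variant", downstream = "downstream_gene_variant",
    UTR3 = "3_prime_UTR_variant", UTR5 = "5_prime_UTR_variant",
    splicing = "splice_region_variant"
  )
  out <- unname(map[region_class])
  as.character(ifelse(is.na(out), region_class, out))
}

#' Simulate a matched cohort with planted sex-exclusive variants
#'
#' Background variants are present in each patient independently with
#' `carrier_prob` (rows present in no patient are resampled); planted
#' variants are carried by exactly the patients of their sex. Positions are
#' unique, drawn without replacement within each chromosome.
#'
#' @param config A [simulation_config()].
#' @return A list with `call_sets` (named list of per-patient key tibbles),
#'   `truth` (per-variant key, `status` in
#'   `background`/`planted_f`/`planted_m`, `region_class`, `variant_type`),
#'   `patients` (metadata tibble) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_total <- config$n_background + config$n_planted_f + config$n_planted_m
  if (n_total > length(.sim_chroms()) * .sim_pos_space) {
    stop("infeasible config: more variants than the position address space",
         call. = FALSE)
  }

  withr::local_seed(config$seed)
  chrom <- sample(.sim_chroms(), n_total, replace = TRUE)
  pos <- integer(n_total)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- sample.int(.sim_pos_space, length(idx), replace = FALSE)
  }
  type <- as.character(
    ifelse(stats::runif(n_total) < config$indel_frac, "InDel", "SNV")
  )
  region <- sample(names(config$region_dist), n_total, replace = TRUE,
                   prob = config$region_dist)
  alleles <- random_alleles(type)
  status <- rep(c("planted_f", "planted_m", "background"),
                c(config$n_planted_f, config$n_planted_m,
                  config$n_background))

  truth <- dplyr::bind_cols(
    variant_key(chrom, pos, alleles$ref, alleles$alt),
    tibble(status = status, region_class = region, variant_type = type)
  )
  truth <- truth[order(factor(truth$chrom, levels = chrom_levels()),
                       truth$pos), ]

  patients <- tibble(
    patient_id = c(paste0("F", seq_len(config$n_f)),
                   paste0("M", seq_len(config$n_m))),
    sex = rep(c("F", "M"), c(config$n_f, config$n_m)),
    phenotype = "MASH",
    pair_id = c(paste0("pairF", seq_len(config$n_f)),
                paste0("pairM", seq_len(config$n_m)))
  )

  bg <- truth$status == "background"
  n_bg <- sum(bg)
  n_pat <- nrow(patients)
  carried <- matrix(FALSE, nrow = nrow(truth), ncol = n_pat,
                    dimnames = list(NULL, patients$patient_id))
  carried[truth$status == "planted_f", patients$sex == "F"] <- TRUE
  carried[truth$status == "planted_m", patients$sex == "M"] <- TRUE
  if (n_bg > 0L) {
    for (j in seq_len(n_pat)) {
      withr::local_seed(derive_seed(config$seed, j))
      carried[bg, j] <- stats::runif(n_bg) < config$carrier_prob
    }
    # background variants present in no patient are resampled
    iter <- 0L
    repeat {
      empty <- bg & rowSums(carried) == 0L
      if (!any(empty) || config$carrier_prob == 0) break
      iter <- iter + 1L
      withr::local_seed(derive_seed(config$seed, 1000L + iter))
      carried[empty, ] <- matrix(
        stats::runif(sum(empty) * n_pat) < config$carrier_prob,
        ncol = n_pat
      )
    }
  }

  keys <- truth[, c("chrom", "pos", "ref", "alt")]
  call_sets <- lapply(seq_len(n_pat), function(j) {
    cs <- keys[carried[, j], , drop = FALSE]
    cs$state <- rep("present", nrow(cs))
    cs
  })
  names(call_sets) <- patients$patient_id

  list(call_sets = call_sets, truth = truth, patients = patients,
       config = config)
}

#' Score pipeline recovery of planted variants
#'
#' @param sim Output of [simulate_cohort()] (or any list with a `truth`
#'   element).
#' @param results Output of [filter_sex_specific()] on the corresponding
#'   cohort.
#' @return A list: `recall` (flagged planted / planted, with the correct
#'   orientation), `precision_planted` (correctly oriented / flagged
#'   planted), `n_false_splits` (background variants flagged significant)
#'   and `n_background`.
#' @export
evaluate_recovery <- function(sim, results) {
  truth <- sim$truth
  joined <- dplyr::left_join(
    truth,
    results[, c("chrom", "pos", "ref", "alt", "pattern", "significant")],
    by = c("chrom", "pos", "ref", "alt")
  )
  joined$significant[is.na(joined$significant)] <- FALSE
  planted <- joined$status != "background"
  want <- ifelse(joined$status == "planted_f", "female_exclusive",
                 "male_exclusive")
  hit <- planted & joined$significant & joined$pattern == want
  n_planted <- sum(planted)
  n_flagged_planted <- sum(planted & joined$significant)
  list(
    recall = if (n_planted > 0L) sum(hit) / n_planted else NA_real_,
    precision_planted = if (n_flagged_planted > 0L) {
      sum(hit) / n_flagged_planted
    } else {
      NA_real_
    },
    n_false_splits = sum(!planted & joined$significant),
    n_background = sum(!planted)
  )
}

#' Write a simulated cohort to disk as VCFs plus metadata tables
#'
#' Emits one single-sample VCF v4.2 per patient (with contig headers and a
#' GT genotype column), a `sample_sheet.csv`, an `annotation.tsv` in the
#' standard annotation schema (one synthetic gene per variant, categories
#' compatible with each variant's region class), and a `truth.tsv`. Output
#' is byte-stable for a fixed seed: no timestamps are written.
#'
#' @param sim Output of [simulate_cohort()] or [build_fixture_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) {
    stop("cannot create output directory: ", dir, call. = FALSE)
  }
  contigs <- chrom_levels()[chrom_levels() %in%
                              unique(unlist(lapply(sim$call_sets,
                                                   function(cs) cs$chrom)))]
  for (pid in names(sim$call_sets)) {
    cs <- sim$call_sets[[pid]]
    cs <- cs[order(factor(cs$chrom, levels = chrom_levels()), cs$pos,
                   cs$ref, cs$alt), ]
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=sexvar-synthetic-cohort",
      paste0("##contig=<ID=", contigs, ">"),
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pid, sep = "\t")
    )
    body <- if (nrow(cs) > 0L) {
      paste(cs$chrom, cs$pos, ".", cs$ref, cs$alt, ".", "PASS", ".",
            "GT", "0/1", sep = "\t")
    } else {
      character()
    }
    writeLines(c(header, body), file.path(dir, paste0(pid, ".vcf")))
  }

  sheet <- sim$patients
  sheet$vcf_path <- paste0(sheet$patient_id, ".vcf")
  readr::write_csv(sheet, file.path(dir, "sample_sheet.csv"),
                   progress = FALSE)

  ann <- cohort_annotation(sim)
  write_annotation_table(ann, file.path(dir, "annotation.tsv"))

  if (!is.null(sim$truth)) {
    readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"),
                     progress = FALSE)
  }
  invisible(dir)
}

# Annotation table for a cohort: the bundled reference rows when the
# cohort was built from them, synthetic single-gene rows otherwise.
cohort_annotation <- function(sim) {
  if (!is.null(sim$annotation)) {
    return(sim$annotation)
  }
  truth <- sim$truth
  tibble(
    chrom = truth$chrom, pos = truth$pos,
    gene_id = sprintf("SIMG%07d", seq_len(nrow(truth))),
    gene_name = sprintf("GENE%05d", seq_len(nrow(truth))),
    cytoband = paste0(sub("^chr", "", truth$chrom), "q00"),
    rsid = "",
    category = region_to_category(truth$region_class),
    ref = truth$ref, alt = truth$alt,
    gene_full_name = "synthetic gene"
  )
}

write_annotation_table <- function(ann, path) {
  out <- tibble(
    `#CHROM` = ann$chrom, POS = ann$pos, Gene_ID = ann$gene_id,
    Gene_Name = ann$gene_name, CytoBand = ann$cytoband,
    Avsnp150 = ann$rsid, Category = ann$category,
    REF = ann$ref, ALT = ann$alt, Gene_Full_Name = ann$gene_full_name
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
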