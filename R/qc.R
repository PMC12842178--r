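#' Variant quality-control thresholds
#'
#' Bundles the filters applied before gene burden testing: the minimum
#' read depth for a genotype call to be trusted (calls below it are set
#' to missing), the maximum population minor allele frequency for a
#' site to count as rare (MAF below the bound is retained; the bound
#' itself is excluded), the consequence terms accepted as predicted
#' loss-of-function, and the minimum number of distinct surviving LoF
#' sites a gene needs to enter the burden test.
#'
#' @param min_depth Minimum read depth in reads; calls with depth below
#'   this are set to missing (default 20).
#' @param max_maf Exclusive upper bound on the population MAF
#'   (default 0.05); sites with frequency at or above it are removed.
#' @param lof_consequences Character vector of consequence terms
#'   treated as predicted loss-of-function.
#' @param min_lof_variants Minimum distinct LoF sites per gene for
#'   burden eligibility (default 5, boundary inclusive).
#' @return An object of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(min_depth = 20L, max_maf = 0.05,
                          lof_consequences = c("stop_gained",
                                               "frameshift_variant",
                                               "splice_acceptor_variant",
                                               "splice_donor_variant",
                                               "start_lost", "stop_lost"),
                          min_lof_variants = 5L) {
  if (min_depth < 0) stop("min_depth must be >= 0")
  if (max_maf <= 0 || max_maf > 1) stop("max_maf must lie in (0, 1]")
  if (length(lof_consequences) == 0L)
    stop("lof_consequences must be non-empty")
  structure(list(min_depth = as.integer(min_depth), max_maf = max_maf,
                 lof_consequences = lof_consequences,
                 min_lof_variants = as.integer(min_lof_variants)),
            class = "qc_thresholds")
}

# consequence vocabulary the classifier recognizes (VEP-style terms)
.csq_vocabulary <- c(
  "stop_gained", "frameshift_variant", "splice_acceptor_variant",
  "splice_donor_variant", "start_lost", "stop_lost",
  "missense_variant", "synonymous_variant", "intron_variant",
  "splice_region_variant", "inframe_deletion", "inframe_insertion",
  "stop_retained_variant", "5_prime_UTR_variant", "3_prime_UTR_variant",
  "upstream_gene_variant", "downstream_gene_variant", "intergenic_variant")

#' Classify consequence terms as predicted loss-of-function
#'
#' A term is LoF iff it belongs to the configured LoF set. Unrecognized
#' terms raise a warning and classify as non-LoF, or an error in strict
#' mode.
#'
#' @param consequence Character vector of consequence terms.
#' @param thresholds A [qc_thresholds()].
#' @param strict Error on unrecognized terms instead of warning.
#' @return Logical vector, one element per term.
#' @examples
#' classify_lof(c("stop_gained", "missense_variant"))
#' @export
classify_lof <- function(consequence, thresholds = qc_thresholds(),
                         strict = FALSE) {
  known <- union(.csq_vocabulary, thresholds$lof_consequences)
  bad <- setdiff(unique(consequence), known)
  if (length(bad)) {
    msg <- paste("unrecognized consequence term(s):",
                 paste(bad, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  consequence %in% thresholds$lof_consequences
}

# append rows to a cohort's removal log
.log_removals <- function(cohort, keys, reason, n_control = NA_integer_) {
  if (!length(keys)) return(cohort)
  entry <- data.frame(variant_key = keys, reason = reason,
                      n_control_carriers = n_control,
                      stringsAsFactors = FALSE)
  cohort$removal_log <- rbind(cohort$removal_log, entry)
  cohort
}

#' Apply depth, frequency, and consequence filters
#'
#' Implements the pre-burden variant QC: genotype calls with read depth
#' below `min_depth` are set to missing; sites with population MAF at
#' or above `max_maf` are removed (sites absent from the reference
#' database, `gnomad_af = NA`, are treated as rare and retained); sites
#' whose consequence is not predicted loss-of-function are removed.
#' The ordering of surviving sites is preserved and removals are
#' appended to the cohort's `removal_log`.
#'
#' @param cohort An `"ndd_cohort"` (or any list with `samples`,
#'   `sites`, `geno`, `depth`).
#' @param thresholds A [qc_thresholds()].
#' @return The filtered cohort.
#' @export
apply_qc <- function(cohort, thresholds = qc_thresholds()) {
  stopifnot(nrow(cohort$samples) == nrow(cohort$geno),
            nrow(cohort$sites) == ncol(cohort$geno))
  if (!is.null(cohort$depth)) {
    low <- cohort$depth < thresholds$min_depth
    cohort$geno[low] <- NA_integer_
  }
  maf_fail <- !is.na(cohort$sites$gnomad_af) &
    cohort$sites$gnomad_af >= thresholds$max_maf
  lof <- classify_lof(cohort$sites$consequence, thresholds)
  cohort <- .log_removals(cohort, cohort$sites$variant_key[maf_fail],
                          "maf_at_or_above_threshold")
  cohort <- .log_removals(cohort, cohort$sites$variant_key[!lof & !maf_fail],
                          "not_predicted_lof")
  keep <- !maf_fail & lof
  cohort$sites <- cohort$sites[keep, , drop = FALSE]
  cohort$geno <- cohort$geno[, keep, drop = FALSE]
  if (!is.null(cohort$depth))
    cohort$depth <- cohort$depth[, keep, drop = FALSE]
  cohort
}

#' Remove case-observed variants present in any control
#'
#' Emulates a fully penetrant Mendelian disease model: any variant
#' carried by at least one control -- in any zygosity state -- is
#' excluded, so every surviving case-observed variant is case-private.
#' Control-only variants cannot contribute to case burden and are
#' dropped from the analysis set as well (CAST carrier counts are
#' unchanged either way). Missing genotypes count as non-carrier.
#' Removals are appended to the cohort's `removal_log` with the
#' triggering control-carrier count.
#'
#' @param cohort An `"ndd_cohort"` whose `samples$status` labels cases
#'   and controls.
#' @return The filtered cohort; `cohort$removal_log` gains one row per
#'   removed site with reason `"shared_case_control"` or
#'   `"control_only"`.
#' @export
penetrant_model_filter <- function(cohort) {
  stopifnot(all(cohort$samples$status %in% c("case", "control")))
  carrier <- !is.na(cohort$geno) & cohort$geno > 0L
  is_case <- cohort$samples$status == "case"
  n_case_carr <- as.integer(colSums(carrier[is_case, , drop = FALSE]))
  n_ctrl_carr <- as.integer(colSums(carrier[!is_case, , drop = FALSE]))
  shared <- n_ctrl_carr > 0L & n_case_carr > 0L
  ctrl_only <- n_ctrl_carr > 0L & n_case_carr == 0L
  cohort <- .log_removals(cohort, cohort$sites$variant_key[shared],
                          "shared_case_control", n_ctrl_carr[shared])
  cohort <- .log_removals(cohort, cohort$sites$variant_key[ctrl_only],
                          "control_only", n_ctrl_carr[ctrl_only])
  keep <- n_ctrl_carr == 0L
  cohort$sites <- cohort$sites[keep, , drop = FALSE]
  cohort$geno <- cohort$geno[, keep, drop = FALSE]
  if (!is.null(cohort$depth))
    cohort$depth <- cohort$depth[, keep, drop = FALSE]
  cohort
}

#' Genes eligible for the burden test
#'
#' A gene is eligible when it retains at least `min_lof_variants`
#' distinct LoF variant sites (across cases and controls) after QC.
#' The boundary is inclusive: a gene with exactly the minimum count is
#' eligible.
#'
#' @param sites Site table (already QC-filtered).
#' @param thresholds A [qc_thresholds()].
#' @return Sorted character vector of eligible gene symbols.
#' @export
eligible_genes <- function(sites, thresholds = qc_thresholds()) {
  if (nrow(sites) == 0L) return(character(0))
  counts <- tapply(sites$variant_key, sites$gene,
                   function(k) length(unique(k)))
  sort(names(counts)[counts >= thresholds$min_lof_variants])
}
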