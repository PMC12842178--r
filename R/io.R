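.gt_strings <- c("0/0", "0/1", "1/1")

#' Write a cohort as VCF plus sample sheet
#'
#' Emits `<out_prefix>.vcf` (VCFv4.2; `GT` and `DP` FORMAT fields;
#' `GENE`, `CSQCLASS` and `GNOMAD_AF` INFO keys, the latter omitted
#' when missing) and `<out_prefix>.samples.tsv` (tab-separated:
#' `sample_id`, `status`, `sex`, `age_months`, `family_history`,
#' `subgroup`). Dosages map to genotypes as 0 -> `0/0`, 1 -> `0/1`,
#' 2 -> `1/1`, missing -> `./.`. The pair round-trips losslessly
#' through [read_cohort()].
#'
#' @param cohort An `"ndd_cohort"` (or compatible list).
#' @param out_prefix Output path prefix.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_cohort <- function(cohort, out_prefix) {
  vcf_path <- paste0(out_prefix, ".vcf")
  sheet_path <- paste0(out_prefix, ".samples.tsv")

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=castburden",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    paste0("##INFO=<ID=CSQCLASS,Number=1,Type=String,",
           "Description=\"Predicted consequence class\">"),
    paste0("##INFO=<ID=GNOMAD_AF,Number=1,Type=Float,",
           "Description=\"gnomAD allele frequency\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", cohort$samples$sample_id), collapse = "\t"))

  n_sites <- nrow(cohort$sites)
  if (n_sites > 0L) {
    info <- paste0("GENE=", cohort$sites$gene,
                   ";CSQCLASS=", cohort$sites$consequence,
                   ifelse(is.na(cohort$sites$gnomad_af), "",
                          paste0(";GNOMAD_AF=",
                                 as.character(cohort$sites$gnomad_af))))
    gt <- matrix("./.", nrow = n_sites, ncol = nrow(cohort$samples))
    dos <- t(cohort$geno)  # sites x samples
    ok <- !is.na(dos)
    gt[ok] <- .gt_strings[dos[ok] + 1L]
    dp <- t(cohort$depth)
    cells <- matrix(paste0(gt, ":", dp), nrow = n_sites)
    body <- paste(cohort$sites$chrom, cohort$sites$pos, ".",
                  cohort$sites$ref, cohort$sites$alt, ".", ".",
                  info, "GT:DP",
                  apply(cells, 1L, paste, collapse = "\t"),
                  sep = "\t")
  } else {
    body <- character(0)
  }
  writeLines(c(header, body), vcf_path)

  utils::write.table(cohort$samples, sheet_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(vcf = vcf_path, samples = sheet_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' Parses the VCF through \pkg{vcfR} and rebuilds the site table,
#' dosage and depth matrices, and sample sheet.
#'
#' @param out_prefix Path prefix used by [write_cohort()].
#' @return An `"ndd_cohort"` list (without `truth`/`config`, which are
#'   simulator-side metadata).
#' @export
read_cohort <- function(out_prefix) {
  vcf_path <- paste0(out_prefix, ".vcf")
  sheet_path <- paste0(out_prefix, ".samples.tsv")
  samples <- utils::read.delim(sheet_path, stringsAsFactors = FALSE,
                               colClasses = c(sample_id = "character",
                                              status = "character",
                                              sex = "character",
                                              age_months = "integer",
                                              family_history = "logical",
                                              subgroup = "character"))

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  n_sites <- nrow(vcf@fix)
  if (n_sites == 0L) {
    empty <- matrix(integer(0), nrow = nrow(samples), ncol = 0L,
                    dimnames = list(samples$sample_id, NULL))
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        gene = character(0), consequence = character(0),
                        gnomad_af = numeric(0), variant_key = character(0),
                        stringsAsFactors = FALSE)
    return(structure(list(samples = samples, sites = sites, geno = empty,
                          depth = empty), class = "ndd_cohort"))
  }

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  sites <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = vcfR::extract.info(vcf, "GENE"),
    consequence = vcfR::extract.info(vcf, "CSQCLASS"),
    gnomad_af = suppressWarnings(
      as.numeric(vcfR::extract.info(vcf, "GNOMAD_AF"))),
    stringsAsFactors = FALSE)
  sites$variant_key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt,
                             sep = ":")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  dose[gt == "0/0"] <- 0L
  dose[gt == "0/1" | gt == "1/0"] <- 1L
  dose[gt == "1/1"] <- 2L
  geno <- t(dose)                       # samples x sites
  depth <- t(dp)
  storage.mode(depth) <- "integer"
  dimnames(geno) <- list(colnames(gt), sites$variant_key)
  dimnames(depth) <- dimnames(geno)
  geno <- geno[samples$sample_id, , drop = FALSE]
  depth <- depth[samples$sample_id, , drop = FALSE]

  structure(list(samples = samples, sites = sites, geno = geno,
                 depth = depth), class = "ndd_cohort")
}

#' Packaged cohort description and findings tables
#'
#' Loads the two fixture tables shipped with the package: the cohort
#' demographic summary (label/value/percent rows: sex, family history,
#' birth term, and NDD subgroup counts for the 94-patient cohort) and
#' the findings table (one row per reported variant: case id,
#' phenotype, gene, transcript, HGVS variant, zygosity, inheritance,
#' segregation; 38 rows across 37 diagnosed cases -- one compound
#' heterozygote contributes two rows).
#'
#' @return List with `cohort_summary` and `findings` data frames.
#' @examples
#' fx <- load_fixture_tables()
#' nrow(fx$findings)
#' @export
load_fixture_tables <- function() {
  dir <- system.file("extdata", package = "castburden", mustWork = TRUE)
  summary_path <- file.path(dir, "cohort_demographics.tsv")
  findings_path <- file.path(dir, "cohort_findings.tsv")
  cohort_summary <- utils::read.delim(summary_path, stringsAsFactors = FALSE)
  findings <- utils::read.delim(findings_path, stringsAsFactors = FALSE,
                                colClasses = "character")
  need <- c("case_id", "phenotype", "gene", "transcript", "variant",
            "zygosity", "inheritance", "segregation")
  if (!all(need %in% names(findings)) ||
      !all(c("label", "value") %in% names(cohort_summary)))
    stop("fixture tables are corrupted")
  list(cohort_summary = cohort_summary, findings = findings)
}
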