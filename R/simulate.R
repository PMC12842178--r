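#' Configuration for the synthetic case/control cohort simulator
#'
#' Captures the design of the emulated study: a small pediatric NDD
#' case series contrasted against a large population-matched healthy
#' control panel, with a handful of genes planted to carry an exact
#' case-only burden of rare predicted loss-of-function (LoF) variants.
#' Defaults mirror the emulated cohort: 94 cases versus 1246 unrelated
#' healthy controls, planted genes with 6 case carriers and 0 control
#' carriers, case ages spanning 1 month to 14 years, and a 27% rate of
#' positive family history among cases.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param n_genes Number of simulated genes.
#' @param n_enriched_genes Number of genes planted with an exact
#'   case-only carrier burden (`<= n_genes`).
#' @param variants_per_gene Number of LoF sites simulated per gene; a
#'   single count or a length-2 inclusive range sampled per gene.
#'   Enriched genes always receive at least as many sites as planted
#'   carriers, so every planted carrier can hold a private variant.
#' @param background_carrier_freq Probability that any given sample
#'   carries a rare LoF allele in a non-enriched gene, independent of
#'   case/control status. Default 0.005 (a realistic cumulative rare-LoF
#'   carrier frequency for an average gene).
#' @param enriched_case_carrier_count,enriched_control_carrier_count
#'   Exact carrier counts planted per enriched gene (defaults 6 and 0,
#'   the "six cases, zero controls" pattern of the strongest reported
#'   burden genes).
#' @param sex_male_prob_cases,sex_male_prob_controls Probability of
#'   male sex (case default 61/94; controls 0.5).
#' @param age_range_cases,age_range_controls Inclusive age ranges in
#'   months (cases default 1-168 months, i.e. 1 month to 14 years;
#'   controls default 1-216 months). The control range deliberately
#'   overlaps the case range: if the two were disjoint, case status
#'   would be perfectly predictable from age alone and any
#'   age-adjusted regression on the cohort would be degenerate.
#' @param famhist_prob_cases,famhist_prob_controls Probability of a
#'   positive family history of neurodevelopmental disorders.
#' @param subgroup_probs Named probabilities over the case NDD
#'   subgroups ASD, ID, GDD, SLD (defaults proportional to 36/39/13/6).
#' @param hom_carrier_prob Probability that a simulated carrier is
#'   homozygous (dosage 2) rather than heterozygous; default 0 (rare
#'   LoF carriers are overwhelmingly het).
#' @param plant_shared_sites Number of extra sites per enriched gene
#'   carried by one case and one control simultaneously; these exist to
#'   exercise the fully-penetrant-model filter, which must remove them.
#' @param depth Constant simulated read depth (default 100, a typical
#'   mean on-target exome depth).
#' @param low_depth_prob Probability that an individual genotype call
#'   gets a sub-threshold depth drawn uniformly from 5-19 reads, to
#'   exercise the depth filter; default 0.
#' @param seed Integer seed; fully determines the simulated cohort.
#' @return An object of class `"cohort_config"` (a validated list).
#' @export
cohort_config <- function(n_cases = 94L, n_controls = 1246L,
                          n_genes = 50L, n_enriched_genes = 4L,
                          variants_per_gene = 6L,
                          background_carrier_freq = 0.005,
                          enriched_case_carrier_count = 6L,
                          enriched_control_carrier_count = 0L,
                          sex_male_prob_cases = 61 / 94,
                          sex_male_prob_controls = 0.5,
                          age_range_cases = c(1L, 168L),
                          age_range_controls = c(1L, 216L),
                          famhist_prob_cases = 0.27,
                          famhist_prob_controls = 0.05,
                          subgroup_probs = c(ASD = 36, ID = 39,
                                             GDD = 13, SLD = 6) / 94,
                          hom_carrier_prob = 0,
                          plant_shared_sites = 0L,
                          depth = 100L,
                          low_depth_prob = 0,
                          seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_genes = as.integer(n_genes),
              n_enriched_genes = as.integer(n_enriched_genes),
              variants_per_gene = as.integer(variants_per_gene),
              background_carrier_freq = background_carrier_freq,
              enriched_case_carrier_count =
                as.integer(enriched_case_carrier_count),
              enriched_control_carrier_count =
                as.integer(enriched_control_carrier_count),
              sex_male_prob_cases = sex_male_prob_cases,
              sex_male_prob_controls = sex_male_prob_controls,
              age_range_cases = as.integer(age_range_cases),
              age_range_controls = as.integer(age_range_controls),
              famhist_prob_cases = famhist_prob_cases,
              famhist_prob_controls = famhist_prob_controls,
              subgroup_probs = subgroup_probs,
              hom_carrier_prob = hom_carrier_prob,
              plant_shared_sites = as.integer(plant_shared_sites),
              depth = as.integer(depth),
              low_depth_prob = low_depth_prob,
              seed = as.integer(seed))

  probs <- c(cfg$background_carrier_freq, cfg$sex_male_prob_cases,
             cfg$sex_male_prob_controls, cfg$famhist_prob_cases,
             cfg$famhist_prob_controls, cfg$hom_carrier_prob,
             cfg$low_depth_prob, cfg$subgroup_probs)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (cfg$n_cases < 1L || cfg$n_controls < 1L || cfg$n_genes < 1L)
    stop("n_cases, n_controls and n_genes must be positive")
  if (cfg$n_enriched_genes > cfg$n_genes)
    stop("n_enriched_genes must not exceed n_genes")
  if (cfg$n_enriched_genes < 0L)
    stop("n_enriched_genes must be non-negative")
  if (cfg$enriched_case_carrier_count > cfg$n_cases)
    stop("enriched_case_carrier_count exceeds n_cases")
  if (cfg$enriched_control_carrier_count > cfg$n_controls)
    stop("enriched_control_carrier_count exceeds n_controls")
  if (!length(cfg$variants_per_gene) %in% 1:2 ||
      any(cfg$variants_per_gene < 1L))
    stop("variants_per_gene must be a positive count or range")
  if (any(cfg$age_range_cases < 0L) || any(cfg$age_range_controls < 0L) ||
      diff(cfg$age_range_cases) < 0 || diff(cfg$age_range_controls) < 0)
    stop("age ranges must be non-negative min-max pairs")
  if (is.null(names(cfg$subgroup_probs)) ||
      !setequal(names(cfg$subgroup_probs), c("ASD", "ID", "GDD", "SLD")))
    stop("subgroup_probs must be named ASD, ID, GDD, SLD")
  structure(cfg, class = "cohort_config")
}

# default LoF consequence terms used when simulating annotation
.sim_lof_terms <- c("stop_gained", "frameshift_variant",
                    "splice_acceptor_variant", "splice_donor_variant")

#' Simulate a case/control rare-variant cohort with planted burden genes
#'
#' Generates samples with covariates, rare LoF variant sites, and a
#' per-sample genotype dosage/depth matrix. Enriched genes receive an
#' *exact* number of case (and control) carriers, each holding a
#' private heterozygous LoF variant; non-enriched genes receive
#' carriers independently of case/control status at the configured
#' background frequency, assigned to a random site within the gene.
#' The seed fully determines the output: identical configurations
#' reproduce identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return An object of class `"ndd_cohort"`: a list with
#'   \describe{
#'     \item{samples}{data frame: `sample_id`, `status` (case/control),
#'       `sex`, `age_months`, `family_history`, `subgroup`.}
#'     \item{sites}{data frame: `chrom`, `pos`, `ref`, `alt`, `gene`,
#'       `consequence`, `gnomad_af` (NA when absent from the reference
#'       database), `variant_key` (`chrom:pos:ref:alt`).}
#'     \item{geno}{integer dosage matrix, samples x sites, values 0/1/2
#'       with NA for missing calls.}
#'     \item{depth}{integer read-depth matrix, samples x sites.}
#'     \item{truth}{character vector of planted enriched gene symbols.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_cases = 20, n_controls = 50,
#'                                         n_genes = 10, seed = 7))
#' table(cohort$samples$status)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)

  n_ca <- config$n_cases
  n_co <- config$n_controls
  n <- n_ca + n_co

  samples <- data.frame(
    sample_id = c(sprintf("CASE%04d", seq_len(n_ca)),
                  sprintf("CTRL%04d", seq_len(n_co))),
    status = rep(c("case", "control"), c(n_ca, n_co)),
    sex = ifelse(stats::runif(n) < rep(c(config$sex_male_prob_cases,
                                         config$sex_male_prob_controls),
                                       c(n_ca, n_co)),
                 "male", "female"),
    age_months = c(sample(config$age_range_cases[1]:config$age_range_cases[2],
                          n_ca, replace = TRUE),
                   sample(config$age_range_controls[1]:
                            config$age_range_controls[2],
                          n_co, replace = TRUE)),
    family_history = stats::runif(n) < rep(c(config$famhist_prob_cases,
                                             config$famhist_prob_controls),
                                           c(n_ca, n_co)),
    subgroup = c(sample(names(config$subgroup_probs), n_ca, replace = TRUE,
                        prob = config$subgroup_probs),
                 rep("none", n_co)),
    stringsAsFactors = FALSE)

  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  enriched <- sort(sample(genes, config$n_enriched_genes))
  planted <- config$enriched_case_carrier_count +
    config$enriched_control_carrier_count + config$plant_shared_sites

  n_sites_gene <- if (length(config$variants_per_gene) == 1L)
    rep(config$variants_per_gene, config$n_genes)
  else
    sample(config$variants_per_gene[1]:config$variants_per_gene[2],
           config$n_genes, replace = TRUE)
  n_sites_gene[genes %in% enriched] <-
    pmax(n_sites_gene[genes %in% enriched], planted)

  gene_of_site <- rep(genes, n_sites_gene)
  n_sites <- length(gene_of_site)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  chrom_gene <- sample(as.character(1:22), config$n_genes, replace = TRUE)
  pos <- rep(seq_len(config$n_genes), n_sites_gene) * 100000L +
    unlist(lapply(n_sites_gene, seq_len)) * 10L
  gnomad_af <- round(stats::runif(n_sites, 0, 0.001), 6)
  gnomad_af[stats::runif(n_sites) < 0.1] <- NA  # absent from the database

  sites <- data.frame(
    chrom = rep(chrom_gene, n_sites_gene),
    pos = pos,
    ref = ref,
    alt = unname(alt),
    gene = gene_of_site,
    consequence = sample(.sim_lof_terms, n_sites, replace = TRUE),
    gnomad_af = gnomad_af,
    stringsAsFactors = FALSE)
  sites$variant_key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt,
                             sep = ":")

  geno <- matrix(0L, nrow = n, ncol = n_sites,
                 dimnames = list(samples$sample_id, sites$variant_key))
  dose <- function(k) ifelse(stats::runif(k) < config$hom_carrier_prob, 2L, 1L)

  for (g in genes) {
    cols <- which(sites$gene == g)
    if (g %in% enriched) {
      ca <- sample(seq_len(n_ca), config$enriched_case_carrier_count)
      for (i in seq_along(ca))
        geno[ca[i], cols[i]] <- dose(1L)
      off <- config$enriched_case_carrier_count
      if (config$enriched_control_carrier_count > 0L) {
        co <- n_ca + sample(seq_len(n_co),
                            config$enriched_control_carrier_count)
        for (i in seq_along(co))
          geno[co[i], cols[off + i]] <- dose(1L)
        off <- off + config$enriched_control_carrier_count
      }
      if (config$plant_shared_sites > 0L) {
        for (i in seq_len(config$plant_shared_sites)) {
          geno[sample(seq_len(n_ca), 1L), cols[off + i]] <- 1L
          geno[n_ca + sample(seq_len(n_co), 1L), cols[off + i]] <- dose(1L)
        }
      }
    } else if (config$background_carrier_freq > 0) {
      carriers <- which(stats::runif(n) < config$background_carrier_freq)
      if (length(carriers)) {
        at <- sample(cols, length(carriers), replace = TRUE)
        for (i in seq_along(carriers))
          geno[carriers[i], at[i]] <-
            max(geno[carriers[i], at[i]], dose(1L))
      }
    }
  }

  depth <- matrix(config$depth, nrow = n, ncol = n_sites,
                  dimnames = dimnames(geno))
  if (config$low_depth_prob > 0) {
    low <- stats::runif(n * n_sites) < config$low_depth_prob
    depth[low] <- sample(5:19, sum(low), replace = TRUE)
  }

  structure(list(samples = samples, sites = sites, geno = geno,
                 depth = depth, truth = enriched, config = config),
            class = "ndd_cohort")
}

#' @export
print.ndd_cohort <- function(x, ...) {
  cat("Synthetic case/control rare-variant cohort\n")
  cat("  samples: ", sum(x$samples$status == "case"), " cases, ",
      sum(x$samples$status == "control"), " controls\n", sep = "")
  cat("  sites:   ", nrow(x$sites), " LoF sites in ",
      length(unique(x$sites$gene)), " genes\n", sep = "")
  cat("  planted: ", if (length(x$truth))
    paste(x$truth, collapse = ", ") else "none", "\n", sep = "")
  invisible(x)
}
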