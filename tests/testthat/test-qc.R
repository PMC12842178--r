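test_that("LoF classification follows the configured vocabulary", {
  th <- qc_thresholds()
  expect_true(classify_lof("stop_gained", th))
  expect_false(classify_lof("synonymous_variant", th))
  expect_false(classify_lof("missense_variant", th))
  expect_true(all(classify_lof(c("frameshift_variant",
                                 "splice_donor_variant"), th)))
  expect_warning(out <- classify_lof("made_up_term", th), "unrecognized")
  expect_false(out)
  expect_error(classify_lof("made_up_term", th, strict = TRUE),
               "unrecognized")
})

test_that("depth, MAF, and consequence filters apply at the boundaries", {
  geno <- matrix(1L, nrow = 2, ncol = 4)
  co <- make_cohort(geno, status = c("case", "control"),
                    genes = "G1",
                    gnomad_af = c(1e-4, 0.06, 0.05, 0.049),
                    consequence = c("stop_gained", "stop_gained",
                                    "stop_gained", "stop_gained"))
  co$depth[1, 1] <- 19L  # just below the 20x bound -> call goes missing
  co$depth[2, 1] <- 20L  # exactly at the bound -> retained
  out <- apply_qc(co)
  # MAF 0.06 and 0.05 removed (bound exclusive), 0.049 and 1e-4 kept
  expect_identical(out$sites$gnomad_af, c(1e-4, 0.049))
  expect_true(is.na(out$geno[1, 1]))
  expect_identical(out$geno[2, 1], 1L)
  expect_setequal(out$removal_log$reason, "maf_at_or_above_threshold")
})

test_that("non-LoF and high-MAF sites are counted out together", {
  # 10 sites: 3 fail MAF, 2 non-LoF -> 5 survive
  geno <- matrix(0L, nrow = 3, ncol = 10)
  co <- make_cohort(geno, status = c("case", "control", "control"),
                    genes = "G1",
                    gnomad_af = c(0.2, 0.3, 0.9, rep(1e-4, 7)),
                    consequence = c(rep("stop_gained", 8),
                                    "missense_variant",
                                    "synonymous_variant"))
  out <- apply_qc(co)
  expect_identical(nrow(out$sites), 5L)
  expect_identical(ncol(out$geno), 5L)
  # ordering of survivors is preserved
  expect_identical(out$sites$variant_key,
                   co$sites$variant_key[4:8])
})

test_that("missing-AF sites are treated as rare and retained", {
  geno <- matrix(0L, 2, 2)
  co <- make_cohort(geno, status = c("case", "control"), genes = "G1",
                    gnomad_af = c(NA, 0.5))
  out <- apply_qc(co)
  expect_identical(nrow(out$sites), 1L)
  expect_true(is.na(out$sites$gnomad_af))
})

test_that("penetrant filter removes control-carried variants in any zygosity", {
  # sites: 1 case+control shared het, 2 case-only, 3 control-only hom,
  #        4 no carriers at all
  geno <- rbind(c(1L, 1L, 0L, 0L),
                c(0L, 0L, 0L, 0L),
                c(1L, 0L, 2L, 0L))
  co <- make_cohort(geno, status = c("case", "case", "control"),
                    genes = "G1")
  out <- penetrant_model_filter(co)
  expect_identical(out$sites$variant_key, co$sites$variant_key[c(2, 4)])
  log <- out$removal_log
  expect_identical(log$reason[log$variant_key == co$sites$variant_key[1]],
                   "shared_case_control")
  expect_identical(log$reason[log$variant_key == co$sites$variant_key[3]],
                   "control_only")
  expect_identical(log$n_control_carriers, c(1L, 1L))
  # surviving case-carried and control-carried key sets are disjoint
  carrier <- !is.na(out$geno) & out$geno > 0
  is_case <- out$samples$status == "case"
  case_keys <- colnames(out$geno)[colSums(carrier[is_case, , drop = FALSE]) > 0]
  ctrl_keys <- colnames(out$geno)[colSums(carrier[!is_case, , drop = FALSE]) > 0]
  expect_length(intersect(case_keys, ctrl_keys), 0)
  # CAST carrier indicators are unchanged by dropping control-only sites
  keep_shared_removed <- co
  keep <- !(colSums((co$geno > 0)[is_case, , drop = FALSE]) > 0 &
              colSums((co$geno > 0)[!is_case, , drop = FALSE]) > 0)
  keep_shared_removed$sites <- co$sites[keep, ]
  keep_shared_removed$geno <- co$geno[, keep, drop = FALSE]
  ind_a <- carrier_indicator("G1", out$sites, out$geno)
  ind_b <- carrier_indicator("G1", keep_shared_removed$sites,
                             keep_shared_removed$geno)
  expect_identical(ind_a[is_case], ind_b[is_case])
})

test_that("filters are idempotent and order-independent on case-carried sites", {
  set.seed(31)
  cfg <- cohort_config(n_cases = 25, n_controls = 60, n_genes = 10,
                       n_enriched_genes = 2, enriched_case_carrier_count = 4,
                       background_carrier_freq = 0.1,
                       plant_shared_sites = 1, low_depth_prob = 0.05,
                       seed = 31)
  co <- simulate_cohort(cfg)
  once <- apply_qc(co)
  twice <- apply_qc(once)
  expect_identical(once$sites, twice$sites)
  expect_identical(once$geno, twice$geno)
  pf_once <- penetrant_model_filter(once)
  pf_twice <- penetrant_model_filter(pf_once)
  expect_identical(pf_once$sites, pf_twice$sites)

  # qc-then-penetrant equals penetrant-then-qc on the surviving
  # case-carried variant set
  a <- penetrant_model_filter(apply_qc(co))
  b <- apply_qc(penetrant_model_filter(co))
  carried_case_keys <- function(x) {
    carrier <- !is.na(x$geno) & x$geno > 0
    is_case <- x$samples$status == "case"
    sort(colnames(x$geno)[colSums(carrier[is_case, , drop = FALSE]) > 0])
  }
  expect_identical(carried_case_keys(a), carried_case_keys(b))
})

test_that("tightening thresholds never recovers sites", {
  set.seed(13)
  cfg <- cohort_config(n_cases = 20, n_controls = 40, n_genes = 8,
                       background_carrier_freq = 0.1,
                       low_depth_prob = 0.1, seed = 13)
  co <- simulate_cohort(cfg)
  n_lenient <- nrow(apply_qc(co, qc_thresholds(min_depth = 10,
                                               max_maf = 0.05))$sites)
  n_strict <- nrow(apply_qc(co, qc_thresholds(min_depth = 30,
                                              max_maf = 0.0005))$sites)
  expect_lte(n_strict, n_lenient)
})

test_that("gene eligibility uses an inclusive >= 5 distinct-site rule", {
  th <- qc_thresholds()
  sites5 <- data.frame(gene = rep("A", 5),
                       variant_key = paste0("1:", 1:5, ":A:T"))
  sites4 <- data.frame(gene = rep("B", 4),
                       variant_key = paste0("2:", 1:4, ":A:T"))
  expect_identical(eligible_genes(rbind(sites5, sites4), th), "A")
  # duplicated keys do not double-count
  dup <- rbind(sites4, sites4[1, ])
  expect_identical(eligible_genes(dup, th), character(0))
  expect_identical(eligible_genes(sites5[0, ], th), character(0))
})
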