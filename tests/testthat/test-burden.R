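test_that("the CAST indicator collapses presence, not dosage", {
  geno <- rbind(c(1L, 0L, 0L, 0L, 0L),   # het at 1 of 5 sites
                c(0L, 2L, 0L, 0L, 0L),   # hom counts once
                c(0L, 0L, 0L, 0L, 0L),
                c(NA, NA, NA, NA, NA))   # all-missing counts as non-carrier
  co <- make_cohort(geno, status = c("case", "case", "control", "control"),
                    genes = "G1")
  ind <- carrier_indicator("G1", co$sites, co$geno)
  expect_identical(ind, c(1L, 1L, 0L, 0L))
  # duplicating a site column leaves the indicator unchanged
  co2 <- co
  co2$sites <- rbind(co$sites, co$sites[1, ])
  co2$geno <- cbind(co$geno, co$geno[, 1, drop = FALSE])
  expect_identical(carrier_indicator("G1", co2$sites, co2$geno), ind)
  # unknown gene warns and returns zeros
  expect_warning(z <- carrier_indicator("NOPE", co$sites, co$geno),
                 "no surviving sites")
  expect_identical(z, rep(0L, 4))
})

test_that("gene_table builds the case/control carrier table", {
  samples <- data.frame(status = rep(c("case", "control"), c(60, 1246)))
  ind <- rep(c(1L, 0L, 0L), c(6, 54, 1246))
  tab <- gene_table(ind, samples)
  expect_identical(as.vector(tab), c(6L, 0L, 54L, 1246L))
  # complement indicator swaps the columns
  tab2 <- gene_table(1L - ind, samples)
  expect_identical(tab2[, "carrier"], tab[, "non_carrier"])
  # all-zero indicator
  tab3 <- gene_table(rep(0L, 1306), samples)
  expect_identical(as.vector(tab3), c(0L, 0L, 60L, 1246L))
})

test_that("planted genes dominate the burden ranking", {
  cfg <- cohort_config(n_cases = 60, n_controls = 400, n_genes = 20,
                       n_enriched_genes = 3, enriched_case_carrier_count = 6,
                       background_carrier_freq = 0.01, seed = 8)
  co <- apply_qc(simulate_cohort(cfg))
  res <- run_burden(co)
  expect_s3_class(res, "burden_result")
  expect_identical(sort(utils::head(res$gene, 3)), co$truth)
  expect_true(all(res$q_firth[res$gene %in% co$truth] <= 0.005))
  expect_true(all(res$converged))
  # q-values never fall below their p-values
  expect_true(all(res$q_fisher >= res$fisher_p - 1e-15))
  expect_true(all(res$q_firth >= res$firth_p - 1e-15))
  # gene with identical carrier pattern gets identical fisher_p
  expect_identical(res$fisher_p[res$gene == co$truth[1]],
                   res$fisher_p[res$gene == co$truth[2]])
})

test_that("genes with no carriers anywhere get p = 1 from both tests", {
  geno <- matrix(0L, nrow = 30, ncol = 10)
  geno[1, 1] <- 1L  # one case carrier in G1 only
  co <- make_cohort(geno, status = rep(c("case", "control"), c(10, 20)),
                    genes = rep(c("G1", "G2"), each = 5))
  res <- run_burden(co, qc_thresholds(min_lof_variants = 5))
  g2 <- res[res$gene == "G2", ]
  expect_identical(g2$fisher_p, 1)
  expect_identical(g2$firth_p, 1)
})

test_that("fisher and firth rankings agree on strong signals", {
  cfg <- cohort_config(n_cases = 50, n_controls = 300, n_genes = 30,
                       n_enriched_genes = 4, enriched_case_carrier_count = 5,
                       background_carrier_freq = 0.02, seed = 19)
  res <- run_burden(apply_qc(simulate_cohort(cfg)))
  rho <- cor(rank(res$fisher_p), rank(res$firth_p), method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("BH significance matches the direct step-up rejection set", {
  cfg <- cohort_config(n_cases = 40, n_controls = 200, n_genes = 25,
                       n_enriched_genes = 2, enriched_case_carrier_count = 5,
                       background_carrier_freq = 0.03, seed = 4)
  res <- run_burden(apply_qc(simulate_cohort(cfg)), fdr = 0.005)
  alpha <- 0.005
  sp <- sort(res$firth_p)
  k <- max(c(0, which(sp <= alpha * seq_along(sp) / length(sp))))
  direct <- if (k == 0) rep(FALSE, nrow(res)) else res$firth_p <= sp[k]
  expect_identical(res$significant, direct)
})

test_that("null fisher p-values are uniform under label permutation", {
  cfg <- cohort_config(n_cases = 100, n_controls = 400, n_genes = 500,
                       n_enriched_genes = 0, background_carrier_freq = 0.02,
                       seed = 55)
  co <- simulate_cohort(cfg)
  # permute case/control labels jointly with covariates
  set.seed(56)
  perm <- sample(nrow(co$samples))
  co$samples <- co$samples[perm, ]
  co$geno <- co$geno[perm, ]
  res <- run_burden(co, firth = FALSE)
  # discrete p-values are conservative; compare against uniform with a
  # one-sided KS and also check the rejection rate directly
  expect_lte(mean(res$fisher_p <= 0.05), 0.06)
  # "greater" detects an anti-conservative excess of small p-values;
  # discrete exact p-values sit at or below the uniform CDF by design
  ks <- suppressWarnings(ks.test(res$fisher_p, "punif",
                                 alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the pipeline is deterministic and respects eligibility", {
  cfg <- cohort_config(n_cases = 30, n_controls = 100, n_genes = 10,
                       n_enriched_genes = 1, enriched_case_carrier_count = 4,
                       variants_per_gene = c(3L, 8L),
                       background_carrier_freq = 0.05, seed = 12)
  co <- apply_qc(simulate_cohort(cfg))
  res1 <- run_burden(co)
  res2 <- run_burden(co)
  expect_identical(res1, res2)
  n_sites <- table(co$sites$gene)
  expect_setequal(res1$gene, names(n_sites)[n_sites >= 5])
  expect_warning(run_burden(make_cohort(matrix(0L, 4, 2),
                                        status = rep(c("case", "control"), 2),
                                        genes = "G1")),
                 "no genes")
})
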