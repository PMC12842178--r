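#' Per-sample CAST carrier indicator for a gene
#'
#' The CAST (Cohort Allelic Sums Test) statistic collapses a gene to a
#' binary per-sample indicator: 1 if the sample carries at least one
#' qualifying allele (non-missing dosage >= 1) at any of the gene's
#' surviving sites, else 0. Zygosity does not matter -- a homozygote
#' counts once -- and duplicated site columns cannot change the value.
#'
#' @param gene Gene symbol.
#' @param sites Site table restricted by upstream filters.
#' @param geno Dosage matrix (samples x sites), columns named by
#'   `variant_key`.
#' @return Integer 0/1 vector, one element per sample.
#' @export
carrier_indicator <- function(gene, sites, geno) {
  keys <- sites$variant_key[sites$gene == gene]
  if (!length(keys)) {
    warning("gene ", gene, " has no surviving sites; all-zero indicator")
    return(integer(nrow(geno)))
  }
  sub <- geno[, colnames(geno) %in% keys, drop = FALSE]
  as.integer(rowSums(!is.na(sub) & sub > 0L) > 0L)
}

#' Case/control carrier contingency table
#'
#' @param indicator 0/1 carrier vector from [carrier_indicator()].
#' @param samples Sample table aligned with `indicator`.
#' @return 2x2 integer matrix, rows case/control, columns
#'   carrier/non-carrier.
#' @export
gene_table <- function(indicator, samples) {
  stopifnot(length(indicator) == nrow(samples))
  is_case <- samples$status == "case"
  tab <- matrix(c(sum(indicator[is_case] == 1L),
                  sum(indicator[is_case] == 0L),
                  sum(indicator[!is_case] == 1L),
                  sum(indicator[!is_case] == 0L)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("case", "control"),
                                c("carrier", "non_carrier")))
  storage.mode(tab) <- "integer"
  tab
}

#' Per-gene CAST burden analysis
#'
#' For every eligible gene (at least `min_lof_variants` surviving LoF
#' sites) the pipeline computes the CAST carrier indicator, the
#' case/control carrier table with its right-tailed Fisher exact
#' p-value, and a Firth bias-reduced logistic regression of
#' case/control status on the carrier indicator adjusted for sex,
#' standardized age, and family history. The Firth p-value is the
#' penalized likelihood-ratio test of the carrier term (the null model
#' without the carrier indicator is fitted once per cohort); Wald
#' inference supplies the odds ratio and its confidence interval.
#' Likelihood-ratio p-values are the convention for bias-reduced
#' logistic fits because Wald statistics lose power drastically under
#' the near-separation regime a case-only burden gene produces.
#' Benjamini-Hochberg adjustment
#' is applied separately to the Fisher and Firth p-value columns across
#' eligible genes, and a gene is flagged significant when its Firth
#' q-value is at or below `fdr`.
#'
#' Inputs are expected to be already QC-filtered (see [apply_qc()] and,
#' when the fully penetrant disease model is wanted,
#' [penetrant_model_filter()]). Genes with no carriers in either group
#' receive p = 1 from both tests. Degenerate covariate columns are
#' dropped from individual Firth fits automatically.
#'
#' @param cohort An `"ndd_cohort"` (or compatible list).
#' @param thresholds A [qc_thresholds()]; only `min_lof_variants` is
#'   used here.
#' @param fdr Significance threshold on the BH-adjusted q-value
#'   (default 0.005, an FDR of 0.5%; boundary inclusive).
#' @param firth Set `FALSE` to skip the Firth fits (Fisher only), e.g.
#'   for large calibration studies.
#' @return Object of class `c("burden_result", "data.frame")`, one row
#'   per eligible gene, sorted by Firth q-value then gene symbol:
#'   `gene`, carrier/total counts, `fisher_p`, `firth_beta`,
#'   `firth_or`, `ci_low`, `ci_high`, `firth_p`, `q_fisher`, `q_firth`,
#'   `converged`, `significant`.
#' @export
run_burden <- function(cohort, thresholds = qc_thresholds(), fdr = 0.005,
                       firth = TRUE) {
  samples <- cohort$samples
  genes <- eligible_genes(cohort$sites, thresholds)
  if (!length(genes)) {
    warning("no genes with at least ", thresholds$min_lof_variants,
            " surviving LoF sites")
    res <- data.frame(gene = character(0))
    class(res) <- c("burden_result", "data.frame")
    return(res)
  }

  y <- as.integer(samples$status == "case")
  sex <- as.integer(samples$sex == "male")
  age <- samples$age_months
  age <- if (stats::sd(age) > 0) (age - mean(age)) / stats::sd(age)
         else rep(0, length(age))
  famhist <- as.integer(samples$family_history)
  n_case <- sum(y)
  n_ctrl <- sum(1 - y)

  fit_null <- if (firth) {
    x0 <- cbind("(Intercept)" = 1, sex = sex, age = age, famhist = famhist)
    suppressWarnings(fit_firth(x0, y))
  }

  one_gene <- function(g) {
    ind <- carrier_indicator(g, cohort$sites, cohort$geno)
    tab <- gene_table(ind, samples)
    fisher_p <- fisher_exact(tab, tail = "right")
    out <- data.frame(gene = g,
                      n_case_carriers = tab["case", "carrier"],
                      n_case_total = n_case,
                      n_control_carriers = tab["control", "carrier"],
                      n_control_total = n_ctrl,
                      fisher_p = fisher_p,
                      firth_beta = NA_real_, firth_or = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      firth_p = NA_real_, converged = NA,
                      stringsAsFactors = FALSE)
    if (!firth) return(out)
    if (all(ind == 0L)) {           # no carriers anywhere: no information
      out$firth_p <- 1
      out$converged <- TRUE
      return(out)
    }
    x <- cbind("(Intercept)" = 1, carrier = ind, sex = sex,
               age = age, famhist = famhist)
    fit <- suppressWarnings(fit_firth(x, y))
    out$converged <- fit$converged
    if (fit$converged && "carrier" %in% names(fit$coefficients)) {
      wi <- wald_inference(fit)
      row <- wi[wi$term == "carrier", ]
      out$firth_beta <- row$estimate
      out$firth_or <- row$or
      out$ci_low <- row$ci_low
      out$ci_high <- row$ci_high
      # null fit may drop a column the gene fit also dropped; refit the
      # null on the gene's retained covariates if they differ
      null_here <- if (setequal(names(fit_null$coefficients),
                                setdiff(names(fit$coefficients), "carrier")))
        fit_null
      else
        suppressWarnings(fit_firth(
          x[, setdiff(names(fit$coefficients), "carrier"), drop = FALSE], y))
      out$firth_p <- firth_lrt(fit, null_here)$p
    } else if (!"carrier" %in% names(fit$coefficients)) {
      out$firth_p <- 1              # indicator degenerate after cleaning
    }
    out
  }

  res <- do.call(rbind, lapply(genes, one_gene))
  res$q_fisher <- bh_adjust(res$fisher_p)
  if (firth) {
    res$q_firth <- NA_real_
    ok <- !is.na(res$firth_p)       # NA only for non-converged fits
    res$q_firth[ok] <- bh_adjust(res$firth_p[ok])
    res$significant <- !is.na(res$q_firth) & res$q_firth <= fdr
    res <- res[order(res$q_firth, res$gene), , drop = FALSE]
  } else {
    res$q_firth <- NA_real_
    res$significant <- res$q_fisher <= fdr
    res <- res[order(res$q_fisher, res$gene), , drop = FALSE]
  }
  rownames(res) <- NULL
  attr(res, "fdr") <- fdr
  attr(res, "n_case") <- n_case
  attr(res, "n_control") <- n_ctrl
  class(res) <- c("burden_result", "data.frame")
  res
}

#' @export
print.burden_result <- function(x, n = 10L, digits = 3, ...) {
  cat("CAST gene burden results: ", nrow(x), " genes tested (",
      attr(x, "n_case"), " cases / ", attr(x, "n_control"),
      " controls), ", sum(x$significant), " significant at q <= ",
      attr(x, "fdr"), "\n\n", sep = "")
  if (nrow(x)) {
    show <- utils::head(as.data.frame(x)[, c("gene", "n_case_carriers",
                                             "n_control_carriers",
                                             "fisher_p", "firth_or",
                                             "firth_p", "q_fisher",
                                             "q_firth", "significant")], n)
    num <- vapply(show, is.numeric, TRUE)
    show[num] <- lapply(show[num], signif, digits = digits)
    print(show, row.names = FALSE)
    if (nrow(x) > n) cat("... and", nrow(x) - n, "more genes\n")
  }
  invisible(x)
}

#' @export
summary.burden_result <- function(object, ...) {
  sig <- object[object$significant, , drop = FALSE]
  cat("Significant genes (q_firth <= ", attr(object, "fdr"), "): ",
      nrow(sig), " of ", nrow(object), "\n", sep = "")
  if (nrow(sig))
    print(as.data.frame(sig)[, c("gene", "n_case_carriers",
                                 "n_control_carriers", "firth_or",
                                 "q_fisher", "q_firth")],
          row.names = FALSE)
  invisible(sig)
}

#' Write burden results to a TSV with a provenance log
#'
#' @param results A `"burden_result"`.
#' @param path Output TSV path; a companion `<path>.log` records the
#'   FDR threshold, sample counts and package version.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log <- c(paste0("castburden version: ",
                  as.character(utils::packageVersion("castburden"))),
           paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           paste0("fdr: ", attr(results, "fdr")),
           paste0("n_case: ", attr(results, "n_case")),
           paste0("n_control: ", attr(results, "n_control")),
           paste0("n_genes_tested: ", nrow(results)))
  writeLines(log, paste0(path, ".log"))
  invisible(path)
}

#' Read back a burden results TSV
#'
#' @param path TSV written by [write_results()].
#' @return A `"burden_result"` data frame.
#' @export
read_results <- function(path) {
  res <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(res) <- c("burden_result", "data.frame")
  res
}
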