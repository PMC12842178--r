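.ndd_groups <- c("ASD", "ID", "GDD", "SLD")

# accept either a Table-1 style summary (label/value) or a sample sheet
.cohort_counts <- function(cohort) {
  if (all(c("label", "value") %in% names(cohort))) {
    get <- function(lab) {
      v <- cohort$value[cohort$label == lab]
      if (!length(v)) NA_integer_ else as.integer(v[1])
    }
    male <- get("male"); female <- get("female")
    list(n_total = male + female,
         groups = stats::setNames(vapply(.ndd_groups, get, 1L), .ndd_groups),
         male = male, family_history = get("family_history"),
         premature = get("premature_birth"),
         case_ids = NULL)
  } else if (all(c("status", "subgroup") %in% names(cohort))) {
    cases <- cohort[cohort$status == "case", , drop = FALSE]
    list(n_total = nrow(cases),
         groups = stats::setNames(
           vapply(.ndd_groups,
                  function(g) sum(cases$subgroup == g), 1L),
           .ndd_groups),
         male = sum(cases$sex == "male"),
         family_history = sum(cases$family_history),
         premature = NA_integer_,
         case_ids = cases$sample_id)
  } else {
    stop("cohort must be a Table-1 style summary (label/value) ",
         "or a sample sheet (status/subgroup)")
  }
}

#' Diagnostic yield of a clinical exome cohort
#'
#' Counts each case with at least one reported finding as diagnosed
#' (a case with several variant records, e.g. a compound heterozygote,
#' counts once) and computes the overall yield plus per-subgroup
#' yields. Two subgroup conventions are reported: `yield_vs_cohort`
#' divides by the whole cohort size (the convention behind the
#' emulated study's printed subgroup yields) and `yield_within_group`
#' divides by the subgroup size. Percentages are kept at full
#' precision; the print method rounds yields to one decimal.
#'
#' @param findings Findings table with columns `case_id` and
#'   `phenotype` (one row per reported variant).
#' @param cohort Either a Table-1 style demographic summary
#'   (`label`/`value` rows) or a sample sheet with `status` and
#'   `subgroup` columns.
#' @return Object of class `"yield_report"`: list with `n_total`,
#'   `n_diagnosed`, `overall_yield` (percent), `by_group` (data frame
#'   with `group`, `n_patients`, `n_diagnosed`, `yield_vs_cohort`,
#'   `yield_within_group`), and `demographics`
#'   (from [summarize_demographics()]).
#' @examples
#' fx <- load_fixture_tables()
#' compute_yields(fx$findings, fx$cohort_summary)
#' @export
compute_yields <- function(findings, cohort) {
  cc <- .cohort_counts(cohort)
  if (nrow(findings)) {
    if (!all(findings$phenotype %in% .ndd_groups))
      stop("unknown phenotype in findings: ",
           paste(setdiff(findings$phenotype, .ndd_groups), collapse = ", "))
    if (!is.null(cc$case_ids) &&
        !all(findings$case_id %in% cc$case_ids))
      stop("finding with unknown case id: ",
           paste(setdiff(findings$case_id, cc$case_ids), collapse = ", "))
  }
  diagnosed_by_group <- vapply(.ndd_groups, function(g)
    length(unique(findings$case_id[findings$phenotype == g])), 1L)
  n_diagnosed <- length(unique(findings$case_id))

  by_group <- data.frame(
    group = .ndd_groups,
    n_patients = unname(cc$groups),
    n_diagnosed = unname(diagnosed_by_group),
    yield_vs_cohort = 100 * unname(diagnosed_by_group) / cc$n_total,
    yield_within_group = ifelse(cc$groups > 0,
                                100 * unname(diagnosed_by_group) /
                                  unname(cc$groups), 0),
    stringsAsFactors = FALSE)

  structure(list(n_total = cc$n_total,
                 n_diagnosed = n_diagnosed,
                 overall_yield = 100 * n_diagnosed / cc$n_total,
                 by_group = by_group,
                 demographics = summarize_demographics(cohort)),
            class = "yield_report")
}

#' @export
print.yield_report <- function(x, ...) {
  cat("Diagnostic yield report\n")
  cat(sprintf("  overall: %.1f%% (%d/%d)\n", round(x$overall_yield, 1),
              x$n_diagnosed, x$n_total))
  tab <- x$by_group
  tab$yield_vs_cohort <- round(tab$yield_vs_cohort, 1)
  tab$yield_within_group <- round(tab$yield_within_group, 1)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Pairwise Fisher tests of diagnostic yield between NDD subgroups
#'
#' For every unordered pair of non-empty subgroups, builds the 2x2
#' table of diagnosed versus undiagnosed patients within each group
#' and computes the two-sided Fisher exact p-value. With
#' `pool_id_gdd = TRUE`, a pooled "ID/GDD" group is additionally
#' compared against the remaining groups (intellectual disability and
#' global developmental delay overlap clinically and are often pooled).
#'
#' @param report A [compute_yields()] result.
#' @param pool_id_gdd Also compare a pooled ID+GDD group against ASD
#'   and SLD.
#' @return Data frame: `group_a`, `group_b`, diagnosed/undiagnosed
#'   counts `a`, `b` (group A) and `c`, `d` (group B), and
#'   `p_two_sided`. Pairs involving an empty group are skipped with a
#'   warning.
#' @export
pairwise_yield_tests <- function(report, pool_id_gdd = FALSE) {
  stopifnot(inherits(report, "yield_report"))
  tab <- report$by_group
  empty <- tab$group[tab$n_patients == 0]
  if (length(empty))
    warning("skipping empty group(s): ", paste(empty, collapse = ", "))
  tab <- tab[tab$n_patients > 0, , drop = FALSE]
  groups <- data.frame(group = tab$group, n = tab$n_patients,
                       k = tab$n_diagnosed, stringsAsFactors = FALSE)
  if (nrow(groups) < 2L) stop("need at least two non-empty groups")
  pairs <- utils::combn(nrow(groups), 2L)
  if (pool_id_gdd && all(c("ID", "GDD") %in% groups$group)) {
    # pooled ID/GDD group compared against the groups outside the pool
    idx <- groups$group %in% c("ID", "GDD")
    pooled <- data.frame(group = "ID/GDD", n = sum(groups$n[idx]),
                         k = sum(groups$k[idx]), stringsAsFactors = FALSE)
    outside <- which(!idx)
    groups <- rbind(groups, pooled)
    pairs <- cbind(pairs, rbind(nrow(groups), outside))
  }
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    ga <- groups[pairs[1, j], ]
    gb <- groups[pairs[2, j], ]
    p <- fisher_exact(ga$k, ga$n - ga$k, gb$k, gb$n - gb$k,
                      tail = "two.sided")
    data.frame(group_a = ga$group, group_b = gb$group,
               a = ga$k, b = ga$n - ga$k, c = gb$k, d = gb$n - gb$k,
               p_two_sided = p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cohort demographic percentages
#'
#' Percentages over the cohort size, rounded to integers in the style
#' of a clinical cohort description table (counts are kept alongside,
#' so full precision is recoverable).
#'
#' @param cohort Table-1 style summary (`label`/`value`) or a sample
#'   sheet (see [compute_yields()]).
#' @return Data frame with `metric`, `count`, `percent` rows for male
#'   sex, positive family history, premature birth (NA when the input
#'   carries no birth data), and the NDD subgroup shares.
#' @examples
#' summarize_demographics(load_fixture_tables()$cohort_summary)
#' @export
summarize_demographics <- function(cohort) {
  cc <- .cohort_counts(cohort)
  counts <- c(male = cc$male, family_history = cc$family_history,
              premature_birth = cc$premature, cc$groups)
  data.frame(metric = names(counts),
             count = unname(counts),
             percent = round(100 * unname(counts) / cc$n_total),
             row.names = NULL, stringsAsFactors = FALSE)
}
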