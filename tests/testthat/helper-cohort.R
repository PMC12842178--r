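# Hand-buildable toy cohort for filter and burden tests.
# geno: samples x sites dosage matrix (NA = missing call).
make_cohort <- function(geno, status, genes, depth = 100L,
                        gnomad_af = NULL, consequence = "stop_gained") {
  n <- nrow(geno); m <- ncol(geno)
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    status = status,
    sex = rep(c("male", "female"), length.out = n),
    age_months = seq(10, 10 + 2 * (n - 1), by = 2),
    family_history = rep(c(TRUE, FALSE, FALSE, FALSE), length.out = n),
    subgroup = ifelse(status == "case", "ID", "none"),
    stringsAsFactors = FALSE)
  sites <- data.frame(
    chrom = rep("1", m), pos = seq_len(m) * 100L,
    ref = rep("A", m), alt = rep("T", m),
    gene = rep(genes, length.out = m),
    consequence = rep(consequence, length.out = m),
    gnomad_af = if (is.null(gnomad_af)) rep(1e-4, m) else gnomad_af,
    stringsAsFactors = FALSE)
  sites$variant_key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt,
                             sep = ":")
  dimnames(geno) <- list(samples$sample_id, sites$variant_key)
  depth_m <- matrix(depth, n, m, dimnames = dimnames(geno))
  structure(list(samples = samples, sites = sites,
                 geno = geno, depth = depth_m),
            class = "ndd_cohort")
}
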