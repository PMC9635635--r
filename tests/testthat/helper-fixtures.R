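# Shared fixture builders: everything is generated in code at test time.

# Call matrix from a named list of per-marker call vectors.
toy_geno <- function(calls, samples = NULL) {
  n <- length(calls[[1]])
  samples <- samples %||% sprintf("s%d", seq_len(n))
  geno <- do.call(cbind, calls)
  dimnames(geno) <- list(samples, names(calls))
  geno
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Annotation tibble for markers on one chromosome at the given cM positions.
toy_ann <- function(markers, chr = "1", cM = seq_along(markers)) {
  tibble::tibble(marker = markers, chr = chr, pos_bp = cM * 2e6,
                 pos_cM = cM, unmappable = FALSE)
}

# Parental-allele tibble.
toy_parents <- function(markers, p1, p2) {
  tibble::tibble(marker = markers, p1 = p1, p2 = p2)
}

# Marker table straight from per-marker calls + parents.
toy_table <- function(calls, p1, p2, ann = NULL) {
  geno <- toy_geno(calls)
  ann <- ann %||% toy_ann(names(calls))
  build_marker_table(geno, ann, toy_parents(names(calls), p1, p2))
}

# Long-format genotype file content for read_genotype_long tests.
write_toy_long <- function(rows, path,
                           header = c("Sample ID", "SNP Name",
                                      "Allele1 - Forward", "Allele2 - Forward")) {
  lines <- c(paste(header, collapse = ","),
             vapply(rows, paste, character(1), collapse = ","))
  writeLines(lines, path)
  path
}

# Multinomial two-locus F2 table at recombination fraction r.
random_f2_table <- function(r, n) {
  probs <- as.vector(t(crossqc::f2_class_probs(r)))
  matrix(rmultinom(1, n, probs), nrow = 3, byrow = TRUE,
         dimnames = list(c("A", "H", "B"), c("A", "H", "B")))
}

# Independent brute-force oracle: maximum-likelihood r over a grid spanning
# both phases, folded to [0, 0.5] like the estimator under test.
grid_mle_r <- function(counts, step = 1e-4) {
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(g) crossqc::rf_f2_loglik(counts, g), numeric(1))
  best <- grid[which.max(ll)]
  min(best, 1 - best)
}

# Simulated cross + consensus parental alleles, ready for the pipeline.
sim_with_parents <- function(config) {
  sim <- simulate_cross(config)
  cons <- consensus_strains(sim$parents, sim$strain_of)
  list(sim = sim, parents = parental_alleles(cons, "P1", "P2"))
}
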