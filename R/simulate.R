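#' Build a regular synthetic marker map
#'
#' Evenly spaced markers on autosome-like chromosomes, as a stand-in for an
#' array annotation. Physical positions are filled at 2 Mb per cM
#' (informational only).
#'
#' @param n_chr Number of chromosomes (named `"1"`, `"2"`, ...).
#' @param n_markers Markers per chromosome.
#' @param spacing_cM Distance between adjacent markers in cM.
#' @return Annotation tibble as from [read_annotation()].
#' @export
sim_map <- function(n_chr = 19, n_markers = 60, spacing_cM = 1.5) {
  stopifnot(n_chr >= 1, n_markers >= 1, spacing_cM >= 0)
  chr <- rep(as.character(seq_len(n_chr)), each = n_markers)
  pos <- rep(seq_len(n_markers) - 1, times = n_chr) * spacing_cM
  tibble(marker = sprintf("c%02d_m%04d", rep(seq_len(n_chr), each = n_markers),
                          rep(seq_len(n_markers), times = n_chr)),
         chr = chr, pos_bp = pos * 2e6, pos_cM = pos, unmappable = FALSE)
}

#' Simulation configuration
#'
#' The defaults reproduce the conditions of a typical MiniMUGA-genotyped
#' mouse intercross: 176 individuals, a genotyping call rate of about 0.93
#' (`missing_rate = 0.073`), fully inbred (homozygous) parents, and a map of
#' evenly spaced autosomal markers.
#'
#' @param cross A [cross_type()].
#' @param n_individuals Number of second-generation individuals.
#' @param map Annotation tibble (sorted per chromosome by cM), e.g. from
#'   [sim_map()].
#' @param missing_rate Per-call probability of a no-call.
#' @param error_spec Named list/vector of marker counts per injected error
#'   class (see [inject_errors()]), or `NULL` for a clean cross.
#' @param parent_het_rate Per-marker probability that a parental call is
#'   residually heterozygous (`H`).
#' @param n_parent_replicates Genotyped samples per parental strain.
#' @param qtl Optional `list(marker =, effect =)` adding an additive effect
#'   to the simulated phenotype at one marker.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(cross = cross_type("F2"), n_individuals = 176,
                       map = sim_map(), missing_rate = 0.073,
                       error_spec = NULL, parent_het_rate = 0,
                       n_parent_replicates = 1, qtl = NULL, seed = 1) {
  stopifnot(inherits(cross, "cross_type"), n_individuals >= 1,
            missing_rate >= 0, missing_rate <= 1,
            parent_het_rate >= 0, parent_het_rate <= 1,
            n_parent_replicates >= 1)
  for (chr in unique(map$chr)) {
    if (is.unsorted(map$pos_cM[map$chr == chr])) {
      stop("sim_config: map must be sorted by cM within each chromosome",
           call. = FALSE)
    }
  }
  structure(list(cross = cross, n_individuals = n_individuals, map = map,
                 missing_rate = missing_rate, error_spec = error_spec,
                 parent_het_rate = parent_het_rate,
                 n_parent_replicates = n_parent_replicates,
                 qtl = qtl, seed = seed),
            class = "sim_config")
}

# One set of gametes: n x m 0/1 matrix (0 = parent-1 origin), Markov along
# each chromosome with crossover probability r between adjacent markers.
sim_gametes <- function(n, map) {
  m <- nrow(map)
  g <- matrix(0L, nrow = n, ncol = m)
  col <- 0
  for (chr in unique(map$chr)) {
    pos <- map$pos_cM[map$chr == chr]
    k <- length(pos)
    g[, col + 1] <- rbinom(n, 1, 0.5)
    if (k > 1) {
      r <- haldane_inv(diff(pos))
      for (j in seq_len(k - 1)) {
        flip <- rbinom(n, 1, r[j])
        g[, col + j + 1] <- (g[, col + j] + flip) %% 2L
      }
    }
    col <- col + k
  }
  g
}

#' Simulate a two-generation cross
#'
#' Simulates meiosis as a Markov chain along each chromosome: a crossover
#' occurs between adjacent markers with the probability given by the inverse
#' Haldane transform of their known cM spacing (no interference). An F2
#' individual receives two independent recombinant gametes; an N2 individual
#' receives one recombinant gamete plus a non-recombinant gamete from the
#' recurrent parent. Each marker is assigned two distinct random parental
#' bases, genotypes are emitted as single-letter allele calls with no-calls
#' at `missing_rate`, and the phenotype is standard normal noise (plus an
#' optional additive marker effect). When `config$error_spec` is set,
#' [inject_errors()] is applied before returning.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cross` with elements `geno` (offspring call
#'   matrix), `parents` (parental call matrix, one or more replicate rows
#'   per strain), `strain_of` (named vector mapping parental sample ->
#'   strain), `pheno` (tibble `id`, `pheno`), `truth` (list: `labels` tibble
#'   of marker/class, `geno` true code matrix), `map`, `config`.
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  map <- config$map
  n <- config$n_individuals
  m <- nrow(map)

  p1_base <- character(m)
  p2_base <- character(m)
  for (i in seq_len(m)) {
    pair <- sample(ALLELE_BASES, 2)
    p1_base[i] <- pair[1]; p2_base[i] <- pair[2]
  }

  gam1 <- sim_gametes(n, map)
  if (config$cross$kind == "F2") {
    gam2 <- sim_gametes(n, map)
  } else {
    gam2 <- matrix(if (config$cross$recurrent == "p1") 0L else 1L,
                   nrow = n, ncol = m)
  }
  dosage <- gam1 + gam2  # copies of the parent-2 allele: 0, 1, 2

  codes <- matrix(c("A", "H", "B")[dosage + 1L], nrow = n, ncol = m)
  ids <- sprintf("ind%04d", seq_len(n))
  dimnames(codes) <- list(ids, map$marker)

  calls <- codes
  p1m <- matrix(p1_base, nrow = n, ncol = m, byrow = TRUE)
  p2m <- matrix(p2_base, nrow = n, ncol = m, byrow = TRUE)
  calls[codes == "A"] <- p1m[codes == "A"]
  calls[codes == "B"] <- p2m[codes == "B"]
  calls[matrix(runif(n * m) < config$missing_rate, n, m)] <- "N"

  reps <- config$n_parent_replicates
  parent_rows <- c(sprintf("P1_rep%d", seq_len(reps)),
                   sprintf("P2_rep%d", seq_len(reps)))
  parents <- rbind(matrix(p1_base, nrow = reps, ncol = m, byrow = TRUE),
                   matrix(p2_base, nrow = reps, ncol = m, byrow = TRUE))
  dimnames(parents) <- list(parent_rows, map$marker)
  if (config$parent_het_rate > 0) {
    parents[matrix(runif(length(parents)) < config$parent_het_rate,
                   nrow(parents), m)] <- "H"
  }
  strain_of <- setNames(rep(c("P1", "P2"), each = reps), parent_rows)

  pheno <- tibble(id = ids, pheno = rnorm(n))
  if (!is.null(config$qtl)) {
    j <- match(config$qtl$marker, map$marker)
    if (is.na(j)) stop("simulate_cross: qtl marker not in map", call. = FALSE)
    pheno$pheno <- pheno$pheno + config$qtl$effect * (dosage[, j] - 1)
  }

  sim <- structure(list(geno = calls, parents = parents,
                        strain_of = strain_of, pheno = pheno,
                        truth = list(labels = tibble(marker = map$marker,
                                                     class = "clean"),
                                     geno = codes,
                                     parent_bases = tibble(marker = map$marker,
                                                           p1 = p1_base,
                                                           p2 = p2_base)),
                        map = map, config = config),
                   class = "sim_cross")
  if (!is.null(config$error_spec)) sim <- inject_errors(sim, config$error_spec)
  sim
}

ERROR_CLASSES <- c("random_call", "parent_mismatch",
                   "parent_monomorphic_sgipoly", "nonpolymorphic",
                   "high_missing")

#' Inject genotyping-error classes into a simulated cross
#'
#' Transforms randomly chosen clean markers into the error patterns the
#' curation cascade must detect:
#' * `random_call` — every offspring call redrawn uniformly from the two
#'   parental homozygotes and the heterozygote (a defective assay whose
#'   output is independent of the true genotype);
#' * `parent_mismatch` — parental alleles replaced by the two bases *not*
#'   segregating in the offspring (parents disagreeing with their reference
#'   counterparts);
#' * `parent_monomorphic_sgipoly` — both parental calls set to the same base
#'   while the offspring stay polymorphic;
#' * `nonpolymorphic` — all non-missing offspring calls set to the first
#'   parent's base;
#' * `high_missing` — each offspring call replaced by a no-call with
#'   probability 0.6, pushing the missing fraction past the default
#'   threshold.
#'
#' Uses the current RNG state (call [set.seed()] first when invoking it
#' outside [simulate_cross()], which seeds everything from `config$seed`).
#'
#' @param sim A `sim_cross` from [simulate_cross()].
#' @param error_spec Named vector/list giving the number of markers per
#'   class; names among `random_call`, `parent_mismatch`,
#'   `parent_monomorphic_sgipoly`, `nonpolymorphic`, `high_missing`.
#' @return The modified `sim_cross` with updated truth labels.
#' @export
inject_errors <- function(sim, error_spec) {
  stopifnot(inherits(sim, "sim_cross"))
  spec <- unlist(error_spec)
  unknown <- setdiff(names(spec), ERROR_CLASSES)
  if (length(unknown) > 0) {
    stop(sprintf("inject_errors: unknown error class(es): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  clean <- sim$truth$labels$marker[sim$truth$labels$class == "clean"]
  if (sum(spec) > length(clean)) {
    stop("inject_errors: more error markers requested than clean markers available",
         call. = FALSE)
  }
  chosen <- sample(clean, sum(spec))
  assign_class <- rep(names(spec), times = spec)
  n <- nrow(sim$geno)

  for (k in seq_along(chosen)) {
    mkr <- chosen[k]
    cls <- assign_class[k]
    p1 <- sim$parents[sim$strain_of == "P1", mkr][1]
    p2 <- sim$parents[sim$strain_of == "P2", mkr][1]
    switch(cls,
      random_call = {
        sim$geno[, mkr] <- sample(c(p1, p2, "H"), n, replace = TRUE)
      },
      parent_mismatch = {
        foreign <- setdiff(ALLELE_BASES, c(p1, p2))
        sim$parents[sim$strain_of == "P1", mkr] <- foreign[1]
        sim$parents[sim$strain_of == "P2", mkr] <- foreign[2]
      },
      parent_monomorphic_sgipoly = {
        sim$parents[, mkr] <- p1
      },
      nonpolymorphic = {
        keep_na <- sim$geno[, mkr] == "N"
        sim$geno[!keep_na, mkr] <- p1
      },
      high_missing = {
        sim$geno[runif(n) < 0.6, mkr] <- "N"
      })
    sim$truth$labels$class[sim$truth$labels$marker == mkr] <- cls
  }
  sim
}

#' Write a simulated cross in the external input formats
#'
#' Emits exactly the files the readers in this package consume, so the
#' simulator can exercise the real parsers end to end: a long-format
#' genotype CSV for the offspring and one for the parental samples, an
#' annotation CSV, a phenotype CSV, and a truth TSV with the per-marker
#' class labels.
#'
#' @param sim A `sim_cross`.
#' @param prefix Output path prefix; files are written as
#'   `<prefix>.geno.csv`, `.parents.csv`, `.annot.csv`, `.pheno.csv`,
#'   `.truth.tsv`.
#' @param dialect Genotype-file dialect used for the long-format outputs.
#' @return Named character vector of the paths written.
#' @export
write_sim <- function(sim, prefix, dialect = geno_dialect()) {
  paths <- c(geno = paste0(prefix, ".geno.csv"),
             parents = paste0(prefix, ".parents.csv"),
             annot = paste0(prefix, ".annot.csv"),
             pheno = paste0(prefix, ".pheno.csv"),
             truth = paste0(prefix, ".truth.tsv"))
  pb <- sim$truth$parent_bases
  pairs <- setNames(paste0(pmin(pb$p1, pb$p2), pmax(pb$p1, pb$p2)), pb$marker)
  write_genotype_long(sim$geno, paths["geno"], dialect, het_pairs = pairs)
  write_genotype_long(sim$parents, paths["parents"], dialect, het_pairs = pairs)
  readr::write_csv(tibble(marker = sim$map$marker, chr = sim$map$chr,
                          bp_mm10 = sim$map$pos_bp, cM_cox = sim$map$pos_cM),
                   paths["annot"], progress = FALSE)
  readr::write_csv(sim$pheno, paths["pheno"], progress = FALSE)
  readr::write_tsv(sim$truth$labels, paths["truth"], progress = FALSE)
  invisible(paths)
}
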