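#' Filter configuration
#'
#' Collects every tunable threshold of the curation cascade with the
#' defaults used throughout: markers are dropped when *more than* half the
#' genotypes are missing (`na_max = 0.5`, strict `>`), and in proportion mode
#' when the proportion of any genotype class falls strictly *below* 10%.
#'
#' @param na_max Maximum tolerated fraction of missing genotypes (strict
#'   `>` fails).
#' @param prop_mode `"proportion"` (minimum class proportions) or `"chi2"`
#'   (chi-square goodness-of-fit against Mendelian expectations).
#' @param prop_min_homo,prop_min_het Minimum class proportions on autosomes
#'   (proportion mode).
#' @param chi2_alpha Significance level for chi-square mode.
#' @param parNH_strict If `TRUE`, exclude markers with one missing or any
#'   heterozygous parental call instead of imputing the missing allele.
#' @param x_prop_min Minimum proportion applied to the two homozygote classes
#'   only on the X chromosome (hemizygous males are read as homozygotes, so
#'   the heterozygote class is not informative without sex metadata).
#' @param bypass_chromosomes Chromosomes exempt from the proportion filter
#'   (Y and mitochondria are effectively haploid/uniparental).
#' @param wrong_homo_tol Backcrosses: number of tolerated homozygotes for the
#'   non-recurrent allele before the allele filter fails the marker.
#' @param estmap_threshold Map-sanity filter: a marker fails when its
#'   estimated Haldane distance to every adjacent retained marker exceeds
#'   this many cM.
#' @param run_estmap Whether [run_pipeline()] runs the map-sanity step.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(na_max = 0.5,
                          prop_mode = c("proportion", "chi2"),
                          prop_min_homo = 0.10,
                          prop_min_het = 0.10,
                          chi2_alpha = 0.05,
                          parNH_strict = FALSE,
                          x_prop_min = 0.10,
                          bypass_chromosomes = c("Y", "M", "MT"),
                          wrong_homo_tol = 0,
                          estmap_threshold = 100,
                          run_estmap = TRUE) {
  prop_mode <- match.arg(prop_mode)
  stopifnot(na_max >= 0, na_max <= 1, prop_min_homo >= 0, prop_min_homo <= 1,
            prop_min_het >= 0, prop_min_het <= 1, chi2_alpha > 0,
            chi2_alpha < 1, x_prop_min >= 0, x_prop_min <= 1,
            wrong_homo_tol >= 0, estmap_threshold > 0)
  structure(list(na_max = na_max, prop_mode = prop_mode,
                 prop_min_homo = prop_min_homo, prop_min_het = prop_min_het,
                 chi2_alpha = chi2_alpha, parNH_strict = isTRUE(parNH_strict),
                 x_prop_min = x_prop_min,
                 bypass_chromosomes = bypass_chromosomes,
                 wrong_homo_tol = wrong_homo_tol,
                 estmap_threshold = estmap_threshold,
                 run_estmap = isTRUE(run_estmap)),
            class = "filter_config")
}

#' Read a filter configuration from YAML
#'
#' Any subset of the [filter_config()] fields may appear in the file;
#' unspecified fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `filter_config`.
#' @export
filter_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(filter_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop(sprintf("config: unknown field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(filter_config, vals)
}

#' Consensus genotype per strain from replicate samples
#'
#' Parental strains are usually genotyped in replicate. Per strain and
#' marker, unanimous non-missing calls give the consensus call; any
#' disagreement among non-missing calls gives `N` (conservative: no majority
#' vote), as does all-missing.
#'
#' @param geno Call matrix containing the parental samples.
#' @param strain_of Named character vector mapping sample id -> strain name.
#'   Every name must be a row of `geno`.
#' @return A strains x markers call matrix with a logical `conflict`
#'   attribute of the same shape marking disagreements.
#' @export
consensus_strains <- function(geno, strain_of) {
  unknown <- setdiff(names(strain_of), rownames(geno))
  if (length(unknown) > 0) {
    stop(sprintf("consensus_strains: sample(s) not in genotype data: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  strains <- unique(strain_of)
  cons <- matrix("N", nrow = length(strains), ncol = ncol(geno),
                 dimnames = list(strains, colnames(geno)))
  conflict <- matrix(FALSE, nrow = length(strains), ncol = ncol(geno),
                     dimnames = dimnames(cons))
  for (s in strains) {
    sub <- geno[names(strain_of)[strain_of == s], , drop = FALSE]
    for (j in seq_len(ncol(sub))) {
      calls <- unique(sub[, j])
      calls <- calls[calls != "N"]
      if (length(calls) == 1) {
        cons[s, j] <- calls
      } else if (length(calls) > 1) {
        conflict[s, j] <- TRUE  # consensus stays N
      }
    }
  }
  attr(cons, "conflict") <- conflict
  cons
}

#' Extract parental alleles for a pair of strains
#'
#' @param consensus Strain x marker matrix from [consensus_strains()] (or any
#'   call matrix with one row per strain).
#' @param p1,p2 Strain (row) names of the two parents of the cross.
#' @return Tibble with columns `marker`, `p1`, `p2` suitable for
#'   [build_marker_table()].
#' @export
parental_alleles <- function(consensus, p1, p2) {
  if (!all(c(p1, p2) %in% rownames(consensus))) {
    stop("parental_alleles: strain not found in consensus matrix", call. = FALSE)
  }
  tibble(marker = colnames(consensus),
         p1 = unname(consensus[p1, ]), p2 = unname(consensus[p2, ]))
}

#' Filter: marker present in both parents and offspring
#'
#' Fails markers absent from the parental genotype data, absent from the
#' offspring data, or unmappable (missing chromosome/cM annotation). Arrays
#' come in several versions with partially overlapping marker sets, so
#' parent and offspring data genotyped on different versions must be reduced
#' to their common markers.
#'
#' @param table Marker table.
#' @param parent_marker_ids Character vector of markers genotyped in the
#'   parents.
#' @return The table with the `match` flag set.
#' @export
mark_match <- function(table, parent_marker_ids) {
  fail <- !(table$marker %in% parent_marker_ids) | !table$in_sgi |
    table$unmappable
  reason <- ifelse(table$unmappable, "match:unmappable", "match:not_shared")
  set_flag(table, "match", fail, reason)
}

#' Filter: allele consistency between parents and offspring
#'
#' Applies the allele-consistency rules: (i) both parental alleles missing;
#' (ii) parents share one allele while the offspring are polymorphic (a
#' heterozygous offspring call counts as evidence of a second allele);
#' (iii) any offspring homozygote for a base carried by neither parent;
#' (iv) backcrosses only: homozygotes for the non-recurrent parent's allele
#' beyond `wrong_homo_tol`; (v) only with `parNH_strict`: one parental allele
#' missing or either parent heterozygous.
#'
#' Without `parNH_strict`, a single missing parental allele is imputed as the
#' unique other base observed among homozygous offspring (recorded with
#' source `"imputed"`); two or more candidate bases make the imputation
#' ambiguous and fail the marker.
#'
#' @param table Marker table with parental alleles attached.
#' @param cross A [cross_type()].
#' @param config A [filter_config()].
#' @return The table with the `allele` flag set and imputations applied.
#' @export
mark_allele <- function(table, cross, config = filter_config()) {
  stopifnot(inherits(cross, "cross_type"))
  known1 <- is_base(table$p1)
  known2 <- is_base(table$p2)

  fail <- rep(FALSE, nrow(table))
  reason <- rep(NA_character_, nrow(table))
  hit <- function(cond, why) {
    new <- cond & !fail
    reason[new] <<- why
    fail[new] <<- TRUE
  }

  # (i) no parental information at all
  hit(!known1 & !known2, "allele:parents_missing")

  # (v) strict mode: refuse het parents and anything not directly observed,
  # including alleles imputed by an earlier non-strict run (provenance kept
  # in p1_source/p2_source)
  if (config$parNH_strict) {
    hit(table$p1_source != "observed" | table$p2_source != "observed",
        "allele:parent_NH")
  }

  # offspring polymorphism evidence (distinct homozygous bases; het adds one)
  bases <- cbind(A = table$n_A, C = table$n_C, G = table$n_G, T = table$n_T)
  n_bases <- rowSums(bases > 0)

  # (ii) parents monomorphic, offspring polymorphic
  hit(known1 & known2 & table$p1 == table$p2 &
        (n_bases >= 2 | table$n_het > 0),
      "allele:parents_monomorphic")

  # impute the single missing parental allele from homozygous offspring calls
  if (!config$parNH_strict) {
    one_missing <- xor(known1, known2) & !fail
    for (i in which(one_missing)) {
      known <- if (known1[i]) table$p1[i] else table$p2[i]
      extra <- ALLELE_BASES[bases[i, ] > 0]
      extra <- setdiff(extra, known)
      if (length(extra) == 1) {
        if (known1[i]) {
          table$p2[i] <- extra; table$p2_source[i] <- "imputed"
        } else {
          table$p1[i] <- extra; table$p1_source[i] <- "imputed"
        }
      } else if (length(extra) >= 2) {
        reason[i] <- "allele:ambiguous_imputation"
        fail[i] <- TRUE
      }  # zero extra bases: nothing to impute, leave unknown
    }
  }
  table <- update_class_counts(table)

  # (iii) offspring homozygous for a base carried by neither parent
  hit(!is.na(table$n_other) & table$n_other > 0, "allele:foreign_allele")

  # (iv) backcross: homozygotes for the wrong (non-recurrent) allele
  if (cross$kind == "N2") {
    wrong <- if (cross$recurrent == "p1") table$n_p2p2 else table$n_p1p1
    hit(!is.na(wrong) & wrong > config$wrong_homo_tol,
        "allele:wrong_homozygote")
  }

  set_flag(table, "allele", fail, reason)
}

#' Filter: missing genotypes
#'
#' Fails markers whose fraction of missing offspring genotypes strictly
#' exceeds `na_max` (default: more than 50% missing).
#'
#' @inheritParams mark_allele
#' @return The table with the `na` flag set.
#' @export
mark_na <- function(table, config = filter_config()) {
  no_data <- table$n_total == 0
  fail <- no_data | (table$n_missing / pmax(table$n_total, 1) > config$na_max)
  reason <- ifelse(no_data, "na:no_data", "na:missing_above_threshold")
  set_flag(table, "na", fail, reason)
}

#' Filter: nonpolymorphic markers
#'
#' Fails markers at which all successfully genotyped offspring carry the same
#' call. Crosses between two inbred strains are expected to be monomorphic at
#' the majority of array markers, so this filter removes most markers. A
#' marker whose non-missing calls are all heterozygous carries no segregation
#' information either and also fails.
#'
#' @param table Marker table.
#' @return The table with the `poly` flag set.
#' @export
mark_poly <- function(table) {
  bases <- cbind(table$n_A, table$n_C, table$n_G, table$n_T)
  n_symbols <- rowSums(bases > 0) + (table$n_het > 0)
  no_data <- table$n_missing >= table$n_total
  fail <- no_data | n_symbols <= 1
  reason <- ifelse(no_data, "poly:no_data", "poly:monomorphic")
  set_flag(table, "poly", fail, reason)
}

#' Chi-square test of Mendelian segregation at one marker
#'
#' Goodness-of-fit of the observed genotype-class counts against the
#' Mendelian expectation: 1:2:1 (P1 homozygote : heterozygote : P2
#' homozygote) for an F2 autosome, 1:1 (recurrent homozygote : heterozygote)
#' for a backcross.
#'
#' @param counts Named vector or list with `n_p1p1`, `n_het`, `n_p2p2`.
#' @param cross A [cross_type()].
#' @return A list with `statistic`, `p_value`, `dof` and `expected` (the
#'   class proportions tested).
#' @export
#' @examples
#' mendelian_chi2(c(n_p1p1 = 40, n_het = 40, n_p2p2 = 20), cross_type("F2"))
mendelian_chi2 <- function(counts, cross) {
  stopifnot(inherits(cross, "cross_type"))
  counts <- as.list(counts)
  if (cross$kind == "F2") {
    obs <- c(counts$n_p1p1, counts$n_het, counts$n_p2p2)
    expected <- c(0.25, 0.5, 0.25)
  } else {
    homo <- if (cross$recurrent == "p1") counts$n_p1p1 else counts$n_p2p2
    obs <- c(homo, counts$n_het)
    expected <- c(0.5, 0.5)
  }
  n <- sum(obs)
  if (is.na(n) || n == 0) {
    stop("mendelian_chi2: no informative individuals", call. = FALSE)
  }
  exp_n <- n * expected
  statistic <- sum((obs - exp_n)^2 / exp_n)
  dof <- length(obs) - 1L
  list(statistic = statistic,
       p_value = pchisq(statistic, df = dof, lower.tail = FALSE),
       dof = dof, expected = expected)
}

#' Filter: Mendelian genotype proportions
#'
#' Autosomes, proportion mode: a marker fails when the proportion of any
#' genotype class among informative individuals falls strictly below the
#' configured minimum (F2: both homozygote classes and the heterozygote
#' class; N2: recurrent homozygote and heterozygote classes). Chi-square
#' mode: fails when [mendelian_chi2()]'s p-value is below `chi2_alpha`.
#' X chromosome: only the two homozygote classes are tested, against
#' `x_prop_min`, in either mode. Chromosomes in `bypass_chromosomes`
#' (default Y and mitochondria) pass untested.
#'
#' @inheritParams mark_allele
#' @return The table with the `prop` flag set.
#' @export
mark_prop <- function(table, cross, config = filter_config()) {
  stopifnot(inherits(cross, "cross_type"))
  n <- nrow(table)
  fail <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  bypass <- table$chr %in% config$bypass_chromosomes
  on_x <- table$chr == "X"

  homo1 <- table$n_p1p1
  homo2 <- table$n_p2p2
  het <- table$n_het
  if (cross$kind == "N2") {
    # only the recurrent homozygote class exists legitimately
    homo_rec <- if (cross$recurrent == "p1") homo1 else homo2
    n_inf <- homo_rec + het
  } else {
    n_inf <- homo1 + het + homo2
  }

  testable <- !bypass & !is.na(n_inf)
  none <- testable & n_inf == 0
  fail[none] <- TRUE
  reason[none] <- "prop:no_data"

  idx <- which(testable & n_inf > 0)
  for (i in idx) {
    if (on_x[i]) {
      # homozygote classes only
      if (cross$kind == "F2") {
        p_h1 <- homo1[i] / n_inf[i]; p_h2 <- homo2[i] / n_inf[i]
        bad <- p_h1 < config$x_prop_min || p_h2 < config$x_prop_min
      } else {
        homo_rec <- if (cross$recurrent == "p1") homo1[i] else homo2[i]
        bad <- homo_rec / n_inf[i] < config$x_prop_min
      }
      if (bad) { fail[i] <- TRUE; reason[i] <- "prop:x_homozygote_deficit" }
    } else if (config$prop_mode == "proportion") {
      if (cross$kind == "F2") {
        bad <- homo1[i] / n_inf[i] < config$prop_min_homo ||
          homo2[i] / n_inf[i] < config$prop_min_homo ||
          het[i] / n_inf[i] < config$prop_min_het
      } else {
        homo_rec <- if (cross$recurrent == "p1") homo1[i] else homo2[i]
        bad <- homo_rec / n_inf[i] < config$prop_min_homo ||
          het[i] / n_inf[i] < config$prop_min_het
      }
      if (bad) { fail[i] <- TRUE; reason[i] <- "prop:class_below_minimum" }
    } else {
      res <- mendelian_chi2(list(n_p1p1 = homo1[i], n_het = het[i],
                                 n_p2p2 = homo2[i]), cross)
      if (res$p_value < config$chi2_alpha) {
        fail[i] <- TRUE; reason[i] <- "prop:chi2_significant"
      }
    }
  }
  tab <- set_flag(table, "prop", fail, reason)
  # bypassed chromosomes and markers without counts: explicit pass / untested
  tab$flag_prop[bypass] <- "pass"
  tab$flag_prop[!bypass & is.na(n_inf)] <- "untested"
  tab
}
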