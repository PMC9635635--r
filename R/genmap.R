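#' Haldane map function
#'
#' Converts a recombination fraction to a genetic distance assuming no
#' crossover interference: `d = -50 * log(1 - 2r)` centimorgans. Fractions at
#' or above 0.5 correspond to infinite distance; they are capped at 0.499
#' before the transform so distances stay finite (about 310 cM), and the cap
#' is what the map-sanity filter sees.
#'
#' @param r Recombination fraction(s) in `[0, 0.5]`.
#' @param cap Cap applied to `r` before the transform.
#' @return Distance(s) in cM.
#' @export
#' @examples
#' haldane(0.25)  # ~34.657 cM
haldane <- function(r, cap = 0.499) {
  -50 * log(1 - 2 * pmin(r, cap))
}

#' Inverse Haldane map function
#'
#' @param d Distance(s) in cM.
#' @return Recombination fraction(s) `r = (1 - exp(-d/50)) / 2`.
#' @export
haldane_inv <- function(d) {
  (1 - exp(-d / 50)) / 2
}

code_to_int <- function(codes) {
  out <- match(codes, c("A", "H", "B"))
  dim(out) <- dim(codes)
  dimnames(out) <- dimnames(codes)
  out
}

#' Joint genotype-class counts for a marker pair
#'
#' Tallies the 3 x 3 table of encoded genotype classes (`A`, `H`, `B`) for
#' two markers over the individuals non-missing at both.
#'
#' @param encoded An [encode_genotypes()] result.
#' @param marker_i,marker_j Marker ids (columns of the encoded genotypes).
#' @return A 3 x 3 integer matrix, rows = classes at `marker_i`.
#' @export
pair_counts <- function(encoded, marker_i, marker_j) {
  ci <- code_to_int(encoded$geno[, marker_i])
  cj <- code_to_int(encoded$geno[, marker_j])
  joint_counts(ci, cj)
}

joint_counts <- function(ci, cj) {
  ok <- !is.na(ci) & !is.na(cj)
  counts <- tabulate((ci[ok] - 1L) * 3L + cj[ok], nbins = 9L)
  matrix(counts, nrow = 3, byrow = TRUE,
         dimnames = list(c("A", "H", "B"), c("A", "H", "B")))
}

rf_estimate <- function(r_hat, n_informative, converged) {
  r_hat <- if (is.na(r_hat)) NA_real_ else min(r_hat, 1 - r_hat)
  list(r_hat = r_hat,
       d_cM = if (is.na(r_hat)) NA_real_ else haldane(r_hat),
       n_informative = n_informative,
       converged = converged)
}

#' Recombination fraction between two backcross markers
#'
#' In a backcross each individual carries a single informative gamete, so
#' the recombination fraction is the direct proportion of individuals whose
#' genotype class differs between the two markers (homozygote at one,
#' heterozygote at the other).
#'
#' @param counts 3 x 3 joint count matrix from [pair_counts()] (the
#'   homozygote rows/columns are collapsed into one class).
#' @return A list with `r_hat` (in `[0, 0.5]`), `d_cM` (Haldane),
#'   `n_informative`, `converged`.
#' @export
rf_backcross <- function(counts) {
  homo <- c(1, 3)
  n <- sum(counts)
  if (n == 0) return(rf_estimate(NA_real_, 0L, FALSE))
  recomb <- sum(counts[homo, 2]) + sum(counts[2, homo])
  rf_estimate(recomb / n, n, TRUE)
}

#' Two-locus genotype class probabilities in an F2
#'
#' Probability of each joint genotype class (3 x 3, classes `A`/`H`/`B` at
#' each marker) for two linked markers at recombination fraction `r`,
#' assuming two independent gametes per individual. The double-heterozygote
#' class mixes the coupling (no recombinant gamete) and repulsion (two
#' recombinant gametes) phases.
#'
#' @param r Recombination fraction.
#' @return 3 x 3 matrix of class probabilities (rows = first marker).
#' @export
f2_class_probs <- function(r) {
  g <- c(`11` = (1 - r) / 2, `22` = (1 - r) / 2, `12` = r / 2, `21` = r / 2)
  p <- matrix(0, 3, 3)
  p[1, 1] <- g[["11"]]^2
  p[3, 3] <- g[["22"]]^2
  p[1, 3] <- g[["12"]]^2
  p[3, 1] <- g[["21"]]^2
  p[1, 2] <- 2 * g[["11"]] * g[["12"]]
  p[2, 1] <- 2 * g[["11"]] * g[["21"]]
  p[2, 3] <- 2 * g[["22"]] * g[["12"]]
  p[3, 2] <- 2 * g[["22"]] * g[["21"]]
  p[2, 2] <- 2 * g[["11"]] * g[["22"]] + 2 * g[["12"]] * g[["21"]]
  p
}

#' EM estimate of the recombination fraction between two F2 markers
#'
#' Each F2 individual carries two informative gametes. All two-locus classes
#' except the double heterozygote determine their recombinant-gamete count
#' exactly (concordant homozygotes: 0; discordant homozygotes: 2;
#' homozygote x heterozygote: 1); the double-heterozygote class mixes
#' coupling and repulsion phases and contributes its conditional expectation
#' `2 r^2 / (r^2 + (1-r)^2)`. The M-step divides expected recombinant
#' gametes by twice the informative count. The iteration runs over
#' `r` in `[0, 1]` and the estimate is folded to `min(r, 1-r)`, so an
#' allele-origin swap at one marker cannot masquerade as a near-certain
#' recombination.
#'
#' @param counts 3 x 3 joint count matrix from [pair_counts()].
#' @param tol Convergence tolerance on successive `r` iterates.
#' @param max_iter Maximum EM iterations.
#' @param r_init Starting value (interior, to avoid boundary fixed points).
#' @return A list with `r_hat` (in `[0, 0.5]`), `d_cM` (Haldane),
#'   `n_informative`, `converged`.
#' @export
rf_f2_em <- function(counts, tol = 1e-6, max_iter = 1000, r_init = 0.25) {
  n <- sum(counts)
  if (n == 0) return(rf_estimate(NA_real_, 0L, FALSE))
  if (counts[2, 2] == n) {
    # only double heterozygotes: the likelihood carries no phase information
    return(rf_estimate(NA_real_, n, FALSE))
  }
  k <- matrix(c(0, 1, 2,
                1, 0, 1,
                2, 1, 0), nrow = 3, byrow = TRUE)
  fixed <- sum(counts * k)  # k[2,2] = 0: the double-het term is added per iteration
  n_hh <- counts[2, 2]
  r <- r_init
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    e_hh <- 2 * r^2 / (r^2 + (1 - r)^2)
    r_new <- (fixed + n_hh * e_hh) / (2 * n)
    if (abs(r_new - r) < tol) {
      r <- r_new
      converged <- TRUE
      break
    }
    r <- r_new
  }
  rf_estimate(r, n, converged)
}

#' Two-locus F2 log-likelihood
#'
#' Multinomial log-likelihood of a 3 x 3 two-locus count table at
#' recombination fraction `r`. Exposed for diagnostics; tests use an
#' independent grid search over this surface as the oracle for [rf_f2_em()].
#'
#' @param counts 3 x 3 joint count matrix.
#' @param r Recombination fraction.
#' @return Log-likelihood value.
#' @export
rf_f2_loglik <- function(counts, r) {
  p <- f2_class_probs(r)
  sum(counts[counts > 0] * log(p[counts > 0]))
}

#' Estimate the genetic map of an encoded cross
#'
#' For every pair of adjacent markers (in known-map order, per chromosome)
#' estimates the recombination fraction — pairwise EM for an intercross,
#' direct recombinant proportion for a backcross — and converts it to a
#' Haldane distance. Cumulative estimated positions start at 0 on each
#' chromosome.
#'
#' @param encoded An [encode_genotypes()] result.
#' @param tol,max_iter Passed to [rf_f2_em()].
#' @return A tibble of class `genmap` with one row per marker: `chr`,
#'   `marker`, `pos_cM` (known), `est_cM` (cumulative estimated), `r_next`,
#'   `d_next`, `n_inf_next`, `converged_next` (all `NA` for the last marker
#'   of a chromosome).
#' @export
estimate_map <- function(encoded, tol = 1e-6, max_iter = 1000) {
  stopifnot(inherits(encoded, "encoded_cross"))
  codes <- code_to_int(encoded$geno)
  mk <- encoded$markers
  is_f2 <- encoded$cross$kind == "F2"
  rows <- vector("list", length(unique(mk$chr)))
  ci <- 0
  for (chr in unique(mk$chr)) {
    sub <- mk[mk$chr == chr, ]
    m <- nrow(sub)
    r_next <- d_next <- rep(NA_real_, m)
    n_inf <- rep(NA_integer_, m)
    conv <- rep(NA, m)
    if (m >= 2) {
      for (j in seq_len(m - 1)) {
        counts <- joint_counts(codes[, sub$marker[j]], codes[, sub$marker[j + 1]])
        est <- if (is_f2) rf_f2_em(counts, tol, max_iter) else rf_backcross(counts)
        r_next[j] <- est$r_hat
        d_next[j] <- est$d_cM
        n_inf[j] <- est$n_informative
        conv[j] <- est$converged
      }
    }
    d_for_pos <- d_next[seq_len(max(m - 1, 0))]
    d_for_pos[is.na(d_for_pos)] <- 0
    ci <- ci + 1
    rows[[ci]] <- tibble(chr = chr, marker = sub$marker, pos_cM = sub$pos_cM,
                         est_cM = cumsum(c(0, d_for_pos)),
                         r_next = r_next, d_next = d_next,
                         n_inf_next = n_inf, converged_next = conv)
  }
  map <- bind_rows(rows)
  class(map) <- c("genmap", class(map))
  attr(map, "cross_kind") <- encoded$cross$kind
  map
}

#' Ratios of estimated to known adjacent-marker distances
#'
#' For each adjacent marker pair whose known *and* estimated distances are
#' at least `min_cm` (small intervals produce exaggerated ratios), returns
#' `estimated / known`. On clean data the ratios sit unimodally around 1;
#' genotyping errors push a tail of pairs to very large values.
#'
#' @param map A `genmap` from [estimate_map()].
#' @param min_cm Minimum known and estimated distance for a pair to enter.
#' @return A tibble with `chr`, `marker_from`, `marker_to`, `known_d`,
#'   `est_d`, `ratio`.
#' @export
expansion_ratios <- function(map, min_cm = 1.0) {
  out <- list()
  for (chr in unique(map$chr)) {
    sub <- map[map$chr == chr, ]
    m <- nrow(sub)
    if (m < 2) next
    known_d <- diff(sub$pos_cM)
    est_d <- sub$d_next[seq_len(m - 1)]
    keep <- !is.na(known_d) & !is.na(est_d) & known_d >= min_cm & est_d >= min_cm
    if (!any(keep)) next
    kd <- known_d[keep]
    ed <- est_d[keep]
    out[[chr]] <- tibble(chr = chr,
                         marker_from = sub$marker[seq_len(m - 1)][keep],
                         marker_to = sub$marker[-1][keep],
                         known_d = kd, est_d = ed, ratio = ed / kd)
  }
  if (length(out) == 0) {
    return(tibble(chr = character(), marker_from = character(),
                  marker_to = character(), known_d = numeric(),
                  est_d = numeric(), ratio = numeric()))
  }
  bind_rows(out)
}

#' Whole-genome estimated/known map length ratio
#'
#' Sums estimated Haldane distances and known cM distances over all adjacent
#' pairs of the map and returns their ratio — the single-number map-expansion
#' diagnostic.
#'
#' @param map A `genmap` from [estimate_map()].
#' @return Ratio of total estimated to total known map length.
#' @export
map_length_ratio <- function(map) {
  known <- est <- 0
  for (chr in unique(map$chr)) {
    sub <- map[map$chr == chr, ]
    m <- nrow(sub)
    if (m < 2) next
    kd <- diff(sub$pos_cM)
    ed <- sub$d_next[seq_len(m - 1)]
    ok <- !is.na(kd) & !is.na(ed)
    known <- known + sum(kd[ok])
    est <- est + sum(ed[ok])
  }
  if (known == 0) return(NA_real_)
  est / known
}

#' Filter: implausible recombination with both neighbors
#'
#' Fails markers whose estimated Haldane distance to *every* adjacent
#' retained marker exceeds `threshold_cM` (markers at a chromosome end are
#' judged on their single neighbor). A defective assay produces genotypes
#' nearly independent of both flanking markers, i.e. apparent distances of
#' hundreds of cM, while genuine adjacent distances are at most a few cM —
#' the default threshold of 100 cM separates the two regimes.
#'
#' @param table Marker table.
#' @param map A `genmap` estimated on the currently retained markers.
#' @param threshold_cM Distance threshold in cM.
#' @return The table with the `estmap` flag set for markers present in the
#'   map (others stay untested).
#' @export
mark_estmap <- function(table, map, threshold_cM = 100) {
  d_prev <- rep(NA_real_, nrow(map))
  for (chr in unique(map$chr)) {
    i <- which(map$chr == chr)
    if (length(i) >= 2) d_prev[i[-1]] <- map$d_next[i[-length(i)]]
  }
  far <- function(d) !is.na(d) & d > threshold_cM
  has_neighbor <- !is.na(d_prev) | !is.na(map$d_next)
  map_fail <- has_neighbor &
    (far(d_prev) | is.na(d_prev)) & (far(map$d_next) | is.na(map$d_next))
  idx <- match(table$marker, map$marker)
  fail <- !is.na(idx) & map_fail[pmax(idx, 1L)]
  tab <- set_flag(table, "estmap", fail, "estmap:high_rf_both_neighbors")
  tab$flag_estmap[is.na(idx)] <- "untested"
  tab
}

#' Export a genetic map as TSV
#'
#' @param map A `genmap`.
#' @param path Output path.
#' @export
write_map_tsv <- function(map, path) {
  readr::write_tsv(as_tibble(map), path, progress = FALSE)
  invisible(path)
}
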