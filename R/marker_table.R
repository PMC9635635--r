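#' Describe the cross design
#'
#' @param kind `"F2"` (intercross) or `"N2"` (backcross).
#' @param recurrent For backcrosses, which parent is the recurrent one:
#'   `"p1"` or `"p2"`. Required iff `kind == "N2"`.
#' @return A list of class `cross_type`.
#' @export
#' @examples
#' cross_type("F2")
#' cross_type("N2", recurrent = "p1")
cross_type <- function(kind = c("F2", "N2"), recurrent = NULL) {
  kind <- match.arg(kind)
  if (kind == "N2") {
    if (is.null(recurrent) || !recurrent %in% c("p1", "p2")) {
      stop("cross_type: a backcross (N2) needs recurrent = \"p1\" or \"p2\"",
           call. = FALSE)
    }
  } else {
    recurrent <- NULL
  }
  structure(list(kind = kind, recurrent = recurrent), class = "cross_type")
}

FILTER_NAMES <- c("match", "allele", "na", "poly", "prop", "estmap")

#' Is each marker of a marker table still retained?
#'
#' A marker is retained while no filter has flagged it `"fail"`; `"untested"`
#' does not count against it.
#'
#' @param table A marker table.
#' @return Logical vector along the rows of `table`.
#' @export
marker_retained <- function(table) {
  flags <- as.matrix(table[, paste0("flag_", FILTER_NAMES)])
  rowSums(flags == "fail") == 0
}

set_flag <- function(table, filter, fail, reason = filter) {
  col <- paste0("flag_", filter)
  fail[is.na(fail)] <- FALSE
  table[[col]] <- ifelse(fail, "fail", "pass")
  if (length(reason) == 1) reason <- rep(reason, nrow(table))
  table$reason <- ifelse(fail & is.na(table$reason), reason, table$reason)
  table
}

# Homozygous-call tallies per base plus het/missing, from a call matrix.
tally_calls <- function(geno) {
  tab <- vapply(c(ALLELE_BASES, "H", "N"),
                function(sym) colSums(geno == sym, na.rm = TRUE),
                numeric(ncol(geno)))
  if (ncol(geno) == 1) tab <- matrix(tab, nrow = 1,
                                     dimnames = list(colnames(geno),
                                                     c(ALLELE_BASES, "H", "N")))
  tab
}

#' Build the per-marker ledger
#'
#' Constructs the central marker table: one row per marker present in the
#' genotype matrix or the annotation, carrying annotation, parental alleles,
#' genotype tallies and one flag per filter (all starting `"untested"`).
#' Genotype-class counts relative to the parents (`n_p1p1`, `n_p2p2`,
#' `n_other`) are filled where the parental alleles are known bases and `NA`
#' otherwise.
#'
#' @param geno Offspring call matrix from [read_genotype_long()].
#' @param ann Annotation tibble from [read_annotation()], or `NULL`. Markers
#'   absent from the annotation are kept with chromosome `"unknown"`.
#' @param parents Parental alleles: a tibble with columns `marker`, `p1`,
#'   `p2` (calls in `{A,C,G,T,H,N}`), e.g. from [parental_alleles()]. `NULL`
#'   leaves both parents unknown.
#' @return A tibble of class `marker_table`.
#' @export
build_marker_table <- function(geno, ann = NULL, parents = NULL) {
  stopifnot(is.matrix(geno), nrow(geno) > 0)
  sgi_markers <- colnames(geno)
  if (is.null(ann)) {
    ann <- tibble(marker = sgi_markers, chr = "unknown",
                  pos_bp = NA_real_, pos_cM = NA_real_, unmappable = TRUE)
  }
  extra <- setdiff(sgi_markers, ann$marker)
  if (length(extra) > 0) {
    ann <- bind_rows(ann, tibble(marker = extra, chr = "unknown",
                                 pos_bp = NA_real_, pos_cM = NA_real_,
                                 unmappable = TRUE))
  }
  tab <- as_tibble(ann[, c("marker", "chr", "pos_bp", "pos_cM", "unmappable")])
  tab$in_sgi <- tab$marker %in% sgi_markers

  counts <- matrix(0, nrow = nrow(tab), ncol = 6,
                   dimnames = list(NULL, c(ALLELE_BASES, "H", "N")))
  present <- tab$in_sgi
  counts[present, ] <- tally_calls(geno[, tab$marker[present], drop = FALSE])
  counts[!present, "N"] <- nrow(geno)
  tab$n_A <- unname(counts[, "A"]); tab$n_C <- unname(counts[, "C"])
  tab$n_G <- unname(counts[, "G"]); tab$n_T <- unname(counts[, "T"])
  tab$n_het <- unname(counts[, "H"]); tab$n_missing <- unname(counts[, "N"])
  tab$n_total <- nrow(geno)

  if (is.null(parents)) {
    parents <- tibble(marker = character(), p1 = character(), p2 = character())
  }
  idx <- match(tab$marker, parents$marker)
  tab$p1 <- ifelse(is.na(idx), "N", parents$p1[idx])
  tab$p2 <- ifelse(is.na(idx), "N", parents$p2[idx])
  tab$p1[is.na(tab$p1)] <- "N"; tab$p2[is.na(tab$p2)] <- "N"
  src <- function(x) ifelse(is_base(x), "observed",
                     ifelse(x == "H", "het", "missing"))
  tab$p1_source <- src(tab$p1)
  tab$p2_source <- src(tab$p2)
  tab$in_parents <- !is.na(idx)

  tab <- update_class_counts(tab)
  for (f in FILTER_NAMES) tab[[paste0("flag_", f)]] <- "untested"
  tab$reason <- NA_character_
  class(tab) <- c("marker_table", class(tab))
  tab
}

# Distinct SGI base alleles as a collapsed string. H contributes the parental
# bases only when both parents are known (the two bases behind an H call are
# then identified); otherwise het presence is noted with "+H".
sgi_allele_string <- function(tab) {
  bases <- cbind(A = tab$n_A, C = tab$n_C, G = tab$n_G, T = tab$n_T)
  vapply(seq_len(nrow(tab)), function(i) {
    seen <- ALLELE_BASES[bases[i, ] > 0]
    if (tab$n_het[i] > 0) {
      if (is_base(tab$p1[i]) && is_base(tab$p2[i])) {
        seen <- union(seen, c(tab$p1[i], tab$p2[i]))
      } else {
        return(paste(c(sort(seen), "+H"), collapse = "/"))
      }
    }
    paste(sort(seen), collapse = "/")
  }, character(1))
}

# Recompute parent-relative genotype-class counts from base tallies.
# With one known parent, n_p1p1/n_p2p2 for the known side is filled and
# n_other counts homozygotes for any base other than the known allele(s).
update_class_counts <- function(tab) {
  bases <- cbind(A = tab$n_A, C = tab$n_C, G = tab$n_G, T = tab$n_T)
  n_homo <- rowSums(bases)
  get_base <- function(p) {
    out <- rep(NA_real_, nrow(tab))
    k <- is_base(p)
    out[k] <- bases[cbind(which(k), match(p[k], ALLELE_BASES))]
    out
  }
  tab$n_p1p1 <- get_base(tab$p1)
  tab$n_p2p2 <- get_base(tab$p2)
  both <- is_base(tab$p1) & is_base(tab$p2)
  same <- both & tab$p1 == tab$p2
  tab$n_other <- ifelse(both & !same, n_homo - tab$n_p1p1 - tab$n_p2p2,
                 ifelse(same, n_homo - tab$n_p1p1,
                 ifelse(is_base(tab$p1), n_homo - tab$n_p1p1,
                 ifelse(is_base(tab$p2), n_homo - tab$n_p2p2, NA_real_))))
  tab$sgi_alleles <- sgi_allele_string(tab)
  tab
}

#' Encode offspring calls relative to parental origin
#'
#' Maps each allele call to the R/qtl-style code: homozygous for the first
#' parent's allele -> `A`, heterozygous -> `H`, homozygous for the second
#' parent's allele -> `B`, missing -> `N`. A homozygous call for a base
#' carried by neither parent cannot be explained by the cross and becomes `N`
#' with a warning. Only markers whose filter flags are all `pass`/`untested`
#' are emitted, ordered by chromosome then cM.
#'
#' @param table Marker table, after [mark_allele()] so that single-missing
#'   parents have been imputed where possible.
#' @param geno Offspring call matrix.
#' @param cross A [cross_type()].
#' @return A list of class `encoded_cross`: `geno` (individuals x markers
#'   code matrix), `markers` (tibble of marker, chr, pos_cM), `cross`.
#' @export
encode_genotypes <- function(table, geno, cross) {
  stopifnot(inherits(cross, "cross_type"))
  keep <- marker_retained(table) & table$in_sgi
  tab <- table[keep, ]
  tab <- tab[order(chromosome_rank(tab$chr), tab$pos_cM, tab$pos_bp,
                   tab$marker), ]
  if (any(!is_base(tab$p1) & !is_base(tab$p2))) {
    stop("encode_genotypes: marker with both parental alleles unknown reached encoding; run mark_allele() first",
         call. = FALSE)
  }
  calls <- geno[, tab$marker, drop = FALSE]
  codes <- matrix("N", nrow = nrow(calls), ncol = ncol(calls),
                  dimnames = dimnames(calls))
  p1 <- matrix(tab$p1, nrow = nrow(calls), ncol = ncol(calls), byrow = TRUE)
  p2 <- matrix(tab$p2, nrow = nrow(calls), ncol = ncol(calls), byrow = TRUE)
  codes[calls == "H"] <- "H"
  codes[calls == p1 & calls != "N"] <- "A"
  codes[calls == p2 & calls != "N"] <- "B"
  unexplained <- sum(calls %in% ALLELE_BASES & codes == "N")
  if (unexplained > 0) {
    warning(sprintf("encode_genotypes: %d homozygous call(s) for a base carried by neither parent set to missing",
                    unexplained), call. = FALSE)
  }
  structure(list(geno = codes,
                 markers = tibble(marker = tab$marker, chr = tab$chr,
                                  pos_cM = tab$pos_cM),
                 cross = cross,
                 n_unexplained = unexplained),
            class = "encoded_cross")
}

#' @export
print.encoded_cross <- function(x, ...) {
  cat(sprintf("Encoded %s cross: %d individuals, %d markers on %d chromosome(s)\n",
              x$cross$kind, nrow(x$geno), ncol(x$geno),
              length(unique(x$markers$chr))))
  invisible(x)
}

#' Tally encoded genotype classes for one marker
#'
#' @param codes Character vector of codes in `{A,H,B,N}`.
#' @return Named vector of class counts.
#' @export
count_codes <- function(codes) {
  c(n_p1p1 = sum(codes == "A"), n_het = sum(codes == "H"),
    n_p2p2 = sum(codes == "B"), n_missing = sum(codes == "N"))
}
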