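#' Column dialect for long-format genotype files
#'
#' Genotyping services deliver long-format files (one row per sample x marker,
#' two allele columns) with service-specific header names. A dialect maps the
#' logical column roles to the header names actually present. Defaults follow
#' MiniMUGA service exports.
#'
#' @param sample,marker,allele1,allele2 Header names for the sample id, marker
#'   id and the two allele columns.
#' @param skip Number of lines to skip before the header (e.g. an Illumina
#'   `[Header]` preamble).
#' @return A named list of class `geno_dialect`.
#' @export
#' @examples
#' geno_dialect(sample = "id", marker = "snp", allele1 = "a1", allele2 = "a2")
geno_dialect <- function(sample = "Sample ID", marker = "SNP Name",
                         allele1 = "Allele1 - Forward",
                         allele2 = "Allele2 - Forward",
                         skip = 0L) {
  structure(list(sample = sample, marker = marker,
                 allele1 = allele1, allele2 = allele2, skip = skip),
            class = "geno_dialect")
}

#' Column dialect for marker annotation files
#'
#' Defaults follow the corrected MiniMUGA annotation (`mini_uwisc_v2`-style
#' column names).
#'
#' @param marker,chr,bp,cM Header names for the marker id, chromosome,
#'   physical position (bp) and genetic position (cM) columns.
#' @return A named list of class `annot_dialect`.
#' @export
annot_dialect <- function(marker = "marker", chr = "chr",
                          bp = "bp_mm10", cM = "cM_cox") {
  structure(list(marker = marker, chr = chr, bp = bp, cM = cM),
            class = "annot_dialect")
}

guess_delim <- function(path, skip = 0L) {
  header <- readr::read_lines(path, skip = skip, n_max = 1L)
  if (grepl("\t", header)) "\t" else ","
}

require_columns <- function(df, wanted, what) {
  missing <- setdiff(unlist(wanted), names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: required column(s) not found: %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Read a long-format genotype file into a call matrix
#'
#' Reads delimited text with one row per sample x marker and two allele
#' columns, and collapses each allele pair into a single-letter call:
#' identical bases give that base, two different bases give `H`
#' (heterozygous), and any `-` in the pair gives `N` (no-call). The marker set
#' is the union over samples; combinations absent from the file are filled
#' with `N`.
#'
#' @param path Path to a comma- or tab-delimited file with a header row.
#' @param dialect A [geno_dialect()] naming the four required columns.
#' @return A character matrix of calls in `{A,C,G,T,H,N}` with samples as rows
#'   and markers as columns.
#' @export
read_genotype_long <- function(path, dialect = geno_dialect()) {
  delim <- guess_delim(path, dialect$skip)
  raw <- readr::read_delim(path, delim = delim, skip = dialect$skip,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  require_columns(raw, dialect[c("sample", "marker", "allele1", "allele2")],
                  "genotype file")
  a1 <- raw[[dialect$allele1]]
  a2 <- raw[[dialect$allele2]]
  ok <- c(ALLELE_BASES, "-")
  bad <- which(!(a1 %in% ok) | !(a2 %in% ok))
  if (length(bad) > 0) {
    stop(sprintf("genotype file: allele symbol outside {A,C,G,T,-} at line %d (%s/%s)",
                 bad[1] + 1L + dialect$skip, a1[bad[1]], a2[bad[1]]),
         call. = FALSE)
  }
  call <- ifelse(a1 == "-" | a2 == "-", "N", ifelse(a1 == a2, a1, "H"))

  samples <- unique(raw[[dialect$sample]])
  markers <- unique(raw[[dialect$marker]])
  if (any(samples == "") || any(markers == "")) {
    stop("genotype file: empty sample or marker id", call. = FALSE)
  }
  i <- match(raw[[dialect$sample]], samples)
  j <- match(raw[[dialect$marker]], markers)
  if (anyDuplicated(cbind(i, j))) {
    d <- which(duplicated(cbind(i, j)))[1]
    stop(sprintf("genotype file: duplicated (sample, marker) pair: (%s, %s)",
                 raw[[dialect$sample]][d], raw[[dialect$marker]][d]),
         call. = FALSE)
  }
  geno <- matrix("N", nrow = length(samples), ncol = length(markers),
                 dimnames = list(samples, markers))
  geno[cbind(i, j)] <- call
  geno
}

#' Write a call matrix back to the long genotype format
#'
#' Inverse of [read_genotype_long()]: each call expands to an allele pair
#' (`A` -> `A,A`; `H` -> the two distinct bases segregating at the marker;
#' `N` -> `-,-`).
#'
#' @param geno Call matrix as returned by [read_genotype_long()].
#' @param path Output path (CSV).
#' @param dialect A [geno_dialect()] supplying the header names.
#' @param het_pairs Optional named character vector (marker -> two-letter
#'   string, e.g. `"AG"`) giving the base pair behind heterozygous calls;
#'   markers not covered fall back to the two distinct bases observed in
#'   `geno`. An `H` call at a marker whose pair cannot be resolved is an
#'   error.
#' @export
write_genotype_long <- function(geno, path, dialect = geno_dialect(),
                                het_pairs = NULL) {
  long <- expand.grid(sample = rownames(geno), marker = colnames(geno),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$call <- as.vector(geno)
  # per-marker pair of observed bases, for expanding H calls
  het_pair <- apply(geno, 2, function(col) {
    b <- sort(unique(col[col %in% ALLELE_BASES]))
    if (length(b) == 2) paste(b, collapse = "") else NA_character_
  })
  if (!is.null(het_pairs)) {
    het_pair[names(het_pairs)] <- het_pairs
  }
  unresolved <- is.na(het_pair) & colSums(geno == "H") > 0
  if (any(unresolved)) {
    stop(sprintf("write_genotype_long: cannot resolve the allele pair behind H calls at marker %s; supply het_pairs",
                 colnames(geno)[unresolved][1]), call. = FALSE)
  }
  pair <- het_pair[long$marker]
  a1 <- ifelse(long$call == "N", "-",
        ifelse(long$call == "H", substr(pair, 1, 1), long$call))
  a2 <- ifelse(long$call == "N", "-",
        ifelse(long$call == "H", substr(pair, 2, 2), long$call))
  out <- tibble(s = long$sample, m = long$marker, x = a1, y = a2)
  names(out) <- c(dialect$sample, dialect$marker, dialect$allele1, dialect$allele2)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

chromosome_rank <- function(chr) {
  num <- suppressWarnings(as.numeric(chr))
  rank <- ifelse(!is.na(num), num,
          ifelse(chr == "X", 1000,
          ifelse(chr == "Y", 1001,
          ifelse(chr %in% c("M", "MT"), 1002,
          ifelse(chr == "unknown", 1e6, 2000)))))
  rank
}

#' Read a marker annotation table
#'
#' Parses a CSV with marker id, chromosome, physical (bp) and genetic (cM)
#' positions, and sorts markers within each chromosome by cM position (ties
#' broken by bp, then marker id). Markers with a missing chromosome or cM
#' position are retained but flagged `unmappable`; downstream they are
#' excluded by the marker-matching filter.
#'
#' @param path Path to the annotation CSV.
#' @param dialect An [annot_dialect()] naming the columns.
#' @return A tibble with columns `marker`, `chr`, `pos_bp`, `pos_cM`,
#'   `unmappable`.
#' @export
read_annotation <- function(path, dialect = annot_dialect()) {
  raw <- readr::read_csv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  require_columns(raw, dialect[c("marker", "chr", "cM")], "annotation file")
  ann <- tibble(
    marker = raw[[dialect$marker]],
    chr = raw[[dialect$chr]],
    pos_bp = if (dialect$bp %in% names(raw))
      suppressWarnings(as.numeric(raw[[dialect$bp]])) else NA_real_,
    pos_cM = raw[[dialect$cM]]
  )
  if (anyDuplicated(ann$marker)) {
    stop(sprintf("annotation file: duplicated marker id: %s",
                 ann$marker[duplicated(ann$marker)][1]), call. = FALSE)
  }
  cm <- suppressWarnings(as.numeric(ann$pos_cM))
  bad <- !is.na(ann$pos_cM) & ann$pos_cM != "" & is.na(cm)
  if (any(bad)) {
    stop(sprintf("annotation file: non-numeric cM position for marker %s",
                 ann$marker[bad][1]), call. = FALSE)
  }
  ann$pos_cM <- cm
  ann$chr[is.na(ann$chr) | ann$chr == ""] <- NA_character_
  ann$unmappable <- is.na(ann$chr) | is.na(ann$pos_cM)
  ann[order(chromosome_rank(ann$chr), ann$pos_cM, ann$pos_bp, ann$marker,
            na.last = TRUE), ]
}

#' Read a phenotype table
#'
#' @param path CSV with one row per individual; the first column (or
#'   `id_col`) holds individual ids, remaining columns are phenotypes.
#' @param id_col Name of the id column; defaults to the first column.
#' @return A tibble; ids are checked for uniqueness.
#' @export
read_phenotypes <- function(path, id_col = NULL) {
  ph <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  id_col <- id_col %||% names(ph)[1]
  if (!id_col %in% names(ph)) {
    stop(sprintf("phenotype file: id column '%s' not found", id_col), call. = FALSE)
  }
  if (ncol(ph) < 2) stop("phenotype file: no phenotype columns", call. = FALSE)
  if (anyDuplicated(ph[[id_col]])) {
    stop("phenotype file: duplicated individual ids", call. = FALSE)
  }
  # id column first
  ph[, c(id_col, setdiff(names(ph), id_col))]
}

#' Export an encoded cross in the R/qtl "csv" format
#'
#' Writes the comma-separated cross file read by `R/qtl`'s
#' `read.cross(format = "csv")`: row 1 holds phenotype column names followed
#' by marker ids, row 2 the chromosome of each marker (blank under the
#' phenotypes), row 3 the cM position, and one row per individual thereafter
#' with phenotype values followed by genotype codes `A`/`H`/`B` (`-` for
#' missing).
#'
#' @param encoded An [encode_genotypes()] result containing only retained
#'   markers, ordered by chromosome then cM.
#' @param phenotypes Tibble of phenotypes; the first column must hold the
#'   individual ids matching the rownames of the encoded genotypes.
#' @param path Output path.
#' @export
write_rqtl <- function(encoded, phenotypes, path) {
  stopifnot(inherits(encoded, "encoded_cross"))
  geno <- encoded$geno
  if (ncol(geno) == 0) stop("write_rqtl: no markers to export", call. = FALSE)
  ids <- rownames(geno)
  miss <- setdiff(ids, as.character(phenotypes[[1]]))
  if (length(miss) > 0) {
    stop(sprintf("write_rqtl: individuals missing from phenotypes: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  ph <- phenotypes[match(ids, as.character(phenotypes[[1]])), ]
  codes <- geno
  codes[codes == "N"] <- "-"
  n_ph <- ncol(ph)
  header <- c(names(ph), encoded$markers$marker)
  chr_row <- c(rep("", n_ph), encoded$markers$chr)
  cm_row <- c(rep("", n_ph), format(encoded$markers$pos_cM, trim = TRUE,
                                    scientific = FALSE))
  ph_chr <- apply(ph, 2, as.character)
  if (is.null(dim(ph_chr))) ph_chr <- matrix(ph_chr, nrow = nrow(ph))
  body <- cbind(ph_chr, codes)
  lines <- c(paste(header, collapse = ","),
             paste(chr_row, collapse = ","),
             paste(cm_row, collapse = ","),
             apply(body, 1, paste, collapse = ","))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read back an R/qtl "csv" cross file
#'
#' Companion to [write_rqtl()], used for round-trip checks and reports.
#'
#' @param path Path to an R/qtl csv cross file.
#' @param n_pheno Number of leading phenotype columns; inferred from the
#'   blanks in the chromosome row when `NULL`.
#' @return A list with `pheno` (tibble), `markers` (tibble of marker, chr,
#'   pos_cM) and `geno` (individuals x markers code matrix, `N` for missing).
#' @export
read_rqtl <- function(path, n_pheno = NULL) {
  lines <- readr::read_lines(path)
  cells <- strsplit(lines, ",", fixed = TRUE)
  header <- cells[[1]]
  chr_row <- cells[[2]]
  length(chr_row) <- length(header)  # trailing blanks may be dropped
  cm_row <- cells[[3]]
  length(cm_row) <- length(header)
  n_pheno <- n_pheno %||% sum(is.na(chr_row) | chr_row == "")
  markers <- tibble(marker = header[-seq_len(n_pheno)],
                    chr = chr_row[-seq_len(n_pheno)],
                    pos_cM = as.numeric(cm_row[-seq_len(n_pheno)]))
  body <- do.call(rbind, cells[-(1:3)])
  pheno <- as_tibble(as.data.frame(body[, seq_len(n_pheno), drop = FALSE],
                                   stringsAsFactors = FALSE),
                     .name_repair = "minimal")
  names(pheno) <- header[seq_len(n_pheno)]
  pheno[] <- lapply(pheno, function(x) utils::type.convert(x, as.is = TRUE))
  geno <- body[, -seq_len(n_pheno), drop = FALSE]
  geno[geno == "-"] <- "N"
  dimnames(geno) <- list(as.character(pheno[[1]]), markers$marker)
  list(pheno = pheno, markers = markers, geno = geno)
}

#' Write the marker report
#'
#' One TSV row per marker — retained and excluded alike — with annotation,
#' parental alleles, genotype counts, every filter's flag and the first
#' exclusion reason.
#'
#' @param table A marker table (see [build_marker_table()]).
#' @param path Output path.
#' @export
write_marker_report <- function(table, path) {
  flag_cols <- grep("^flag_", names(table), value = TRUE)
  out <- table[, c("marker", "chr", "pos_bp", "pos_cM", "p1", "p2",
                   "p1_source", "p2_source", "sgi_alleles",
                   "n_p1p1", "n_het", "n_p2p2", "n_other", "n_missing",
                   "n_total", flag_cols, "reason")]
  out$retained <- marker_retained(table)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Overall genotyping call rate of a call matrix
#'
#' @param geno Call matrix from [read_genotype_long()].
#' @return Fraction of entries that are not `N`.
#' @export
call_rate <- function(geno) 1 - mean(geno == "N")
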