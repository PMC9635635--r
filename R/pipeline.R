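#' Run the full curation cascade
#'
#' Executes the filters in pipeline order — marker matching, allele
#' consistency, missingness, polymorphism, Mendelian proportions, then the
#' recombination-fraction map-sanity step (genotypes are encoded, the
#' genetic map estimated, and markers with implausible distances to all
#' neighbors dropped) — and re-encodes the surviving markers. Every step is
#' logged with the number of markers entering, excluded and retained.
#'
#' @param geno Offspring call matrix from [read_genotype_long()].
#' @param ann Annotation tibble from [read_annotation()] (or `NULL`).
#' @param parents Parental alleles tibble (`marker`, `p1`, `p2`), e.g. from
#'   [parental_alleles()].
#' @param cross A [cross_type()].
#' @param config A [filter_config()].
#' @param parent_marker_ids Markers genotyped in the parents; defaults to
#'   `parents$marker`.
#' @return A list of class `curation_result`: `table` (final marker table),
#'   `encoded` (encoded cross of retained markers), `map` (the `genmap`
#'   estimated on the pre-map-filter markers, `NULL` when the step is
#'   skipped), `log` (tibble: step, n_in, n_excluded, n_out, params),
#'   `config`.
#' @export
run_pipeline <- function(geno, ann, parents, cross,
                         config = filter_config(),
                         parent_marker_ids = NULL) {
  stopifnot(inherits(cross, "cross_type"))
  parent_marker_ids <- parent_marker_ids %||% parents$marker

  table <- build_marker_table(geno, ann, parents)
  log <- tibble(step = "import", n_in = nrow(table), n_excluded = 0L,
                n_out = nrow(table), params = "")

  log_step <- function(table, step, params = "") {
    n_in <- log$n_out[nrow(log)]
    n_out <- sum(marker_retained(table))
    log <<- bind_rows(log, tibble(step = step, n_in = n_in,
                                  n_excluded = n_in - n_out, n_out = n_out,
                                  params = params))
    table
  }

  table <- log_step(mark_match(table, parent_marker_ids), "match")
  table <- log_step(mark_allele(table, cross, config), "allele",
                    sprintf("parNH_strict=%s", config$parNH_strict))
  table <- log_step(mark_na(table, config), "na",
                    sprintf("na_max=%g", config$na_max))
  table <- log_step(mark_poly(table), "poly")
  table <- log_step(mark_prop(table, cross, config), "prop",
                    if (config$prop_mode == "proportion") {
                      sprintf("mode=proportion min_homo=%g min_het=%g x_min=%g",
                              config$prop_min_homo, config$prop_min_het,
                              config$x_prop_min)
                    } else {
                      sprintf("mode=chi2 alpha=%g x_min=%g",
                              config$chi2_alpha, config$x_prop_min)
                    })

  map <- NULL
  if (config$run_estmap) {
    pre <- encode_genotypes(table, geno, cross)
    map <- estimate_map(pre)
    table <- log_step(mark_estmap(table, map, config$estmap_threshold),
                      "estmap",
                      sprintf("threshold_cM=%g", config$estmap_threshold))
  }

  encoded <- encode_genotypes(table, geno, cross)
  structure(list(table = table, encoded = encoded, map = map, log = log,
                 config = config),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat(sprintf("Curation of a %s cross: %d/%d markers retained\n",
              x$encoded$cross$kind, sum(marker_retained(x$table)),
              nrow(x$table)))
  print(as.data.frame(x$log), row.names = FALSE)
  invisible(x)
}

#' Format a run log as text lines
#'
#' @param log The `log` tibble of a [run_pipeline()] result.
#' @return Character vector of aligned text lines.
#' @export
format_run_log <- function(log) {
  utils::capture.output(print(as.data.frame(log), row.names = FALSE))
}
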