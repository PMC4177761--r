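#' Filtering and classification thresholds
#'
#' Bundles every threshold used along the pipeline. The defaults are the
#' annotation criteria used throughout: profile hits are kept when the
#' E-value is at most `evalue_max` and the aligned span covers at least
#' `coverage_min` of the profile; genomes with fewer than `min_genes` genes
#' (or flagged obligate parasites) are excluded; an enzyme is "widely
#' distributed" in a cellular domain when it is present in strictly more
#' than `wide_fraction` of that domain's clades.
#'
#' @param evalue_max Maximum E-value for a hit to be retained (inclusive).
#' @param coverage_min Minimum fraction of the profile covered by the
#'   alignment (inclusive), in `[0, 1]`.
#' @param min_genes Genomes with fewer genes than this are treated as
#'   reduced and excluded (strict: a genome with exactly `min_genes` genes
#'   is retained).
#' @param wide_fraction An enzyme is classed `widely` in a domain when its
#'   clade fraction strictly exceeds this value.
#' @param presence_cutoff A clade counts as "present" for an enzyme when
#'   its clade-level average strictly exceeds this value. The default 0
#'   means any retained genus member suffices.
#' @param sparse_fraction Upper bound (inclusive) on the clade fraction for
#'   the `sparsely` class; fractions in `(sparse_fraction, wide_fraction]`
#'   are `partially`. A convention, not a biological constant: the wide
#'   threshold is the only one that feeds LCA attribution.
#' @param exclusive_best_hit If `TRUE`, keep a single best hit per
#'   (genome, query) so a query is assigned to at most one profile. The
#'   default `FALSE` resolves the best hit per (genome, query, profile),
#'   which lets one protein carry several activities (e.g. the
#'   bifunctional PurH with EC 2.1.2.3 and 3.5.4.10).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(evalue_max = 1e-10,
                          coverage_min = 0.55,
                          min_genes = 1000L,
                          wide_fraction = 0.5,
                          presence_cutoff = 0,
                          sparse_fraction = 0.1,
                          exclusive_best_hit = FALSE) {
  stopifnot(
    is.numeric(evalue_max), length(evalue_max) == 1L, evalue_max >= 0,
    is.numeric(coverage_min), coverage_min >= 0, coverage_min <= 1,
    is.numeric(min_genes), min_genes >= 0,
    is.numeric(wide_fraction), wide_fraction >= 0, wide_fraction <= 1,
    is.numeric(presence_cutoff), presence_cutoff >= 0, presence_cutoff < 1,
    is.numeric(sparse_fraction), sparse_fraction >= 0,
    is.logical(exclusive_best_hit), length(exclusive_best_hit) == 1L
  )
  if (sparse_fraction > wide_fraction) {
    stop("`sparse_fraction` must not exceed `wide_fraction`")
  }
  structure(
    list(
      evalue_max = as.numeric(evalue_max),
      coverage_min = as.numeric(coverage_min),
      min_genes = as.integer(min_genes),
      wide_fraction = as.numeric(wide_fraction),
      presence_cutoff = as.numeric(presence_cutoff),
      sparse_fraction = as.numeric(sparse_fraction),
      exclusive_best_hit = exclusive_best_hit
    ),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  cat(sprintf("  E-value max:        %g\n", x$evalue_max))
  cat(sprintf("  profile coverage:   >= %g\n", x$coverage_min))
  cat(sprintf("  min genes/genome:   %d\n", x$min_genes))
  cat(sprintf("  widely threshold:   clade fraction > %g\n", x$wide_fraction))
  cat(sprintf("  clade presence:     average > %g\n", x$presence_cutoff))
  cat(sprintf("  sparse threshold:   clade fraction <= %g\n", x$sparse_fraction))
  cat(sprintf("  exclusive best hit: %s\n", x$exclusive_best_hit))
  invisible(x)
}

as_filter_config <- function(config) {
  if (inherits(config, "filter_config")) return(config)
  if (is.list(config)) return(do.call(filter_config, config))
  stop("`config` must be a filter_config or a list of its fields")
}
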