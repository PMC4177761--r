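#' Path to a packaged data file
#'
#' @param ... Path components under the package's `extdata` directory;
#'   with no arguments, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
ancenz_file <- function(...) {
  if (!length(list(...))) {
    return(list.files(system.file("extdata", package = "ancenz"),
                      recursive = TRUE))
  }
  path <- system.file("extdata", ..., package = "ancenz")
  if (!nzchar(path)) stop("no packaged file: ", file.path(...))
  path
}

#' The packaged nucleotide-metabolism profile catalogue
#'
#' 151 enzyme profiles covering 120 distinct EC numbers of purine and
#' pyrimidine metabolism, with subunit, analog and paralog groupings
#' (e.g. PurQ + PurL subunits for EC 6.3.5.3; the non-homologous PurN and
#' PurT families for EC 2.1.2.2; PurO as the archaeal analog of PurH's
#' IMP cyclohydrolase activity). This catalogue is a synthetic
#' reconstruction assembled from standard purine/pyrimidine pathway
#' enzymology, not a redistribution of any profile database; profile
#' lengths are plausible placeholders.
#'
#' @return A `profile_catalogue` data frame.
#' @export
load_catalogue <- function() {
  read_catalogue(ancenz_file("profile_catalogue_synthetic.tsv"))
}

#' Packaged pathway graphs
#'
#' Transcriptions of the purine and pyrimidine reaction diagrams into
#' step tables. Available names: `purine_denovo`, `purine_salvage`,
#' `purine_ancestral`, `pyrimidine_denovo`, `pyrimidine_from_ump`,
#' `pyrimidine_salvage`, `pyrimidine_ancestral`. Each step's `diagram`
#' column names the diagram it encodes; semienzymatic steps are tagged
#' `nonenzymatic` and never receive an ancestry label.
#'
#' @param name Pathway name (see above).
#' @return A `pathway` object.
#' @export
load_pathway <- function(name) {
  read_pathway(ancenz_file("pathways", paste0(name, ".tsv")))
}

#' Packaged qualitative distribution classes
#'
#' Per-EC, per-domain distribution classes (`widely` / `partially` /
#' `sparsely` / `absent`) transcribing the study narrative's qualitative
#' statements (e.g. the five PRPP-to-AIR steps widely distributed in all
#' three domains; PurP and PurO confined to Archaea; ThyA/ThyX's
#' complementary patterns). Clade fractions are not part of the fixture,
#' so `clade_fraction` is `NA`; only `dist_class` is meaningful.
#'
#' @return A `distribution_summary` data frame (long format: one row per
#'   enzyme x domain).
#' @export
load_qualitative_distribution <- function() {
  wide <- utils::read.delim(ancenz_file("distribution_qualitative.tsv"),
                            stringsAsFactors = FALSE)
  doms <- cellular_domains()
  out <- do.call(rbind, lapply(doms, function(d) {
    data.frame(enzyme = wide$enzyme, domain = d,
               n_clades = NA_integer_, present_clades = NA_integer_,
               clade_fraction = NA_real_, dist_class = wide[[d]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("distribution_summary", "data.frame")
  out
}
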