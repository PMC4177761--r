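#' Construct a taxonomy
#'
#' A taxonomy is the nested hierarchy domain -> clade -> genus -> genome
#' with per-genome metadata used by the inclusion rule (gene count,
#' obligate-parasite flag). Clades are the intermediate divisions (JGI-IMG
#' style categories) that act as the denominator of the wide-distribution
#' rule. The hierarchy must be a tree: every genus belongs to exactly one
#' clade, every clade to exactly one domain.
#'
#' @param records Data frame with columns `genome_id`, `domain` (one of
#'   `Bacteria`, `Archaea`, `Eukarya`), `clade`, `genus`, `gene_count`,
#'   `obligate_parasite` (logical or TRUE/FALSE strings).
#' @return An object of class `taxonomy` (the validated record table).
#' @export
taxonomy <- function(records) {
  need <- c("genome_id", "domain", "clade", "genus", "gene_count",
            "obligate_parasite")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("taxonomy lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[need]
  records$gene_count <- as.integer(records$gene_count)
  records$obligate_parasite <- as.logical(records$obligate_parasite)
  if (anyDuplicated(records$genome_id)) {
    stop("duplicate genome_id: ",
         paste(unique(records$genome_id[duplicated(records$genome_id)]),
               collapse = ", "))
  }
  bad_dom <- setdiff(unique(records$domain), cellular_domains())
  if (length(bad_dom)) {
    stop("unknown domain(s): ", paste(bad_dom, collapse = ", "),
         " (expected ", paste(cellular_domains(), collapse = "/"), ")")
  }
  if (any(records$gene_count < 0L) || anyNA(records$gene_count)) {
    stop("gene_count must be a non-negative integer")
  }
  if (anyNA(records$obligate_parasite)) {
    stop("obligate_parasite must be TRUE/FALSE")
  }
  g2c <- unique(records[c("genus", "clade")])
  dup_g <- unique(g2c$genus[duplicated(g2c$genus)])
  if (length(dup_g)) {
    stop("genus mapped to more than one clade: ",
         paste(dup_g, collapse = ", "))
  }
  c2d <- unique(records[c("clade", "domain")])
  dup_c <- unique(c2d$clade[duplicated(c2d$clade)])
  if (length(dup_c)) {
    stop("clade mapped to more than one domain: ",
         paste(dup_c, collapse = ", "))
  }
  class(records) <- c("taxonomy", "data.frame")
  records
}

#' The three cellular domains
#' @return Character vector `c("Bacteria", "Archaea", "Eukarya")`.
#' @export
cellular_domains <- function() c("Bacteria", "Archaea", "Eukarya")

#' Read a taxonomy table
#'
#' @param path TSV with header `genome_id`, `domain`, `clade`, `genus`,
#'   `gene_count`, `obligate_parasite`.
#' @return A [taxonomy()] object.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy table not found: ", path)
  taxonomy(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a taxonomy table
#' @param tax A [taxonomy()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(as.data.frame(tax), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> %d genomes, %d genera, %d clades, %d domain(s)\n",
              nrow(x), length(unique(x$genus)), length(unique(x$clade)),
              length(unique(x$domain))))
  invisible(x)
}

#' Apply the genome inclusion rule
#'
#' Removes genomes flagged as obligate parasites and genomes with fewer
#' than `config$min_genes` genes (reduced genomes), the guard against
#' massive-gene-loss bias in the presence/absence statistics. Genera and
#' clades emptied by the filter disappear from the hierarchy, so all
#' downstream denominators (the >50%-of-clades rule in particular) count
#' surviving clades only.
#'
#' @param tax A [taxonomy()].
#' @param config A [filter_config()]; only `min_genes` is used.
#' @return The filtered [taxonomy()]. The attribute `removed` holds counts
#'   by reason (`parasite`, `reduced`; a genome failing both rules counts
#'   under both).
#' @export
filter_genomes <- function(tax, config = filter_config()) {
  config <- as_filter_config(config)
  parasite <- tax$obligate_parasite
  reduced <- tax$gene_count < config$min_genes
  keep <- !(parasite | reduced)
  out <- tax[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("no genomes survive the inclusion rule")
  }
  attr(out, "removed") <- c(parasite = sum(parasite),
                            reduced = sum(reduced),
                            total = sum(!keep))
  class(out) <- c("taxonomy", "data.frame")
  out
}

# genus -> clade and clade -> domain lookups as named character vectors
genus_index <- function(tax) {
  u <- unique(as.data.frame(tax)[c("genus", "clade")])
  stats::setNames(u$clade, u$genus)
}

clade_index <- function(tax) {
  u <- unique(as.data.frame(tax)[c("clade", "domain")])
  stats::setNames(u$domain, u$clade)
}
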