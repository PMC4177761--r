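#' Write an average (or presence) matrix as TSV
#'
#' Layout mirrors the supplementary-matrix convention: column 1 is the
#' enzyme identifier, subsequent columns are taxonomic divisions, rows
#' sorted EC-numerically (so 2.4.2.14 precedes 2.7.6.1). Note the matrix
#' is transposed on disk relative to the in-memory orientation (in memory
#' rows are taxa, on disk rows are enzymes). Values are written at full
#' precision and round-trip exactly through [read_matrix()].
#'
#' @param a Matrix with taxa as rows, enzymes as columns.
#' @param path Output TSV path.
#' @param id_column Header for the enzyme id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(a, path, id_column = "enzyme") {
  if (is.null(dim(a)) || nrow(a) == 0L || ncol(a) == 0L) {
    stop("matrix must be non-empty")
  }
  t_a <- t(a)
  t_a <- t_a[match(sort_ec(rownames(t_a)), rownames(t_a)), , drop = FALSE]
  df <- data.frame(rownames(t_a), t_a, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  vals <- format(t_a, digits = 17, trim = TRUE, scientific = FALSE)
  for (j in seq_len(ncol(t_a))) df[[j + 1L]] <- vals[, j]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#'
#' @param path TSV path.
#' @param level Level attribute to restore (`"genus"`, `"clade"`, ...).
#' @return Numeric matrix, taxa as rows, enzymes as columns.
#' @export
read_matrix <- function(path, level = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  out <- t(m)
  if (!is.null(level)) attr(out, "level") <- level
  out
}

#' Run configuration for the end-to-end pipeline
#'
#' @param hits_manifest Path to the hit-table manifest TSV (or a single
#'   13-column hit table via `hits_table`).
#' @param hits_table Optional single hit table with a genome_id column;
#'   exactly one of `hits_manifest`/`hits_table` must be given.
#' @param taxonomy_path Path to the taxonomy TSV.
#' @param catalogue_path Path to the profile catalogue TSV.
#' @param pathway_paths Named character vector of pathway TSVs to
#'   annotate (may be empty).
#' @param out_dir Output directory (created if missing).
#' @param config A [filter_config()].
#' @param ec_level Report distributions/LCA at EC level (after
#'   subunit/analog resolution) rather than per profile. Profile-level
#'   matrices are exported either way.
#' @return Object of class `run_config`.
#' @export
run_config <- function(hits_manifest = NULL, hits_table = NULL,
                       taxonomy_path, catalogue_path,
                       pathway_paths = character(), out_dir,
                       config = filter_config(), ec_level = TRUE) {
  if (is.null(hits_manifest) == is.null(hits_table)) {
    stop("supply exactly one of `hits_manifest` or `hits_table`")
  }
  for (p in c(hits_manifest, hits_table, taxonomy_path, catalogue_path,
              pathway_paths)) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(list(hits_manifest = hits_manifest, hits_table = hits_table,
                 taxonomy_path = taxonomy_path,
                 catalogue_path = catalogue_path,
                 pathway_paths = pathway_paths, out_dir = out_dir,
                 config = as_filter_config(config), ec_level = ec_level),
            class = "run_config")
}

#' Run the full inference pipeline
#'
#' Reads hits, catalogue and taxonomy; applies the genome inclusion rule
#' and the hit filters; builds genome presence, genus and clade averages;
#' classifies distributions; attributes enzymes to the LCA; annotates any
#' supplied pathway graphs; and writes every artifact plus a
#' machine-readable run log (thresholds used, record counts in/out at
#' each stage) under `cfg$out_dir`.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory artifacts (`taxonomy`,
#'   `presence`, `genus_avg`, `clade_avg`, `summary`, `lca`, `pathways`,
#'   `log`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  fc <- cfg$config
  log <- list(thresholds = unclass(fc))

  catalogue <- read_catalogue(cfg$catalogue_path)
  tax <- read_taxonomy(cfg$taxonomy_path)
  log$genomes_in <- nrow(tax)
  tax <- filter_genomes(tax, fc)
  log$genomes_removed <- as.list(attr(tax, "removed"))
  log$genomes_kept <- nrow(tax)

  hits <- if (!is.null(cfg$hits_manifest)) {
    read_hit_manifest(cfg$hits_manifest)
  } else {
    read_hits(cfg$hits_table)
  }
  log$hits_in <- nrow(hits)
  hits <- hits[hits$genome_id %in% tax$genome_id, , drop = FALSE]
  log$hits_in_kept_genomes <- nrow(hits)
  hits <- filter_hits(hits, catalogue, fc)
  log$hits_retained <- nrow(hits)
  utils::write.table(hits, file.path(cfg$out_dir, "filtered_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  presence <- build_presence(hits, tax, catalogue)
  write_matrix(presence, file.path(cfg$out_dir, "presence_profile.tsv"),
               id_column = "profile_id")
  enz_matrix <- if (cfg$ec_level) ec_presence(presence, catalogue) else presence
  gm <- genus_average(enz_matrix, tax)
  cm <- clade_average(gm, tax)
  write_matrix(gm, file.path(cfg$out_dir, "genus_average.tsv"))
  write_matrix(cm, file.path(cfg$out_dir, "clade_average.tsv"))
  # profile-level clade averages mirror the per-profile supplementary view
  cm_profile <- clade_average(genus_average(presence, tax), tax)
  write_matrix(cm_profile,
               file.path(cfg$out_dir, "clade_average_profile.tsv"),
               id_column = "profile_id")

  summary <- classify_distribution(cm, tax, fc)
  lca <- infer_lca(summary)
  summary$lca_verdict <- lca$lca_verdict[match(summary$enzyme, lca$enzyme)]
  utils::write.table(summary,
                     file.path(cfg$out_dir, "distribution_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(lca[lca$lca_verdict, "enzyme", drop = FALSE],
                     file.path(cfg$out_dir, "lca_enzymes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log$enzymes_classified <- nrow(lca)
  log$lca_attributed <- sum(lca$lca_verdict)

  pathways <- list()
  for (nm in names(cfg$pathway_paths)) {
    g <- read_pathway(cfg$pathway_paths[[nm]])
    g <- annotate_steps(g, lca)
    pathway_to_json(g, file.path(cfg$out_dir, paste0("pathway_", nm, ".json")))
    pathway_to_dot(g, file.path(cfg$out_dir, paste0("pathway_", nm, ".dot")))
    pathways[[nm]] <- g
  }
  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(taxonomy = tax, presence = presence, genus_avg = gm,
                 clade_avg = cm, summary = summary, lca = lca,
                 pathways = pathways, log = log))
}
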