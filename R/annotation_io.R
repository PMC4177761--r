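#' Read a profile-search hit table
#'
#' Parses BLAST tabular output ("outfmt 6", 12 columns) where the subject
#' is an enzyme profile: `qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore`. Subject coordinates
#' (`sstart`/`send`) are 1-based inclusive positions on the profile. An
#' optional 13th column gives the genome id per row; otherwise supply one
#' `genome_id` for the whole file (one-file-per-genome layout).
#'
#' Malformed rows (wrong column count, non-numeric E-value/score, reversed
#' coordinate spans, negative E-values) are dropped with a warning listing
#' their line numbers; well-formed rows are returned in file order.
#'
#' @param path Path to a tab-separated hit table.
#' @param genome_id Genome identifier applied to every row when the file
#'   has no 13th column.
#' @return A data frame of class `profile_hits` with columns `genome_id`,
#'   `query_id`, `profile_id`, `percent_identity`, `align_length`,
#'   `mismatch`, `gapopen`, `query_start`, `query_end`, `profile_start`,
#'   `profile_end`, `evalue`, `bitscore`.
#' @export
read_hits <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  nonblank <- nzchar(trimws(lines))
  if (!any(nonblank)) {
    warning("empty hit table: ", path)
    return(empty_hits())
  }
  keep_lines <- which(nonblank)
  fields <- strsplit(lines[keep_lines], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  shape_ok <- ncols == 12L | ncols == 13L
  fmat <- matrix(NA_character_, nrow = length(fields), ncol = 13L)
  for (i in which(shape_ok)) fmat[i, seq_len(ncols[i])] <- fields[[i]]
  num <- suppressWarnings(
    matrix(as.numeric(fmat[, 3:12, drop = FALSE]), ncol = 10L)
  )
  value_ok <- shape_ok &
    !apply(is.na(num), 1L, any) &
    num[, 2] >= 1 &                 # align_length
    num[, 5] <= num[, 6] &          # query span
    num[, 7] <= num[, 8] &          # profile span
    num[, 9] >= 0                   # evalue
  value_ok[is.na(value_ok)] <- FALSE
  if (any(!value_ok)) {
    warning(sprintf("dropped %d malformed hit row(s) at line(s) %s in %s",
                    sum(!value_ok),
                    paste(keep_lines[!value_ok], collapse = ", "), path))
  }
  if (!any(value_ok)) return(empty_hits())
  fmat <- fmat[value_ok, , drop = FALSE]
  num <- num[value_ok, , drop = FALSE]
  gid <- fmat[, 13]
  if (anyNA(gid)) {
    if (is.null(genome_id)) {
      stop("hit table ", path,
           " has no genome_id column and no `genome_id` was supplied")
    }
    gid[is.na(gid)] <- genome_id
  }
  out <- data.frame(
    genome_id = gid,
    query_id = fmat[, 1],
    profile_id = fmat[, 2],
    percent_identity = num[, 1],
    align_length = as.integer(num[, 2]),
    mismatch = as.integer(num[, 3]),
    gapopen = as.integer(num[, 4]),
    query_start = as.integer(num[, 5]),
    query_end = as.integer(num[, 6]),
    profile_start = as.integer(num[, 7]),
    profile_end = as.integer(num[, 8]),
    evalue = num[, 9],
    bitscore = num[, 10],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("profile_hits", "data.frame")
  out
}

empty_hits <- function() {
  out <- data.frame(
    genome_id = character(), query_id = character(), profile_id = character(),
    percent_identity = numeric(), align_length = integer(),
    mismatch = integer(), gapopen = integer(),
    query_start = integer(), query_end = integer(),
    profile_start = integer(), profile_end = integer(),
    evalue = numeric(), bitscore = numeric(),
    stringsAsFactors = FALSE
  )
  class(out) <- c("profile_hits", "data.frame")
  out
}

#' Read hit tables for many genomes via a manifest
#'
#' @param manifest_path TSV with header `genome_id<TAB>path`; each path is
#'   a per-genome hit table (resolved relative to the manifest's
#'   directory when not absolute).
#' @return A single `profile_hits` data frame, rows in manifest order.
#' @export
read_hit_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path)
  }
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "path") %in% names(man))) {
    stop("manifest must have columns genome_id, path")
  }
  base <- dirname(manifest_path)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(base, man$path))
  parts <- suppressWarnings(
    mapply(read_hits, paths, man$genome_id, SIMPLIFY = FALSE)
  )
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("profile_hits", "data.frame")
  out
}

#' Read the profile catalogue
#'
#' The catalogue maps every searched profile to its EC number, its role in
#' resolving an enzymatic step, its structural superfamily and its length.
#' Roles: `single` (one profile, one activity); `subunit` (the profiles of
#' a `group_id` are components of one complex and are combined with AND,
#' e.g. PurQ + PurL for EC 6.3.5.3); `analog` (non-homologous
#' isofunctional families combined with OR, e.g. PurN and PurT for EC
#' 2.1.2.2); `paralog` (same-family variants, also OR).
#'
#' @param path TSV with columns `profile_id`, `ec_number`, `role`,
#'   `group_id`, `superfamily`, `profile_length`.
#' @return A data frame of class `profile_catalogue`.
#' @export
read_catalogue <- function(path) {
  if (!file.exists(path)) stop("catalogue not found: ", path)
  cat_df <- utils::read.delim(path, stringsAsFactors = FALSE,
                              colClasses = "character")
  validate_catalogue(cat_df)
}

#' Validate (and class) a profile catalogue data frame
#'
#' @param cat_df Data frame with the catalogue columns (see
#'   [read_catalogue()]).
#' @return The validated data frame, classed `profile_catalogue`.
#' @export
validate_catalogue <- function(cat_df) {
  need <- c("profile_id", "ec_number", "role", "group_id",
            "superfamily", "profile_length")
  missing_cols <- setdiff(need, names(cat_df))
  if (length(missing_cols)) {
    stop("catalogue lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  cat_df$profile_length <- as.integer(cat_df$profile_length)
  if (anyDuplicated(cat_df$profile_id)) {
    stop("duplicate profile_id in catalogue: ",
         paste(unique(cat_df$profile_id[duplicated(cat_df$profile_id)]),
               collapse = ", "))
  }
  if (any(cat_df$profile_length < 1L, na.rm = TRUE) ||
      anyNA(cat_df$profile_length)) {
    stop("profile_length must be a positive integer for every profile")
  }
  bad_ec <- !grepl("^[^.]+\\.[^.]+\\.[^.]+\\.[^.]+$", cat_df$ec_number)
  if (any(bad_ec)) {
    stop("ec_number must have 4 dot-separated fields; offending: ",
         paste(unique(cat_df$ec_number[bad_ec]), collapse = ", "))
  }
  ok_roles <- c("single", "subunit", "analog", "paralog")
  if (!all(cat_df$role %in% ok_roles)) {
    stop("role must be one of ", paste(ok_roles, collapse = "/"))
  }
  grouped <- cat_df$role != "single"
  if (any(grouped & !nzchar(cat_df$group_id))) {
    stop("subunit/analog/paralog profiles need a group_id")
  }
  gsz <- table(cat_df$group_id[grouped])
  lone <- names(gsz)[gsz < 2L]
  if (length(lone)) {
    stop("group(s) with fewer than 2 member profiles: ",
         paste(lone, collapse = ", "))
  }
  # a group never spans two roles or (for subunits) two ECs
  for (g in unique(cat_df$group_id[grouped])) {
    sel <- cat_df$group_id == g & grouped
    if (length(unique(cat_df$role[sel])) != 1L) {
      stop("group ", g, " mixes roles")
    }
    if (cat_df$role[sel][1] == "subunit" &&
        length(unique(cat_df$ec_number[sel])) != 1L) {
      stop("subunit group ", g, " spans several EC numbers")
    }
  }
  class(cat_df) <- c("profile_catalogue", "data.frame")
  cat_df
}

#' Fraction of a profile covered by a hit
#'
#' Coverage is computed relative to the profile: the 1-based inclusive
#' aligned span on the profile divided by the profile length,
#' `(profile_end - profile_start + 1) / profile_length`. Query coverage is
#' ignored.
#'
#' @param hits A `profile_hits` data frame (or any data frame with
#'   `profile_start`/`profile_end` columns).
#' @param profile_length Profile length(s) in residues, recycled along
#'   rows of `hits`.
#' @return Numeric vector of coverages in `(0, 1]`.
#' @export
profile_coverage <- function(hits, profile_length) {
  span <- hits$profile_end - hits$profile_start + 1L
  too_long <- hits$profile_end > profile_length
  if (any(too_long)) {
    stop("alignment end beyond profile length for profile(s): ",
         paste(unique(hits$profile_id[too_long]), collapse = ", "))
  }
  span / profile_length
}

#' Filter profile hits by E-value, profile coverage and best-hit rule
#'
#' Keeps hits with `evalue <= evalue_max` and profile coverage
#' `>= coverage_min` (both thresholds inclusive), then resolves the single
#' best surviving hit per (genome, query, profile) — or per (genome,
#' query) when `config$exclusive_best_hit` is `TRUE`. Best means lowest
#' E-value; ties broken by highest bitscore, then lowest `profile_start`,
#' then lexicographic `profile_id`, so the output is deterministic
#' whatever the input order.
#'
#' @param hits A `profile_hits` data frame.
#' @param catalogue A `profile_catalogue`; every `profile_id` in `hits`
#'   must appear in it (supplies the coverage denominator).
#' @param config A [filter_config()].
#' @return The retained subset of `hits`, re-sorted deterministically.
#' @export
filter_hits <- function(hits, catalogue, config = filter_config()) {
  config <- as_filter_config(config)
  catalogue <- validate_catalogue(as.data.frame(catalogue))
  if (nrow(hits) == 0L) return(hits)
  idx <- match(hits$profile_id, catalogue$profile_id)
  if (anyNA(idx)) {
    stop("hit(s) reference unknown profile(s): ",
         paste(unique(hits$profile_id[is.na(idx)]), collapse = ", "))
  }
  cov <- profile_coverage(hits, catalogue$profile_length[idx])
  keep <- hits$evalue <= config$evalue_max & cov >= config$coverage_min
  out <- hits[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    rownames(out) <- NULL
    return(out)
  }
  key <- if (config$exclusive_best_hit) {
    paste(out$genome_id, out$query_id, sep = "\r")
  } else {
    paste(out$genome_id, out$query_id, out$profile_id, sep = "\r")
  }
  ord <- order(key, out$evalue, -out$bitscore, out$profile_start,
               out$profile_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  key <- key[ord]
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
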