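#' Binary presence/absence matrix from retained hits
#'
#' One row per genome in the taxonomy, one column per catalogue profile;
#' a cell is 1 when the genome has at least one retained hit to the
#' profile. Genomes without any hit get all-zero rows, so the matrix shape
#' is fixed by the taxonomy and the catalogue, not by the hit set.
#'
#' @param hits Retained hits, i.e. the output of [filter_hits()].
#' @param tax A [taxonomy()] (normally already through [filter_genomes()]).
#' @param catalogue A `profile_catalogue`.
#' @return Integer 0/1 matrix, genomes x profiles, with attribute
#'   `level = "genome"`.
#' @export
build_presence <- function(hits, tax, catalogue) {
  genomes <- tax$genome_id
  profiles <- catalogue$profile_id
  m <- matrix(0L, nrow = length(genomes), ncol = length(profiles),
              dimnames = list(genomes, profiles))
  if (nrow(hits) > 0L) {
    gi <- match(hits$genome_id, genomes)
    if (anyNA(gi)) {
      stop("hit(s) from genome(s) absent from the taxonomy: ",
           paste(unique(hits$genome_id[is.na(gi)]), collapse = ", "))
    }
    pi <- match(hits$profile_id, profiles)
    if (anyNA(pi)) {
      stop("hit(s) to profile(s) absent from the catalogue: ",
           paste(unique(hits$profile_id[is.na(pi)]), collapse = ", "))
    }
    m[cbind(gi, pi)] <- 1L
  }
  attr(m, "level") <- "genome"
  m
}

#' Collapse profile columns to EC-level presence
#'
#' Resolves multi-profile enzymatic steps: within an EC number, each
#' subunit group contributes presence only when ALL of its member profiles
#' are present (the complex needs every component, e.g. PurQ and PurL for
#' EC 6.3.5.3); analog and paralog groups, and single profiles, contribute
#' when ANY member is present (isofunctional alternatives). The EC is
#' present in a genome when any of its contributing units evaluates true.
#'
#' @param m Genome-level presence matrix from [build_presence()].
#' @param catalogue A `profile_catalogue` covering every column of `m`.
#' @return Integer 0/1 matrix, genomes x EC numbers, columns in EC-numeric
#'   order.
#' @export
ec_presence <- function(m, catalogue) {
  catalogue <- validate_catalogue(as.data.frame(catalogue))
  miss <- setdiff(colnames(m), catalogue$profile_id)
  if (length(miss)) {
    stop("matrix column(s) absent from catalogue: ",
         paste(miss, collapse = ", "))
  }
  ecs <- sort_ec(unique(catalogue$ec_number))
  out <- matrix(0L, nrow = nrow(m), ncol = length(ecs),
                dimnames = list(rownames(m), ecs))
  for (ec in ecs) {
    sub <- catalogue[catalogue$ec_number == ec, , drop = FALSE]
    sub <- sub[sub$profile_id %in% colnames(m), , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("EC ", ec, " has no profile present in the matrix")
    }
    # each unit is a subunit group (AND) or an individual OR-profile
    unit_hit <- rep(FALSE, nrow(m))
    subunit_groups <- unique(sub$group_id[sub$role == "subunit"])
    for (g in subunit_groups) {
      members <- sub$profile_id[sub$role == "subunit" & sub$group_id == g]
      block <- m[, members, drop = FALSE]
      unit_hit <- unit_hit | rowSums(block) == length(members)
    }
    or_profiles <- sub$profile_id[sub$role != "subunit"]
    if (length(or_profiles)) {
      unit_hit <- unit_hit | rowSums(m[, or_profiles, drop = FALSE]) > 0L
    }
    out[, ec] <- as.integer(unit_hit)
  }
  attr(out, "level") <- attr(m, "level") %||% "genome"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genus-level average presence
#'
#' First normalization step: the unweighted mean of presence over each
#' genus's genomes, removing the redundancy of heavily sequenced species.
#'
#' @param m Genome-level presence (or EC-level presence) matrix.
#' @param tax A [taxonomy()] covering every row of `m`.
#' @return Numeric matrix in `[0, 1]`, genera x enzymes, attribute
#'   `level = "genus"`.
#' @export
genus_average <- function(m, tax) {
  idx <- match(rownames(m), tax$genome_id)
  if (anyNA(idx)) {
    stop("matrix row(s) absent from taxonomy: ",
         paste(rownames(m)[is.na(idx)], collapse = ", "))
  }
  grp <- tax$genus[idx]
  sums <- rowsum(m + 0, grp)
  n <- as.vector(table(grp)[rownames(sums)])
  avg <- sums / n
  attr(avg, "level") <- "genus"
  avg
}

#' Clade-level average presence
#'
#' Second normalization step: the unweighted mean of genus averages within
#' each clade. Every genus carries weight 1 regardless of how many genomes
#' it holds, so a clade value is NOT the pooled fraction of its genomes.
#'
#' @param g Genus-level matrix from [genus_average()].
#' @param tax A [taxonomy()].
#' @return Numeric matrix in `[0, 1]`, clades x enzymes, attribute
#'   `level = "clade"`.
#' @export
clade_average <- function(g, tax) {
  if (!identical(attr(g, "level"), "genus")) {
    stop("`g` must be a genus-level average matrix")
  }
  g2c <- genus_index(tax)
  cl <- g2c[rownames(g)]
  if (anyNA(cl)) {
    stop("genus row(s) absent from taxonomy: ",
         paste(rownames(g)[is.na(cl)], collapse = ", "))
  }
  sums <- rowsum(g + 0, as.vector(cl))
  n <- as.vector(table(as.vector(cl))[rownames(sums)])
  avg <- sums / n
  attr(avg, "level") <- "clade"
  avg
}

#' Pooled (genome-weighted) per-domain presence fraction
#'
#' Companion diagnostic to the two-step normalization: the plain fraction
#' of a domain's genomes carrying the enzyme. Never feeds classification;
#' exposed so the effect of genus/clade weighting can be inspected.
#'
#' @param m Genome-level presence matrix.
#' @param tax A [taxonomy()].
#' @return Numeric matrix, domains x enzymes.
#' @export
pooled_domain_fraction <- function(m, tax) {
  idx <- match(rownames(m), tax$genome_id)
  if (anyNA(idx)) stop("matrix row(s) absent from taxonomy")
  dom <- tax$domain[idx]
  sums <- rowsum(m + 0, dom)
  n <- as.vector(table(dom)[rownames(sums)])
  sums / n
}

#' Classify taxonomic distributions per domain
#'
#' A clade counts as "present" for an enzyme when its clade-level average
#' strictly exceeds `config$presence_cutoff` (default 0: any retained
#' member genus suffices). Per domain, `clade_fraction` = present clades /
#' clades of the domain; the class is `widely` when the fraction strictly
#' exceeds `config$wide_fraction` (present in more than 50 percent of the
#' domain's clades by default), `absent` at 0, `sparsely` in
#' `(0, sparse_fraction]`, `partially` otherwise.
#'
#' @param cm Clade-level matrix from [clade_average()].
#' @param tax A [taxonomy()].
#' @param config A [filter_config()].
#' @return Data frame of class `distribution_summary` with columns
#'   `enzyme`, `domain`, `n_clades`, `present_clades`, `clade_fraction`,
#'   `dist_class`.
#' @export
classify_distribution <- function(cm, tax, config = filter_config()) {
  config <- as_filter_config(config)
  if (!identical(attr(cm, "level"), "clade")) {
    stop("`cm` must be a clade-level average matrix")
  }
  c2d <- clade_index(tax)
  dom_of_row <- c2d[rownames(cm)]
  if (anyNA(dom_of_row)) {
    stop("clade row(s) absent from taxonomy: ",
         paste(rownames(cm)[is.na(dom_of_row)], collapse = ", "))
  }
  domains <- intersect(cellular_domains(), unique(as.vector(dom_of_row)))
  empty <- setdiff(unique(tax$domain), domains)
  if (length(empty)) {
    stop("domain(s) with zero clades in the matrix: ",
         paste(empty, collapse = ", "))
  }
  res <- list()
  for (d in domains) {
    rows <- cm[dom_of_row == d, , drop = FALSE]
    present <- colSums(rows > config$presence_cutoff)
    frac <- present / nrow(rows)
    cls <- ifelse(frac > config$wide_fraction, "widely",
           ifelse(frac == 0, "absent",
           ifelse(frac <= config$sparse_fraction, "sparsely", "partially")))
    res[[d]] <- data.frame(
      enzyme = colnames(cm), domain = d,
      n_clades = nrow(rows), present_clades = as.integer(present),
      clade_fraction = as.numeric(frac), dist_class = as.character(cls),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("distribution_summary", "data.frame")
  out
}

#' LCA attribution from distribution classes
#'
#' An enzyme is attributed to the last common ancestor when it is classed
#' `widely` distributed in all three cellular domains. Enzymes confined to
#' one or two domains, or only partially/sparsely distributed somewhere,
#' are not attributed.
#'
#' @param summary A `distribution_summary` from [classify_distribution()],
#'   covering all three domains for every enzyme.
#' @return Data frame with columns `enzyme`, `lca_verdict` (logical), one
#'   row per enzyme, in the enzyme order of `summary`.
#' @export
infer_lca <- function(summary) {
  doms <- cellular_domains()
  missing_dom <- setdiff(doms, unique(summary$domain))
  if (length(missing_dom)) {
    stop("summary lacks domain(s): ", paste(missing_dom, collapse = ", "))
  }
  enzymes <- unique(summary$enzyme)
  wide <- vapply(enzymes, function(e) {
    sub <- summary[summary$enzyme == e, , drop = FALSE]
    if (!all(doms %in% sub$domain)) {
      stop("enzyme ", e, " lacks a classification for domain(s): ",
           paste(setdiff(doms, sub$domain), collapse = ", "))
    }
    all(sub$dist_class[match(doms, sub$domain)] == "widely")
  }, logical(1))
  data.frame(enzyme = enzymes, lca_verdict = as.logical(wide),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sort identifiers in EC-numeric order
#'
#' Orders dotted identifiers field-wise and numerically (2.4.2.14 before
#' 2.7.6.1, and 2.4.2.9 before 2.4.2.14). Non-numeric fields (e.g.
#' preliminary "n" sub-numbers) sort after numeric ones, alphabetically.
#'
#' @param ids Character vector of dotted identifiers.
#' @return `ids`, sorted.
#' @export
sort_ec <- function(ids) {
  ids <- unique(ids)
  parts <- strsplit(ids, ".", fixed = TRUE)
  maxlen <- max(lengths(parts))
  keys <- lapply(seq_len(maxlen), function(i) {
    f <- vapply(parts, function(p) if (length(p) >= i) p[i] else "",
                character(1))
    num <- suppressWarnings(as.numeric(f))
    list(is_char = is.na(num) & nzchar(f), num = ifelse(is.na(num), Inf, num), chr = f)
  })
  ord_args <- list()
  for (k in keys) {
    ord_args <- c(ord_args, list(k$num, k$chr))
  }
  ids[do.call(order, ord_args)]
}
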