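#' Scenario configuration for the synthetic generator
#'
#' Describes a simulated comparative-genomics study: a balanced
#' three-domain taxonomy and a presence/absence history built from
#' ancestral presence with per-genome loss, domain-restricted innovation,
#' horizontal transfer noise, and parasite genome reduction. The defaults
#' are the study conditions used throughout the package's validation: 10
#' clades x 3 genera x 3 genomes per domain (270 genomes), 50 ancestral
#' enzymes, independent per-genome loss probability 0.2.
#'
#' @param n_clades_per_domain,n_genera_per_clade,n_genomes_per_genus
#'   Hierarchy sizes (each >= 1).
#' @param ancestral_enzymes Character vector of enzyme (profile) ids
#'   present in the root ancestor. Default `"anc001"..."anc050"`.
#' @param loss_prob Per-genome probability that an ancestral enzyme was
#'   lost on the lineage to that genome (i.i.d. across genomes).
#' @param genus_loss_prob Optional lineage-correlated loss: probability
#'   that a whole genus lost the enzyme before the per-genome draws.
#'   Clustered loss is the realistic stressor for the >50%-of-clades
#'   rule; default 0 (pure i.i.d. loss).
#' @param domain_gains Named list `enzyme -> list(domain=, prob=)`:
#'   enzymes absent from the ancestor that arose within one domain and
#'   occur in each of that domain's genomes with probability `prob`.
#' @param hgt_rate Per genome x non-ancestral-enzyme probability of a
#'   sporadic horizontal acquisition anywhere in the taxonomy.
#' @param parasite_fraction Fraction of genomes flagged obligate parasites
#'   and given gene counts below 1,000 (so the inclusion rule removes
#'   them).
#' @param seed Integer seed; all sampling flows through it, so equal
#'   seeds give byte-identical outputs.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(n_clades_per_domain = 10L,
                            n_genera_per_clade = 3L,
                            n_genomes_per_genus = 3L,
                            ancestral_enzymes = sprintf("anc%03d", 1:50),
                            loss_prob = 0.2,
                            genus_loss_prob = 0,
                            domain_gains = list(),
                            hgt_rate = 0,
                            parasite_fraction = 0,
                            seed = 1L) {
  stopifnot(
    n_clades_per_domain >= 1, n_genera_per_clade >= 1,
    n_genomes_per_genus >= 1,
    loss_prob >= 0, loss_prob <= 1,
    genus_loss_prob >= 0, genus_loss_prob <= 1,
    hgt_rate >= 0, hgt_rate <= 1,
    parasite_fraction >= 0, parasite_fraction <= 1,
    is.numeric(seed), length(seed) == 1L
  )
  gained <- names(domain_gains)
  for (e in gained) {
    spec <- domain_gains[[e]]
    if (!all(c("domain", "prob") %in% names(spec)) ||
        !spec$domain %in% cellular_domains() ||
        spec$prob < 0 || spec$prob > 1) {
      stop("domain_gains[['", e,
           "']] must be list(domain = <cellular domain>, prob = <0..1>)")
    }
  }
  both <- intersect(gained, ancestral_enzymes)
  if (length(both)) {
    stop("enzyme(s) listed both ancestral and domain-gain: ",
         paste(both, collapse = ", "))
  }
  structure(
    list(n_clades_per_domain = as.integer(n_clades_per_domain),
         n_genera_per_clade = as.integer(n_genera_per_clade),
         n_genomes_per_genus = as.integer(n_genomes_per_genus),
         ancestral_enzymes = as.character(ancestral_enzymes),
         loss_prob = loss_prob, genus_loss_prob = genus_loss_prob,
         domain_gains = domain_gains, hgt_rate = hgt_rate,
         parasite_fraction = parasite_fraction, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

with_scenario_seed <- function(cfg, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((cfg$seed + offset) %% .Machine$integer.max)
  force(expr)
}

#' Simulate a balanced three-domain taxonomy
#'
#' Deterministic ids given the seed: genomes are named
#' `<domain_letter><clade>_<genus>_<genome>` (e.g. `B03_2_1`). A
#' `parasite_fraction` of genomes, drawn uniformly, are flagged obligate
#' parasites with gene counts in `[300, 999]`; all other genomes get gene
#' counts in `[1000, 8000]`.
#'
#' @param cfg A [scenario_config()].
#' @return A [taxonomy()].
#' @export
simulate_taxonomy <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_scenario_seed(cfg, 101L, {
    rows <- expand.grid(
      genome = seq_len(cfg$n_genomes_per_genus),
      genus = seq_len(cfg$n_genera_per_clade),
      clade = seq_len(cfg$n_clades_per_domain),
      domain = cellular_domains(),
      stringsAsFactors = FALSE
    )
    letter <- substr(rows$domain, 1, 1)
    clade_id <- sprintf("%s%02d", letter, rows$clade)
    genus_id <- sprintf("%s_%d", clade_id, rows$genus)
    genome_id <- sprintf("%s_%d", genus_id, rows$genome)
    n <- nrow(rows)
    parasite <- stats::runif(n) < cfg$parasite_fraction
    gene_count <- ifelse(parasite,
                         sample(300:999, n, replace = TRUE),
                         sample(1000:8000, n, replace = TRUE))
    taxonomy(data.frame(
      genome_id = genome_id, domain = rows$domain, clade = clade_id,
      genus = genus_id, gene_count = gene_count,
      obligate_parasite = parasite, stringsAsFactors = FALSE
    ))
  })
}

#' Simulate enzyme presence/absence under a gain/loss history
#'
#' Ancestral enzymes start present in every genome and are lost
#' independently per genome with `loss_prob` (optionally preceded by
#' genus-level loss with `genus_loss_prob`, modelling lineage-correlated
#' loss). Domain-gain enzymes occur only within their domain, in each
#' genome with the stated probability. Horizontal transfer then sprinkles
#' non-ancestral enzymes anywhere at `hgt_rate`.
#'
#' @param tax A [taxonomy()], normally from [simulate_taxonomy()].
#' @param cfg A [scenario_config()].
#' @return List with `presence` (genomes x enzymes 0/1 matrix), `truth`
#'   (data frame `enzyme`, `truly_ancestral`) and `pre_noise` (the
#'   realized presence matrix before HGT noise).
#' @export
simulate_evolution <- function(tax, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  enzymes <- c(cfg$ancestral_enzymes, names(cfg$domain_gains))
  if (!length(enzymes)) stop("scenario defines no enzymes")
  with_scenario_seed(cfg, 202L, {
    n_g <- nrow(tax)
    m <- matrix(0L, nrow = n_g, ncol = length(enzymes),
                dimnames = list(tax$genome_id, enzymes))
    genera <- unique(tax$genus)
    for (e in cfg$ancestral_enzymes) {
      present <- rep(TRUE, n_g)
      if (cfg$genus_loss_prob > 0) {
        lost_genus <- genera[stats::runif(length(genera)) < cfg$genus_loss_prob]
        present[tax$genus %in% lost_genus] <- FALSE
      }
      present <- present & stats::runif(n_g) >= cfg$loss_prob
      m[, e] <- as.integer(present)
    }
    for (e in names(cfg$domain_gains)) {
      spec <- cfg$domain_gains[[e]]
      in_dom <- tax$domain == spec$domain
      m[in_dom, e] <- as.integer(stats::runif(sum(in_dom)) < spec$prob)
    }
    pre_noise <- m   # realized presence before HGT sprinkling
    if (cfg$hgt_rate > 0 && length(names(cfg$domain_gains))) {
      for (e in names(cfg$domain_gains)) {
        gained <- stats::runif(n_g) < cfg$hgt_rate
        m[, e] <- as.integer(m[, e] | gained)
      }
    }
    attr(m, "level") <- "genome"
    attr(pre_noise, "level") <- "genome"
    list(presence = m,
         truth = data.frame(
           enzyme = enzymes,
           truly_ancestral = enzymes %in% cfg$ancestral_enzymes,
           stringsAsFactors = FALSE
         ),
         pre_noise = pre_noise)
  })
}

#' Build a minimal catalogue for a set of simulated enzymes
#'
#' One `single` profile per enzyme id, EC-shaped identifiers, fixed
#' profile length 300. Convenience for scenarios that do not exercise
#' subunit/analog semantics.
#'
#' @param enzymes Character vector of enzyme ids.
#' @param profile_length Length assigned to every profile.
#' @return A `profile_catalogue`.
#' @export
simulated_catalogue <- function(enzymes, profile_length = 300L) {
  validate_catalogue(data.frame(
    profile_id = enzymes,
    ec_number = sprintf("9.9.9.%d", seq_along(enzymes)),
    role = "single", group_id = "", superfamily = "",
    profile_length = profile_length, stringsAsFactors = FALSE
  ))
}

#' Emit synthetic hit tables from a presence matrix
#'
#' The inverse of the filtering stage: every present (genome, profile)
#' cell emits one hit guaranteed to survive [filter_hits()] (E-value
#' log-uniform in `[1e-40, 1e-10]`, profile coverage >= 0.55); absent
#' cells emit, with probability `decoy_prob`, a decoy hit engineered to
#' fail exactly one threshold (E-value in `(1e-10, 1e-6]` with passing
#' coverage, or coverage in `[0.30, 0.55)` with passing E-value), so the
#' boundary logic of the filter is exercised. Round trip:
#' `build_presence(filter_hits(read_hit_manifest(manifest)))` reproduces
#' the matrix exactly.
#'
#' @param m Genome-level 0/1 presence matrix.
#' @param catalogue A `profile_catalogue` covering the columns of `m`
#'   (supplies profile lengths).
#' @param cfg A [scenario_config()] (for the seed).
#' @param dir Output directory; one hit TSV per genome plus
#'   `manifest.tsv`.
#' @param decoy_prob Decoy emission probability per absent cell.
#' @return Path to the manifest, invisibly.
#' @export
emit_hits <- function(m, catalogue, cfg, dir, decoy_prob = 0.05) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  catalogue <- validate_catalogue(as.data.frame(catalogue))
  plen <- stats::setNames(catalogue$profile_length, catalogue$profile_id)
  miss <- setdiff(colnames(m), names(plen))
  if (length(miss)) {
    stop("matrix column(s) absent from catalogue: ",
         paste(miss, collapse = ", "))
  }
  with_scenario_seed(cfg, 303L, {
    manifest <- data.frame(genome_id = rownames(m),
                           path = paste0(rownames(m), "_hits.tsv"),
                           stringsAsFactors = FALSE)
    for (gi in seq_len(nrow(m))) {
      genome <- rownames(m)[gi]
      rows <- character()
      for (p in colnames(m)) {
        len <- plen[[p]]
        if (m[gi, p] == 1L) {
          rows <- c(rows, hit_row(genome, p, len, kind = "true"))
        } else if (decoy_prob > 0 && stats::runif(1) < decoy_prob) {
          kind <- if (stats::runif(1) < 0.5) "decoy_evalue" else "decoy_coverage"
          rows <- c(rows, hit_row(genome, p, len, kind = kind))
        }
      }
      writeLines(rows, file.path(dir, manifest$path[gi]))
    }
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file.path(dir, "manifest.tsv"))
  })
}

# one BLAST-tabular row; `kind` decides which thresholds it satisfies
hit_row <- function(genome, profile, len, kind) {
  if (kind == "true") {
    evalue <- 10^stats::runif(1, -40, -10)
    span <- sample(ceiling(0.55 * len):len, 1L)
  } else if (kind == "decoy_evalue") {
    evalue <- 10^stats::runif(1, -9.9, -6)   # strictly above 1e-10
    span <- sample(ceiling(0.55 * len):len, 1L)
  } else {
    lo <- max(1L, ceiling(0.30 * len))
    hi <- ceiling(0.55 * len) - 1L           # strictly below 0.55
    if (hi < lo) {
      # profile too short for a coverage decoy; fail on E-value instead
      evalue <- 10^stats::runif(1, -9.9, -6)
      span <- len
    } else {
      evalue <- 10^stats::runif(1, -40, -10)
      span <- sample(lo:hi, 1L)
    }
  }
  start <- sample(seq_len(len - span + 1L), 1L)
  end <- start + span - 1L
  qlen <- span + sample(0:20, 1L)
  paste(
    sprintf("%s_q_%s", genome, profile),     # query id
    profile,
    sprintf("%.1f", stats::runif(1, 30, 95)),
    span, sample(0:30, 1L), sample(0:5, 1L),
    1L, qlen, start, end,
    format(evalue, digits = 6, scientific = TRUE),
    sprintf("%.1f", stats::runif(1, 60, 900)),
    sep = "\t"
  )
}
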