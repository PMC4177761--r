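# Independent oracles and small fixture builders used across the suite.

# Exact two-step (genus -> clade) nested mean, in rational arithmetic.
# Returns exact numerator and denominator matrices (clades x enzymes);
# all integers stay far below 2^53 at the instance sizes used, so double
# storage is exact.
rational_two_step <- function(m, tax) {
  clades <- unique(tax$clade)
  enz <- colnames(m)
  num <- den <- matrix(0, nrow = length(clades), ncol = length(enz),
                       dimnames = list(clades, enz))
  for (cl in clades) {
    genera <- unique(tax$genus[tax$clade == cl])
    sizes <- vapply(genera, function(g) sum(tax$genus == g), numeric(1))
    prod_n <- prod(sizes)
    for (j in seq_along(enz)) {
      total <- 0
      for (i in seq_along(genera)) {
        gsum <- sum(m[tax$genome_id[tax$genus == genera[i]], j])
        total <- total + gsum * prod_n / sizes[i]
      }
      num[cl, j] <- total
      den[cl, j] <- length(genera) * prod_n
    }
  }
  list(num = num, den = den)
}

# Random nested taxonomy + presence matrix: up to 3 domains x 4 clades x
# 4 genera x 5 genomes, at least one clade per domain.
random_instance <- function(n_enzymes = 2L) {
  doms <- cellular_domains()[seq_len(sample(1:3, 1))]
  rows <- list()
  for (d in doms) {
    for (cl in seq_len(sample(1:4, 1))) {
      clade_id <- paste0(d, "_c", cl)
      for (ge in seq_len(sample(1:4, 1))) {
        genus_id <- paste0(clade_id, "_g", ge)
        for (gn in seq_len(sample(1:5, 1))) {
          rows[[length(rows) + 1L]] <- data.frame(
            genome_id = paste0(genus_id, "_", gn), domain = d,
            clade = clade_id, genus = genus_id,
            gene_count = 2000L, obligate_parasite = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  tax <- taxonomy(do.call(rbind, rows))
  m <- matrix(rbinom(nrow(tax) * n_enzymes, 1L, 0.5),
              nrow = nrow(tax),
              dimnames = list(tax$genome_id,
                              paste0("e", seq_len(n_enzymes))))
  attr(m, "level") <- "genome"
  list(tax = tax, m = m)
}

# Brute-force reachability: enumerate simple paths over steps whose
# ancestry matches `require`; independent of the igraph-backed code path.
brute_route <- function(g, source, target, require = "lca") {
  steps <- g$steps[g$steps$ancestry == require, , drop = FALSE]
  edges <- list()
  for (i in seq_len(nrow(steps))) {
    for (s in steps$substrates[[i]]) for (p in steps$products[[i]]) {
      edges[[length(edges) + 1L]] <- c(s, p)
      if (isTRUE(steps$reversible[i])) {
        edges[[length(edges) + 1L]] <- c(p, s)
      }
    }
  }
  if (source == target) return(TRUE)
  seen <- character()
  stack <- source
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    for (e in edges) if (e[1] == v) {
      if (e[2] == target) return(TRUE)
      stack <- c(stack, e[2])
    }
  }
  FALSE
}

# Minimal hand-built taxonomy: 3 domains x 2 clades x 2 genera x 2 genomes.
toy_taxonomy <- function() {
  rows <- expand.grid(gn = 1:2, ge = 1:2, cl = 1:2,
                      d = cellular_domains(), stringsAsFactors = FALSE)
  taxonomy(data.frame(
    genome_id = sprintf("%s_c%d_g%d_%d", rows$d, rows$cl, rows$ge, rows$gn),
    domain = rows$d,
    clade = sprintf("%s_c%d", rows$d, rows$cl),
    genus = sprintf("%s_c%d_g%d", rows$d, rows$cl, rows$ge),
    gene_count = 3000L, obligate_parasite = FALSE,
    stringsAsFactors = FALSE))
}

toy_catalogue <- function() {
  validate_catalogue(data.frame(
    profile_id = c("pA", "pB", "subQ", "subL", "anX", "anY"),
    ec_number = c("1.1.1.1", "2.2.2.2", "6.3.5.3", "6.3.5.3",
                  "5.4.2.9", "5.4.2.9"),
    role = c("single", "single", "subunit", "subunit", "analog", "analog"),
    group_id = c("", "", "gQL", "gQL", "gXY", "gXY"),
    superfamily = "",
    profile_length = c(100L, 200L, 150L, 300L, 120L, 140L),
    stringsAsFactors = FALSE))
}

# One BLAST-tabular line (13 columns incl. genome id).
hit_line <- function(query = "q1", profile = "pA", evalue = 1e-20,
                     bitscore = 200, sstart = 1, send = 100,
                     qstart = 1, qend = 100, genome = "G1",
                     length = send - sstart + 1) {
  paste(query, profile, "50.0", length, "10", "1", qstart, qend,
        sstart, send, format(evalue, digits = 16, scientific = TRUE),
        bitscore, genome, sep = "\t")
}

write_hit_file <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

hits_df <- function(...) {
  read_hits(write_hit_file(c(...)))
}
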