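test_that("presence matrices binarize hits over the full genome set", {
  tax <- toy_taxonomy()
  cat_df <- toy_catalogue()
  g <- tax$genome_id[1]
  h <- hits_df(
    hit_line(query = "q1", profile = "pA", send = 90, genome = g),
    hit_line(query = "q2", profile = "pA", send = 80, genome = g),
    hit_line(query = "q3", profile = "pA", send = 70, genome = g)
  )
  m <- build_presence(h, tax, cat_df)
  expect_equal(dim(m), c(nrow(tax), nrow(cat_df)))
  expect_equal(m[g, "pA"], 1L)              # three hits, still 1
  expect_true(all(m[tax$genome_id[-1], ] == 0L))  # hitless genomes all-zero
  expect_setequal(unique(as.vector(m)), c(0L, 1L))

  stranger <- h
  stranger$genome_id <- "not_a_genome"
  expect_error(build_presence(stranger, tax, cat_df), "not_a_genome")
})

test_that("genus averages are unweighted means of genome presence", {
  rows <- data.frame(
    genome_id = c("a1", "a2", "a3", "b1"),
    domain = "Bacteria", clade = "c1",
    genus = c("A", "A", "A", "B"),
    gene_count = 2000L, obligate_parasite = FALSE,
    stringsAsFactors = FALSE)
  tax <- taxonomy(rows)
  m <- matrix(c(1L, 0L, 1L, 1L), ncol = 1,
              dimnames = list(rows$genome_id, "e1"))
  attr(m, "level") <- "genome"
  g <- genus_average(m, tax)
  expect_equal(g["A", "e1"], 2 / 3)
  expect_equal(g["B", "e1"], 1)      # single-genome genus: identity
  m0 <- m; m0[, 1] <- 0L
  expect_equal(unname(genus_average(m0, tax)["A", "e1"]), 0)
})

test_that("clade averages weight genera equally, not genomes", {
  # genus A: 9 genomes all present; genus B: 1 genome absent
  rows <- data.frame(
    genome_id = c(sprintf("a%d", 1:9), "b1"),
    domain = "Bacteria", clade = "c1",
    genus = c(rep("A", 9), "B"),
    gene_count = 2000L, obligate_parasite = FALSE,
    stringsAsFactors = FALSE)
  tax <- taxonomy(rows)
  m <- matrix(c(rep(1L, 9), 0L), ncol = 1,
              dimnames = list(rows$genome_id, "e1"))
  attr(m, "level") <- "genome"
  cm <- clade_average(genus_average(m, tax), tax)
  expect_equal(unname(cm["c1", "e1"]), 0.5)   # not the pooled 0.9
  expect_equal(unname(pooled_domain_fraction(m, tax)["Bacteria", "e1"]), 0.9)
})

test_that("two-step averaging matches the exact rational oracle", {
  set.seed(20260926)
  for (i in 1:300) {
    inst <- random_instance()
    cm <- clade_average(genus_average(inst$m, inst$tax), inst$tax)
    oracle <- rational_two_step(inst$m, inst$tax)
    expected <- oracle$num / oracle$den
    expect_lt(max(abs(cm[rownames(expected), ] - expected)), 1e-12)
    expect_true(all(cm >= 0 & cm <= 1))
  }
})

test_that("flipping a presence bit 0 -> 1 never demotes anything", {
  set.seed(31)
  for (rep in 1:20) {
    inst <- random_instance()
    zeros <- which(inst$m == 0L, arr.ind = TRUE)
    if (!nrow(zeros)) next
    flip <- zeros[sample.int(nrow(zeros), 1L), ]
    m2 <- inst$m
    m2[flip["row"], flip["col"]] <- 1L
    cm1 <- clade_average(genus_average(inst$m, inst$tax), inst$tax)
    cm2 <- clade_average(genus_average(m2, inst$tax), inst$tax)
    expect_true(all(cm2 >= cm1 - 1e-15))
    doms_present <- length(unique(inst$tax$domain)) == 3L
    if (doms_present) {
      s1 <- classify_distribution(cm1, inst$tax)
      s2 <- classify_distribution(cm2, inst$tax)
      expect_true(all(s2$clade_fraction >= s1$clade_fraction))
      v1 <- infer_lca(s1); v2 <- infer_lca(s2)
      expect_true(all(v2$lca_verdict >= v1$lca_verdict))
    }
  }
})

test_that("degenerate nesting reduces to the raw presence fraction", {
  # one genome per genus, one genus per clade
  rows <- expand.grid(cl = 1:4, d = cellular_domains(),
                      stringsAsFactors = FALSE)
  tax <- taxonomy(data.frame(
    genome_id = sprintf("%s%d", rows$d, rows$cl), domain = rows$d,
    clade = sprintf("%s_c%d", rows$d, rows$cl),
    genus = sprintf("%s_g%d", rows$d, rows$cl),
    gene_count = 2000L, obligate_parasite = FALSE,
    stringsAsFactors = FALSE))
  set.seed(5)
  m <- matrix(rbinom(nrow(tax) * 3, 1, 0.5), nrow = nrow(tax),
              dimnames = list(tax$genome_id, c("e1", "e2", "e3")))
  attr(m, "level") <- "genome"
  cm <- clade_average(genus_average(m, tax), tax)
  s <- classify_distribution(cm, tax)
  pooled <- pooled_domain_fraction(m, tax)
  for (k in seq_len(nrow(s))) {
    expect_equal(s$clade_fraction[k],
                 unname(pooled[s$domain[k], s$enzyme[k]]))
  }
})

test_that("the widely class requires strictly more than half the clades", {
  rows <- data.frame(
    genome_id = sprintf("g%02d", 1:30),
    domain = rep(cellular_domains(), each = 10),
    clade = sprintf("%s_c%d", rep(cellular_domains(), each = 10), 1:10),
    genus = sprintf("ge%02d", 1:30),
    gene_count = 2000L, obligate_parasite = FALSE,
    stringsAsFactors = FALSE)
  tax <- taxonomy(rows)
  m <- matrix(0L, nrow = 30, ncol = 3,
              dimnames = list(rows$genome_id, c("six", "five", "zero")))
  m[rows$domain == "Bacteria", ] <- 0L
  b <- which(rows$domain == "Bacteria")
  m[b[1:6], "six"] <- 1L
  m[b[1:5], "five"] <- 1L
  attr(m, "level") <- "genome"
  s <- classify_distribution(clade_average(genus_average(m, tax), tax), tax)
  sb <- s[s$domain == "Bacteria", ]
  expect_equal(sb$dist_class[sb$enzyme == "six"], "widely")     # 0.6
  expect_equal(sb$dist_class[sb$enzyme == "five"], "partially") # 0.5 exactly
  expect_equal(sb$dist_class[sb$enzyme == "zero"], "absent")
  expect_equal(sb$clade_fraction[sb$enzyme == "six"], 0.6)
})

test_that("LCA attribution needs widely in all three domains", {
  s <- expand.grid(enzyme = c("eAll", "eTwo", "eNone"),
                   domain = cellular_domains(),
                   stringsAsFactors = FALSE)
  s$dist_class <- "widely"
  s$dist_class[s$enzyme == "eTwo" & s$domain == "Eukarya"] <- "partially"
  s$dist_class[s$enzyme == "eNone"] <- "absent"
  v <- infer_lca(s)
  expect_true(v$lca_verdict[v$enzyme == "eAll"])
  expect_false(v$lca_verdict[v$enzyme == "eTwo"])
  expect_false(v$lca_verdict[v$enzyme == "eNone"])

  expect_error(infer_lca(s[s$domain != "Eukarya", ]), "Eukarya")
  holey <- s[!(s$enzyme == "eTwo" & s$domain == "Archaea"), ]
  expect_error(infer_lca(holey), "eTwo")
})

test_that("EC presence ANDs subunits and ORs analogs", {
  cat_df <- toy_catalogue()
  genomes <- c("gBoth", "gQonly", "gX", "gNone")
  m <- matrix(0L, nrow = 4, ncol = nrow(cat_df),
              dimnames = list(genomes, cat_df$profile_id))
  m["gBoth", c("subQ", "subL")] <- 1L
  m["gQonly", "subQ"] <- 1L       # one subunit of the complex
  m["gX", "anX"] <- 1L            # one analog family of the step
  attr(m, "level") <- "genome"
  ec <- ec_presence(m, cat_df)
  expect_equal(unname(ec[, "6.3.5.3"]), c(1L, 0L, 0L, 0L))
  expect_equal(unname(ec[, "5.4.2.9"]), c(0L, 0L, 1L, 0L))
  expect_true(all(ec["gNone", ] == 0L))

  # a singles-only catalogue is the identity on columns
  singles <- cat_df[cat_df$role == "single", ]
  ms <- m[, singles$profile_id]
  ms["gBoth", "pA"] <- 1L
  ec_s <- ec_presence(ms, singles)
  remap <- setNames(singles$ec_number, singles$profile_id)
  expect_equal(unname(ec_s[, remap["pA"]]), unname(ms[, "pA"]))
  expect_equal(unname(ec_s[, remap["pB"]]), unname(ms[, "pB"]))

  expect_error(ec_presence(m[, c("pA", "pB")], cat_df),
               "no profile present")
})

test_that("EC-numeric ordering sorts field-wise numerically", {
  expect_equal(sort_ec(c("2.7.6.1", "2.4.2.14", "2.4.2.9")),
               c("2.4.2.9", "2.4.2.14", "2.7.6.1"))
  expect_equal(sort_ec(c("10.1.1.1", "2.1.1.1")),
               c("2.1.1.1", "10.1.1.1"))
  # non-numeric sub-numbers sort after numeric ones
  expect_equal(sort_ec(c("1.1.1.n3", "1.1.1.2")),
               c("1.1.1.2", "1.1.1.n3"))
})
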