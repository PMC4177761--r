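#' Read a pathway definition
#'
#' A pathway is a directed metabolite graph whose edges are enzymatic
#' steps. Each step carries one or more alternative EC numbers (any one
#' catalyzes the step), a reversibility flag, and free-form tags (e.g.
#' `folate_dependent`, `archaea_specific`, `de_novo`, `salvage`,
#' `nonenzymatic`). Steps tagged `nonenzymatic` may have an empty EC list
#' and never take part in ancestry labelling.
#'
#' @param path TSV with columns `step_id`, `substrates` (comma-joined
#'   metabolite ids), `products`, `ec_list` (comma-joined EC numbers),
#'   `reversible` (TRUE/FALSE), `tags` (comma-joined, may be empty).
#'   Extra columns are kept as step metadata.
#' @return An object of class `pathway`: a list with `steps` (data frame)
#'   and `metabolites` (character vector).
#' @export
read_pathway <- function(path) {
  if (!file.exists(path)) stop("pathway file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  new_pathway(df)
}

split_csv <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE),
         function(p) trimws(p[nzchar(trimws(p))]))
}

new_pathway <- function(df) {
  need <- c("step_id", "substrates", "products", "ec_list", "reversible",
            "tags")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("pathway table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$step_id)) {
    stop("duplicate step_id: ",
         paste(unique(df$step_id[duplicated(df$step_id)]), collapse = ", "))
  }
  steps <- data.frame(step_id = df$step_id, stringsAsFactors = FALSE)
  steps$substrates <- split_csv(df$substrates)
  steps$products <- split_csv(df$products)
  steps$ec_list <- split_csv(df$ec_list)
  steps$reversible <- as.logical(df$reversible)
  steps$tags <- split_csv(df$tags)
  extra <- setdiff(names(df), need)
  for (col in extra) steps[[col]] <- df[[col]]
  if (anyNA(steps$reversible)) stop("reversible must be TRUE/FALSE")
  for (i in seq_len(nrow(steps))) {
    subs <- steps$substrates[[i]]
    prods <- steps$products[[i]]
    if (!length(subs) || !length(prods)) {
      stop("step ", steps$step_id[i], " lacks substrates or products")
    }
    if (length(intersect(subs, prods))) {
      stop("step ", steps$step_id[i],
           " lists the same metabolite as substrate and product")
    }
    ecs <- steps$ec_list[[i]]
    nonenz <- "nonenzymatic" %in% steps$tags[[i]]
    if (!length(ecs) && !nonenz) {
      stop("step ", steps$step_id[i],
           " has an empty EC list and is not tagged nonenzymatic")
    }
    bad <- ecs[!grepl("^[^.]+\\.[^.]+\\.[^.]+\\.[^.]+$", ecs)]
    if (length(bad)) {
      stop("step ", steps$step_id[i], " has malformed EC number(s): ",
           paste(bad, collapse = ", "))
    }
  }
  if (!"ancestry" %in% names(steps)) {
    steps$ancestry <- rep("undetermined", nrow(steps))
  }
  metabolites <- sort(unique(c(unlist(steps$substrates),
                               unlist(steps$products))))
  structure(list(steps = steps, metabolites = metabolites),
            class = "pathway")
}

#' Write a pathway back to its TSV form
#'
#' Inverse of [read_pathway()]: reading the written file reproduces the
#' pathway (round trip on list-typed columns via comma joins).
#'
#' @param g A `pathway`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pathway <- function(g, path) {
  steps <- g$steps
  df <- data.frame(
    step_id = steps$step_id,
    substrates = vapply(steps$substrates, paste, character(1), collapse = ","),
    products = vapply(steps$products, paste, character(1), collapse = ","),
    ec_list = vapply(steps$ec_list, paste, character(1), collapse = ","),
    reversible = steps$reversible,
    tags = vapply(steps$tags, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(steps), c(names(df), "ancestry"))
  for (col in extra) df[[col]] <- steps[[col]]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.pathway <- function(x, ...) {
  cat(sprintf("<pathway> %d steps, %d metabolites\n",
              nrow(x$steps), length(x$metabolites)))
  anc <- table(factor(x$steps$ancestry,
                      levels = c("lca", "non_lca", "undetermined")))
  cat(sprintf("  ancestry: %d lca, %d non_lca, %d undetermined\n",
              anc[["lca"]], anc[["non_lca"]], anc[["undetermined"]]))
  invisible(x)
}

#' Project LCA verdicts onto pathway steps
#'
#' A step is labelled `lca` when ANY of its alternative EC numbers has a
#' true LCA verdict (the reaction was available to the ancestor if any
#' catalyzing family was); `non_lca` when every EC resolves and all are
#' false; `undetermined` when some EC has no verdict and none is true.
#' Steps tagged `nonenzymatic` stay `undetermined`.
#'
#' @param g A `pathway`.
#' @param verdicts Either the data frame returned by [infer_lca()] or a
#'   named logical vector keyed by EC number.
#' @return The pathway with its `ancestry` column filled in.
#' @export
annotate_steps <- function(g, verdicts) {
  if (is.data.frame(verdicts)) {
    verdicts <- stats::setNames(verdicts$lca_verdict, verdicts$enzyme)
  }
  stopifnot(is.logical(verdicts), !is.null(names(verdicts)))
  g$steps$ancestry <- vapply(seq_len(nrow(g$steps)), function(i) {
    if ("nonenzymatic" %in% g$steps$tags[[i]]) return("undetermined")
    ecs <- g$steps$ec_list[[i]]
    v <- verdicts[ecs]
    if (any(v, na.rm = TRUE)) "lca"
    else if (anyNA(v)) "undetermined"
    else "non_lca"
  }, character(1))
  g
}

pathway_igraph <- function(g, steps_keep = rep(TRUE, nrow(g$steps))) {
  edges <- list()
  for (i in which(steps_keep)) {
    subs <- g$steps$substrates[[i]]
    prods <- g$steps$products[[i]]
    pairs <- expand.grid(from = subs, to = prods,
                         stringsAsFactors = FALSE)
    pairs$step_id <- g$steps$step_id[i]
    edges[[length(edges) + 1L]] <- pairs
    if (isTRUE(g$steps$reversible[i])) {
      rev <- data.frame(from = pairs$to, to = pairs$from,
                        step_id = pairs$step_id,
                        stringsAsFactors = FALSE)
      edges[[length(edges) + 1L]] <- rev
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(),
               step_id = character(), stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = data.frame(name = g$metabolites))
}

#' Is a route achievable using only steps with a given ancestry label?
#'
#' Answers whether `target` is reachable from `source` through steps whose
#' `ancestry` equals `require` (after [annotate_steps()]). When reachable,
#' one witness path is returned as the sequence of step ids along a
#' shortest such route.
#'
#' @param g An annotated `pathway`.
#' @param source,target Metabolite identifiers in the graph.
#' @param require Ancestry label steps must carry (default `"lca"`).
#' @return List with `complete` (logical) and `path` (character vector of
#'   step ids; empty when incomplete, or when `source == target`).
#' @export
route_complete <- function(g, source, target, require = "lca") {
  for (mtb in c(source, target)) {
    if (!mtb %in% g$metabolites) stop("unknown metabolite: ", mtb)
  }
  keep <- g$steps$ancestry == require
  ig <- pathway_igraph(g, keep)
  sp <- suppressWarnings(
    igraph::shortest_paths(ig, from = source, to = target,
                           mode = "out", output = "epath")
  )
  epath <- sp$epath[[1]]
  if (source != target && length(epath) == 0L) {
    return(list(complete = FALSE, path = character()))
  }
  list(complete = TRUE,
       path = igraph::edge_attr(ig, "step_id", epath))
}

#' Export an annotated pathway as JSON
#'
#' @param g A `pathway`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
pathway_to_json <- function(g, path) {
  steps <- lapply(seq_len(nrow(g$steps)), function(i) {
    list(step_id = g$steps$step_id[i],
         substrates = g$steps$substrates[[i]],
         products = g$steps$products[[i]],
         ec_list = g$steps$ec_list[[i]],
         reversible = g$steps$reversible[i],
         tags = g$steps$tags[[i]],
         ancestry = g$steps$ancestry[i])
  })
  jsonlite::write_json(list(metabolites = g$metabolites, steps = steps),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export an annotated pathway as Graphviz DOT
#'
#' Steps are edges; ancestry is rendered as edge color (lca = red,
#' non_lca = blue, undetermined = gray), mirroring the usual coloring of
#' ancestral-step diagrams.
#'
#' @param g A `pathway`.
#' @param path Output `.dot` file path.
#' @return `path`, invisibly.
#' @export
pathway_to_dot <- function(g, path) {
  col <- c(lca = "red", non_lca = "blue", undetermined = "gray")
  lines <- c("digraph pathway {", "  rankdir=LR;")
  for (i in seq_len(nrow(g$steps))) {
    color <- col[[g$steps$ancestry[i]]]
    label <- paste(g$steps$ec_list[[i]], collapse = ",")
    if (!nzchar(label)) label <- g$steps$step_id[i]
    for (s in g$steps$substrates[[i]]) {
      for (p in g$steps$products[[i]]) {
        lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"%s\", color=%s];",
                                  s, p, label, color))
        if (isTRUE(g$steps$reversible[i])) {
          lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [color=%s];",
                                    p, s, color))
        }
      }
    }
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
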