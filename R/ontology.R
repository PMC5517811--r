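# Canonical namespace codes used throughout the package.
GO_NAMESPACES <- c("BP", "MF", "CC")

.ns_canonical <- c(
  biological_process = "BP", molecular_function = "MF", cellular_component = "CC",
  BP = "BP", MF = "MF", CC = "CC", P = "BP", F = "MF", C = "CC"
)

.ns_long <- c(BP = "biological_process", MF = "molecular_function",
              CC = "cellular_component")

#' Construct an ontology graph from term and edge vectors
#'
#' Low-level constructor shared by [read_obo()] and [simulate_ontology()].
#' Only is-a edges are represented: each term maps to its direct is-a
#' parents. The root of each namespace is detected structurally as the
#' term without any is-a parent; exactly one root per namespace is
#' required.
#'
#' @param terms character vector of primary term identifiers.
#' @param namespace named character vector mapping each term to one of
#'   `"BP"`, `"MF"`, `"CC"`.
#' @param parents named list mapping each term to a character vector of
#'   its direct is-a parents (may be empty for roots).
#' @param alt_ids named character vector mapping alias identifiers to
#'   primary identifiers (may be empty).
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(terms, namespace, parents, alt_ids = character()) {
  terms <- unique(terms)
  stopifnot(all(terms %in% names(namespace)), all(terms %in% names(parents)))
  namespace <- namespace[terms]
  parents <- parents[terms]
  bad_ns <- !namespace %in% GO_NAMESPACES
  if (any(bad_ns)) stop("unknown namespace for term(s): ",
                        paste(terms[bad_ns], collapse = ", "))

  # drop edges pointing outside the term set (e.g. to obsolete parents)
  parents <- lapply(parents, function(p) p[p %in% terms])

  edge_df <- data.frame(
    child = rep(terms, lengths(parents)),
    parent = unlist(parents, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (nrow(edge_df) > 0L) {
    g <- igraph::graph_from_data_frame(edge_df, directed = TRUE,
                                       vertices = data.frame(name = terms))
    if (!igraph::is_dag(g)) stop("cycle detected in is-a graph")
    cross <- namespace[edge_df$child] != namespace[edge_df$parent]
    if (any(cross)) stop("is-a edge crosses namespaces: ",
                         edge_df$child[which(cross)[1L]])
  }

  children <- split(edge_df$child, factor(edge_df$parent, levels = terms))

  # The namespace root is detected structurally: among terms without an
  # is-a parent, the one from which the most terms descend. Other
  # parentless terms (e.g. connected only by part_of in the source
  # file) are kept as orphans with a warning; their closure is just
  # themselves.
  parentless <- terms[lengths(parents) == 0L]
  n_desc <- function(t) {
    seen <- character(); stack <- t
    while (length(stack)) {
      x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (x %in% seen) next
      seen <- c(seen, x); stack <- c(stack, children[[x]])
    }
    length(seen)
  }
  root_of <- character()
  for (ns in unique(unname(namespace))) {
    cand <- parentless[namespace[parentless] == ns]
    if (!length(cand))
      stop("namespace ", ns, " has no root (every term has an is-a parent)")
    if (length(cand) > 1L) {
      sizes <- vapply(cand, n_desc, numeric(1))
      root <- cand[which.max(sizes)]
      warning("namespace ", ns, " has ", length(cand) - 1L,
              " parentless non-root term(s), kept as orphans: ",
              paste(setdiff(cand, root), collapse = ", "))
    } else root <- cand
    root_of[ns] <- root
  }

  obj <- list(
    terms = terms,
    namespace = namespace,
    parents = parents,
    children = children,
    roots = root_of,
    alt_ids = alt_ids,
    masked = character(0),
    cache = new.env(parent = emptyenv())
  )
  class(obj) <- "ontology_graph"
  obj
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", length(x$terms), "terms,",
      sum(lengths(x$parents)), "is-a edges\n")
  for (ns in names(x$roots)) {
    cat("  ", ns, ": root ", x$roots[[ns]], ", ",
        sum(x$namespace == ns), " terms\n", sep = "")
  }
  if (length(x$masked))
    cat("  masked terms:", length(x$masked), "\n")
  invisible(x)
}

#' Read an OBO 1.2 flat file
#'
#' Parses `[Term]` stanzas keeping only the is-a subclass relationship;
#' `part_of`, `regulates` and other `relationship:` lines are ignored.
#' Obsolete terms are dropped, `alt_id` aliases are recorded, and terms
#' lacking a namespace are rejected with a warning. The root of each
#' namespace is the term without an is-a parent.
#'
#' @param path path to an OBO 1.2 file.
#' @return An `ontology_graph`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found in OBO file: ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  ids <- character(); nss <- character(); plist <- list()
  alt <- character(); alt_to <- character()
  for (k in seq_along(starts)) {
    if (lines[starts[k]] != "[Term]") next
    body <- lines[(starts[k] + 1L):ends[k]]
    body <- body[nzchar(body)]
    kv <- regmatches(body, regexpr("^[^:]+", body))
    val <- sub("^[^:]+:\\s*", "", body)
    id <- val[kv == "id"][1L]
    if (is.na(id)) next
    if (any(kv == "is_obsolete" & grepl("^true", val))) next
    ns_raw <- val[kv == "namespace"][1L]
    if (is.na(ns_raw) || is.na(.ns_canonical[ns_raw])) {
      warning("term ", id, " has no recognised namespace; dropped")
      next
    }
    isa <- val[kv == "is_a"]
    isa <- sub("\\s*!.*$", "", isa)           # strip trailing "! label"
    isa <- trimws(isa)
    aids <- trimws(sub("\\s*!.*$", "", val[kv == "alt_id"]))
    ids <- c(ids, id)
    nss <- c(nss, unname(.ns_canonical[ns_raw]))
    plist[[id]] <- isa
    if (length(aids)) {
      alt <- c(alt, aids)
      alt_to <- c(alt_to, rep(id, length(aids)))
    }
  }
  if (!length(ids)) stop("no usable [Term] stanzas in ", path)
  ontology_graph(ids, stats::setNames(nss, ids), plist,
                 alt_ids = stats::setNames(alt_to, alt))
}

#' Resolve a possibly-aliased term identifier
#'
#' @param graph an `ontology_graph`.
#' @param term term identifier (primary or alt_id alias).
#' @return The primary identifier, or `NA_character_` if unknown.
#' @export
resolve_term <- function(graph, term) {
  if (term %in% graph$terms) return(term)
  hit <- graph$alt_ids[term]
  if (!is.na(hit) && hit %in% graph$terms) return(unname(hit))
  NA_character_
}

#' Ancestor closure of a term
#'
#' The set used by the term-similarity score: the term itself plus every
#' term reachable upward via is-a edges, excluding the namespace root
#' (roots carry no functional information) and excluding any masked
#' terms (see [mask_terms()]). The closure of a root is empty. Results
#' are memoized per graph.
#'
#' @param graph an `ontology_graph`.
#' @param term term identifier.
#' @return Character vector of term identifiers.
#' @export
ancestors <- function(graph, term) {
  term <- resolve_term(graph, term)
  if (is.na(term)) stop("unannotatable term: not present in ontology")
  key <- paste0("anc.", term)
  hit <- graph$cache[[key]]
  if (!is.null(hit)) return(hit)
  # iterative DFS up the parent lists
  seen <- character(); stack <- term
  while (length(stack)) {
    t <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (t %in% seen) next
    seen <- c(seen, t)
    stack <- c(stack, graph$parents[[t]])
  }
  seen <- setdiff(seen, c(unname(graph$roots), graph$masked))
  assign(key, seen, envir = graph$cache)
  seen
}

#' Descendant closure of a term (term plus all is-a specialisations)
#'
#' Used by the synthetic-data generator to draw annotations from the
#' sub-DAG below an operon's theme term. Memoized per graph.
#'
#' @inheritParams ancestors
#' @return Character vector including `term` itself.
#' @export
descendants <- function(graph, term) {
  term <- resolve_term(graph, term)
  if (is.na(term)) stop("unannotatable term: not present in ontology")
  key <- paste0("desc.", term)
  hit <- graph$cache[[key]]
  if (!is.null(hit)) return(hit)
  seen <- character(); stack <- term
  while (length(stack)) {
    t <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (t %in% seen) next
    seen <- c(seen, t)
    stack <- c(stack, graph$children[[t]])
  }
  assign(key, seen, envir = graph$cache)
  seen
}

#' Similarity between two GO terms (ancestor-set Jaccard)
#'
#' The Jaccard index of the two terms' ancestor closures (each term plus
#' its is-a predecessors, excluding the namespace root). Symmetric,
#' bounded in \[0, 1\], and equal to 1 exactly when the closures
#' coincide. Root terms are rejected: with the root excluded from every
#' closure they carry no information.
#'
#' @param graph an `ontology_graph`.
#' @param go1,go2 term identifiers in the same namespace.
#' @return Numeric similarity in \[0, 1\].
#' @export
go_sim <- function(graph, go1, go2) {
  t1 <- resolve_term(graph, go1); t2 <- resolve_term(graph, go2)
  if (is.na(t1) || is.na(t2)) stop("unannotatable term: not present in ontology")
  if (t1 %in% graph$roots || t2 %in% graph$roots)
    stop("root terms carry no information")
  if (t1 == t2) return(1)
  key <- if (t1 < t2) paste0("sim.", t1, "|", t2) else paste0("sim.", t2, "|", t1)
  hit <- graph$cache[[key]]
  if (!is.null(hit)) return(hit)
  s1 <- ancestors(graph, t1); s2 <- ancestors(graph, t2)
  u <- length(union(s1, s2))
  val <- if (u == 0L) 0 else length(intersect(s1, s2)) / u
  assign(key, val, envir = graph$cache)
  val
}

#' Mask terms from ancestor closures
#'
#' Returns a copy of the graph in which the given terms are excluded
#' from every ancestor closure (they remain vertices, so reachability
#' through them is unaffected). Used to keep filtered high-frequency
#' terms from re-entering similarity scores via the closures of retained
#' rare terms. Caches are reset.
#'
#' @param graph an `ontology_graph`.
#' @param terms character vector of term identifiers to mask.
#' @return A new `ontology_graph`.
#' @export
mask_terms <- function(graph, terms) {
  graph$masked <- unique(c(graph$masked, terms))
  graph$cache <- new.env(parent = emptyenv())
  graph
}

#' Term frequencies in a background annotation pool
#'
#' Counts, for each GO term, the number of background proteins that list
#' it among their direct annotations (once per protein, regardless of
#' namespace or repetition), and expresses it as a fraction of the
#' proteins carrying at least one GO term.
#'
#' @param background an `annotation_map` or `background_pool`.
#' @return A data frame with columns `term`, `count`, `frequency`, of
#'   class `term_freq`, carrying attribute `n_proteins`.
#' @export
term_frequencies <- function(background) {
  entries <- if (inherits(background, "background_pool")) background$entries
             else unclass(background)
  per_protein <- lapply(entries, function(e) unique(unlist(e, use.names = FALSE)))
  annotated <- lengths(per_protein) > 0L
  n <- sum(annotated)
  if (n == 0L) stop("background pool contains no annotated proteins")
  tab <- table(unlist(per_protein[annotated], use.names = FALSE))
  out <- data.frame(term = names(tab), count = as.integer(tab),
                    frequency = as.integer(tab) / n,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$count, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_proteins") <- n
  class(out) <- c("term_freq", class(out))
  out
}

#' Write / read a term-frequency table as TSV
#'
#' Two columns (term, count) after a header comment recording the number
#' of annotated background proteins.
#'
#' @param freqs a `term_freq` table.
#' @param path output path.
#' @export
write_term_frequencies <- function(freqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#n_proteins=%d", attr(freqs, "n_proteins")), con)
  writeLines("term\tcount", con)
  writeLines(sprintf("%s\t%d", freqs$term, freqs$count), con)
  invisible(path)
}

#' @rdname write_term_frequencies
#' @export
read_term_frequencies <- function(path) {
  first <- readLines(path, n = 1L)
  n <- as.integer(sub("^#n_proteins=", "", first))
  tab <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  out <- data.frame(term = tab$term, count = as.integer(tab$count),
                    frequency = tab$count / n, stringsAsFactors = FALSE)
  attr(out, "n_proteins") <- n
  class(out) <- c("term_freq", class(out))
  out
}

#' Remove abundant GO terms from an annotation map
#'
#' Terms whose background frequency strictly exceeds `cutoff` are removed
#' from every gene's direct annotation sets. A gene whose set becomes
#' empty in a namespace is simply unannotated there. The removed terms
#' are attached as attribute `dropped_terms`; pass them to [mask_terms()]
#' to also exclude them from ancestor closures during similarity
#' computation (the package default pipeline does both, see
#' [apply_term_filter()]).
#'
#' @param annotations an `annotation_map`.
#' @param freqs a `term_freq` table from [term_frequencies()].
#' @param cutoff frequency cutoff in \[0, 1\]; terms with frequency
#'   `> cutoff` are removed. Default 0.05.
#' @return A filtered `annotation_map` with attribute `dropped_terms`.
#' @export
filter_abundant_terms <- function(annotations, freqs, cutoff = 0.05) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  drop <- freqs$term[freqs$frequency > cutoff]
  out <- lapply(unclass(annotations), function(e)
    lapply(e, function(terms) setdiff(terms, drop)))
  class(out) <- "annotation_map"
  attr(out, "dropped_terms") <- drop
  out
}

#' Filter abundant terms from annotations and closures in one step
#'
#' Convenience wrapper: computes which terms exceed the frequency cutoff
#' in the background, removes them from the annotation map, and (by
#' default) masks them from ancestor closures so they cannot re-enter
#' similarity scores through the closure of a retained term.
#'
#' @inheritParams filter_abundant_terms
#' @param graph an `ontology_graph`.
#' @param mask_closures also exclude the dropped terms from ancestor
#'   closures (default `TRUE`).
#' @return List with elements `annotations`, `graph`, `dropped`.
#' @export
apply_term_filter <- function(annotations, graph, freqs, cutoff = 0.05,
                              mask_closures = TRUE) {
  filtered <- filter_abundant_terms(annotations, freqs, cutoff)
  dropped <- attr(filtered, "dropped_terms")
  if (mask_closures && length(dropped)) graph <- mask_terms(graph, dropped)
  list(annotations = filtered, graph = graph, dropped = dropped)
}
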