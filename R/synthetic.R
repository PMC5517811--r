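#' Configuration for the synthetic ontology/genome generator
#'
#' The generator emulates the statistical structure the method relies
#' on: genes organized into operons along a circular chromosome, with
#' operon mates annotated near a shared "theme" term of a rooted GO-like
#' DAG, so that chromosomal neighbors share function far more often than
#' random gene pairs.
#'
#' @param seed master integer seed; all randomness flows from it through
#'   named substreams (ontology / genome / annotation), so stages can be
#'   regenerated independently.
#' @param n_terms named integer vector: terms per namespace, including
#'   the root (default 120 each).
#' @param max_parents maximum is-a parents per non-root term (default 2).
#' @param n_genes genes on the chromosome (default 2000).
#' @param operon_mean_size mean operon size; sizes are geometric with
#'   this mean (default 3).
#' @param frac_annotated probability a gene is annotated in each
#'   namespace (default 0.7).
#' @param rho within-operon sharing probability: chance an annotation is
#'   drawn from the operon theme's sub-DAG rather than uniformly
#'   (default 0.8).
#' @param noise probability of drawing a uniformly random term instead
#'   of following the theme (default 0.1); the effective theme-draw
#'   probability is `rho * (1 - noise)`.
#' @param terms_per_gene_mean mean number of terms per annotated gene
#'   per namespace; counts are `1 + Poisson(mean - 1)` (default 2).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_terms = c(BP = 120L, MF = 120L, CC = 120L),
                              max_parents = 2L,
                              n_genes = 2000L,
                              operon_mean_size = 3,
                              frac_annotated = 0.7,
                              rho = 0.8,
                              noise = 0.1,
                              terms_per_gene_mean = 2) {
  stopifnot(all(n_terms >= 2L), n_genes >= 1L, operon_mean_size >= 1,
            frac_annotated >= 0, frac_annotated <= 1,
            rho >= 0, rho <= 1, noise >= 0, noise <= 1,
            terms_per_gene_mean >= 1)
  if (is.null(names(n_terms))) names(n_terms) <- GO_NAMESPACES
  structure(list(seed = as.integer(seed), n_terms = n_terms,
                 max_parents = as.integer(max_parents),
                 n_genes = as.integer(n_genes),
                 operon_mean_size = operon_mean_size,
                 frac_annotated = frac_annotated,
                 rho = rho, noise = noise,
                 terms_per_gene_mean = terms_per_gene_mean),
            class = "simulation_config")
}

#' Simulate a rooted GO-like DAG per namespace
#'
#' Terms are added in order; each non-root term attaches to 1 to
#' `max_parents` uniformly chosen earlier terms of its namespace, which
#' guarantees acyclicity and a single root per namespace. Term
#' identifiers use disjoint numeric blocks per namespace.
#'
#' @param config a `simulation_config`.
#' @return An `ontology_graph`.
#' @export
simulate_ontology <- function(config) {
  withr_seed(substream_seed(config$seed, "ontology"), {
    ids <- character(); nss <- character(); plist <- list()
    block <- c(BP = 1e6, MF = 2e6, CC = 3e6)
    for (ns in GO_NAMESPACES) {
      n <- config$n_terms[[ns]]
      terms <- sprintf("GO:%07d", block[[ns]] + seq_len(n))
      plist[[terms[1L]]] <- character()
      for (i in seq_len(n)[-1L]) {
        k <- sample.int(min(config$max_parents, i - 1L), 1L)
        plist[[terms[i]]] <- terms[sample.int(i - 1L, k)]
      }
      ids <- c(ids, terms)
      nss <- c(nss, rep(ns, n))
    }
    ontology_graph(ids, stats::setNames(nss, ids), plist)
  })
}

#' Simulate an operon-structured genome with correlated annotations
#'
#' Partitions a circular gene order into operons with geometric sizes,
#' one strand per operon, assigns each operon a theme term per
#' namespace, and annotates each gene (with probability
#' `frac_annotated` per namespace) by drawing terms from the theme's
#' sub-DAG with probability `rho * (1 - noise)` and uniformly from all
#' non-root terms otherwise. This plants functional correlation at the
#' operon level — the strongest neighborhood signal in bacteria — which
#' the +-3 window then reads.
#'
#' @param config a `simulation_config`.
#' @param graph an `ontology_graph`, typically from
#'   [simulate_ontology()].
#' @return List with `genome` (a circular single-replicon
#'   `genome_table`) and `annotations` (an `annotation_map`).
#' @export
simulate_genome <- function(config, graph) {
  n <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))
  geom_p <- 1 / config$operon_mean_size

  structure_part <- withr_seed(substream_seed(config$seed, "genome"), {
    sizes <- integer()
    while (sum(sizes) < n)
      sizes <- c(sizes, 1L + stats::rgeom(1L, geom_p))
    extra <- sum(sizes) - n
    sizes[length(sizes)] <- sizes[length(sizes)] - extra
    sizes <- sizes[sizes > 0L]
    operon_id <- rep(sprintf("op%04d", seq_along(sizes)), sizes)
    strand <- rep(sample(c("+", "-"), length(sizes), replace = TRUE), sizes)
    list(operon_id = operon_id, strand = strand, n_operons = length(sizes))
  })

  genome <- genome_table(data.frame(
    replicon = "chr", gene_id = gene_ids, rank = seq_len(n) - 1L,
    strand = structure_part$strand, operon_id = structure_part$operon_id,
    stringsAsFactors = FALSE
  ), topology = "circular")

  nonroot <- lapply(stats::setNames(GO_NAMESPACES, GO_NAMESPACES), function(ns)
    setdiff(graph$terms[graph$namespace == ns], graph$roots))

  ann <- withr_seed(substream_seed(config$seed, "annotation"), {
    themes <- lapply(stats::setNames(GO_NAMESPACES, GO_NAMESPACES), function(ns)
      sample(nonroot[[ns]], structure_part$n_operons, replace = TRUE))
    p_theme <- config$rho * (1 - config$noise)
    acc <- vector("list", n)
    names(acc) <- gene_ids
    op_index <- as.integer(factor(structure_part$operon_id,
                                  levels = unique(structure_part$operon_id)))
    for (i in seq_len(n)) {
      e <- list()
      for (ns in GO_NAMESPACES) {
        if (stats::runif(1L) >= config$frac_annotated) next
        k <- 1L + stats::rpois(1L, config$terms_per_gene_mean - 1)
        theme <- themes[[ns]][op_index[i]]
        pool_theme <- setdiff(descendants(graph, theme), unname(graph$roots))
        if (!length(pool_theme)) pool_theme <- theme
        from_theme <- stats::runif(k) < p_theme
        terms <- character(k)
        if (any(from_theme))
          terms[from_theme] <- sample(pool_theme, sum(from_theme),
                                      replace = TRUE)
        if (any(!from_theme))
          terms[!from_theme] <- sample(nonroot[[ns]], sum(!from_theme),
                                       replace = TRUE)
        e[[ns]] <- unique(terms)
      }
      acc[[i]] <- e
    }
    acc
  })

  list(genome = genome, annotations = annotation_map(ann))
}

#' Write an ontology graph as OBO 1.2
#'
#' Emits `[Term]` stanzas with `id`, `name`, `namespace` and `is_a`
#' lines, so synthetic ontologies round-trip through [read_obo()].
#'
#' @param graph an `ontology_graph`.
#' @param path output path.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in graph$terms) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", t), con)
    writeLines(paste0("name: synthetic term ", t), con)
    writeLines(paste0("namespace: ", .ns_long[[graph$namespace[[t]]]]), con)
    for (p in graph$parents[[t]])
      writeLines(paste0("is_a: ", p, " ! synthetic term ", p), con)
    writeLines("", con)
  }
  invisible(path)
}
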