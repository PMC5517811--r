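# Shared hand-built fixtures and small generators used across test files.

# Chain ontology: root -> X -> Y (single namespace).
chain_ontology <- function(ns = "BP") {
  terms <- c("R", "X", "Y")
  ontology_graph(terms,
                 setNames(rep(ns, 3L), terms),
                 list(R = character(), X = "R", Y = "X"))
}

# Diamond: root -> P, root -> Q, P -> A, Q -> A.
diamond_ontology <- function(ns = "BP") {
  terms <- c("R", "P", "Q", "A")
  ontology_graph(terms,
                 setNames(rep(ns, 4L), terms),
                 list(R = character(), P = "R", Q = "R", A = c("P", "Q")))
}

# Fork: root -> P, P -> A, P -> B (closures {A,P} and {B,P}).
fork_ontology <- function(ns = "BP") {
  terms <- c("R", "P", "A", "B")
  ontology_graph(terms,
                 setNames(rep(ns, 4L), terms),
                 list(R = character(), P = "R", A = "P", B = "P"))
}

# Random rooted DAG in one namespace: term i attaches to 1-2 earlier terms.
random_dag <- function(n_terms, ns = "BP") {
  terms <- sprintf("T%03d", seq_len(n_terms))
  plist <- c(list(character()),
             lapply(seq_len(n_terms)[-1L], function(i) {
               k <- sample.int(min(2L, i - 1L), 1L)
               terms[sample.int(i - 1L, k)]
             }))
  names(plist) <- terms
  ontology_graph(terms, setNames(rep(ns, n_terms), terms), plist)
}

# Independent oracle for ancestor closures: igraph reachability along
# child->parent edges, minus the root.
oracle_closure <- function(graph, term) {
  edges <- data.frame(
    child = rep(graph$terms, lengths(graph$parents)),
    parent = unlist(graph$parents, use.names = FALSE)
  )
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = graph$terms))
  reach <- names(igraph::subcomponent(g, term, mode = "out"))
  setdiff(reach, unname(graph$roots))
}

oracle_jaccard <- function(graph, t1, t2) {
  s1 <- oracle_closure(graph, t1)
  s2 <- oracle_closure(graph, t2)
  u <- length(union(s1, s2))
  if (u == 0L) 0 else length(intersect(s1, s2)) / u
}

# Tiny circular genome: n genes, one replicon, alternating 2-gene
# operons unless operon_sizes is given.
toy_genome <- function(n, strand = rep("+", n), operon_sizes = NULL,
                       topology = "circular") {
  operon_id <- if (is.null(operon_sizes)) NA_character_ else
    rep(sprintf("op%02d", seq_along(operon_sizes)), operon_sizes)
  genome_table(data.frame(
    replicon = "chr", gene_id = sprintf("g%02d", seq_len(n)),
    rank = seq_len(n) - 1L, strand = strand, operon_id = operon_id,
    stringsAsFactors = FALSE
  ), topology = topology)
}

# Annotation map from a named list of term vectors, single namespace.
toy_annotations <- function(lst, ns = "BP") {
  annotation_map(lapply(lst, function(terms) setNames(list(terms), ns)))
}

# Cached default synthetic study: built once per test run and reused by
# the acceptance checks (2000 genes, rho = 0.8).
default_study <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- simulation_config(seed = 20170719L, n_genes = 2000L, rho = 0.8)
    graph <- simulate_ontology(cfg)
    sim <- simulate_genome(cfg, graph)
    pool <- background_pool(sim$annotations)
    freqs <- term_frequencies(pool)
    filt <- apply_term_filter(sim$annotations, graph, freqs, cutoff = 0.05)
    prof_c <- build_profiles(sim$genome, filt$annotations, filt$graph)
    rand <- random_annotation(filt$annotations, background_pool(filt$annotations),
                              seed = substream_seed_for_tests(20170719L))
    prof_r <- build_profiles(sim$genome, rand, filt$graph)
    model <- estimate_likelihoods(prof_c, prof_r)
    cache <<- list(config = cfg, graph = filt$graph, genome = sim$genome,
                   annotations = filt$annotations, random = rand,
                   profiles_correct = prof_c, profiles_random = prof_r,
                   model = model)
    cache
  }
})

# Fixed derived seed for the randomization stream in fixtures.
substream_seed_for_tests <- function(seed) (seed + 104729L) %% 2147483647L
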