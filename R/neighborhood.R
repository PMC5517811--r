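#' Chromosomal neighbors of a gene
#'
#' Returns the genes at offsets -window..+window (excluding 0) around a
#' focal gene. Circular replicons wrap; linear replicons truncate at the
#' ends (missing offsets are absent from the result). Offsets never
#' cross replicon boundaries, and on a replicon shorter than
#' `2 * window + 1` an offset that would wrap back onto the focal gene
#' itself is dropped.
#'
#' @param genome a `genome_table`.
#' @param gene_id focal gene identifier.
#' @param window neighborhood half-width (default 3).
#' @return Named character vector of neighbor gene_ids; names are the
#'   signed offsets.
#' @export
neighbors <- function(genome, gene_id, window = 3L) {
  stopifnot(window >= 1L)
  i <- match(gene_id, genome$gene_id)
  if (is.na(i)) stop("unknown gene_id: ", gene_id)
  rep_id <- genome$replicon[i]
  sub <- genome[genome$replicon == rep_id, , drop = FALSE]
  sub <- sub[order(sub$rank), , drop = FALSE]
  n <- nrow(sub)
  r0 <- genome$rank[i]
  circular <- attr(genome, "topology")[[rep_id]] == "circular"
  offs <- setdiff(seq.int(-window, window), 0L)
  out <- character(); nm <- character()
  for (o in offs) {
    r <- r0 + o
    if (circular) r <- r %% n else if (r < 0L || r >= n) next
    if (r == r0) next                      # wrap onto self on a tiny replicon
    out <- c(out, sub$gene_id[r + 1L])
    nm <- c(nm, as.character(o))
  }
  stats::setNames(out, nm)
}

# All (gene, offset, neighbor) triples for a genome, vectorised per
# replicon; columns same_strand / same_operon are filled for downstream
# model variants.
neighbor_pairs <- function(genome, window = 3L) {
  res <- vector("list", 0L)
  topo <- attr(genome, "topology")
  for (rep_id in unique(genome$replicon)) {
    sub <- genome[genome$replicon == rep_id, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    n <- nrow(sub)
    circular <- topo[[rep_id]] == "circular"
    for (o in setdiff(seq.int(-window, window), 0L)) {
      r <- sub$rank + o
      if (circular) {
        r <- r %% n
        keep <- r != sub$rank
      } else {
        keep <- r >= 0L & r < n
      }
      if (!any(keep)) next
      gi <- which(keep)
      ni <- r[keep] + 1L
      res[[length(res) + 1L]] <- data.frame(
        gene_id = sub$gene_id[gi],
        offset = o,
        neighbor_id = sub$gene_id[ni],
        same_strand = sub$strand[gi] == sub$strand[ni],
        same_operon = !is.na(sub$operon_id[gi]) & !is.na(sub$operon_id[ni]) &
          sub$operon_id[gi] == sub$operon_id[ni],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res))
    return(data.frame(gene_id = character(), offset = integer(),
                      neighbor_id = character(), same_strand = logical(),
                      same_operon = logical()))
  do.call(rbind, res)
}

#' Gene function similarity between two term sets
#'
#' The maximum term similarity ([go_sim()]) over all cross pairs of the
#' two genes' annotation sets in one namespace; the maximum accommodates
#' genes carrying different numbers of terms. `NA` (missing) when either
#' set is empty.
#'
#' @param graph an `ontology_graph`.
#' @param a1,a2 character vectors of non-root term identifiers from one
#'   namespace.
#' @return Similarity in \[0, 1\], or `NA_real_` if either set is empty.
#' @export
gene_function_similarity <- function(graph, a1, a2) {
  if (!length(a1) || !length(a2)) return(NA_real_)
  best <- 0
  for (t1 in a1) for (t2 in a2) {
    s <- go_sim(graph, t1, t2)
    if (s > best) best <- s
    if (best >= 1) return(1)
  }
  best
}

#' Build neighborhood observation profiles for a genome
#'
#' For every gene and every existing neighbor offset, computes the gene
#' function similarity in each GO namespace, yielding up to 18
#' observations per gene (6 offsets x 3 namespaces). An observation's
#' `gfs` is `NA` (missing) when either gene of the pair is unannotated
#' in that namespace; in `"operon"` mode it is additionally `NA` for
#' neighbors not sharing the focal gene's operon. `"strand"` mode keeps
#' all observations and records whether the neighbor lies on the same
#' strand, for strand-stratified likelihoods.
#'
#' @param genome a `genome_table`.
#' @param annotations an `annotation_map` (already term-filtered).
#' @param graph an `ontology_graph`.
#' @param mode `"plain"`, `"operon"`, or `"strand"`.
#' @param window neighborhood half-width (default 3).
#' @return A long data frame of class `observation_profiles` with
#'   columns `gene_id`, `offset`, `namespace`, `gfs`, `same_strand`,
#'   `same_operon`, and attributes `mode`, `window`.
#' @export
build_profiles <- function(genome, annotations, graph,
                           mode = c("plain", "operon", "strand"),
                           window = 3L) {
  mode <- match.arg(mode)
  pairs <- neighbor_pairs(genome, window)
  ann <- unclass(annotations)
  empty_ns <- lapply(stats::setNames(GO_NAMESPACES, GO_NAMESPACES),
                     function(ns) character())
  get_terms <- function(gene, ns) {
    e <- ann[[gene]]
    if (is.null(e)) character() else e[[ns]]
  }
  # GFS cache over unordered gene pairs per namespace: each physical
  # pair appears twice in the long table (once from each side).
  gfs_cache <- new.env(parent = emptyenv())
  pair_gfs <- function(g1, g2, ns) {
    key <- if (g1 < g2) paste0(ns, ".", g1, "|", g2)
           else paste0(ns, ".", g2, "|", g1)
    hit <- gfs_cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- gene_function_similarity(graph, get_terms(g1, ns), get_terms(g2, ns))
    assign(key, v, envir = gfs_cache)
    v
  }
  n <- nrow(pairs)
  blocks <- vector("list", length(GO_NAMESPACES))
  for (k in seq_along(GO_NAMESPACES)) {
    ns <- GO_NAMESPACES[k]
    gfs <- numeric(n)
    for (i in seq_len(n))
      gfs[i] <- pair_gfs(pairs$gene_id[i], pairs$neighbor_id[i], ns)
    blocks[[k]] <- data.frame(
      gene_id = pairs$gene_id, offset = pairs$offset, namespace = ns,
      gfs = gfs, same_strand = pairs$same_strand,
      same_operon = pairs$same_operon, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, blocks)
  if (mode == "operon") out$gfs[!out$same_operon] <- NA_real_
  out <- out[order(out$gene_id, out$offset, out$namespace), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "window") <- as.integer(window)
  class(out) <- c("observation_profiles", "data.frame")
  out
}

#' Observation profile of a single gene
#'
#' @inheritParams build_profiles
#' @param gene_id focal gene identifier.
#' @return One gene's rows of the [build_profiles()] table.
#' @export
build_profile <- function(genome, annotations, graph, gene_id,
                          mode = c("plain", "operon", "strand"),
                          window = 3L) {
  mode <- match.arg(mode)
  if (!gene_id %in% genome$gene_id) stop("unknown gene_id: ", gene_id)
  prof <- build_profiles(genome, annotations, graph, mode = mode,
                         window = window)
  out <- prof[prof$gene_id == gene_id, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "window") <- as.integer(window)
  class(out) <- class(prof)
  out
}

#' Eligibility of genes for PAC computation
#'
#' A gene is eligible when it has at least one non-missing GFS
#' observation in its neighborhood (in operon mode, among same-operon
#' neighbors, since the others are already missing).
#'
#' @param profiles an `observation_profiles` table.
#' @return Named logical vector over the gene_ids present in `profiles`.
#' @export
profile_eligibility <- function(profiles) {
  tab <- tapply(!is.na(profiles$gfs), profiles$gene_id, any)
  stats::setNames(as.logical(tab), names(tab))
}

#' Export profiles as long-format TSV
#'
#' @param profiles an `observation_profiles` table.
#' @param path output path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(as.data.frame(profiles), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
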