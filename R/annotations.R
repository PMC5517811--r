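#' Construct an annotation map
#'
#' Per-gene, per-namespace GO term sets. Genes may be unannotated in any
#' or all namespaces.
#'
#' @param x named list mapping gene_id to a list with elements `BP`,
#'   `MF`, `CC` (character vectors of term identifiers; missing elements
#'   are treated as empty).
#' @return An object of class `annotation_map`.
#' @export
annotation_map <- function(x = list()) {
  out <- lapply(x, function(e) {
    e <- as.list(e)
    lapply(stats::setNames(GO_NAMESPACES, GO_NAMESPACES),
           function(ns) unique(as.character(if (is.null(e[[ns]])) character() else e[[ns]])))
  })
  class(out) <- "annotation_map"
  out
}

#' @export
print.annotation_map <- function(x, ...) {
  n <- length(x)
  cat("annotation_map:", n, "genes,", length(annotated_genes(x)),
      "with >=1 GO term\n")
  invisible(x)
}

#' Gene identifiers carrying at least one GO term
#'
#' @param annotations an `annotation_map`.
#' @return Character vector of gene identifiers.
#' @export
annotated_genes <- function(annotations) {
  keep <- vapply(unclass(annotations),
                 function(e) any(lengths(e) > 0L), logical(1))
  names(annotations)[keep]
}

#' Construct an ordered gene table
#'
#' @param df data frame with columns `replicon`, `gene_id`, `strand`
#'   (`"+"` or `"-"`), optional `operon_id`, and either `rank` (0-based
#'   order within the replicon) or `start` (genes are ranked by start
#'   coordinate within each replicon).
#' @param topology `"circular"` (bacterial default) or `"linear"`;
#'   either a single value or a named vector per replicon.
#' @return A data frame of class `genome_table` with columns `replicon`,
#'   `gene_id`, `rank`, `strand`, `operon_id`, carrying a per-replicon
#'   `topology` attribute.
#' @export
genome_table <- function(df, topology = "circular") {
  stopifnot(all(c("replicon", "gene_id", "strand") %in% names(df)))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in gene table: ",
         df$gene_id[duplicated(df$gene_id)][1L])
  if (any(is.na(df$strand)) || !all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every gene")
  if (is.null(df$operon_id)) df$operon_id <- NA_character_
  if (is.null(df$rank)) {
    if (is.null(df$start)) stop("gene table needs either 'rank' or 'start'")
    df <- df[order(df$replicon, df$start), , drop = FALSE]
    df$rank <- stats::ave(seq_len(nrow(df)), df$replicon,
                          FUN = function(i) seq_along(i) - 1L)
  } else {
    df <- df[order(df$replicon, df$rank), , drop = FALSE]
    ok <- tapply(df$rank, df$replicon,
                 function(r) identical(as.integer(sort(r)),
                                       seq_len(length(r)) - 1L))
    if (!all(unlist(ok)))
      stop("ranks within a replicon must be consecutive integers from 0")
  }
  reps <- unique(df$replicon)
  topo <- if (length(topology) == 1L && is.null(names(topology)))
    stats::setNames(rep(topology, length(reps)), reps)
  else {
    missing <- setdiff(reps, names(topology))
    c(topology, stats::setNames(rep("circular", length(missing)), missing))[reps]
  }
  stopifnot(all(topo %in% c("circular", "linear")))

  # operon sanity: members contiguous in rank and on one strand
  ops <- df[!is.na(df$operon_id), , drop = FALSE]
  if (nrow(ops)) {
    for (op in unique(ops$operon_id)) {
      m <- ops[ops$operon_id == op, , drop = FALSE]
      if (length(unique(m$strand)) > 1L)
        warning("operon ", op, " spans both strands")
      if (length(unique(m$replicon)) == 1L && nrow(m) > 1L) {
        r <- sort(m$rank)
        n_rep <- sum(df$replicon == m$replicon[1L])
        contiguous <- all(diff(r) == 1L) ||
          (topo[m$replicon[1L]] == "circular" &&
             all(diff(sort((r - r[1L]) %% n_rep)) == 1L))
        if (!contiguous)
          warning("operon ", op, " is not contiguous in gene order")
      }
    }
  }
  out <- df[, c("replicon", "gene_id", "rank", "strand", "operon_id")]
  rownames(out) <- NULL
  attr(out, "topology") <- topo
  class(out) <- c("genome_table", "data.frame")
  out
}

#' Read an ordered gene table from TSV or GFF3
#'
#' The TSV dialect has a header line and columns `replicon`, `gene_id`,
#' `start`, `end`, `strand`, and optionally `operon_id` (1-based
#' inclusive coordinates). GFF3 input (requires the rtracklayer package)
#' keeps `gene`-type features, using the `ID` attribute as gene_id and an
#' `operon` attribute, when present, as operon_id. In both cases genes
#' are ordered by start coordinate within each replicon.
#'
#' @param path input file.
#' @param topology per-replicon topology, as in [genome_table()].
#' @param format `"auto"` (by extension), `"tsv"`, or `"gff3"`.
#' @return A `genome_table`.
#' @export
read_gene_table <- function(path, topology = "circular",
                            format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3" else "tsv"
  }
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("replicon", "gene_id", "start", "strand") %in% names(df)))
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- as.data.frame(rtracklayer::import(path))
    gr <- gr[as.character(gr$type) == "gene", , drop = FALSE]
    df <- data.frame(
      replicon = as.character(gr$seqnames),
      gene_id = as.character(gr$ID),
      start = gr$start,
      strand = as.character(gr$strand),
      stringsAsFactors = FALSE
    )
    df$operon_id <- if ("operon" %in% names(gr))
      as.character(gr$operon) else NA_character_
    if (any(!df$strand %in% c("+", "-")))
      stop("GFF3 gene feature with undefined strand")
  }
  genome_table(df, topology = topology)
}

#' Write a gene table as TSV
#'
#' @param genome a `genome_table`.
#' @param path output path. Ranks are converted back to synthetic
#'   1-based start/end coordinates so the file round-trips through
#'   [read_gene_table()].
#' @export
write_gene_table <- function(genome, path) {
  df <- as.data.frame(genome)
  out <- data.frame(
    replicon = df$replicon, gene_id = df$gene_id,
    start = df$rank * 1000L + 1L, end = df$rank * 1000L + 900L,
    strand = df$strand, operon_id = df$operon_id,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene-to-GO annotations from a GAF 2.x file
#'
#' Rows with a `NOT` qualifier are skipped; terms are bucketed by the
#' ontology's namespace assignment (not the GAF aspect column); alt_id
#' aliases are resolved; terms absent from the ontology, and root terms,
#' are dropped with a warning. The GAF object identifier (column 2) must
#' match the gene table's gene_id; an optional two-column alias TSV
#' (`alias`, `gene_id`) remaps identifiers first.
#'
#' @param path GAF 2.1/2.2 file (`!`-prefixed comment lines ignored).
#' @param graph an `ontology_graph`.
#' @param alias optional path to a two-column TSV remapping object
#'   identifiers to gene identifiers.
#' @return An `annotation_map`.
#' @export
read_gaf <- function(path, graph, alias = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  alias_map <- NULL
  if (!is.null(alias)) {
    am <- utils::read.delim(alias, header = TRUE, stringsAsFactors = FALSE)
    alias_map <- stats::setNames(am[[2L]], am[[1L]])
  }
  acc <- list()
  n_bad <- 0L; n_unknown <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 15L) {
      n_bad <- n_bad + 1L
      message("read_gaf: skipping malformed row at data line ", i)
      next
    }
    if (grepl("(^|\\|)NOT($|\\|)", f[4L])) next
    gene <- f[2L]
    if (!is.null(alias_map) && !is.na(alias_map[gene])) gene <- alias_map[[gene]]
    term <- resolve_term(graph, f[5L])
    if (is.na(term) || term %in% graph$roots) {
      n_unknown <- n_unknown + 1L
      next
    }
    ns <- graph$namespace[[term]]
    acc[[gene]][[ns]] <- c(acc[[gene]][[ns]], term)
  }
  if (n_unknown > 0L)
    warning(n_unknown, " GAF row(s) referenced terms absent from the ontology (or roots); dropped")
  annotation_map(acc)
}

#' Write an annotation map as GAF 2.1
#'
#' Minimal but valid 17-column rows (IEA evidence, synthetic reference),
#' so that synthetic annotations flow through [read_gaf()].
#'
#' @param annotations an `annotation_map`.
#' @param graph an `ontology_graph` (for namespace -> aspect letters).
#' @param path output path.
#' @export
write_gaf <- function(annotations, graph, path) {
  aspect <- c(BP = "P", MF = "F", CC = "C")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.1", con)
  today <- format(Sys.Date(), "%Y%m%d")
  for (gene in names(annotations)) {
    e <- annotations[[gene]]
    for (ns in GO_NAMESPACES) {
      for (term in e[[ns]]) {
        row <- c("SYN", gene, gene, "", term, "SYN_REF:0000001", "IEA", "",
                 aspect[[ns]], "", "", "protein", "taxon:0", today, "SYN", "", "")
        writeLines(paste(row, collapse = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Build a background pool from annotated entries
#'
#' Restricts to entries carrying at least one GO term; these are the
#' proteins from which [random_annotation()] draws whole annotation
#' transfers, and the denominator population for [term_frequencies()].
#'
#' @param annotations an `annotation_map` (or another `background_pool`,
#'   returned unchanged).
#' @return An object of class `background_pool`.
#' @export
background_pool <- function(annotations) {
  if (inherits(annotations, "background_pool")) return(annotations)
  ids <- annotated_genes(annotations)
  if (!length(ids)) stop("no annotated entries to build a background pool from")
  structure(list(entries = unclass(annotations)[ids]),
            class = "background_pool")
}

#' @export
print.background_pool <- function(x, ...) {
  cat("background_pool:", length(x$entries), "annotated entries\n")
  invisible(x)
}

#' Randomize annotations by whole-protein transfer from a pool
#'
#' Each gene carrying at least one GO term is reassigned the complete
#' per-namespace term sets of one entry drawn uniformly (with
#' replacement across genes) from the background pool. Unannotated genes
#' stay unannotated, so the randomization preserves *which* genes are
#' annotated and only replaces *what* the annotation is.
#'
#' @param annotations an `annotation_map`.
#' @param pool a `background_pool` (or an `annotation_map` to pool).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A new `annotation_map`.
#' @export
random_annotation <- function(annotations, pool, seed) {
  pool <- background_pool(pool)
  targets <- annotated_genes(annotations)
  out <- unclass(annotations)
  if (length(targets)) {
    idx <- withr_seed(seed, sample.int(length(pool$entries), length(targets),
                                       replace = TRUE))
    out[targets] <- pool$entries[idx]
  }
  class(out) <- "annotation_map"
  out
}

# Evaluate expr under a local RNG seed without disturbing the caller's
# RNG state.
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child seed for a named substream, kept below 2^31.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) + 97003 * h) %% 2147483647)
}
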