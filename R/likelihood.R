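#' Equal-width binning scheme over [0, 1]
#'
#' GFS values are continuous; the likelihood tables are empirical
#' frequencies over equal-width bins. Bins are left-closed with the last
#' bin right-closed, so `bin_of(0) = 1` and `bin_of(1) = n_bins`.
#'
#' @param n_bins number of bins (default 10).
#' @return An object of class `binning_scheme` with elements `n_bins`
#'   and `edges`.
#' @export
binning_scheme <- function(n_bins = 10L) {
  stopifnot(n_bins >= 1L)
  structure(list(n_bins = as.integer(n_bins),
                 edges = seq(0, 1, length.out = n_bins + 1L)),
            class = "binning_scheme")
}

#' Bin index of a similarity value
#'
#' @param x numeric vector in \[0, 1\] (NAs pass through).
#' @param scheme a `binning_scheme`.
#' @return Integer bin indices in 1..n_bins.
#' @export
bin_of <- function(x, scheme) {
  idx <- findInterval(x, scheme$edges, rightmost.closed = TRUE)
  idx[!is.na(x) & (x < 0 | x > 1)] <- NA_integer_
  as.integer(idx)
}

# Cell key for likelihood tables: offset x namespace, with a strand
# stratum in strand mode.
cell_key <- function(offset, namespace, same_strand = NULL) {
  if (is.null(same_strand)) paste0(offset, "|", namespace)
  else paste0(offset, "|", namespace, "|",
              ifelse(same_strand, "same", "opposite"))
}

smoothed_probs <- function(counts, pseudocount) {
  K <- length(counts)
  N <- sum(counts)
  if (N == 0 && pseudocount == 0)
    stop("empty likelihood cell with pseudocount 0; use pseudocount > 0")
  (counts + pseudocount) / (N + pseudocount * K)
}

#' Estimate per-position empirical likelihoods
#'
#' Builds the conditional probability tables Pr(observation | correct
#' annotation) and Pr(observation | incorrect annotation), one cell per
#' (offset, namespace) — per (offset, namespace, strand stratum) in
#' strand mode — from two observation-profile collections: the genome
#' under its given annotation (assumed correct) and under a randomized
#' annotation (assumed incorrect). Within each cell, bin probabilities
#' are Laplace-smoothed empirical frequencies,
#' `(count + a) / (N + a * K)` with `a` the pseudocount and `K` the
#' number of bins; missing observations contribute nothing.
#'
#' @param profiles_correct,profiles_random `observation_profiles` built
#'   in the same mode and window over the same genome geometry.
#' @param scheme a `binning_scheme` (default 10 equal-width bins).
#' @param pseudocount Laplace smoothing constant (default 1); with a
#'   positive pseudocount no probability is exactly zero, which keeps a
#'   single unusual observation from forcing a posterior of exactly 0
#'   or 1.
#' @return An object of class `likelihood_model`.
#' @export
estimate_likelihoods <- function(profiles_correct, profiles_random,
                                 scheme = binning_scheme(),
                                 pseudocount = 1) {
  mode <- attr(profiles_correct, "mode")
  window <- attr(profiles_correct, "window")
  if (!identical(mode, attr(profiles_random, "mode")))
    stop("profile collections were built in different modes")
  if (!identical(window, attr(profiles_random, "window")))
    stop("profile collections were built with different windows")
  stopifnot(pseudocount >= 0)
  strand_strata <- if (mode == "strand") c(TRUE, FALSE) else NULL

  offsets <- setdiff(seq.int(-window, window), 0L)
  tables <- list()
  count_cell <- function(prof, off, ns, strand) {
    sel <- prof$offset == off & prof$namespace == ns & !is.na(prof$gfs)
    if (!is.null(strand)) sel <- sel & prof$same_strand == strand
    tabulate(bin_of(prof$gfs[sel], scheme), nbins = scheme$n_bins)
  }
  for (off in offsets) for (ns in GO_NAMESPACES) {
    strata <- if (is.null(strand_strata)) list(NULL) else as.list(strand_strata)
    for (st in strata) {
      cc <- count_cell(profiles_correct, off, ns, st)
      ci <- count_cell(profiles_random, off, ns, st)
      tables[[cell_key(off, ns, st)]] <- list(
        counts_correct = cc, counts_incorrect = ci,
        p_correct = smoothed_probs(cc, pseudocount),
        p_incorrect = smoothed_probs(ci, pseudocount),
        n_correct = sum(cc), n_incorrect = sum(ci)
      )
    }
  }
  structure(list(scheme = scheme, pseudocount = pseudocount, mode = mode,
                 window = window, tables = tables),
            class = "likelihood_model")
}

#' @export
print.likelihood_model <- function(x, ...) {
  cat("likelihood_model: mode", x$mode, "| window", x$window,
      "|", x$scheme$n_bins, "bins | pseudocount", x$pseudocount, "\n")
  cat("  cells:", length(x$tables), "\n")
  invisible(x)
}

#' Look up a likelihood for one observation
#'
#' @param model a `likelihood_model`.
#' @param offset signed neighbor offset.
#' @param namespace `"BP"`, `"MF"`, or `"CC"`.
#' @param gfs observed gene function similarity (must be non-missing;
#'   callers skip missing observations).
#' @param same_strand logical strand flag, required in strand mode.
#' @param hypothesis `"correct"` or `"incorrect"`.
#' @return The bin probability.
#' @export
likelihood_lookup <- function(model, offset, namespace, gfs,
                              same_strand = NA,
                              hypothesis = c("correct", "incorrect")) {
  hypothesis <- match.arg(hypothesis)
  if (is.na(gfs)) stop("missing observation has no likelihood; skip it")
  st <- if (model$mode == "strand") {
    if (is.na(same_strand)) stop("strand mode requires a same_strand flag")
    same_strand
  } else NULL
  cell <- model$tables[[cell_key(offset, namespace, st)]]
  if (is.null(cell)) stop("no likelihood cell for offset ", offset,
                          ", namespace ", namespace)
  p <- if (hypothesis == "correct") cell$p_correct else cell$p_incorrect
  p[[bin_of(gfs, model$scheme)]]
}

# Vectorised log-likelihood lookup over profile rows; rows with missing
# gfs (or, in strand mode, any needed stratum) return NA and are skipped
# by the caller.
profile_loglik <- function(profiles, model) {
  keys <- if (model$mode == "strand")
    cell_key(profiles$offset, profiles$namespace, profiles$same_strand)
  else cell_key(profiles$offset, profiles$namespace)
  bins <- bin_of(profiles$gfs, model$scheme)
  lc <- rep(NA_real_, nrow(profiles))
  li <- rep(NA_real_, nrow(profiles))
  ok <- !is.na(bins)
  if (any(ok)) {
    uk <- unique(keys[ok])
    for (k in uk) {
      cell <- model$tables[[k]]
      if (is.null(cell)) stop("profiles reference a cell absent from the model (", k,
                              "); was the model built with the same mode/window?")
      sel <- ok & keys == k
      lc[sel] <- log(cell$p_correct[bins[sel]])
      li[sel] <- log(cell$p_incorrect[bins[sel]])
    }
  }
  list(log_correct = lc, log_incorrect = li)
}

#' Save / load a likelihood model as versioned JSON
#'
#' The serialized model carries the binning scheme, pseudocount, mode,
#' window, and per-cell counts and probabilities, so conditional
#' probabilities estimated on one genome can be applied to another
#' (likelihood transfer). Loading rejects schema-version or structural
#' mismatches.
#'
#' @param model a `likelihood_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  doc <- list(
    format = "annopac-likelihood-model",
    version = 1L,
    mode = model$mode,
    window = model$window,
    pseudocount = model$pseudocount,
    scheme = list(n_bins = model$scheme$n_bins, edges = model$scheme$edges),
    cells = lapply(names(model$tables), function(k) {
      cell <- model$tables[[k]]
      c(list(key = k), cell)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(doc$format, "annopac-likelihood-model") ||
      !identical(as.integer(doc$version), 1L))
    stop("unrecognized model file schema/version: ", path)
  scheme <- structure(list(n_bins = as.integer(doc$scheme$n_bins),
                           edges = as.numeric(doc$scheme$edges)),
                      class = "binning_scheme")
  tables <- list()
  for (cell in doc$cells) {
    key <- cell$key
    cell$key <- NULL
    cell$counts_correct <- as.numeric(cell$counts_correct)
    cell$counts_incorrect <- as.numeric(cell$counts_incorrect)
    cell$p_correct <- as.numeric(cell$p_correct)
    cell$p_incorrect <- as.numeric(cell$p_incorrect)
    tables[[key]] <- cell
  }
  structure(list(scheme = scheme, pseudocount = doc$pseudocount,
                 mode = doc$mode, window = as.integer(doc$window),
                 tables = tables),
            class = "likelihood_model")
}

#' Check a model is applicable to a profile collection
#'
#' Likelihood transfer across genomes is allowed; mode or window
#' mismatches are not.
#'
#' @param model a `likelihood_model`.
#' @param profiles an `observation_profiles` table.
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
check_model_compatibility <- function(model, profiles) {
  if (!identical(model$mode, attr(profiles, "mode")))
    stop("model mode '", model$mode, "' does not match profile mode '",
         attr(profiles, "mode"), "'")
  if (!identical(model$window, attr(profiles, "window")))
    stop("model window ", model$window, " does not match profile window ",
         attr(profiles, "window"))
  invisible(TRUE)
}
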