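#' Probability of annotation confidence for profile collections
#'
#' Combines each gene's non-missing neighborhood observations through
#' Bayes' rule under the independence assumption: the posterior that the
#' gene's annotation is correct is
#' `prior * L_c / (prior * L_c + (1 - prior) * L_inc)` where `L_c` and
#' `L_inc` are the products over observations of the per-cell
#' likelihoods under the correct and incorrect hypotheses. Missing
#' observations are skipped from both products on the grounds that
#' absent information arises equally under either hypothesis. Products
#' are accumulated in log space. A gene with no non-missing observation
#' is ineligible and gets `NA`.
#'
#' @param profiles an `observation_profiles` table (any number of genes).
#' @param model a compatible `likelihood_model`.
#' @param prior_correct prior probability that an annotation is correct,
#'   in (0, 1); default 0.5.
#' @return Data frame with columns `gene_id`, `n_obs` (non-missing
#'   observations used) and `pac` (`NA` for ineligible genes).
#' @export
compute_pac <- function(profiles, model, prior_correct = 0.5) {
  stopifnot(prior_correct > 0, prior_correct < 1)
  check_model_compatibility(model, profiles)
  ll <- profile_loglik(profiles, model)
  ok <- !is.na(ll$log_correct)
  genes <- unique(profiles$gene_id)
  sum_c <- tapply(ifelse(ok, ll$log_correct, 0), profiles$gene_id, sum)
  sum_i <- tapply(ifelse(ok, ll$log_incorrect, 0), profiles$gene_id, sum)
  n_obs <- tapply(ok, profiles$gene_id, sum)
  out <- data.frame(
    gene_id = names(sum_c),
    n_obs = as.integer(n_obs[names(sum_c)]),
    pac = .posterior(as.numeric(sum_c), as.numeric(sum_i), prior_correct),
    stringsAsFactors = FALSE
  )
  out$pac[out$n_obs == 0L] <- NA_real_
  out <- out[match(genes, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Numerically stable posterior from summed log-likelihoods.
.posterior <- function(loglik_correct, loglik_incorrect, prior) {
  a <- log(prior) + loglik_correct
  b <- log1p(-prior) + loglik_incorrect
  m <- pmax(a, b)
  exp(a - m) / (exp(a - m) + exp(b - m))
}

#' PAC of a single gene
#'
#' @param profile one gene's `observation_profiles` rows (e.g. from
#'   [build_profile()]).
#' @inheritParams compute_pac
#' @return One-row data frame (`gene_id`, `n_obs`, `pac`).
#' @export
pac_for_gene <- function(profile, model, prior_correct = 0.5) {
  stopifnot(length(unique(profile$gene_id)) <= 1L)
  compute_pac(profile, model, prior_correct)
}

#' Estimate a first-order dependent (chain) likelihood model
#'
#' The dependent variant relaxes the independence assumption within each
#' direction of the neighborhood: the observation at offset `+/-1`
#' enters through its marginal table, and the observation at `+/-k`
#' (k = 2, 3) is conditioned on the adjacent observation toward the
#' focal gene, via binned first-order conditional tables estimated from
#' gene profiles where both observations are non-missing. Rows of each
#' conditional table are Laplace-smoothed.
#'
#' @inheritParams estimate_likelihoods
#' @return A `chain_model`: the marginal `likelihood_model` plus
#'   per-(offset, namespace) conditional bin matrices under each
#'   hypothesis.
#' @export
estimate_chain_model <- function(profiles_correct, profiles_random,
                                 scheme = binning_scheme(),
                                 pseudocount = 1) {
  marginal <- estimate_likelihoods(profiles_correct, profiles_random,
                                   scheme, pseudocount)
  if (marginal$mode == "strand")
    stop("the dependent model is defined for plain/operon profiles")
  K <- scheme$n_bins
  window <- marginal$window
  cond_from <- function(prof) {
    res <- list()
    # wide per-gene bin matrix for fast pairing of adjacent offsets
    for (ns in GO_NAMESPACES) {
      sub <- prof[prof$namespace == ns, , drop = FALSE]
      bins <- bin_of(sub$gfs, scheme)
      for (o in setdiff(seq.int(-window, window), c(-1L, 0L, 1L))) {
        inner <- o - sign(o)                       # offset toward the gene
        bo <- bins[sub$offset == o]
        gi <- sub$gene_id[sub$offset == o]
        bi <- bins[sub$offset == inner]
        gii <- sub$gene_id[sub$offset == inner]
        bi <- bi[match(gi, gii)]
        keep <- !is.na(bo) & !is.na(bi)
        counts <- matrix(0, K, K)
        if (any(keep))
          for (i in which(keep))
            counts[bi[i], bo[i]] <- counts[bi[i], bo[i]] + 1
        probs <- t(apply(counts, 1L, smoothed_probs, pseudocount = pseudocount))
        res[[cell_key(o, ns)]] <- probs
      }
    }
    res
  }
  structure(list(marginal = marginal,
                 conditional = list(correct = cond_from(profiles_correct),
                                    incorrect = cond_from(profiles_random))),
            class = "chain_model")
}

#' PAC under the dependent (chain) model
#'
#' Per gene, namespace and direction, the likelihood factorizes as
#' `Pr(O_1 | A) * Pr(O_2 | O_1, A) * Pr(O_3 | O_2, A)` (and mirrored
#' upstream); when the conditioning observation is missing, the
#' conditioned one falls back to its marginal table. Bayes combination
#' and eligibility are as in [compute_pac()]. With conditional tables
#' equal to the marginals, the result reduces exactly to the independent
#' model.
#'
#' @param profiles an `observation_profiles` table.
#' @param chain_model a `chain_model` from [estimate_chain_model()].
#' @param prior_correct prior probability of a correct annotation.
#' @return Data frame as in [compute_pac()].
#' @export
pac_dependent <- function(profiles, chain_model, prior_correct = 0.5) {
  stopifnot(prior_correct > 0, prior_correct < 1)
  marginal <- chain_model$marginal
  check_model_compatibility(marginal, profiles)
  scheme <- marginal$scheme
  genes <- unique(profiles$gene_id)
  out <- data.frame(gene_id = genes, n_obs = 0L, pac = NA_real_,
                    stringsAsFactors = FALSE)
  bins_all <- bin_of(profiles$gfs, scheme)
  for (gi in seq_along(genes)) {
    sel <- profiles$gene_id == genes[gi]
    sub <- profiles[sel, , drop = FALSE]
    bins <- bins_all[sel]
    lc <- 0; li <- 0; n_used <- 0L
    for (ns in GO_NAMESPACES) {
      nsel <- sub$namespace == ns
      b_of <- stats::setNames(bins[nsel], sub$offset[nsel])
      for (o in setdiff(seq.int(-marginal$window, marginal$window), 0L)) {
        b <- b_of[as.character(o)]
        if (length(b) == 0L || is.na(b)) next
        n_used <- n_used + 1L
        inner <- o - sign(o)
        b_in <- if (inner == 0L) NA_integer_ else b_of[as.character(inner)]
        if (abs(o) >= 2L && length(b_in) == 1L && !is.na(b_in)) {
          key <- cell_key(o, ns)
          lc <- lc + log(chain_model$conditional$correct[[key]][b_in, b])
          li <- li + log(chain_model$conditional$incorrect[[key]][b_in, b])
        } else {
          cell <- marginal$tables[[cell_key(o, ns)]]
          lc <- lc + log(cell$p_correct[b])
          li <- li + log(cell$p_incorrect[b])
        }
      }
    }
    out$n_obs[gi] <- n_used
    if (n_used > 0L)
      out$pac[gi] <- .posterior(lc, li, prior_correct)
  }
  out
}

#' PAC histogram bin counts
#'
#' Twenty bins of width 0.05: \[0, 0.05), ..., \[0.90, 0.95),
#' \[0.95, 1\] — the last bin is closed so that the high-confidence bin
#' of the AQS is exactly one histogram bin.
#'
#' @param pac numeric vector of PAC values (NAs ignored).
#' @return Named integer vector of length 20 (names are bin right ends).
#' @export
pac_histogram <- function(pac) {
  pac <- pac[!is.na(pac)]
  # the small fuzz keeps values like 0.95 (not exactly representable)
  # in their intended bin
  idx <- pmin(floor(pac * 20 + 1e-9) + 1L, 20L)
  counts <- tabulate(idx, nbins = 20L)
  stats::setNames(as.integer(counts), sprintf("%.2f", seq(0.05, 1, by = 0.05)))
}

#' Annotation quality score
#'
#' The fraction of PAC-eligible genes whose PAC falls in \[0.95, 1\].
#'
#' @param pac numeric vector of PAC values; `NA` marks ineligible genes
#'   and is excluded from the denominator.
#' @return The AQS, or `NA` if no gene is eligible.
#' @export
aqs <- function(pac) {
  elig <- pac[!is.na(pac)]
  if (!length(elig)) return(NA_real_)
  # same bin convention (and boundary fuzz) as pac_histogram
  sum(elig * 20 + 1e-9 >= 19) / length(elig)
}

#' Score a genome's annotation
#'
#' Builds observation profiles for every gene, computes each gene's PAC
#' under the supplied likelihood model, and summarizes the genome as the
#' AQS with a 20-bin PAC histogram. Genes with no eligible observation
#' (including genes on replicons too short to have neighbors) are
#' reported with `NA` PAC and excluded from the AQS denominator.
#'
#' @param genome a `genome_table`.
#' @param annotations an `annotation_map` (already term-filtered).
#' @param graph an `ontology_graph`.
#' @param model a `likelihood_model`.
#' @param mode profile mode; defaults to the model's mode.
#' @param prior_correct prior probability of a correct annotation.
#' @param window neighborhood half-width; defaults to the model's.
#' @return An object of class `genome_score`: list with `results`
#'   (per-gene data frame), `n_genes`, `n_eligible`, `aqs`,
#'   `bin_counts`.
#' @export
score_genome <- function(genome, annotations, graph, model,
                         mode = model$mode, prior_correct = 0.5,
                         window = model$window) {
  profiles <- build_profiles(genome, annotations, graph, mode = mode,
                             window = window)
  score_profiles(profiles, model, prior_correct = prior_correct,
                 all_genes = genome$gene_id)
}

#' Score pre-built profiles
#'
#' @param profiles an `observation_profiles` table.
#' @param model a `likelihood_model`.
#' @param prior_correct prior probability of a correct annotation.
#' @param all_genes optional full gene_id vector; genes without profile
#'   rows are reported as ineligible.
#' @return A `genome_score`.
#' @export
score_profiles <- function(profiles, model, prior_correct = 0.5,
                           all_genes = NULL) {
  res <- compute_pac(profiles, model, prior_correct)
  if (!is.null(all_genes)) {
    missing <- setdiff(all_genes, res$gene_id)
    if (length(missing))
      res <- rbind(res, data.frame(gene_id = missing, n_obs = 0L,
                                   pac = NA_real_, stringsAsFactors = FALSE))
    res <- res[match(all_genes, res$gene_id), , drop = FALSE]
    rownames(res) <- NULL
  }
  structure(list(results = res,
                 n_genes = nrow(res),
                 n_eligible = sum(!is.na(res$pac)),
                 aqs = aqs(res$pac),
                 bin_counts = pac_histogram(res$pac)),
            class = "genome_score")
}

#' @export
print.genome_score <- function(x, ...) {
  cat("genome_score:", x$n_genes, "genes,", x$n_eligible, "eligible\n")
  cat(sprintf("  AQS = %.3f (%d genes with PAC in [0.95, 1])\n",
              x$aqs, x$bin_counts[["1.00"]]))
  invisible(x)
}

#' Calibration curve (reliability diagram) of PAC values
#'
#' Pools each eligible gene's PAC under the correct annotation with its
#' PAC under a randomized annotation, bins the pooled values with the
#' PAC histogram convention, and reports per bin the fraction of pooled
#' entries that came from the correct annotation. A well-calibrated
#' model puts this fraction near the bin's right-end PAC value. Empty
#' bins are reported with `NA` fraction, not zero.
#'
#' @param scores_correct,scores_random `genome_score` objects computed
#'   under the same model.
#' @return Data frame with columns `bin_right`, `n_correct`,
#'   `n_incorrect`, `fraction_correct`.
#' @export
calibration_curve <- function(scores_correct, scores_random) {
  pc <- scores_correct$results$pac
  pr <- scores_random$results$pac
  nc <- pac_histogram(pc)
  ni <- pac_histogram(pr)
  total <- nc + ni
  frac <- ifelse(total > 0, nc / total, NA_real_)
  data.frame(bin_right = seq(0.05, 1, by = 0.05),
             n_correct = as.integer(nc), n_incorrect = as.integer(ni),
             fraction_correct = frac)
}

#' Write per-gene results and genome summary
#'
#' @param score a `genome_score`.
#' @param tsv_path per-gene TSV (`gene_id`, `n_obs`, `pac`; empty pac
#'   field for ineligible genes).
#' @param json_path optional summary JSON (`n_genes`, `n_eligible`,
#'   `aqs`, `bin_counts`).
#' @export
write_genome_score <- function(score, tsv_path, json_path = NULL) {
  df <- score$results
  df$pac <- ifelse(is.na(df$pac), "", format(df$pac, digits = 10))
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_genes = score$n_genes, n_eligible = score$n_eligible,
           aqs = score$aqs, bin_counts = as.list(score$bin_counts)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}

#' Write a calibration curve as TSV
#'
#' @param curve output of [calibration_curve()].
#' @param path output path.
#' @export
write_calibration <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
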