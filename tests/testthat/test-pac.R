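# Hand-built likelihood model over given per-cell probabilities, for
# exact Bayes arithmetic checks.
manual_model <- function(cells, n_bins = 10L, mode = "plain", window = 3L) {
  tables <- lapply(cells, function(cell) {
    list(counts_correct = rep(0, n_bins), counts_incorrect = rep(0, n_bins),
         p_correct = cell$p_correct, p_incorrect = cell$p_incorrect,
         n_correct = 0, n_incorrect = 0)
  })
  structure(list(scheme = binning_scheme(n_bins), pseudocount = 1,
                 mode = mode, window = window, tables = tables),
            class = "likelihood_model")
}

# one cell with a spike of mass p_hit in the bin of `at`, uniform rest
spike <- function(p_hit, at, n_bins = 10L) {
  v <- rep((1 - p_hit) / (n_bins - 1), n_bins)
  v[bin_of(at, binning_scheme(n_bins))] <- p_hit
  v
}

prof1 <- function(gene, offset, ns, gfs) {
  df <- data.frame(gene_id = gene, offset = offset, namespace = ns,
                   gfs = gfs, same_strand = TRUE, same_operon = TRUE,
                   stringsAsFactors = FALSE)
  attr(df, "mode") <- "plain"; attr(df, "window") <- 3L
  class(df) <- c("observation_profiles", "data.frame")
  df
}

test_that("a single observation combines with the prior exactly as Bayes' rule", {
  m <- manual_model(list(`1|BP` = list(p_correct = spike(0.9, 0.85),
                                       p_incorrect = spike(0.1, 0.85))))
  res <- pac_for_gene(prof1("g", 1L, "BP", 0.85), m, prior_correct = 0.5)
  # 0.5 * 0.9 / (0.5 * 0.9 + 0.5 * 0.1)
  expect_equal(res$pac, 0.9, tolerance = 1e-12)
  expect_equal(res$n_obs, 1L)
})

test_that("two observations multiply into the hand-computed posterior 0.36/0.37", {
  m <- manual_model(list(
    `1|BP` = list(p_correct = spike(0.9, 0.85), p_incorrect = spike(0.1, 0.85)),
    `2|BP` = list(p_correct = spike(0.8, 0.85), p_incorrect = spike(0.2, 0.85))
  ))
  prof <- prof1("g", c(1L, 2L), "BP", c(0.85, 0.85))
  res <- pac_for_gene(prof, m, prior_correct = 0.5)
  expect_equal(res$pac, 0.36 / 0.37, tolerance = 1e-12)   # ~0.973
})

test_that("likelihood-ratio-one profiles return exactly the prior", {
  eq <- list(p_correct = spike(0.7, 0.3), p_incorrect = spike(0.7, 0.3))
  m <- manual_model(list(`1|BP` = eq, `-1|BP` = eq, `2|MF` = eq))
  prof <- rbind(prof1("g", c(1L, -1L), "BP", c(0.3, 0.3)),
                prof1("g", 2L, "MF", 0.3))
  attr(prof, "mode") <- "plain"; attr(prof, "window") <- 3L
  class(prof) <- c("observation_profiles", "data.frame")
  expect_equal(pac_for_gene(prof, m, prior_correct = 0.5)$pac, 0.5)
  expect_equal(pac_for_gene(prof, m, prior_correct = 0.3)$pac, 0.3,
               tolerance = 1e-12)
})

test_that("genes without usable observations are ineligible", {
  m <- manual_model(list(`1|BP` = list(p_correct = spike(0.9, 0.9),
                                       p_incorrect = spike(0.1, 0.9))))
  res <- pac_for_gene(prof1("g", 1L, "BP", NA_real_), m)
  expect_true(is.na(res$pac))
  expect_equal(res$n_obs, 0L)
})

test_that("posterior and its complement sum to one for every synthetic gene", {
  study <- default_study()
  res_c <- compute_pac(study$profiles_correct, study$model, 0.5)
  # complement computed the same way with hypotheses swapped
  swapped <- study$model
  swapped$tables <- lapply(swapped$tables, function(cell) {
    tmp <- cell$p_correct; cell$p_correct <- cell$p_incorrect
    cell$p_incorrect <- tmp; cell
  })
  res_i <- compute_pac(study$profiles_correct, swapped, 0.5)
  ok <- !is.na(res_c$pac)
  expect_true(all(abs(res_c$pac[ok] + res_i$pac[ok] - 1) < 1e-12))
})

test_that("PAC increases monotonically in a single observation's likelihood ratio", {
  pacs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 0.99), function(p) {
    m <- manual_model(list(
      `1|BP` = list(p_correct = spike(p, 0.9), p_incorrect = spike(0.5, 0.9)),
      `2|BP` = list(p_correct = spike(0.6, 0.2), p_incorrect = spike(0.4, 0.2))
    ))
    pac_for_gene(prof1("g", c(1L, 2L), "BP", c(0.9, 0.2)), m)$pac
  }, numeric(1))
  expect_true(all(diff(pacs) > 0))
})

test_that("AQS is the high-confidence fraction of eligible genes", {
  # the printed worked ratios: in-bin / eligible counts
  pac_ecoli <- c(rep(0.97, 1021), rep(0.5, 3117 - 1021))
  expect_equal(round(aqs(pac_ecoli), 2), 0.33)
  pac_rand <- c(rep(0.96, 49), rep(0.2, 3117 - 49))
  expect_equal(round(aqs(pac_rand), 3), 0.016)
  pac_cth <- c(rep(0.99, 403), rep(0.5, 1671 - 403))
  expect_equal(round(aqs(pac_cth), 2), 0.24)
  pac_old <- c(rep(0.99, 349), rep(0.5, 1582 - 349))
  expect_equal(round(aqs(pac_old), 2), 0.22)
  # ineligible genes are excluded from the denominator
  expect_equal(aqs(c(0.99, NA, NA, 0.2)), 0.5)
  expect_equal(aqs(rep(0.96, 5)), 1.0)
  expect_true(is.na(aqs(rep(NA_real_, 3))))
})

test_that("PAC histogram puts [0.95, 1] in exactly the last bin", {
  h <- pac_histogram(c(0, 0.049, 0.05, 0.949, 0.95, 1.0, NA))
  expect_equal(sum(h), 6L)
  expect_equal(unname(h[1L]), 2L)       # 0 and 0.049
  expect_equal(unname(h[2L]), 1L)       # 0.05 joins the second bin
  expect_equal(unname(h[19L]), 1L)      # 0.949
  expect_equal(unname(h[20L]), 2L)      # 0.95 and 1.0 both in the closed bin
})

test_that("score_genome reports every gene and a consistent AQS", {
  study <- default_study()
  sc <- score_profiles(study$profiles_correct, study$model,
                       all_genes = study$genome$gene_id)
  expect_equal(nrow(sc$results), nrow(study$genome))
  expect_equal(sc$n_eligible, sum(!is.na(sc$results$pac)))
  expect_equal(sc$aqs, aqs(sc$results$pac))
  expect_equal(sum(sc$bin_counts), sc$n_eligible)
  expect_equal(unname(sc$bin_counts[20L]),
               sum(sc$results$pac >= 0.95, na.rm = TRUE))
  # per-gene TSV + summary JSON round out with the same numbers
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_genome_score(sc, tsv, js)
  back <- utils::read.delim(tsv)
  expect_equal(sum(!is.na(back$pac)), sc$n_eligible)
  summ <- jsonlite::read_json(js)
  expect_equal(summ$aqs, sc$aqs)
})

test_that("calibration pools correct and random PACs with hand-tallied fractions", {
  fake_score <- function(pacs) {
    structure(list(results = data.frame(gene_id = seq_along(pacs),
                                        n_obs = 1L, pac = pacs),
                   n_genes = length(pacs),
                   n_eligible = sum(!is.na(pacs)),
                   aqs = aqs(pacs), bin_counts = pac_histogram(pacs)),
              class = "genome_score")
  }
  curve <- calibration_curve(
    fake_score(c(0.02, 0.97, 0.98, 0.52)),      # correct
    fake_score(c(0.03, 0.04, 0.96, 0.53)))      # random
  b <- function(x) which(abs(curve$bin_right - x) < 1e-9)
  expect_equal(curve$fraction_correct[b(0.05)], 1 / 3)
  expect_equal(curve$fraction_correct[b(1.00)], 2 / 3)
  expect_equal(curve$fraction_correct[b(0.55)], 1 / 2)
  empty <- setdiff(seq_len(20), c(b(0.05), b(1.00), b(0.55)))
  expect_true(all(is.na(curve$fraction_correct[empty])))
  expect_true(all(curve$n_correct[empty] + curve$n_incorrect[empty] == 0))
})

test_that("the chain model degenerates to the independent model when conditionals equal marginals", {
  study_small <- local({
    cfg <- simulation_config(seed = 21, n_genes = 120,
                             n_terms = c(BP = 30, MF = 30, CC = 30))
    g <- simulate_ontology(cfg)
    sim <- simulate_genome(cfg, g)
    rand <- random_annotation(sim$annotations,
                              background_pool(sim$annotations), seed = 22)
    pc <- build_profiles(sim$genome, sim$annotations, g)
    pr <- build_profiles(sim$genome, rand, g)
    list(pc = pc, pr = pr)
  })
  chain <- estimate_chain_model(study_small$pc, study_small$pr)
  # overwrite conditionals with row-stacked marginals
  for (hyp in c("correct", "incorrect")) {
    for (key in names(chain$conditional[[hyp]])) {
      cell <- chain$marginal$tables[[key]]
      p <- if (hyp == "correct") cell$p_correct else cell$p_incorrect
      K <- length(p)
      chain$conditional[[hyp]][[key]] <- matrix(rep(p, each = K), K, K)
    }
  }
  dep <- pac_dependent(study_small$pc, chain, 0.5)
  ind <- compute_pac(study_small$pc, chain$marginal, 0.5)
  expect_equal(dep$pac[order(dep$gene_id)], ind$pac[order(ind$gene_id)],
               tolerance = 1e-12)
  expect_equal(dep$n_obs[order(dep$gene_id)], ind$n_obs[order(ind$gene_id)])
})

test_that("single-observation profiles are identical under chain and independent models", {
  study_small <- local({
    cfg <- simulation_config(seed = 31, n_genes = 80,
                             n_terms = c(BP = 25, MF = 25, CC = 25),
                             frac_annotated = 0.3)
    g <- simulate_ontology(cfg)
    sim <- simulate_genome(cfg, g)
    rand <- random_annotation(sim$annotations,
                              background_pool(sim$annotations), seed = 32)
    list(pc = build_profiles(sim$genome, sim$annotations, g),
         pr = build_profiles(sim$genome, rand, g))
  })
  chain <- estimate_chain_model(study_small$pc, study_small$pr)
  dep <- pac_dependent(study_small$pc, chain, 0.5)
  ind <- compute_pac(study_small$pc, chain$marginal, 0.5)
  one_obs <- ind$gene_id[ind$n_obs == 1L]
  skip_if(length(one_obs) == 0L, "no single-observation gene in fixture")
  for (g_id in one_obs)
    expect_equal(dep$pac[dep$gene_id == g_id], ind$pac[ind$gene_id == g_id],
                 tolerance = 1e-12)
})

test_that("a three-observation chain matches hand arithmetic", {
  K <- 10L
  marg <- manual_model(list(
    `1|BP` = list(p_correct = spike(0.7, 0.95), p_incorrect = spike(0.2, 0.95)),
    `2|BP` = list(p_correct = spike(0.6, 0.55), p_incorrect = spike(0.3, 0.55)),
    `3|BP` = list(p_correct = spike(0.5, 0.15), p_incorrect = spike(0.4, 0.15))
  ))
  cond <- function(p_hit, at) {
    m <- matrix(1 / K, K, K)
    col <- bin_of(at, binning_scheme(K))
    m[, col] <- 0.05
    m[bin_of(0.95, binning_scheme(K)), ] <- (1 - p_hit) / (K - 1)
    m[bin_of(0.95, binning_scheme(K)), col] <- p_hit
    m
  }
  # conditionals keyed by the outer offset; rows indexed by inner bin
  chain <- structure(list(
    marginal = marg,
    conditional = list(
      correct = list(`2|BP` = cond(0.9, 0.55), `3|BP` = cond(0.8, 0.15)),
      incorrect = list(`2|BP` = cond(0.1, 0.55), `3|BP` = cond(0.3, 0.15))
    )), class = "chain_model")
  prof <- prof1("g", c(1L, 2L, 3L), "BP", c(0.95, 0.55, 0.15))
  res <- pac_dependent(prof, chain, 0.5)
  # chain likelihoods: O1 marginal, O2 | O1 (bin of 0.95), O3 | O2 (bin of 0.55)
  b95 <- bin_of(0.95, binning_scheme(K)); b55 <- bin_of(0.55, binning_scheme(K))
  b15 <- bin_of(0.15, binning_scheme(K))
  lc <- 0.7 * chain$conditional$correct$`2|BP`[b95, b55] *
    chain$conditional$correct$`3|BP`[b55, b15]
  li <- 0.2 * chain$conditional$incorrect$`2|BP`[b95, b55] *
    chain$conditional$incorrect$`3|BP`[b55, b15]
  expect_equal(res$pac, lc / (lc + li), tolerance = 1e-12)
  expect_equal(res$n_obs, 3L)
  # with the middle observation missing, O3 falls back to its marginal
  prof_gap <- prof1("g", c(1L, 3L), "BP", c(0.95, 0.15))
  res_gap <- pac_dependent(prof_gap, chain, 0.5)
  lc2 <- 0.7 * 0.5; li2 <- 0.2 * 0.4
  expect_equal(res_gap$pac, lc2 / (lc2 + li2), tolerance = 1e-12)
})
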