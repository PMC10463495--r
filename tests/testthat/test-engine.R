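test_that("degenerate and missing-data columns take their closed-form likelihoods", {
  m <- ccs_model(alpha = 1, k = 1)
  tr <- ape::read.tree(text = "(A:0,B:0);")
  ll <- site_log_likelihood(tr, m, c(A = "A", B = "A"))
  expect_equal(ll, log(jtt_frequencies()[["A"]]), tolerance = 1e-12)
  # an all-missing column carries no information: probability one
  tr3 <- tree3()
  expect_equal(site_log_likelihood(tr3, m, c(A = "-", B = "X", C = "-")), 0,
               tolerance = 1e-12)
})

test_that("pruning matches exhaustive internal-state enumeration", {
  withr::local_seed(11)
  tr <- tree4()
  for (k in c(1L, 2L)) {
    m <- ccs_model(alpha = 0.6, k = k)
    for (i in 1:4) {
      col <- random_column(tr$tip.label, p_gap = ifelse(i > 2, 0.2, 0))
      expect_equal(site_log_likelihood(tr, m, col),
                   oracle_site_likelihood(tr, m, col), tolerance = 1e-10)
    }
  }
  # 5-taxon tree, two internal state layers
  tr5 <- ape::read.tree(text = "(((A:0.1,B:0.2):0.06,C:0.15):0.04,(D:0.2,E:0.1):0.12);")
  m <- ccs_model(alpha = 0.9, k = 1)
  col <- random_column(tr5$tip.label)
  expect_equal(site_log_likelihood(tr5, m, col),
               oracle_site_likelihood(tr5, m, col), tolerance = 1e-10)
})

test_that("pruning likelihood is invariant to re-rooting under reversibility", {
  withr::local_seed(3)
  tr <- tree4()
  m <- ccs_model(alpha = 0.8, k = 2)
  aln <- simulate_null(tr, m, 50, seed = 5)
  ll1 <- alignment_log_likelihood(tr, m, aln)$total
  rerooted <- ape::root(ape::unroot(tr), outgroup = "C", resolve.root = TRUE)
  ll2 <- alignment_log_likelihood(rerooted, m, aln)$total
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("likelihoods agree with an independent phylogenetics library", {
  skip_if_not_installed("phangorn")
  tr <- tree4()
  m <- ccs_model(alpha = 0.7, k = 4)
  aln <- simulate_null(tr, m, 200, seed = 11)
  mine <- alignment_log_likelihood(tr, m, aln)$total
  pd <- phangorn::phyDat(unclass(aln), type = "AA")
  ref <- phangorn::pml(tr, pd, model = "JTT", k = 4, shape = 0.7)$logLik
  expect_equal(mine, ref, tolerance = 1e-8)
})

test_that("marginal ancestral posteriors equal explicit Bayes enumeration", {
  withr::local_seed(21)
  tr <- tree3()
  root_node <- 4L  # 3 tips -> nodes 4 (root) and 5
  for (k in c(1L, 2L)) {
    m <- ccs_model(alpha = 0.6, k = k)
    for (i in 1:3) {
      col <- random_column(tr$tip.label, p_gap = ifelse(i == 3, 0.3, 0))
      aln <- aa_alignment(matrix(col, ncol = 1, dimnames = list(names(col), NULL)))
      asr <- marginal_ancestral_states(tr, m, aln)
      for (node in asr$nodes) {
        expect_equal(as.numeric(asr$posterior[[as.character(node)]]),
                     oracle_node_posterior(tr, m, col, node), tolerance = 1e-10)
      }
    }
  }
})

test_that("ancestral posteriors are normalised and certain for unanimous tips", {
  tr <- ape::read.tree(
    text = "((A:0.01,B:0.01):0.005,(C:0.01,(D:0.01,E:0.01):0.005):0.005);")
  m <- ccs_model(alpha = 0.5)
  aln <- aa_alignment(stats::setNames(rep("W", 5), tr$tip.label))
  asr <- marginal_ancestral_states(tr, m, aln)
  for (node in asr$nodes) {
    expect_equal(colSums(asr$posterior[[as.character(node)]]), 1, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_true(all(asr$map == "W"))
  expect_true(all(asr$max_posterior > 0.99))
})

test_that("MAP ties break to the alphabetically first residue", {
  tr <- tree3()
  m <- ccs_model(exchangeabilities = "JTT", freqs = rep(1 / 20, 20), alpha = 1, k = 1)
  aln <- aa_alignment(c(A = "-", B = "-", C = "-"))  # posterior = uniform prior
  asr <- marginal_ancestral_states(tr, m, aln)
  expect_true(all(asr$map == "A"))
})

test_that("identical sequences drive all branch lengths to the lower bound", {
  tr <- tree4()
  aln <- aa_alignment(stats::setNames(rep("ARNDARND", 4), tr$tip.label))
  fit <- fit_parameters(aln, tr, ccs_model(alpha = 1, k = 1), optimize_alpha = FALSE)
  expect_true(all(fit$tree$edge.length < 1e-4))
})

test_that("the optimiser ascends monotonically and its tidiers are consistent", {
  tr <- tree4()
  m <- ccs_model(alpha = 0.5)
  aln <- simulate_null(tr, m, 400, seed = 9)
  tr0 <- tr; tr0$edge.length[] <- 0.05
  fit <- fit_parameters(aln, tr0)
  expect_true(all(diff(fit$trace) > -1e-6))
  expect_true(fit$converged)
  td <- tidy(fit)
  expect_equal(nrow(td), nrow(fit$tree$edge))
  expect_equal(td$length, fit$tree$edge.length)
  gl <- glance(fit)
  expect_equal(gl$logLik, fit$loglik)
  expect_equal(gl$alpha, fit$model$alpha)
  # the quoted log-likelihood is the actual likelihood of the fitted tree
  expect_equal(alignment_log_likelihood(fit$tree, fit$model, aln)$total,
               fit$loglik, tolerance = 1e-6)
})
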