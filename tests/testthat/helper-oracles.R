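# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive re-implementations (enumeration, quadrature, explicit
# set logic) kept separate from the package's vectorised code paths.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Quadrature oracle for mean-of-bin discrete gamma rates.
oracle_gamma_rates <- function(alpha, k) {
  q <- c(0, stats::qgamma(seq_len(k - 1) / k, alpha, alpha), Inf)
  sapply(seq_len(k), function(i) {
    k * stats::integrate(function(x) x * stats::dgamma(x, alpha, alpha),
                         q[i], q[i + 1], rel.tol = 1e-10)$value
  })
}

# Exhaustive pruning oracle: enumerates every assignment of states to the
# internal nodes and sums path probabilities, mixing rate categories with
# equal prior weight.  Only feasible for tiny trees.
oracle_site_likelihood <- function(tree, model, column) {
  rm <- ccscan::build_rate_matrix(model)
  rates <- model$category_rates
  tr <- stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_int <- tr$Nnode
  internal_ids <- (n_tip + 1):(n_tip + n_int)
  tip_state <- match(column[tr$tip.label], AA20)   # NA = missing
  total <- 0
  for (ki in seq_along(rates)) {
    p_edge <- lapply(tr$edge.length, function(t)
      ccscan::transition_matrix(rm, t, rates[ki]))
    grid <- as.matrix(expand.grid(rep(list(1:20), n_int)))
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      assign_state <- function(node) {
        if (node <= n_tip) tip_state[node] else grid[g, node - n_tip]
      }
      pr <- rm$freqs[assign_state(n_tip + 1)]   # root prior
      for (e in seq_len(nrow(tr$edge))) {
        a <- assign_state(tr$edge[e, 1])
        b <- assign_state(tr$edge[e, 2])
        pr <- pr * if (is.na(b)) 1 else p_edge[[e]][a, b]
      }
      lik <- lik + pr
    }
    total <- total + lik / length(rates)
  }
  log(total)
}

# Explicit Bayes-rule oracle for the marginal posterior at one internal node.
oracle_node_posterior <- function(tree, model, column, node) {
  rm <- ccscan::build_rate_matrix(model)
  rates <- model$category_rates
  tr <- stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_int <- tr$Nnode
  tip_state <- match(column[tr$tip.label], AA20)
  post <- numeric(20)
  for (ki in seq_along(rates)) {
    p_edge <- lapply(tr$edge.length, function(t)
      ccscan::transition_matrix(rm, t, rates[ki]))
    grid <- as.matrix(expand.grid(rep(list(1:20), n_int)))
    for (g in seq_len(nrow(grid))) {
      assign_state <- function(nd) {
        if (nd <= n_tip) tip_state[nd] else grid[g, nd - n_tip]
      }
      pr <- rm$freqs[assign_state(n_tip + 1)]
      for (e in seq_len(nrow(tr$edge))) {
        a <- assign_state(tr$edge[e, 1])
        b <- assign_state(tr$edge[e, 2])
        pr <- pr * if (is.na(b)) 1 else p_edge[[e]][a, b]
      }
      post[assign_state(node)] <- post[assign_state(node)] + pr / length(rates)
    }
  }
  post / sum(post)
}

# Brute-force convergence rule checker, written as plain set logic.
# Returns a data frame of (residue, relaxed, ccs, strict) for one column.
oracle_classify_column <- function(column, fg_taxa, bg_taxa, m,
                                   gap_policy = "exclude_site") {
  fg <- column[fg_taxa]
  bg <- column[bg_taxa]
  is_missing <- function(x) !(x %in% AA20)
  if (gap_policy == "exclude_site" && any(is_missing(c(fg, bg)))) {
    return(NULL)
  }
  fg_obs <- fg[!is_missing(fg)]
  bg_obs <- bg[!is_missing(bg)]
  bg_unanimous <- length(bg_obs) == length(bg) && length(unique(bg_obs)) == 1
  rows <- NULL
  for (a in unique(fg_obs)) {
    carriers <- sum(fg_obs == a)
    if (carriers >= m && !(a %in% bg_obs)) {
      rows <- rbind(rows, data.frame(
        residue = a,
        ccs = bg_unanimous,
        strict = bg_unanimous && carriers == length(fg),
        n_carriers = carriers
      ))
    }
  }
  if (!is.null(rows)) rows[order(rows$residue), , drop = FALSE] else NULL
}

# Independent predicate oracles for the evidence filters.
oracle_dnds_keep <- function(r) {
  !(r$dS > 1 ||
      r$N > r$sequence_length ||
      (r$N + r$S_sites) >= r$sequence_length + 50 ||
      r$N * r$dN < 1 ||
      r$S_sites * r$dS < 1)
}
oracle_psg_keep <- function(r) {
  paml <- r$lrt_fdr_paml < 0.05 && r$beb_max_posterior > 0.95
  hyphy <- r$lrt_fdr_hyphy < 0.05
  paml && hyphy
}
oracle_deg_keep <- function(r) {
  r$fdr <= 0.05 && r$basemean >= 10 && abs(r$log2fc) >= 0.3
}

# Random result tables for filter tests.
random_dnds_table <- function(n) {
  tibble::tibble(
    gene = sprintf("g%04d", seq_len(n)),
    dN = round(runif(n, 0, 0.3), 3),
    dS = round(runif(n, 0, 1.5), 3),
    N = round(runif(n, 50, 900)),
    S_sites = round(runif(n, 20, 400)),
    sequence_length = round(runif(n, 200, 1200))
  )
}

random_psg_table <- function(n) {
  tibble::tibble(
    gene = sprintf("g%04d", seq_len(n)),
    lrt_fdr_paml = round(runif(n), 3),
    beb_max_posterior = round(runif(n), 3),
    lrt_fdr_hyphy = round(runif(n), 3)
  )
}

random_deg_table <- function(n) {
  tab <- tibble::tibble(
    gene = sprintf("g%04d", sample.int(ceiling(n / 2), n, replace = TRUE)),
    region = sample(c("FB", "MB", "HB"), n, replace = TRUE),
    fdr = round(runif(n), 3),
    basemean = round(runif(n, 0, 100), 1),
    log2fc = round(runif(n, -2, 2), 2)
  )
  dplyr::distinct(tab, gene, region, .keep_all = TRUE)
}

# Small fixed fixtures.
tree4 <- function() ape::read.tree(text = "((A:0.12,B:0.07):0.05,(C:0.2,D:0.09):0.11);")
tree3 <- function() ape::read.tree(text = "((A:0.1,B:0.25):0.07,C:0.3);")

random_column <- function(taxa, p_gap = 0) {
  pool <- c(AA20, if (p_gap > 0) c("-", "X"))
  probs <- c(rep((1 - p_gap) / 20, 20), if (p_gap > 0) rep(p_gap / 2, 2))
  stats::setNames(sample(pool, length(taxa), replace = TRUE, prob = probs), taxa)
}
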