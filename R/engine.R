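# Likelihood engine: Felsenstein pruning over discrete-gamma rate categories,
# maximum-likelihood branch-length / gamma-shape estimation on a fixed
# topology, and marginal empirical-Bayes ancestral state reconstruction.
#
# Partial likelihoods are kept as states-by-sites matrices, one per node and
# rate category, with per-node log-scaling vectors to prevent underflow.  All
# heavy steps are matrix products over site blocks, so no compiled code is
# needed.

# ---- tree indexing ---------------------------------------------------------

# Postorder edge table plus the per-node bookkeeping the passes need.
tree_index <- function(tree) {
  tr <- stats::reorder(validate_tree(tree), "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- max(tr$edge)
  children_edges <- vector("list", n_node)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]
    children_edges[[p]] <- c(children_edges[[p]], e)
  }
  list(
    tree = tr,
    edge = tr$edge,
    lengths = tr$edge.length,
    n_tip = n_tip,
    n_node = n_node,
    root = n_tip + 1L,
    tip_labels = tr$tip.label,
    children_edges = children_edges
  )
}

# 0/1 (or all-ones for missing) partial matrices for the tips, shared across
# rate categories.
tip_partials <- function(ti, aln, n_states = 20L) {
  codes <- aa_encode(unclass(aln)[ti$tip_labels, , drop = FALSE])
  s <- ncol(codes)
  lapply(seq_len(ti$n_tip), function(i) {
    m <- matrix(0, n_states, s)
    ci <- codes[i, ]
    obs <- which(!is.na(ci))
    m[cbind(ci[obs], obs)] <- 1
    if (length(obs) < s) m[, setdiff(seq_len(s), obs)] <- 1
    m
  })
}

col_max <- function(m) {
  mx <- m[1, ]
  for (r in 2:nrow(m)) mx <- pmax(mx, m[r, ])
  mx
}

# Rescale a partial matrix column-wise; returns list(part, log_scale).
rescale_partial <- function(m, ls) {
  mx <- col_max(m)
  mx[mx == 0] <- 1
  list(part = m / rep(mx, each = nrow(m)), ls = ls + log(mx))
}

# Per-category transition matrices for every edge.
edge_p_matrices <- function(rm, lengths, rates) {
  lapply(rates, function(r) lapply(lengths, function(t) transition_matrix(rm, t, r)))
}

# Post-order (inside) pass for one rate category.
inside_pass <- function(ti, p_edges, tips) {
  part <- vector("list", ti$n_node)
  ls <- vector("list", ti$n_node)
  s <- ncol(tips[[1]])
  zero <- numeric(s)
  for (i in seq_len(ti$n_tip)) {
    part[[i]] <- tips[[i]]
    ls[[i]] <- zero
  }
  seen <- integer(ti$n_node)
  n_children <- lengths(ti$children_edges)
  for (e in seq_len(nrow(ti$edge))) {
    p <- ti$edge[e, 1]
    c <- ti$edge[e, 2]
    msg <- p_edges[[e]] %*% part[[c]]
    if (is.null(part[[p]])) {
      part[[p]] <- msg
      ls[[p]] <- ls[[c]]
    } else {
      part[[p]] <- part[[p]] * msg
      ls[[p]] <- ls[[p]] + ls[[c]]
    }
    seen[p] <- seen[p] + 1L
    if (seen[p] == n_children[p]) {
      sc <- rescale_partial(part[[p]], ls[[p]])
      part[[p]] <- sc$part
      ls[[p]] <- sc$ls
    }
  }
  list(part = part, ls = ls)
}

# log(sum(exp(.))) over the rows of a k-by-s matrix.
log_sum_exp_rows <- function(m) {
  mx <- apply(m, 2, max)
  mx + log(colSums(exp(m - rep(mx, each = nrow(m)))))
}

# Per-site log-likelihood mixed over rate categories, from cached inside
# passes.  Returns a vector over sites.
site_loglik_from_inside <- function(ti, insides, freqs, k) {
  ll <- vapply(seq_len(k), function(ki) {
    root_part <- insides[[ki]]$part[[ti$root]]
    log(colSums(freqs * root_part)) + insides[[ki]]$ls[[ti$root]]
  }, numeric(ncol(insides[[1]]$part[[ti$root]])))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)  # single site
  log_sum_exp_rows(t(ll)) - log(k)
}

# Full per-site log-likelihood for an alignment (no pattern compression).
alignment_site_logliks <- function(tree, model, aln) {
  check_leaf_match(tree, aln)
  ti <- tree_index(tree)
  rm <- build_rate_matrix(model)
  tips <- tip_partials(ti, aln, n_states = nrow(rm$Q))
  pk <- edge_p_matrices(rm, ti$lengths, model$category_rates)
  insides <- lapply(pk, function(pe) inside_pass(ti, pe, tips))
  site_loglik_from_inside(ti, insides, rm$freqs, model$k)
}

#' Site log-likelihood under the substitution model
#'
#' Computes the pruning log-likelihood of a single alignment column: the
#' discrete-gamma mixture `log( (1/K) * sum_k sum_a pi_a * L_k(a) )` where
#' `L_k(a)` is the partial likelihood of the tips given root state `a` at
#' category rate `r_k`.  Gaps and unknowns contribute all-ones partials, so a
#' fully missing column has log-likelihood 0.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param model A [ccs_model()].
#' @param column Named character vector of residues, names = tree tip labels.
#' @return A single log-likelihood value.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,C:0.2);")
#' site_log_likelihood(tr, ccs_model(alpha = 1, k = 1),
#'                     c(A = "S", B = "S", C = "T"))
site_log_likelihood <- function(tree, model, column) {
  if (is.null(names(column))) stop("column must be named by taxon", call. = FALSE)
  aln <- aa_alignment(matrix(column, ncol = 1, dimnames = list(names(column), NULL)),
                      orthogroup_id = "column")
  as.numeric(alignment_site_logliks(tree, model, aln))
}

#' Alignment log-likelihood
#'
#' @inheritParams site_log_likelihood
#' @param aln An `aa_alignment` whose taxa equal the tree leaves.
#' @return A list with `total` (sum over sites) and `site` (per-site vector).
#' @export
alignment_log_likelihood <- function(tree, model, aln) {
  site <- alignment_site_logliks(tree, model, aln)
  list(total = sum(site), site = site)
}

# ---- maximum-likelihood fitting -------------------------------------------

BL_MIN <- 1e-8
BL_MAX <- 50

# Pattern compression: unique columns and their multiplicities.
compress_patterns <- function(aln) {
  m <- unclass(aln)
  key <- apply(m, 2, paste, collapse = "\r")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  list(
    aln = aa_alignment(m[, first, drop = FALSE], attr(aln, "orthogroup_id")),
    weights = as.numeric(tabulate(idx, nbins = sum(first))),
    index = idx
  )
}

# Weighted total log-likelihood from per-category inside passes.
total_loglik <- function(ti, insides, freqs, k, w) {
  sum(w * site_loglik_from_inside(ti, insides, freqs, k))
}

# Log-likelihood profile of one edge length, given the sibling/outside
# product R (per category, with log-scales) and the inside partial of the
# child.  Everything except this edge's transition matrix is fixed.
edge_profile <- function(t, rm, rates, r_list, r_ls, in_c, in_ls, w, k) {
  ll <- vapply(seq_len(k), function(ki) {
    p <- transition_matrix(rm, t, rates[ki])
    lik <- colSums(r_list[[ki]] * (p %*% in_c[[ki]]))
    log(lik) + r_ls[[ki]] + in_ls[[ki]]
  }, numeric(length(w)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  sum(w * (log_sum_exp_rows(t(ll)) - log(k)))
}

#' Fit branch lengths and gamma shape by maximum likelihood
#'
#' Coordinate-wise optimisation on a fixed topology: each cycle performs one
#' exact Gauss-Seidel sweep over the branch lengths (every edge optimised by
#' bounded golden-section search against up-to-date partial likelihoods,
#' which are refreshed along the traversal) followed by a bounded search on
#' the gamma shape.  Cycles repeat until the relative log-likelihood
#' improvement drops below `tol` or `max_cycles` is reached.  The fit is
#' deterministic given its inputs.
#'
#' @param aln An `aa_alignment`.
#' @param tree Rooted `phylo` topology; existing branch lengths are used as
#'   starting values, missing ones start at 0.1.
#' @param model A [ccs_model()]; when `NULL`, a JTT model with empirical
#'   (+F) frequencies and starting alpha 0.5 is built from the alignment.
#' @param optimize_alpha Estimate the gamma shape (default `TRUE`).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_cycles Maximum optimisation cycles.
#' @return A `ccs_fit` with the fitted `tree`, `model`, `loglik`, the
#'   per-cycle `trace`, and convergence diagnostics.
#' @export
fit_parameters <- function(aln, tree, model = NULL, optimize_alpha = TRUE,
                           tol = 1e-6, max_cycles = 100) {
  check_leaf_match(tree, aln)
  if (nrow(aln) < 2) stop("at least two taxa required", call. = FALSE)
  if (is.null(model)) {
    model <- ccs_model(freqs = "empirical", alpha = 0.5, aln = aln)
  }
  ti <- tree_index(tree)
  if (is.null(ti$lengths)) ti$lengths <- rep(0.1, nrow(ti$edge))
  ti$lengths <- pmin(pmax(ti$lengths, BL_MIN), BL_MAX)

  cp <- compress_patterns(aln)
  tips <- tip_partials(ti, cp$aln, n_states = nrow(model$exchangeabilities))
  w <- cp$weights
  k <- model$k
  rm <- build_rate_matrix(model)

  run_inside <- function(rates, lengths) {
    pk <- edge_p_matrices(rm, lengths, rates)
    list(pk = pk, insides = lapply(pk, function(pe) inside_pass(ti, pe, tips)))
  }

  st <- run_inside(model$category_rates, ti$lengths)
  ll <- total_loglik(ti, st$insides, rm$freqs, k, w)
  if (!is.finite(ll)) {
    site_ll <- site_loglik_from_inside(ti, st$insides, rm$freqs, k)
    stop("non-finite likelihood at start (first offending site pattern: ",
         which(!is.finite(site_ll))[1], ")", call. = FALSE)
  }
  trace <- ll

  # Exact branch sweep: depth-first, refreshing inside partials on return so
  # every single-edge optimisation sees current partials (monotone ascent).
  sweep_branches <- function(lengths, pk, insides) {
    env <- environment()
    dfs <- function(node, out_part, out_ls) {
      for (e in ti$children_edges[[node]]) {
        child <- ti$edge[e, 2]
        r_list <- vector("list", k)
        r_ls <- vector("list", k)
        for (ki in seq_len(k)) {
          r <- out_part[[ki]]
          rls <- out_ls[[ki]]
          for (e2 in setdiff(ti$children_edges[[node]], e)) {
            s2 <- ti$edge[e2, 2]
            r <- r * (env$pk[[ki]][[e2]] %*% env$insides[[ki]]$part[[s2]])
            rls <- rls + env$insides[[ki]]$ls[[s2]]
          }
          sc <- rescale_partial(r, rls)
          r_list[[ki]] <- sc$part
          r_ls[[ki]] <- sc$ls
        }
        in_c <- lapply(seq_len(k), function(ki) env$insides[[ki]]$part[[child]])
        in_ls <- lapply(seq_len(k), function(ki) env$insides[[ki]]$ls[[child]])
        opt <- stats::optimize(
          function(t) edge_profile(t, rm, model$category_rates,
                                   r_list, r_ls, in_c, in_ls, w, k),
          interval = c(BL_MIN, BL_MAX), maximum = TRUE, tol = 1e-7
        )
        cur <- edge_profile(env$lengths[e], rm, model$category_rates,
                            r_list, r_ls, in_c, in_ls, w, k)
        if (opt$objective > cur) {
          env$lengths[e] <- opt$maximum
          for (ki in seq_len(k)) {
            env$pk[[ki]][[e]] <- transition_matrix(rm, opt$maximum,
                                                   model$category_rates[ki])
          }
        }
        if (child > ti$n_tip) {
          child_out <- vector("list", k)
          child_ls <- vector("list", k)
          for (ki in seq_len(k)) {
            sc <- rescale_partial(crossprod(env$pk[[ki]][[e]], r_list[[ki]]), r_ls[[ki]])
            child_out[[ki]] <- sc$part
            child_ls[[ki]] <- sc$ls
          }
          dfs(child, child_out, child_ls)
          # refresh the child's inside partial with its updated subtree
          for (ki in seq_len(k)) {
            m <- NULL
            mls <- 0
            for (e2 in ti$children_edges[[child]]) {
              s2 <- ti$edge[e2, 2]
              msg <- env$pk[[ki]][[e2]] %*% env$insides[[ki]]$part[[s2]]
              m <- if (is.null(m)) msg else m * msg
              mls <- mls + env$insides[[ki]]$ls[[s2]]
            }
            sc <- rescale_partial(m, mls)
            env$insides[[ki]]$part[[child]] <- sc$part
            env$insides[[ki]]$ls[[child]] <- sc$ls
          }
        }
      }
    }
    s <- length(w)
    root_out <- lapply(seq_len(k), function(ki) matrix(rm$freqs, nrow(rm$Q), s))
    root_ls <- lapply(seq_len(k), function(ki) numeric(s))
    dfs(ti$root, root_out, root_ls)
    list(lengths = env$lengths, pk = env$pk, insides = env$insides)
  }

  cycles <- 0L
  converged <- FALSE
  repeat {
    cycles <- cycles + 1L
    sw <- sweep_branches(ti$lengths, st$pk, st$insides)
    ti$lengths <- sw$lengths
    st <- list(pk = sw$pk, insides = sw$insides)

    if (optimize_alpha) {
      lo <- max(0.02, model$alpha / 4)
      hi <- min(100, model$alpha * 4)
      opt_a <- stats::optimize(function(a) {
        rates <- discrete_gamma_rates(a, k)
        total_loglik(ti, run_inside(rates, ti$lengths)$insides, rm$freqs, k, w)
      }, interval = c(lo, hi), maximum = TRUE, tol = 1e-4)
      if (opt_a$objective > total_loglik(ti, st$insides, rm$freqs, k, w)) {
        model <- update_model(model, alpha = opt_a$maximum)
      }
      st <- run_inside(model$category_rates, ti$lengths)
    }

    ll_new <- total_loglik(ti, st$insides, rm$freqs, k, w)
    trace <- c(trace, ll_new)
    if (ll_new - ll < tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll <- max(ll, ll_new)
      break
    }
    ll <- ll_new
    if (cycles >= max_cycles) break
  }

  fitted_tree <- ti$tree
  fitted_tree$edge.length <- ti$lengths
  structure(list(
    tree = fitted_tree,
    model = model,
    loglik = ll,
    n_cycles = cycles,
    converged = converged,
    trace = trace,
    n_sites = ncol(aln),
    n_patterns = length(w)
  ), class = "ccs_fit")
}

#' @export
print.ccs_fit <- function(x, ...) {
  cat("<ccs_fit> logLik ", format(x$loglik, digits = 8), ", alpha ",
      signif(x$model$alpha, 4), ", ", nrow(x$tree$edge), " edges, ",
      x$n_sites, " sites (", x$n_patterns, " patterns), ",
      x$n_cycles, " cycles", if (x$converged) " [converged]", "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted phylogenetic model
#'
#' @param x A `ccs_fit`.
#' @param ... Unused.
#' @return A tibble with one row per edge: `parent`, `child`, `label` (tip
#'   name or internal node id) and fitted `length`.
#' @export
tidy.ccs_fit <- function(x, ...) {
  tibble::tibble(
    parent = x$tree$edge[, 1],
    child = x$tree$edge[, 2],
    label = node_label(x$tree, x$tree$edge[, 2]),
    length = x$tree$edge.length
  )
}

#' Glance at a fitted phylogenetic model
#'
#' @param x A `ccs_fit`.
#' @param ... Unused.
#' @return One-row tibble with `logLik`, `alpha`, `n_edges`, `n_sites`,
#'   `n_cycles`, `converged`.
#' @export
glance.ccs_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    alpha = x$model$alpha,
    n_edges = nrow(x$tree$edge),
    n_sites = x$n_sites,
    n_cycles = x$n_cycles,
    converged = x$converged
  )
}

# ---- marginal ancestral reconstruction ------------------------------------

# Pre-order (outside) pass for one category, built on an inside pass.
outside_pass <- function(ti, p_edges, inside, freqs) {
  s <- ncol(inside$part[[ti$root]])
  n_states <- nrow(inside$part[[ti$root]])
  out <- vector("list", ti$n_node)
  ls <- vector("list", ti$n_node)
  out[[ti$root]] <- matrix(freqs, n_states, s)
  ls[[ti$root]] <- numeric(s)
  for (e in rev(seq_len(nrow(ti$edge)))) {   # reverse postorder = preorder
    p <- ti$edge[e, 1]
    c <- ti$edge[e, 2]
    r <- out[[p]]
    rls <- ls[[p]]
    for (e2 in setdiff(ti$children_edges[[p]], e)) {
      s2 <- ti$edge[e2, 2]
      r <- r * (p_edges[[e2]] %*% inside$part[[s2]])
      rls <- rls + inside$ls[[s2]]
    }
    sc <- rescale_partial(crossprod(p_edges[[e]], r), rls)
    out[[c]] <- sc$part
    ls[[c]] <- sc$ls
  }
  list(part = out, ls = ls)
}

#' Marginal empirical-Bayes ancestral state reconstruction
#'
#' For each requested internal node and site, computes the marginal posterior
#' over residues given the tips, tree and model, mixing the discrete-gamma
#' rate categories by their per-site posterior weights (empirical Bayes over
#' categories).  The MAP residue breaks posterior ties (within 1e-12) by alphabetical
#' order.
#'
#' @param tree Rooted `phylo` tree with branch lengths (e.g. from
#'   [fit_parameters()]).
#' @param model A [ccs_model()].
#' @param aln An `aa_alignment` matching the tree leaves.
#' @param nodes Internal node ids to reconstruct (default: all).
#' @param sites Site indices to reconstruct (default: all).
#' @param chunk_size Number of sites processed per block (memory control).
#' @return A `ccs_asr` with `posterior` (list per node of 20-by-sites
#'   matrices), `map` (nodes-by-sites residue matrix), `max_posterior`,
#'   `nodes`, `sites`, and the `tree`.
#' @export
marginal_ancestral_states <- function(tree, model, aln, nodes = NULL,
                                      sites = NULL, chunk_size = 20000L) {
  check_leaf_match(tree, aln)
  ti <- tree_index(tree)
  if (is.null(ti$lengths)) stop("tree has no branch lengths", call. = FALSE)
  if (is.null(nodes)) nodes <- (ti$n_tip + 1L):ti$n_node
  if (any(nodes <= ti$n_tip | nodes > ti$n_node)) {
    stop("nodes must be internal node ids", call. = FALSE)
  }
  if (is.null(sites)) sites <- seq_len(ncol(aln))
  rm <- build_rate_matrix(model)
  n_states <- nrow(rm$Q)
  k <- model$k

  sub <- aa_alignment(unclass(aln)[, sites, drop = FALSE], attr(aln, "orthogroup_id"))
  s_total <- ncol(sub)
  posterior <- lapply(nodes, function(n) matrix(NA_real_, n_states, s_total))
  names(posterior) <- as.character(nodes)

  pk <- edge_p_matrices(rm, ti$lengths, model$category_rates)
  chunks <- split(seq_len(s_total), ceiling(seq_len(s_total) / chunk_size))
  for (ch in chunks) {
    block <- aa_alignment(unclass(sub)[, ch, drop = FALSE], "block")
    tips <- tip_partials(ti, block, n_states = n_states)
    insides <- lapply(pk, function(pe) inside_pass(ti, pe, tips))
    outsides <- lapply(seq_len(k), function(ki)
      outside_pass(ti, pk[[ki]], insides[[ki]], rm$freqs))
    for (ni in seq_along(nodes)) {
      v <- nodes[ni]
      # joint (state, category) numerators with per-category log-scales;
      # summing over categories here applies the per-site category posterior
      # weights automatically.
      logs <- vapply(seq_len(k), function(ki)
        insides[[ki]]$ls[[v]] + outsides[[ki]]$ls[[v]], numeric(length(ch)))
      if (is.null(dim(logs))) logs <- matrix(logs, nrow = 1)
      m <- apply(logs, 1, max)
      num <- matrix(0, n_states, length(ch))
      for (ki in seq_len(k)) {
        sc <- exp(logs[, ki] - m)
        num <- num + (insides[[ki]]$part[[v]] * outsides[[ki]]$part[[v]]) *
          rep(sc, each = n_states)
      }
      tot <- colSums(num)
      tot[tot == 0] <- 1
      posterior[[ni]][, ch] <- num / rep(tot, each = n_states)
    }
  }

  # MAP with alphabetical tie-break ("A" first among exact ties).
  alpha_order <- order(AA_STATES)
  map <- matrix(NA_character_, length(nodes), s_total,
                dimnames = list(as.character(nodes), NULL))
  max_post <- matrix(NA_real_, length(nodes), s_total,
                     dimnames = list(as.character(nodes), NULL))
  for (ni in seq_along(nodes)) {
    pr <- posterior[[ni]][alpha_order, , drop = FALSE]
    mx <- col_max(pr)
    near_max <- pr >= rep(mx - 1e-12, each = nrow(pr))   # ties within tolerance
    w <- max.col(t(near_max), ties.method = "first")
    map[ni, ] <- AA_STATES[alpha_order][w]
    max_post[ni, ] <- mx
  }

  structure(list(
    posterior = posterior,
    map = map,
    max_posterior = max_post,
    nodes = nodes,
    sites = sites,
    tree = ti$tree
  ), class = "ccs_asr")
}

#' @export
print.ccs_asr <- function(x, ...) {
  cat("<ccs_asr> ", length(x$nodes), " internal nodes x ",
      length(x$sites), " sites\n", sep = "")
  invisible(x)
}

#' Tidy an ancestral reconstruction
#'
#' @param x A `ccs_asr`.
#' @param ... Unused.
#' @return Tibble with `node`, `site` (original alignment coordinates,
#'   1-based), `map` residue and `max_posterior`.
#' @export
tidy.ccs_asr <- function(x, ...) {
  tibble::tibble(
    node = rep(x$nodes, each = length(x$sites)),
    site = rep(x$sites, times = length(x$nodes)),
    map = as.vector(t(x$map)),
    max_posterior = as.vector(t(x$max_posterior))
  )
}
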