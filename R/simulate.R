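# Null-sequence simulator and planted-convergence ground truth.  The
# simulator draws a rate category per site, a root residue from the
# stationary distribution, and propagates states down the tree by sampling
# transition-matrix rows -- the classic generator-tool behaviour used to
# calibrate convergence noise.  No indels are produced.

#' Simulate a null amino-acid alignment along a tree
#'
#' Evolves `n_sites` independent sites under the substitution model: per
#' site, a gamma category is drawn uniformly, the root residue is drawn from
#' the stationary frequencies, and each branch applies `P(Q * r * t)`.  The
#' output contains no convergent signal beyond chance and no gaps, and is
#' byte-identical for identical seeds.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param model A [ccs_model()].
#' @param n_sites Number of sites to simulate (>= 1).
#' @param seed Integer seed; recorded in the output attributes.
#' @param orthogroup_id Identifier for the resulting alignment.
#' @return An `aa_alignment` with attribute `seed`.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);")
#' simulate_null(tr, ccs_model(alpha = 0.5), n_sites = 100, seed = 1)
simulate_null <- function(tree, model, n_sites, seed, orthogroup_id = "simulated") {
  if (n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  ti <- tree_index(tree)
  rm <- build_rate_matrix(model)
  n_states <- nrow(rm$Q)
  withr::with_seed(as.integer(seed), {
    cat_of_site <- sample.int(model$k, n_sites, replace = TRUE)
    states <- matrix(NA_integer_, ti$n_node, n_sites)
    states[ti$root, ] <- sample.int(n_states, n_sites, replace = TRUE, prob = rm$freqs)
    for (e in rev(seq_len(nrow(ti$edge)))) {     # preorder
      p <- ti$edge[e, 1]
      c <- ti$edge[e, 2]
      child <- integer(n_sites)
      for (ki in seq_len(model$k)) {
        in_cat <- which(cat_of_site == ki)
        if (length(in_cat) == 0) next
        pm <- transition_matrix(rm, ti$lengths[e], model$category_rates[ki])
        parent_states <- states[p, in_cat]
        for (a in unique(parent_states)) {
          idx <- in_cat[parent_states == a]
          child[idx] <- sample.int(n_states, length(idx), replace = TRUE, prob = pm[a, ])
        }
      }
      states[c, ] <- child
    }
    m <- aa_decode(states[seq_len(ti$n_tip), , drop = FALSE])
    rownames(m) <- ti$tip_labels
    out <- aa_alignment(m, orthogroup_id = orthogroup_id)
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Specify sites to plant strict parallel substitutions at
#'
#' @param site Integer sites (1-based, disjoint).
#' @param fg_residue Residue planted in every foreground taxon.
#' @param bg_residue Residue planted in every background taxon; must differ
#'   from `fg_residue` at each site.
#' @return A tibble with columns `site`, `fg_residue`, `bg_residue`.
#' @export
plant_spec <- function(site, fg_residue, bg_residue) {
  spec <- tibble::tibble(site = as.integer(site),
                         fg_residue = toupper(fg_residue),
                         bg_residue = toupper(bg_residue))
  if (anyDuplicated(spec$site)) stop("validation error: planted sites must be disjoint", call. = FALSE)
  if (any(spec$fg_residue == spec$bg_residue)) {
    stop("validation error: fg_residue must differ from bg_residue", call. = FALSE)
  }
  if (!all(c(spec$fg_residue, spec$bg_residue) %in% AA_STATES)) {
    stop("validation error: planted residues must be canonical amino acids", call. = FALSE)
  }
  spec
}

#' Plant strict parallel substitutions into an alignment
#'
#' Overwrites the chosen sites so that all foreground taxa carry one residue
#' and all background taxa carry a single different residue -- an unambiguous
#' ground truth for the strict parallel rule.  Untouched sites are returned
#' bit-identically.
#'
#' @param aln An `aa_alignment`.
#' @param traits A [trait_map()] covering the alignment taxa.
#' @param spec A [plant_spec()] tibble (columns `site`, `fg_residue`,
#'   `bg_residue`).
#' @return List with the modified `alignment` and the `truth` tibble
#'   (orthogroup, site, fg_residue, bg_residue).
#' @export
plant_convergence <- function(aln, traits, spec) {
  spec <- plant_spec(spec$site, spec$fg_residue, spec$bg_residue)
  if (nrow(spec) > 0 && (any(spec$site < 1) || any(spec$site > ncol(aln)))) {
    stop("validation error: planted site out of range", call. = FALSE)
  }
  missing_taxa <- setdiff(c(traits$foreground, traits$background), taxa(aln))
  if (length(missing_taxa) > 0) {
    stop("validation error: trait taxa absent from alignment: ",
         paste(missing_taxa, collapse = ", "), call. = FALSE)
  }
  out <- unclass(aln)
  for (i in seq_len(nrow(spec))) {
    out[traits$foreground, spec$site[i]] <- spec$fg_residue[i]
    out[traits$background, spec$site[i]] <- spec$bg_residue[i]
  }
  planted <- aa_alignment(out, orthogroup_id = attr(aln, "orthogroup_id"))
  attr(planted, "seed") <- attr(aln, "seed")
  truth <- tibble::tibble(
    orthogroup = attr(aln, "orthogroup_id"),
    site = spec$site,
    fg_residue = spec$fg_residue,
    bg_residue = spec$bg_residue
  )
  list(alignment = planted, truth = truth)
}

# Documented sub-seed rule: gene g of a run seeded with s gets seed
# (s + 7919 * g) mod 2^31 - 1, so gene sets are order-independent.
gene_seed <- function(seed, gene_index) {
  as.integer((as.numeric(seed) + 7919 * gene_index) %% (2^31 - 1))
}

#' Generate a synthetic orthogroup set
#'
#' Simulates `n_genes` independent null alignments and plants strict
#' parallel substitutions into a chosen fraction of them, writing per-gene
#' FASTA files, a truth TSV, and a JSON manifest recording the seed and
#' configuration.  Each gene uses a deterministic sub-seed so regeneration
#' with the same master seed reproduces identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param traits A [trait_map()].
#' @param model A [ccs_model()].
#' @param n_genes Number of orthogroups (>= 1).
#' @param sites_per_gene Sites per orthogroup (>= 1).
#' @param planted_fraction Fraction of genes receiving planted convergent
#'   substitutions (in \[0, 1\]; rounded down to a gene count).
#' @param sites_per_planted_gene Planted sites in each selected gene.
#' @param seed Master integer seed.
#' @return Invisibly, a list with `genes` (tibble: orthogroup, path,
#'   planted), `truth` (planted-site tibble), and `manifest` (path to the
#'   JSON manifest).
#' @export
generate_orthogroup_set <- function(out_dir, tree, traits, model,
                                    n_genes, sites_per_gene,
                                    planted_fraction = 0,
                                    sites_per_planted_gene = 1,
                                    seed = 1) {
  stopifnot(n_genes >= 1, sites_per_gene >= 1,
            planted_fraction >= 0, planted_fraction <= 1)
  if (!setequal(tree$tip.label, c(traits$foreground, traits$background))) {
    stop("validation error: trait map taxa and tree leaves differ", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_planted <- floor(planted_fraction * n_genes)
  planted_genes <- withr::with_seed(as.integer(seed),
                                    sort(sample.int(n_genes, n_planted)))
  truth <- list()
  genes <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    og <- sprintf("OG%04d", g)
    sg <- gene_seed(seed, g)
    aln <- simulate_null(tree, model, sites_per_gene, seed = sg, orthogroup_id = og)
    is_planted <- g %in% planted_genes
    if (is_planted) {
      pl <- withr::with_seed(sg + 1L, {
        sites <- sort(sample.int(sites_per_gene, sites_per_planted_gene))
        ab <- vapply(seq_along(sites), function(i) sample(AA_STATES, 2), character(2))
        plant_spec(sites, ab[1, ], ab[2, ])
      })
      res <- plant_convergence(aln, traits, pl)
      aln <- res$alignment
      truth[[length(truth) + 1]] <- res$truth
    }
    path <- file.path(out_dir, paste0(og, ".fasta"))
    write_alignment(aln, path)
    genes[[g]] <- tibble::tibble(orthogroup = og, path = path, planted = is_planted)
  }
  genes <- dplyr::bind_rows(genes)
  truth <- if (length(truth) > 0) dplyr::bind_rows(truth) else
    tibble::tibble(orthogroup = character(), site = integer(),
                   fg_residue = character(), bg_residue = character())
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    seed = as.integer(seed),
    n_genes = n_genes,
    sites_per_gene = sites_per_gene,
    planted_fraction = planted_fraction,
    sites_per_planted_gene = sites_per_planted_gene,
    planted_genes = genes$orthogroup[genes$planted],
    alpha = model$alpha,
    k = model$k,
    taxa = c(traits$foreground, traits$background)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(genes = genes, truth = truth, manifest = manifest_path))
}
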