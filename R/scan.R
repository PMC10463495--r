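# Core classification: per-site convergence calls, the conservative-site
# (CCS) restriction, random/false noise attribution against a reconstructed
# background ancestor, convergently-evolving-gene (CEG) calls, and the noise
# report comparing the relaxed and CCS-restricted stages.

#' Scan configuration
#'
#' @param min_foreground Minimum number of foreground taxa sharing a residue
#'   for a relaxed convergence call (`m`, default 3).
#' @param require_all_foreground_for_ceg If `TRUE` (default) a gene is a CEG
#'   only via strict parallel sites (all foreground taxa share the residue);
#'   if `FALSE`, any conservative-site convergence qualifies.
#' @param gap_policy `"exclude_site"` (default): any gap/unknown among the
#'   scanned taxa removes the site from classification.
#'   `"treat_as_mismatch"`: missing residues never count as carriers and
#'   break background unanimity, but the site is still classified.
#' @return A `scan_config` list.
#' @export
scan_config <- function(min_foreground = 3,
                        require_all_foreground_for_ceg = TRUE,
                        gap_policy = c("exclude_site", "treat_as_mismatch")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(min_foreground >= 1)
  structure(list(
    min_foreground = as.integer(min_foreground),
    require_all_foreground_for_ceg = isTRUE(require_all_foreground_for_ceg),
    gap_policy = gap_policy
  ), class = "scan_config")
}

#' Classify every site of an alignment for convergence
#'
#' A site is a *relaxed convergence* for residue `a` when at least
#' `min_foreground` foreground taxa carry `a` and `a` is absent from every
#' background taxon.  It is additionally a *conservative-site convergence*
#' (CCS) when all background taxa share one identical residue `b` (which then
#' necessarily differs from `a`).  A site is *strict parallel* (the
#' CEG-qualifying pattern) when every foreground taxon carries `a` and every
#' background taxon carries the same `b != a`.  If two residues each reach
#' the carrier threshold, the site yields one row per qualifying residue.
#'
#' @param aln An `aa_alignment`.
#' @param traits A [trait_map()] whose taxa are all present in the alignment.
#' @param config A [scan_config()].
#' @return A tibble with one row per (site, qualifying residue):
#'   `orthogroup`, `site` (1-based), `class`
#'   (`"relaxed_convergence"`/`"ccs_convergence"`), `fg_residue`,
#'   `bg_residue` (`NA` unless the background is unanimous),
#'   `n_fg_carriers`, `strict_parallel`, `excluded` sites are omitted.
#' @export
classify_sites <- function(aln, traits, config = scan_config()) {
  missing_taxa <- setdiff(c(traits$foreground, traits$background), taxa(aln))
  if (length(missing_taxa) > 0) {
    stop("validation error: trait taxa absent from alignment: ",
         paste(missing_taxa, collapse = ", "), call. = FALSE)
  }
  m <- unclass(aln)
  fg <- aa_encode(m[traits$foreground, , drop = FALSE])
  bg <- aa_encode(m[traits$background, , drop = FALSE])
  s <- ncol(fg)
  n_fg <- nrow(fg)

  usable <- rep(TRUE, s)
  if (config$gap_policy == "exclude_site") {
    usable <- colSums(is.na(fg)) == 0 & colSums(is.na(bg)) == 0
  }

  # residue-by-site carrier counts in the foreground and presence in the
  # background (missing residues never carry and never block absence)
  fg_counts <- vapply(seq_len(20), function(r) colSums(fg == r, na.rm = TRUE),
                      numeric(s))
  bg_present <- vapply(seq_len(20), function(r) colSums(bg == r, na.rm = TRUE) > 0,
                       logical(s))
  if (s == 1) {
    fg_counts <- matrix(fg_counts, nrow = 1)
    bg_present <- matrix(bg_present, nrow = 1)
  }

  bg_first <- bg[1, ]
  bg_unanimous <- colSums(is.na(bg)) == 0 &
    colSums(bg == rep(bg_first, each = nrow(bg))) == nrow(bg)
  bg_unanimous[is.na(bg_unanimous)] <- FALSE

  qualifies <- fg_counts >= config$min_foreground & !bg_present   # sites x 20
  qualifies[!usable, ] <- FALSE
  hit <- which(qualifies, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(tibble::tibble(
      orthogroup = character(), site = integer(), class = character(),
      fg_residue = character(), bg_residue = character(),
      n_fg_carriers = integer(), strict_parallel = logical()
    ))
  }
  site <- hit[, 1]
  res <- hit[, 2]
  is_ccs <- bg_unanimous[site]
  out <- tibble::tibble(
    orthogroup = attr(aln, "orthogroup_id"),
    site = as.integer(site),
    class = ifelse(is_ccs, "ccs_convergence", "relaxed_convergence"),
    fg_residue = AA_STATES[res],
    bg_residue = ifelse(is_ccs, AA_STATES[bg_first[site]], NA_character_),
    n_fg_carriers = as.integer(fg_counts[cbind(site, res)]),
    strict_parallel = is_ccs & fg_counts[cbind(site, res)] == n_fg
  )
  dplyr::arrange(out, .data$site, .data$fg_residue)
}

#' Classify a single alignment column
#'
#' Single-column wrapper around [classify_sites()]; returns zero rows when
#' the column carries no convergence call.
#'
#' @param column Named character vector of residues (names = taxa).
#' @param traits A [trait_map()].
#' @param config A [scan_config()].
#' @return A tibble as in [classify_sites()] (0 or more rows, `site = 1`).
#' @export
classify_site <- function(column, traits, config = scan_config()) {
  aln <- aa_alignment(matrix(column, ncol = 1, dimnames = list(names(column), NULL)),
                      orthogroup_id = "column")
  classify_sites(aln, traits, config)
}

#' Attribute detected convergences to noise classes
#'
#' For each detected site the inferred ancestor of the background clade
#' (the MRCA of all background taxa except the outgroup) is compared with the
#' outgroup's observed residue: if the MAP reconstruction differs, the
#' detection is attributed to ancestral-state misreconstruction
#' (`"false"`), otherwise to chance identical substitutions (`"random"`).
#' Sites whose outgroup residue is missing are skipped with a warning.  The
#' literal diagnostic "more than two foreground taxa share a residue with
#' some background taxon" is recorded as `fg_matches_bg_gt2` but does not
#' drive the classification.
#'
#' @param calls Site-call tibble from [classify_sites()].
#' @param aln The scanned `aa_alignment`.
#' @param tree Rooted `phylo` with branch lengths (used for the ASR).
#' @param traits A [trait_map()].
#' @param model A [ccs_model()] (the same parameters as the simulation /
#'   fit, per the empirical-Bayes protocol).
#' @param asr Optional precomputed `ccs_asr` covering the MRCA node and the
#'   called sites; computed on the called sites when `NULL`.
#' @return `calls` with added columns `noise_class` (`"random"`/`"false"`),
#'   `ancestor_map`, `outgroup_residue`, `fg_matches_bg_gt2`.
#' @export
classify_noise <- function(calls, aln, tree, traits, model, asr = NULL) {
  if (nrow(calls) == 0) {
    return(dplyr::mutate(calls, noise_class = character(),
                         ancestor_map = character(),
                         outgroup_residue = character(),
                         fg_matches_bg_gt2 = logical()))
  }
  check_leaf_match(tree, aln, traits)
  anc_node <- ape::getMRCA(tree, setdiff(traits$background, traits$outgroup))
  sites <- sort(unique(calls$site))
  if (is.null(asr)) {
    asr <- marginal_ancestral_states(tree, model, aln, nodes = anc_node, sites = sites)
  }
  asr_tab <- tidy(asr)
  asr_tab <- asr_tab[asr_tab$node == anc_node, ]
  anc_map <- stats::setNames(asr_tab$map, asr_tab$site)

  m <- unclass(aln)
  og_res <- m[traits$outgroup, calls$site]
  missing_og <- og_res %in% c(GAP_CHAR, UNKNOWN_CHAR)
  if (any(missing_og)) {
    warning(sum(missing_og), " site(s) skipped: outgroup residue missing", call. = FALSE)
  }

  # diagnostic: > 2 foreground taxa share a residue with some background taxon
  fg <- aa_encode(m[traits$foreground, calls$site, drop = FALSE])
  bg <- aa_encode(m[traits$background, calls$site, drop = FALSE])
  diag_flag <- vapply(seq_len(ncol(fg)), function(j) {
    shared <- intersect(fg[, j], bg[, j])
    shared <- shared[!is.na(shared)]
    sum(fg[, j] %in% shared, na.rm = TRUE) > 2
  }, logical(1))

  out <- dplyr::mutate(
    calls,
    ancestor_map = unname(anc_map[as.character(calls$site)]),
    outgroup_residue = ifelse(missing_og, NA_character_, og_res),
    noise_class = dplyr::case_when(
      missing_og ~ NA_character_,
      ancestor_map != outgroup_residue ~ "false",
      TRUE ~ "random"
    ),
    fg_matches_bg_gt2 = diag_flag
  )
  out[!missing_og, , drop = FALSE]
}

#' Scan a set of orthogroup alignments for convergently evolving genes
#'
#' Applies [classify_sites()] to every alignment and calls a gene a CEG when
#' it contains at least one strict parallel site (all foreground taxa share
#' one residue, all background taxa share a single different residue).
#' Genes whose taxa do not match the tree/trait map are recorded as errors
#' and the scan continues.
#'
#' @param alignments A list of `aa_alignment` objects, or a directory path
#'   containing `.fasta`/`.fa` files.
#' @param traits A [trait_map()].
#' @param config A [scan_config()].
#' @return A list with `cegs` (tibble: orthogroup, n_sites; one row per
#'   CEG), `sites` (all qualifying site calls across genes, deterministic
#'   gene-then-site order), and `errors` (tibble: orthogroup, message).
#' @export
scan_orthogroups <- function(alignments, traits, config = scan_config()) {
  if (is.character(alignments) && length(alignments) == 1 && dir.exists(alignments)) {
    paths <- sort(list.files(alignments, pattern = "\\.(fasta|fa|faa)$", full.names = TRUE))
    alignments <- lapply(paths, read_alignment)
  }
  names(alignments) <- vapply(alignments, attr, character(1), "orthogroup_id")
  alignments <- alignments[order(names(alignments))]

  sites_list <- list()
  errors <- list()
  scan_taxa <- c(traits$foreground, traits$background)
  for (og in names(alignments)) {
    aln <- alignments[[og]]
    res <- tryCatch({
      if (!all(scan_taxa %in% taxa(aln))) {
        stop("taxa mismatch with trait map", call. = FALSE)
      }
      classify_sites(aln, traits, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[og]] <- tibble::tibble(orthogroup = og, message = conditionMessage(res))
    } else if (nrow(res) > 0) {
      sites_list[[og]] <- res
    }
  }
  sites <- if (length(sites_list) > 0) dplyr::bind_rows(sites_list) else
    tibble::tibble(
      orthogroup = character(), site = integer(), class = character(),
      fg_residue = character(), bg_residue = character(),
      n_fg_carriers = integer(), strict_parallel = logical()
    )
  qualifying <- if (config$require_all_foreground_for_ceg) {
    dplyr::filter(sites, .data$strict_parallel)
  } else {
    dplyr::filter(sites, .data$class == "ccs_convergence")
  }
  cegs <- dplyr::summarise(dplyr::group_by(qualifying, .data$orthogroup),
                           n_sites = dplyr::n(),
                           sites = paste(.data$site, collapse = ","),
                           .groups = "drop")
  cegs <- dplyr::arrange(cegs, .data$orthogroup)
  list(
    cegs = cegs,
    sites = dplyr::arrange(sites, .data$orthogroup, .data$site),
    errors = if (length(errors) > 0) dplyr::bind_rows(errors) else
      tibble::tibble(orthogroup = character(), message = character())
  )
}

#' Noise report: relaxed vs conservative-site convergence counts
#'
#' Runs the full noise-estimation protocol on a null (no convergent
#' evolution) alignment: classify every site, reconstruct the background
#' ancestor at the detected sites, attribute each detection to random or
#' false convergence, and compare the relaxed stage (all detections) with
#' the CCS-restricted stage (background unanimous).  Percent reduction is
#' `100 * (1 - after / before)`, reported `NA` when the before-count is 0.
#'
#' @param null_aln A simulated null `aa_alignment` (see [simulate_null()]).
#' @param tree Rooted `phylo` with branch lengths (as used to simulate).
#' @param traits A [trait_map()].
#' @param model The [ccs_model()] used for the simulation (the ancestral
#'   reconstruction reuses the same parameters).
#' @param config A [scan_config()].
#' @return A `ccs_noise_report`: list with `counts` (tibble: stage,
#'   noise_class, n), `reductions` (tibble: noise_class, before, after,
#'   percent_reduction), `n_sites`, `seed`, `config`, and the per-site
#'   `calls`.
#' @export
noise_report <- function(null_aln, tree, traits, model, config = scan_config()) {
  calls <- classify_sites(null_aln, traits, config)
  calls <- classify_noise(calls, null_aln, tree, traits, model)
  # counts are over distinct sites; a multi-residue site counts once per stage
  per_site <- dplyr::distinct(calls, .data$site, .data$class, .data$noise_class)
  relaxed <- dplyr::count(dplyr::distinct(per_site, .data$site, .data$noise_class),
                          .data$noise_class)
  ccs <- dplyr::count(
    dplyr::distinct(dplyr::filter(per_site, .data$class == "ccs_convergence"),
                    .data$site, .data$noise_class),
    .data$noise_class)
  classes <- c("random", "false")
  n_of <- function(tab, cl) {
    i <- match(cl, tab$noise_class)
    ifelse(is.na(i), 0L, tab$n[i])
  }
  counts <- tibble::tibble(
    stage = rep(c("relaxed", "ccs"), each = 2),
    noise_class = rep(classes, 2),
    n = c(n_of(relaxed, classes), n_of(ccs, classes))
  )
  reductions <- tibble::tibble(
    noise_class = classes,
    before = n_of(relaxed, classes),
    after = n_of(ccs, classes),
    percent_reduction = ifelse(before == 0, NA_real_, 100 * (1 - after / before))
  )
  structure(list(
    counts = counts,
    reductions = reductions,
    n_sites = ncol(null_aln),
    seed = attr(null_aln, "seed"),
    config = config,
    calls = calls
  ), class = "ccs_noise_report")
}

#' @export
print.ccs_noise_report <- function(x, ...) {
  cat("<ccs_noise_report> ", x$n_sites, " null sites",
      if (!is.null(x$seed)) paste0(" (seed ", x$seed, ")"), "\n", sep = "")
  r <- x$reductions
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-7s %5d -> %4d  (%s%% reduction)\n",
                r$noise_class[i], r$before[i], r$after[i],
                ifelse(is.na(r$percent_reduction[i]), "n/a",
                       sprintf("%.1f", r$percent_reduction[i]))))
  }
  invisible(x)
}

#' Plot a noise report
#'
#' Bar chart of random and false convergence counts before (relaxed) and
#' after the conservative-site restriction.
#'
#' @param object A `ccs_noise_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ccs_noise_report <- function(object, ...) {
  d <- dplyr::mutate(object$counts,
                     stage = factor(.data$stage, levels = c("relaxed", "ccs"),
                                    labels = c("relaxed", "CCS-restricted")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$noise_class, y = .data$n,
                                  fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "noise class", y = "convergent sites", fill = NULL,
                  title = "Convergence noise before/after the conservative-site restriction") +
    ggplot2::theme_minimal()
}
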