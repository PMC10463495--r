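# I/O layer: aligned FASTA, Newick trees, trait maps.  Alignments are stored
# as taxa-by-sites character matrices (class "aa_alignment"); trees are
# ape::phylo objects; trait maps are small validated lists.

#' Construct an amino-acid alignment
#'
#' @param x Character matrix (taxa in rows, sites in columns) of single-letter
#'   residues, or a named character vector of equal-length sequences.
#' @param orthogroup_id Identifier carried through scans and reports.
#' @return An `aa_alignment`: a character matrix with row names (taxa) and
#'   attributes `orthogroup_id`.
#' @export
#' @examples
#' aa_alignment(c(sp1 = "ARND", sp2 = "ARNE"), orthogroup_id = "OG1")
aa_alignment <- function(x, orthogroup_id = "orthogroup") {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
      stop("sequences must be named by taxon", call. = FALSE)
    }
    widths <- nchar(x)
    if (length(unique(widths)) > 1) {
      stop("alignment error: sequences have unequal lengths (",
           paste(unique(widths), collapse = ", "), ")", call. = FALSE)
    }
    m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    rownames(m) <- names(x)
    x <- m
  }
  stopifnot(is.matrix(x), is.character(x))
  if (is.null(rownames(x))) stop("alignment matrix must have taxon row names", call. = FALSE)
  if (anyDuplicated(rownames(x))) {
    stop("format error: duplicate taxon name '",
         rownames(x)[duplicated(rownames(x))][1], "'", call. = FALSE)
  }
  norm <- normalize_residues(x)
  if (norm$n_mapped > 0) {
    warning(norm$n_mapped, " residue(s) outside the 20-letter alphabet mapped to UNKNOWN",
            call. = FALSE)
  }
  m <- matrix(norm$chars, nrow = nrow(x), dimnames = list(rownames(x), NULL))
  structure(m, orthogroup_id = orthogroup_id, class = c("aa_alignment", "matrix", "array"))
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("<aa_alignment> ", attr(x, "orthogroup_id"), ": ",
      nrow(x), " taxa x ", ncol(x), " sites\n", sep = "")
  invisible(x)
}

#' Number of sites in an alignment
#' @param aln An `aa_alignment`.
#' @return Integer site count.
#' @export
n_sites <- function(aln) ncol(aln)

#' Taxa of an alignment
#' @param aln An `aa_alignment`.
#' @return Character vector of taxon names.
#' @export
taxa <- function(aln) rownames(aln)

#' Read an aligned amino-acid FASTA file
#'
#' Sequences must be pre-aligned (equal lengths).  Characters outside the
#' 20-letter alphabet (ambiguity codes B, Z, X, J, U, O and stops) are mapped
#' to UNKNOWN with a warning; `-` is kept as GAP.
#'
#' @param path Path to a FASTA file.
#' @param orthogroup_id Identifier for the alignment; defaults to the file
#'   name without extension.
#' @return An [aa_alignment()].
#' @export
read_alignment <- function(path, orthogroup_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("alignment error: no sequences in ", path, call. = FALSE)
  widths <- Biostrings::width(ss)
  if (length(unique(widths)) > 1) {
    stop("alignment error: sequences in ", path, " have unequal lengths (",
         paste(unique(widths), collapse = ", "), ")", call. = FALSE)
  }
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (is.null(orthogroup_id)) {
    orthogroup_id <- sub("\\.[^.]*$", "", basename(path))
  }
  aa_alignment(seqs, orthogroup_id = orthogroup_id)
}

#' Write an alignment to FASTA
#'
#' @param aln An `aa_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read a rooted Newick tree
#'
#' The tree must be binary (polytomies are rejected by default), rooted, and
#' carry non-negative branch lengths on every non-root edge.
#'
#' @param path Path to a Newick file.
#' @param polytomies Either `"reject"` (default) or `"resolve"` to break
#'   polytomies arbitrarily into zero-length edges via [ape::multi2di()].
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(path, polytomies = c("reject", "resolve")) {
  polytomies <- match.arg(polytomies)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("format error: could not parse Newick in ", path, call. = FALSE)
  validate_tree(tree, polytomies = polytomies)
}

#' @rdname read_tree
#' @param tree An `ape::phylo` object to validate directly.
#' @export
validate_tree <- function(tree, polytomies = c("reject", "resolve")) {
  polytomies <- match.arg(polytomies)
  if (!inherits(tree, "phylo")) stop("not a phylo tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) stop("format error: duplicate tip labels", call. = FALSE)
  if (!ape::is.binary(tree)) {
    if (polytomies == "reject") {
      stop("format error: tree contains polytomies (set polytomies = \"resolve\" to break them)",
           call. = FALSE)
    }
    tree <- ape::multi2di(tree)
  }
  if (!ape::is.rooted(tree)) stop("format error: tree is not rooted", call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    bad <- if (is.null(tree$edge.length)) "all edges" else {
      child <- tree$edge[is.na(tree$edge.length), 2]
      paste(node_label(tree, child), collapse = ", ")
    }
    stop("format error: missing branch length for ", bad, call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("format error: negative branch length", call. = FALSE)
  tree
}

node_label <- function(tree, node) {
  ifelse(node <= length(tree$tip.label),
         tree$tip.label[node],
         paste0("node_", node))
}

#' Write a tree to Newick
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Construct a trait map
#'
#' Partitions the taxa into foreground (trait-bearing, e.g. cleaner fishes)
#' and background (all others), with one designated outgroup taxon that must
#' belong to the background.
#'
#' @param foreground Character vector of foreground taxa.
#' @param background Character vector of background taxa.
#' @param outgroup Single background taxon used to audit ancestral
#'   reconstructions.
#' @return A `trait_map` list with elements `foreground`, `background`,
#'   `outgroup`.
#' @export
trait_map <- function(foreground, background, outgroup) {
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  if (length(foreground) == 0) stop("validation error: empty foreground set", call. = FALSE)
  if (length(background) == 0) stop("validation error: empty background set", call. = FALSE)
  both <- intersect(foreground, background)
  if (length(both) > 0) {
    stop("validation error: taxa labelled both foreground and background: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  if (length(outgroup) != 1) stop("validation error: exactly one outgroup required", call. = FALSE)
  if (outgroup %in% foreground) {
    stop("validation error: outgroup '", outgroup, "' is listed as foreground", call. = FALSE)
  }
  if (!outgroup %in% background) {
    stop("validation error: outgroup '", outgroup, "' is not a background taxon", call. = FALSE)
  }
  structure(list(foreground = foreground, background = background, outgroup = outgroup),
            class = "trait_map")
}

#' @export
print.trait_map <- function(x, ...) {
  cat("<trait_map> ", length(x$foreground), " foreground / ",
      length(x$background), " background (outgroup: ", x$outgroup, ")\n", sep = "")
  invisible(x)
}

#' Read a trait map from TSV
#'
#' Expects a two-column tab-separated file (no header) mapping taxon to one of
#' the labels `foreground`, `background` or `outgroup`; the outgroup row is
#' also a background taxon.
#'
#' @param path Path to the TSV file.
#' @return A [trait_map()].
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("taxon", "label"))
  lab <- tolower(trimws(tab$label))
  ok <- lab %in% c("foreground", "background", "outgroup")
  if (!all(ok)) {
    stop("validation error: unknown trait label(s): ",
         paste(unique(tab$label[!ok]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$taxon)) {
    stop("validation error: taxon listed more than once: ",
         paste(unique(tab$taxon[duplicated(tab$taxon)]), collapse = ", "), call. = FALSE)
  }
  og <- tab$taxon[lab == "outgroup"]
  if (length(og) != 1) stop("validation error: exactly one outgroup row required", call. = FALSE)
  trait_map(foreground = tab$taxon[lab == "foreground"],
            background = c(tab$taxon[lab == "background"], og),
            outgroup = og)
}

#' Write a trait map to TSV
#' @param traits A [trait_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traits <- function(traits, path) {
  rows <- rbind(
    data.frame(taxon = traits$foreground, label = "foreground"),
    data.frame(taxon = setdiff(traits$background, traits$outgroup), label = "background"),
    data.frame(taxon = traits$outgroup, label = "outgroup")
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Leaf-set equality check used by every alignment/tree pairing; violation is
# an error, never silent subsetting.
check_leaf_match <- function(tree, aln, traits = NULL) {
  tips <- sort(tree$tip.label)
  tx <- sort(taxa(aln))
  if (!identical(tips, tx)) {
    stop("validation error: tree leaves and alignment taxa differ (",
         paste(setdiff(union(tips, tx), intersect(tips, tx)), collapse = ", "), ")",
         call. = FALSE)
  }
  if (!is.null(traits)) {
    tt <- sort(c(traits$foreground, traits$background))
    if (!identical(tips, tt)) {
      stop("validation error: trait map taxa and tree leaves differ", call. = FALSE)
    }
  }
  invisible(TRUE)
}
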