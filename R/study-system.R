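# Built-in study system: a 14-taxon fish phylogeny with six cleaner
# (foreground) wrasses, two non-cleaner wrasses, and six reference species
# with the spotted gar as outgroup.  Branch lengths are in expected
# amino-acid substitutions per site, chosen to mimic proteome-scale
# divergence (root-to-tip depth roughly 0.3); they are the default study
# conditions for simulations and noise reports.

CLEANER_NEWICK <- paste0(
  "(L_oculatus:0.28,",
  "(D_rerio:0.22,",
  "((G_aculeatus:0.12,(T_rubripes:0.11,(O_latipes:0.09,X_maculatus:0.09):0.02):0.01):0.035,",
  "(C_undulatus:0.065,",
  "(S_pulcher:0.055,",
  "((L_bergylta:0.03,(S_melops:0.025,T_adspersus:0.025):0.005):0.02,",
  "(L_dimidiatus:0.04,(T_bifasciatum:0.035,N_celidotus:0.035):0.005):0.01",
  "):0.01):0.01):0.09):0.04):0.06);"
)

#' Example cleaner-fish phylogeny
#'
#' A rooted 14-taxon tree shaped like the study system: eight wrasses (six
#' cleaners, two non-cleaners) nested among six reference fish species, with
#' the spotted gar (`L_oculatus`) as outgroup.  Note the non-cleaners are
#' paraphyletic: the two non-cleaner wrasses sit inside the wrasse clade, so
#' the ancestor of all non-outgroup background taxa also subtends the
#' cleaners.
#'
#' @return An `ape::phylo` tree with branch lengths in expected amino-acid
#'   substitutions per site.
#' @export
#' @examples
#' tr <- cleaner_fish_tree()
#' length(tr$tip.label)
cleaner_fish_tree <- function() {
  validate_tree(ape::read.tree(text = CLEANER_NEWICK))
}

#' Example cleaner-fish trait map
#'
#' Six cleaner wrasses as foreground; the two non-cleaner wrasses and six
#' reference species as background, with the spotted gar as outgroup.
#'
#' @return A [trait_map()].
#' @export
cleaner_fish_traits <- function() {
  trait_map(
    foreground = c("L_dimidiatus", "T_bifasciatum", "S_melops",
                   "T_adspersus", "S_pulcher", "L_bergylta"),
    background = c("C_undulatus", "N_celidotus", "O_latipes", "T_rubripes",
                   "G_aculeatus", "D_rerio", "X_maculatus", "L_oculatus"),
    outgroup = "L_oculatus"
  )
}
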