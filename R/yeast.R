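#' The 18-taxon ascomycetous yeast backbone constraint tree
#'
#' The well-accepted relationships among 18 ascomycetous yeasts, with
#' regions of uncertainty collapsed into polytomies: the five-species
#' \emph{Saccharomyces sensu stricto} ladder is resolved, the placement of
#' \emph{Candida glabrata} and \emph{Saccharomyces castellii} at the base of
#' the post-WGD (whole-genome duplication) clade is a trifurcation, the four
#' pre-WGD species form a polytomy, and the CTG clade (six species, with the
#' \emph{Debaryomyces hansenii} + \emph{Pichia guilliermondii} pair
#' resolved) holds a five-way polytomy. \emph{Yarrowia lipolytica} is the
#' outgroup. Resolving all polytomies yields 3 x 15 x 105 = 4725 binary
#' trees; excluding the arrangement in which \emph{C. glabrata} and
#' \emph{S. castellii} are sister species leaves 2 x 15 x 105 = 3150
#' candidate topologies.
#'
#' @return a multifurcating \code{phylo} with 18 leaves.
#' @examples
#' bb <- yeast_backbone()
#' count_resolutions(bb)  # 4725
#' @export
yeast_backbone <- function() {
  read_newick_one(paste0(
    "(Yarrowia_lipolytica,",
    "(((((((Saccharomyces_cerevisiae,Saccharomyces_paradoxus),",
    "Saccharomyces_mikatae),Saccharomyces_kudriavzevii),",
    "Saccharomyces_bayanus),Candida_glabrata,Saccharomyces_castellii),",
    "(Saccharomyces_kluyveri,Kluyveromyces_waltii,Kluyveromyces_lactis,",
    "Ashbya_gossypii)),",
    "(Pichia_stipitis,Lodderomyces_elongisporus,Candida_albicans,",
    "Candida_tropicalis,",
    "(Debaryomyces_hansenii,Pichia_guilliermondii))));"))
}

#' Candidate tree set from the yeast backbone
#'
#' Enumerates all binary resolutions of \code{\link{yeast_backbone}} and
#' drops those in which \emph{C. glabrata} and \emph{S. castellii} form a
#' clade (the sister arrangement, excluded from the candidate set and
#' tested separately in the original analysis), leaving 3150 topologies.
#'
#' @param exclude_sister drop the sister arrangement (default TRUE).
#' @return \code{multiPhylo}.
#' @export
yeast_candidate_set <- function(exclude_sister = TRUE) {
  trees <- enumerate_resolutions(yeast_backbone())
  if (exclude_sister) {
    pair <- c("Candida_glabrata", "Saccharomyces_castellii")
    keep <- !vapply(trees, has_clade, TRUE, taxa = pair)
    trees <- trees[keep]
    class(trees) <- "multiPhylo"
  }
  trees
}
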