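#' The bundled Potentilla example data set
#'
#' A worked cytonuclear-discordance example for the genus
#' \emph{Potentilla} (Rosaceae): schematic nuclear (ITS+ETS) and
#' chloroplast (trnL/F + trnS/G) consensus-tree topologies with
#' posterior-probability supports, and a table of published ploidal
#' levels, clade assignments and two floral characters (style shape
#' L/N/G/C and anther shape A-D) for 65 ingroup and 7 outgroup taxa.
#'
#' The trees are synthetic encodings of the published clade structure
#' (files \code{*_synthetic.tre}): topology and supports follow the
#' described clades A-F and their conflicting placements, with supports
#' of 0.99 where a placement is described only as well-supported, and
#' unit branch lengths throughout, since the original consensus trees'
#' branch lengths are not part of the bundled data. Ancestral-state
#' reconstructions on these trees are therefore qualitative. One taxon
#' (\emph{P. clusiana}) appears in the table but not in the trees - its
#' sequences were excluded from the original analyses after a
#' recombination screen.
#'
#' @return A list: \code{nuclear} and \code{chloroplast} (\code{phylo}
#'   with supports and unit branch lengths), \code{ploidy} (a
#'   \code{ploidy_table} with columns taxon, ploidy, clade, clade_name,
#'   style, anther) and \code{characters} (taxa x 2 character matrix of
#'   style and anther states, \code{NA} = not scored).
#' @examples
#' fx <- potentilla_fixture()
#' pairs <- find_conflicting_pairs(fx$nuclear, fx$chloroplast)
#' events <- cluster_events(pairs, fx$nuclear, fx$chloroplast)
#' summary(flag_events(events, fx$ploidy))
#' @export
potentilla_fixture <- function() {
  dir <- system.file("extdata", "potentilla", package = "phyloconflict")
  if (!nzchar(dir)) stop("fixture data not installed")
  unit <- function(tr) {
    tr$edge.length <- rep(1, nrow(tr$edge))
    tr
  }
  nuclear <- unit(read_trees(file.path(dir, "nuclear_synthetic.tre")))
  chloroplast <- unit(read_trees(file.path(dir, "chloroplast_synthetic.tre")))
  tab <- utils::read.delim(file.path(dir, "ploidy_characters.tsv"),
                           sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE, na.strings = NULL)
  # clade column carries the clade name on its first row ("A Anserina")
  letter <- sub("^([A-Za-z]+).*$", "\\1", tab$clade)
  name <- trimws(sub("^[A-Za-z]+\\s*", "", tab$clade))
  clade_names <- stats::setNames(name[nzchar(name)], letter[nzchar(name)])
  tab$clade <- letter
  tab$clade_name <- ifelse(tab$clade %in% names(clade_names),
                           clade_names[tab$clade], tab$clade)
  # style/anther: spelled-out forms on first use, single letters elsewhere
  tab$style <- ifelse(nzchar(tab$style), toupper(substr(tab$style, 1, 1)), NA)
  tab$anther <- ifelse(nzchar(tab$anther), toupper(tab$anther), NA)
  ploidy <- parse_ploidy_table(tab)
  characters <- cbind(style = tab$style, anther = tab$anther)
  rownames(characters) <- tab$taxon
  list(nuclear = nuclear, chloroplast = chloroplast,
       ploidy = ploidy, characters = characters)
}
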