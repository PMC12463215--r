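#' Write a simulation's phylogeny as a newick string
#'
#' Builds the species tree implied by the origination events: each speciation
#' splits the parent branch at the event's age; branch lengths are in Myr.
#' Tips are all species ever alive, labelled `sp<id>`; extinct tips end at
#' their extinction age, extant tips at the final slice. Two events at the
#' same age produce zero-length internal branches.
#'
#' @param record A `simulation_record`.
#' @return A newick string (terminated by `;`), parseable by
#'   [ape::read.tree()].
#' @export
write_phylogeny <- function(record) {
  tab <- record$species
  if (nrow(tab) == 0) stop("record has no species")
  t_final <- min(record$times)
  kids_of <- function(s) {
    k <- tab[!is.na(tab$parent) & tab$parent == s, , drop = FALSE]
    k[order(-k$origin_age, k$id), , drop = FALSE]
  }
  tip_end <- function(s) {
    e <- tab$extinct_age[tab$id == s]
    if (is.na(e)) t_final else e
  }
  # branch of species s from age `from`, with `kids` (its not-yet-placed
  # children, sorted oldest first)
  desc <- function(s, from, kids) {
    if (nrow(kids) == 0)
      return(sprintf("sp%d:%g", s, from - tip_end(s)))
    ev <- kids$origin_age[1]
    child <- kids$id[1]
    sprintf("(%s,%s):%g",
            desc(s, ev, kids[-1, , drop = FALSE]),
            desc(child, ev, kids_of(child)),
            from - ev)
  }
  root <- tab$id[is.na(tab$parent)][1]
  nwk <- desc(root, tab$origin_age[tab$id == root], kids_of(root))
  if (nrow(tab) == 1) nwk <- sprintf("(%s)", nwk)  # single-tip tree
  paste0(nwk, ";")
}
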