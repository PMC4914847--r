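.readBundledTable <- function(file) {
  path <- system.file("extdata", file, package = "EGFRcomplement",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
}

#' Bundled species-by-complement matrices
#'
#' The transcribed published survey: the receptor table (35 species across 19
#' major animal clades; per-species EGFR count and count of receptors with an
#' inactive tyrosine-kinase domain) and the ligand table (34 species; totals
#' split into EGF-type and NRG-type ligands). Counts not covered by a table
#' are \code{NA}; see \code{\link{combineComplements}} to merge the two.
#'
#' @param which \code{"EGFR_TABLE"} or \code{"LIGAND_TABLE"}.
#' @return a \linkS4class{ComplementMatrix} with provenance
#'   \code{"TRANSCRIBED"}.
#' @examples
#' complementTable(bundledComplementMatrix("EGFR_TABLE"))
#' @export
bundledComplementMatrix <- function(which = c("EGFR_TABLE", "LIGAND_TABLE")) {
  which <- match.arg(which)
  if (which == "EGFR_TABLE") {
    t <- .readBundledTable("egfr_table.tsv")
    n <- as.integer(t$n_egfr)
    inact <- vapply(seq_len(nrow(t)), function(i) {
      if (n[i] == 0L) return(0L)
      sum(.parseMulti(t$inactive_tk[i], n[i], "No") == "Yes")
    }, integer(1))
    tab <- data.frame(species = t$species, clade = t$clade,
                      egfr_count = n, inactive_tk_count = inact,
                      egf_like_count = NA_integer_,
                      nrg_like_count = NA_integer_,
                      stringsAsFactors = FALSE)
  } else {
    t <- .readBundledTable("ligand_table.tsv")
    toInt <- function(x) ifelse(x %in% c("-", "–"), 0L,
                                suppressWarnings(as.integer(x)))
    tab <- data.frame(species = t$species, clade = t$clade,
                      egfr_count = NA_integer_,
                      inactive_tk_count = NA_integer_,
                      egf_like_count = toInt(t$egf_like),
                      nrg_like_count = toInt(t$nrg_like),
                      stringsAsFactors = FALSE)
  }
  new("ComplementMatrix", table = tab,
      qc = data.frame(), provenance = "TRANSCRIBED")
}

#' Merge the receptor and ligand complement tables
#'
#' Produces a complete complement matrix over the union of species. A species
#' present only in the receptor survey (the phoronid, for which no ligand row
#' is printed and no EGF-type ligand was recovered) gets ligand counts 0.
#'
#' @param egfr,ligand \linkS4class{ComplementMatrix} objects as returned by
#'   \code{\link{bundledComplementMatrix}}; default the bundled ones.
#' @return a \linkS4class{ComplementMatrix}.
#' @export
combineComplements <- function(egfr = bundledComplementMatrix("EGFR_TABLE"),
                               ligand = bundledComplementMatrix("LIGAND_TABLE")) {
  e <- complementTable(egfr)
  l <- complementTable(ligand)
  tab <- e[, c("species", "clade", "egfr_count", "inactive_tk_count")]
  idx <- match(tab$species, l$species)
  tab$egf_like_count <- ifelse(is.na(idx), 0L, l$egf_like_count[idx])
  tab$nrg_like_count <- ifelse(is.na(idx), 0L, l$nrg_like_count[idx])
  extra <- setdiff(l$species, tab$species)
  if (length(extra)) {
    le <- l[l$species %in% extra, ]
    le$egfr_count <- 0L
    le$inactive_tk_count <- 0L
    tab <- rbind(tab, le[, colnames(tab)])
  }
  new("ComplementMatrix", table = tab, qc = data.frame(),
      provenance = if (provenance(egfr) == "TRANSCRIBED" &&
                       provenance(ligand) == "TRANSCRIBED")
        "TRANSCRIBED" else "SCANNED")
}

#' Bundled metazoan species tree
#'
#' The rooted species tree of the survey (ctenophore-first backbone;
#' Bilateria = Xenacoelomorpha + (Protostomia + Deuterostomia)). Tips carry
#' underscored species names matching
#' \code{.tipName} of the bundled matrices' species column; key internal
#' nodes are labeled (Metazoa, Bilateria, Protostomia, Deuterostomia,
#' Ecdysozoa, Spiralia, ...). Within multi-species clades whose branching
#' order the survey does not resolve, tips are attached as polytomies.
#'
#' @return an \code{ape} \code{phylo} object.
#' @examples
#' tr <- bundledSpeciesTree()
#' ape::Ntip(tr)
#' @export
bundledSpeciesTree <- function() {
  path <- system.file("extdata", "species_tree.nwk",
                      package = "EGFRcomplement", mustWork = TRUE)
  ape::read.tree(path)
}
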