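## Residue conservation scoring on ortholog alignments and a species tree.
##
## The phosphorylation-conservation feature is
##     RCS = MBL * RCR = MBL * Np / N
## where MBL is the longest tree path distance between any two species
## carrying a phosphorylatable residue at the aligned position, Np the
## number of such species, and N the number of analysis species in the
## smallest clade (MRCA subtree) spanning them.

#' Construct an ortholog alignment object
#'
#' @param sequences named character vector of aligned sequences (equal
#'   lengths; gap character \code{"-"}), one per species.
#' @param reference_species name of the reference (query-organism) row.
#' @return object of class \code{ortholog_alignment}.
#' @export
ortholog_alignment <- function(sequences, reference_species) {
  sequences <- toupper(sequences)
  if (length(unique(nchar(sequences))) != 1L) {
    stop("all alignment rows must have equal length", call. = FALSE)
  }
  if (!reference_species %in% names(sequences)) {
    stop("reference species '", reference_species,
         "' not among alignment rows", call. = FALSE)
  }
  structure(list(sequences = sequences,
                 reference_species = reference_species),
            class = "ortholog_alignment")
}

#' Read an aligned FASTA file as an ortholog alignment
#'
#' @param path aligned FASTA; headers are species labels.
#' @param reference_species the reference row's label.
#' @return an [ortholog_alignment()].
#' @export
read_alignment <- function(path, reference_species) {
  fa <- read_fasta(path)
  ortholog_alignment(setNames(fa$sequence, fa$accession), reference_species)
}

#' Map a reference residue position to an alignment column
#'
#' Positions are 1-based indices into the ungapped reference sequence;
#' gaps in the reference row are skipped while counting.
#'
#' @param msa an [ortholog_alignment()].
#' @param position 1-based residue index in the ungapped reference.
#' @return 1-based alignment column index.
#' @export
#' @examples
#' msa <- ortholog_alignment(c(ref = "M-ST", A = "MAST"), "ref")
#' map_site_to_column(msa, 2)  # column 3 holds the S
map_site_to_column <- function(msa, position) {
  ref <- strsplit(msa$sequences[[msa$reference_species]], "")[[1L]]
  notgap <- which(ref != "-")
  if (position < 1L || position > length(notgap)) {
    stop("position ", position, " outside ungapped reference length ",
         length(notgap), call. = FALSE)
  }
  notgap[[position]]
}

## Phosphoacceptor equivalence: S and T form one class (serine/threonine
## kinases act on either), Y its own class. strict = exact-residue match.
phospho_equivalent <- function(chars, site_residue, strict = FALSE) {
  if (strict) return(chars == site_residue)
  if (site_residue %in% c("S", "T")) chars %in% c("S", "T") else chars == "Y"
}

#' Species carrying a conserved phosphorylatable residue at a column
#'
#' The reference species is always a member. With the default residue
#' classes, S and T are interchangeable while Y matches only Y; set
#' \code{strict_residue = TRUE} for exact-residue matching.
#'
#' @param msa an [ortholog_alignment()].
#' @param column 1-based alignment column.
#' @param site_residue the reference residue (S, T or Y).
#' @param strict_residue logical; exact residue match.
#' @return character vector of species names.
#' @export
conserved_species <- function(msa, column, site_residue,
                              strict_residue = FALSE) {
  chars <- vapply(msa$sequences, function(s) substr(s, column, column),
                  character(1))
  hit <- phospho_equivalent(chars, site_residue, strict_residue)
  out <- union(msa$reference_species, names(chars)[hit])
  out[order(match(out, names(msa$sequences)))]
}

#' Maximum branch length spanned by a species set
#'
#' The longest path distance (sum of branch lengths) between any two
#' species of the set; all endpoint pairs attaining the maximum are
#' returned. A singleton set has MBL 0 and no pair.
#'
#' @param tree \code{phylo} object with branch lengths.
#' @param species_set character vector of tip labels.
#' @return list: \code{MBL} (numeric), \code{pairs} (2-column character
#'   matrix of tied endpoint pairs, 0 rows for a singleton).
#' @export
max_branch_length <- function(tree, species_set) {
  missing <- setdiff(species_set, tree$tip.label)
  if (length(missing)) {
    stop("species absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(species_set) < 2L) {
    return(list(MBL = 0,
                pairs = matrix(character(0), ncol = 2,
                               dimnames = list(NULL, c("a", "b")))))
  }
  d <- ape::cophenetic.phylo(tree)[species_set, species_set, drop = FALSE]
  mbl <- max(d)
  idx <- which(d == mbl & upper.tri(d), arr.ind = TRUE)
  pairs <- cbind(a = rownames(d)[idx[, 1L]], b = colnames(d)[idx[, 2L]])
  list(MBL = mbl, pairs = pairs)
}

#' Residue conservation score of a phosphosite
#'
#' Computes RCS = MBL * Np / N for one site: the conserved species set at
#' the site's alignment column, the maximum branch length it spans on the
#' species tree, and the conservation ratio within the smallest clade
#' spanning the conserved species. Species without an ortholog row in the
#' alignment are excluded from both Np and N. A site conserved only in
#' the reference species has MBL 0 and hence RCS 0.
#'
#' @param msa an [ortholog_alignment()].
#' @param tree \code{phylo} species tree containing all alignment species.
#' @param position 1-based residue position in the reference protein.
#' @param site_residue the phosphoacceptor residue (S, T, Y).
#' @param strict_residue logical, see [conserved_species()].
#' @return list of class \code{conservation_score}: \code{MBL},
#'   \code{Np}, \code{N}, \code{RCR}, \code{RCS}, \code{conserved}
#'   (species vector).
#' @export
residue_conservation_score <- function(msa, tree, position, site_residue,
                                       strict_residue = FALSE) {
  analysis_species <- names(msa$sequences)
  missing <- setdiff(analysis_species, tree$tip.label)
  if (length(missing)) {
    stop("alignment species absent from tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  col <- map_site_to_column(msa, position)
  cons <- conserved_species(msa, col, site_residue, strict_residue)
  if (length(cons) < 2L) {
    return(structure(list(MBL = 0, Np = 1L, N = 1L, RCR = 1,
                          RCS = 0, conserved = cons),
                     class = "conservation_score"))
  }
  mbl <- max_branch_length(tree, cons)
  ## smallest clade (MRCA subtree) spanning the conserved species
  mrca <- ape::getMRCA(tree, cons)
  clade_tips <- if (is.null(mrca)) tree$tip.label else
    ape::extract.clade(tree, mrca)$tip.label
  N <- length(intersect(clade_tips, analysis_species))
  Np <- length(cons)  # conserved set lies inside its spanning clade
  structure(list(MBL = mbl$MBL, Np = Np, N = N, RCR = Np / N,
                 RCS = mbl$MBL * Np / N, conserved = cons),
            class = "conservation_score")
}

#' Conservation scores for a phosphosite table
#'
#' Looks up each site's ortholog alignment (aligned FASTA named
#' \code{<accession>.fasta} under \code{msa_dir}) and scores it against
#' the species tree. Sites whose protein has no alignment file get
#' RCS 0 (no detectable ortholog conservation).
#'
#' @param sites data.frame with \code{accession}, \code{position},
#'   \code{residue}, \code{site_id}.
#' @param msa_dir directory of per-protein aligned FASTA files.
#' @param tree \code{phylo} species tree.
#' @param reference_species reference species label used in the MSAs.
#' @param strict_residue logical, see [conserved_species()].
#' @return data.frame: \code{site_id}, \code{MBL}, \code{Np}, \code{N},
#'   \code{RCR}, \code{RCS}.
#' @export
score_conservation_table <- function(sites, msa_dir, tree,
                                     reference_species,
                                     strict_residue = FALSE) {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    path <- file.path(msa_dir, paste0(sites$accession[i], ".fasta"))
    if (!file.exists(path)) {
      return(data.frame(site_id = sites$site_id[i], MBL = 0, Np = 1L,
                        N = 1L, RCR = 1, RCS = 0,
                        stringsAsFactors = FALSE))
    }
    msa <- read_alignment(path, reference_species)
    sc <- residue_conservation_score(msa, tree, sites$position[i],
                                     sites$residue[i], strict_residue)
    data.frame(site_id = sites$site_id[i], MBL = sc$MBL, Np = sc$Np,
               N = sc$N, RCR = sc$RCR, RCS = sc$RCS,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
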