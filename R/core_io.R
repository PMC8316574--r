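## Domain containers and format readers shared by all stages.
##
## Phosphosite tables, protein sets and annotation bundles are plain data
## frames / lists with light validation, in the style of limma's targets
## frames: easy to inspect, easy to write back out as TSV.

#' Build a site identifier
#'
#' Site identifiers have the canonical form \code{"accession:residue+position"},
#' e.g. \code{"P12345:S42"}, matching the residue-numbering convention used
#' in curated phosphosite tables (1-based, inclusive).
#'
#' @param accession protein accession.
#' @param residue phosphoacceptor residue, one of \code{"S"}, \code{"T"},
#'   \code{"Y"}.
#' @param position 1-based residue position.
#' @return character vector of site ids.
#' @export
#' @examples
#' make_site_id("P1", "S", 2)
make_site_id <- function(accession, residue, position) {
  paste0(accession, ":", residue, position)
}

#' Read a tab-delimited phosphosite table
#'
#' Expects four tab-separated columns: protein accession, full protein
#' sequence, 1-based phosphorylation position, and phosphoacceptor residue
#' (S, T or Y). Each record is validated against its protein sequence: the
#' residue at the declared position must equal the declared residue.
#' Sequences are deduplicated by accession; duplicate accessions carrying
#' conflicting sequences are an error.
#'
#' @param path path to the TSV file (header row required; columns
#'   \code{accession}, \code{sequence}, \code{position}, \code{residue}).
#' @return a list with components \code{sites} (data.frame: accession,
#'   position, residue, site_id) and \code{proteins} (data.frame:
#'   accession, sequence).
#' @export
read_site_table <- function(path) {
  tab <- read_tsv_table(path)
  required <- c("accession", "sequence", "position", "residue")
  if (!identical(sort(intersect(names(tab), required)), sort(required)) ||
      ncol(tab) != 4L) {
    stop("site table must have exactly the 4 tab-separated columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  tab$position <- as.integer(tab$position)
  validate_site_table(tab[, required])
}

#' Validate an in-memory phosphosite table
#'
#' @param tab data.frame with columns accession, sequence, position, residue.
#' @return as [read_site_table()].
#' @export
validate_site_table <- function(tab) {
  if (any(is.na(tab$position)) || any(tab$position < 1L)) {
    stop("positions must be integers >= 1", call. = FALSE)
  }
  bad_res <- !tab$residue %in% c("S", "T", "Y")
  if (any(bad_res)) {
    stop("residue must be one of S, T, Y; offending rows: ",
         paste(which(bad_res), collapse = ", "), call. = FALSE)
  }
  tab$sequence <- toupper(tab$sequence)
  ## sequences deduplicated by accession; conflicts are an error
  prot <- unique(tab[, c("accession", "sequence")])
  if (anyDuplicated(prot$accession)) {
    dup <- unique(prot$accession[duplicated(prot$accession)])
    stop("duplicate accessions with conflicting sequences: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  seq_of <- setNames(prot$sequence, prot$accession)
  too_far <- tab$position > nchar(seq_of[tab$accession])
  if (any(too_far)) {
    stop("position beyond protein length for: ",
         paste(make_site_id(tab$accession, tab$residue,
                            tab$position)[too_far], collapse = ", "),
         call. = FALSE)
  }
  at_pos <- substr(seq_of[tab$accession], tab$position, tab$position)
  mism <- at_pos != tab$residue
  if (any(mism)) {
    stop("declared residue does not match sequence at: ",
         paste0(tab$accession[mism], " position ", tab$position[mism],
                " (found ", at_pos[mism], ", declared ",
                tab$residue[mism], ")", collapse = "; "),
         call. = FALSE)
  }
  sites <- data.frame(
    accession = tab$accession,
    position = tab$position,
    residue = tab$residue,
    site_id = make_site_id(tab$accession, tab$residue, tab$position),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(sites$site_id)) {
    stop("duplicate site ids: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]),
               collapse = ", "), call. = FALSE)
  }
  list(sites = sites,
       proteins = data.frame(accession = prot$accession,
                             sequence = prot$sequence,
                             stringsAsFactors = FALSE))
}

#' Write a phosphosite table
#'
#' Inverse of [read_site_table()]; the round trip is lossless.
#'
#' @param sites,proteins as returned by [read_site_table()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_site_table <- function(sites, proteins, path) {
  seq_of <- setNames(proteins$sequence, proteins$accession)
  out <- data.frame(accession = sites$accession,
                    sequence = unname(seq_of[sites$accession]),
                    position = sites$position,
                    residue = sites$residue,
                    stringsAsFactors = FALSE)
  write_tsv_table(out, path)
}

#' Read protein sequences from FASTA
#'
#' Headers are parsed to the first whitespace token as the accession
#' (UniProt convention). Sequences are uppercased on read.
#'
#' @param path FASTA file.
#' @return data.frame with columns \code{accession}, \code{sequence},
#'   in file order.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  acc <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(acc)) {
    stop("duplicate accessions in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(accession = acc,
             sequence = unname(toupper(as.character(aa))),
             stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#'
#' @param proteins data.frame with \code{accession}, \code{sequence}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::BStringSet(setNames(proteins$sequence,
                                        proteins$accession))
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths from Newick
#'
#' The tree must be single, have unique leaf labels, and carry a
#' non-negative branch length on every edge (path distances between
#' species are read off the tree as given, with no re-scaling).
#'
#' @param path Newick file.
#' @return an [ape::read.tree()] \code{phylo} object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) {
    stop("expected a single tree, found ", length(tr), call. = FALSE)
  }
  if (is.null(tr)) stop("could not parse Newick file: ", path, call. = FALSE)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length)) {
    stop("every edge must carry a branch length", call. = FALSE)
  }
  if (any(tr$edge.length < 0)) {
    stop("negative branch length in tree", call. = FALSE)
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  tr
}

#' Path distance between two leaves of a tree
#'
#' Sum of branch lengths along the unique path joining two tips;
#' symmetric, zero on the diagonal.
#'
#' @param tree \code{phylo} object.
#' @param a,b tip labels.
#' @return numeric distance.
#' @export
tree_path_distance <- function(tree, a, b) {
  d <- ape::cophenetic.phylo(tree)
  if (!a %in% rownames(d) || !b %in% rownames(d)) {
    stop("tip not in tree: ", paste(setdiff(c(a, b), rownames(d)),
                                    collapse = ", "), call. = FALSE)
  }
  d[a, b]
}

#' Assemble an annotation bundle
#'
#' Collects the per-site annotation tables that stand in for upstream
#' predictor output: kinase-site edges (kinase family granularity),
#' predicted acetylation sites, domain spans with per-domain interaction
#' partner counts, relative surface accessibility (RSA), and secondary
#' structure probabilities (helix/strand/coil).
#'
#' @param kinase_edges data.frame (\code{kinase_family}, \code{site_id}).
#' @param acetyl_sites data.frame (\code{accession}, \code{position}).
#' @param domain_spans data.frame (\code{accession}, \code{start},
#'   \code{end}, \code{domain_id}).
#' @param domain_partner_counts data.frame (\code{domain_id},
#'   \code{n_partners}).
#' @param rsa data.frame (\code{site_id}, \code{rsa}), rsa in [0,1].
#' @param ss_probs data.frame (\code{site_id}, \code{p_helix},
#'   \code{p_strand}, \code{p_coil}), each triple summing to 1 within 0.01.
#' @return an object of class \code{annotation_bundle}.
#' @export
annotation_bundle <- function(kinase_edges = empty_df("kinase_family", "site_id"),
                              acetyl_sites = empty_df("accession", "position"),
                              domain_spans = empty_df("accession", "start", "end", "domain_id"),
                              domain_partner_counts = empty_df("domain_id", "n_partners"),
                              rsa = empty_df("site_id", "rsa"),
                              ss_probs = empty_df("site_id", "p_helix", "p_strand", "p_coil")) {
  structure(list(kinase_edges = kinase_edges,
                 acetyl_sites = acetyl_sites,
                 domain_spans = domain_spans,
                 domain_partner_counts = domain_partner_counts,
                 rsa = rsa,
                 ss_probs = ss_probs),
            class = "annotation_bundle")
}

empty_df <- function(...) {
  cols <- c(...)
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  df
}

#' Validate an annotation bundle against a protein/site universe
#'
#' Checks referential integrity and value invariants of every annotation
#' table: acetylation positions and domain spans within protein length,
#' known accessions and site ids, RSA in [0,1], secondary-structure
#' probability triples non-negative and summing to 1 within 0.01.
#'
#' In strict mode (the default) any violation is an error; silent row
#' dropping would corrupt enrichment backgrounds. In lenient mode
#' offending rows are dropped and counted in the returned report.
#'
#' @param bundle an [annotation_bundle()].
#' @param proteins data.frame (\code{accession}, \code{sequence}).
#' @param sites data.frame with a \code{site_id} column; the known site
#'   universe.
#' @param strict logical; raise on first problem (default \code{TRUE}).
#' @return a list: \code{bundle} (possibly filtered), \code{report}
#'   (data.frame of table, problem, n_dropped), \code{ok}.
#' @export
validate_annotations <- function(bundle, proteins, sites, strict = TRUE) {
  stopifnot(inherits(bundle, "annotation_bundle"))
  plen <- setNames(nchar(proteins$sequence), proteins$accession)
  known_sites <- sites$site_id
  report <- list()
  flag <- function(tab, bad, table, problem) {
    nbad <- sum(bad)
    if (nbad > 0L) {
      if (strict) {
        stop("annotation validation failed [", table, "]: ", problem,
             " (", nbad, " rows)", call. = FALSE)
      }
      report[[length(report) + 1L]] <<- data.frame(
        table = table, problem = problem, n_dropped = nbad,
        stringsAsFactors = FALSE)
    }
    tab[!bad, , drop = FALSE]
  }

  ke <- bundle$kinase_edges
  ke <- flag(ke, !(ke$site_id %in% known_sites),
             "kinase_edges", "unknown site_id")

  ac <- bundle$acetyl_sites
  ac <- flag(ac, !(ac$accession %in% names(plen)),
             "acetyl_sites", "unknown accession")
  ac <- flag(ac, ac$position < 1L | ac$position > plen[ac$accession],
             "acetyl_sites", "position outside protein")

  dm <- bundle$domain_spans
  dm <- flag(dm, !(dm$accession %in% names(plen)),
             "domain_spans", "unknown accession")
  dm <- flag(dm, !(dm$start >= 1L & dm$start <= dm$end &
                     dm$end <= plen[dm$accession]),
             "domain_spans", "span outside 1..protein length")

  rs <- bundle$rsa
  rs <- flag(rs, !(rs$site_id %in% known_sites), "rsa", "unknown site_id")
  rs <- flag(rs, !(rs$rsa >= 0 & rs$rsa <= 1), "rsa", "rsa outside [0,1]")

  ss <- bundle$ss_probs
  ss <- flag(ss, !(ss$site_id %in% known_sites), "ss_probs",
             "unknown site_id")
  if (nrow(ss)) {
    tot <- ss$p_helix + ss$p_strand + ss$p_coil
    bad_ss <- ss$p_helix < 0 | ss$p_strand < 0 | ss$p_coil < 0 |
      abs(tot - 1) > 0.01
    ss <- flag(ss, bad_ss, "ss_probs",
               "probabilities negative or not summing to 1 +/- 0.01")
  }

  out <- annotation_bundle(kinase_edges = ke, acetyl_sites = ac,
                           domain_spans = dm,
                           domain_partner_counts = bundle$domain_partner_counts,
                           rsa = rs, ss_probs = ss)
  rep_df <- if (length(report)) do.call(rbind, report) else
    data.frame(table = character(0), problem = character(0),
               n_dropped = integer(0), stringsAsFactors = FALSE)
  list(bundle = out, report = rep_df, ok = nrow(rep_df) == 0L)
}

#' Read annotation tables from a fixture directory
#'
#' Expects the flat TSV layout written by [simulate_fixture()]:
#' \code{kinase_edges.tsv}, \code{acetyl.tsv}, \code{domains.tsv},
#' \code{partners.tsv}, \code{rsa.tsv}, \code{ss.tsv}. Missing files yield
#' empty tables.
#'
#' @param dir directory containing the annotation TSVs.
#' @return an [annotation_bundle()].
#' @export
read_annotation_bundle <- function(dir) {
  rd <- function(name, empty) {
    p <- file.path(dir, name)
    if (file.exists(p)) read_tsv_table(p) else empty
  }
  annotation_bundle(
    kinase_edges = rd("kinase_edges.tsv", empty_df("kinase_family", "site_id")),
    acetyl_sites = rd("acetyl.tsv", empty_df("accession", "position")),
    domain_spans = rd("domains.tsv", empty_df("accession", "start", "end", "domain_id")),
    domain_partner_counts = rd("partners.tsv", empty_df("domain_id", "n_partners")),
    rsa = rd("rsa.tsv", empty_df("site_id", "rsa")),
    ss_probs = rd("ss.tsv", empty_df("site_id", "p_helix", "p_strand", "p_coil"))
  )
}

#' Write an annotation bundle to a directory
#'
#' @param bundle an [annotation_bundle()].
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
write_annotation_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_table(bundle$kinase_edges, file.path(dir, "kinase_edges.tsv"))
  write_tsv_table(bundle$acetyl_sites, file.path(dir, "acetyl.tsv"))
  write_tsv_table(bundle$domain_spans, file.path(dir, "domains.tsv"))
  write_tsv_table(bundle$domain_partner_counts, file.path(dir, "partners.tsv"))
  write_tsv_table(bundle$rsa, file.path(dir, "rsa.tsv"))
  write_tsv_table(bundle$ss_probs, file.path(dir, "ss.tsv"))
  invisible(dir)
}
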