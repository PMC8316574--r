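## Encoding of the six functional-site features into the model's
## feature table. Columns, in fixed order:
##   ukf_count  - number of distinct upstream kinase families (feature i)
##   rcs        - residue conservation score (feature ii)
##   idm_count  - interacting domains/motifs of containing domains (iii)
##   asc        - acetylation co-occurrence flag within +/-15 aa (iv)
##   rsa        - predicted relative surface accessibility (v)
##   ss_helix, ss_strand, ss_coil - secondary structure probabilities (vi)

FEATURE_COLUMNS <- c("ukf_count", "rcs", "idm_count", "asc", "rsa",
                     "ss_helix", "ss_strand", "ss_coil")

#' Count distinct upstream kinase families for a site
#'
#' Kinase-site edges are consumed at family granularity; duplicate edges
#' and multiple kinases of one family count once (set semantics).
#'
#' @param kinase_edges data.frame (\code{kinase_family}, \code{site_id}).
#' @param site_id site identifier.
#' @return non-negative integer count.
#' @export
count_upstream_kinase_families <- function(kinase_edges, site_id) {
  length(unique(kinase_edges$kinase_family[kinase_edges$site_id == site_id]))
}

#' Count interacting domains/motifs for a site
#'
#' Sums the interaction-partner counts of every domain whose span contains
#' the site's position (overlapping domains each contribute, or the
#' maximum is taken with \code{overlap = "max"}). A site inside no domain
#' scores 0.
#'
#' @param domain_spans data.frame (\code{accession}, \code{start},
#'   \code{end}, \code{domain_id}); spans 1-based inclusive.
#' @param domain_partner_counts data.frame (\code{domain_id},
#'   \code{n_partners}).
#' @param accession,position the site's protein and residue position.
#' @param overlap how to combine counts across overlapping containing
#'   domains: \code{"sum"} (default) or \code{"max"}.
#' @return non-negative integer count.
#' @export
count_interacting_domains_motifs <- function(domain_spans,
                                             domain_partner_counts,
                                             accession, position,
                                             overlap = c("sum", "max")) {
  overlap <- match.arg(overlap)
  hit <- domain_spans$accession == accession &
    domain_spans$start <= position & position <= domain_spans$end
  doms <- unique(domain_spans$domain_id[hit])
  if (length(doms) == 0L) return(0L)
  counts <- domain_partner_counts$n_partners[
    match(doms, domain_partner_counts$domain_id)]
  counts[is.na(counts)] <- 0L
  as.integer(if (overlap == "sum") sum(counts) else max(counts))
}

#' Acetylation co-occurrence flag
#'
#' 1 if any predicted acetylation site on the same protein lies within
#' \code{window} residues of the phosphosite (inclusive on both ends,
#' i.e. the [-15, +15] window by default), else 0.
#'
#' @param acetyl_sites data.frame (\code{accession}, \code{position}).
#' @param accession,position the phosphosite's protein and position.
#' @param window half-width of the co-occurrence window (default 15).
#' @return 0 or 1.
#' @export
acetylation_cooccurrence_flag <- function(acetyl_sites, accession, position,
                                          window = 15L) {
  same <- acetyl_sites$accession == accession
  as.integer(any(abs(acetyl_sites$position[same] - position) <= window))
}

#' Assemble the feature table for a set of phosphosites
#'
#' Encodes all six features into one row per site, eight numeric columns
#' in fixed order. Conservation scores arrive precomputed (see
#' [score_conservation_table()]); RSA and secondary-structure values come
#' from the annotation bundle. Sites missing an RSA or SS annotation are
#' either an error (\code{missing_policy = "error"}) or imputed as zero
#' with the imputation count reported (\code{"impute-zero"}; the SS
#' triple is imputed as all-zero and exempted from the sum-to-one check).
#'
#' @param sites data.frame (\code{accession}, \code{position},
#'   \code{residue}, \code{site_id}).
#' @param bundle an [annotation_bundle()].
#' @param conservation data.frame (\code{site_id}, \code{RCS}), typically
#'   from [score_conservation_table()]; missing sites fall under the
#'   missing policy.
#' @param missing_policy \code{"error"} or \code{"impute-zero"}.
#' @param overlap passed to [count_interacting_domains_motifs()].
#' @return data.frame: \code{site_id} plus the eight feature columns;
#'   attribute \code{n_imputed} counts imputed cells.
#' @export
assemble_feature_table <- function(sites, bundle, conservation,
                                   missing_policy = c("error", "impute-zero"),
                                   overlap = "sum") {
  missing_policy <- match.arg(missing_policy)
  n_imputed <- 0L
  lookup <- function(values, ids, site_id, what) {
    i <- match(site_id, ids)
    if (is.na(i)) {
      if (missing_policy == "error") {
        stop("site ", site_id, " has no ", what, " annotation",
             call. = FALSE)
      }
      n_imputed <<- n_imputed + 1L
      return(NA_real_)
    }
    values[i]
  }
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    sid <- sites$site_id[i]
    rcs <- lookup(conservation$RCS, conservation$site_id, sid,
                  "conservation")
    rsa <- lookup(bundle$rsa$rsa, bundle$rsa$site_id, sid, "rsa")
    ssi <- match(sid, bundle$ss_probs$site_id)
    if (is.na(ssi) && missing_policy == "error") {
      stop("site ", sid, " has no secondary-structure annotation",
           call. = FALSE)
    }
    if (is.na(ssi)) n_imputed <<- n_imputed + 1L
    data.frame(
      site_id = sid,
      ukf_count = count_upstream_kinase_families(bundle$kinase_edges, sid),
      rcs = if (is.na(rcs)) 0 else rcs,
      idm_count = count_interacting_domains_motifs(
        bundle$domain_spans, bundle$domain_partner_counts,
        sites$accession[i], sites$position[i], overlap),
      asc = acetylation_cooccurrence_flag(bundle$acetyl_sites,
                                          sites$accession[i],
                                          sites$position[i]),
      rsa = if (is.na(rsa)) 0 else rsa,
      ss_helix = if (is.na(ssi)) 0 else bundle$ss_probs$p_helix[ssi],
      ss_strand = if (is.na(ssi)) 0 else bundle$ss_probs$p_strand[ssi],
      ss_coil = if (is.na(ssi)) 0 else bundle$ss_probs$p_coil[ssi],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_imputed = n_imputed)
}
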