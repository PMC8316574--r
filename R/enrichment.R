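## Enrichment statistics: one-sided hypergeometric E-ratio tests for
## kinase substrates and pathways, and a Z-test for per-gene score sets.

#' One-sided hypergeometric enrichment test
#'
#' For a background of \code{N} items of which \code{n} are annotated to
#' the unit, and a regulated set of \code{M} items of which \code{m} are
#' annotated: the enrichment ratio is E = (m/M) / (n/N) and the p-value
#' is the upper hypergeometric tail
#' \eqn{p = \sum_{m'=m}^{\min(n,M)} C(M,m') C(N-M,n-m') / C(N,n)}.
#' (The tail's upper limit is min(n, M); terms beyond are zero.)
#'
#' @param N background size (> 0).
#' @param n background items annotated to the unit (0 < n <= N).
#' @param M regulated set size (0 < M <= N).
#' @param m regulated items annotated to the unit (0 <= m <= min(n, M)).
#' @return list: \code{N}, \code{n}, \code{M}, \code{m}, \code{e_ratio},
#'   \code{p}.
#' @export
#' @examples
#' hypergeom_enrichment(N = 10, n = 4, M = 5, m = 4)  # E = 2, p = 5/210
hypergeom_enrichment <- function(N, n, M, m) {
  if (!(M > 0 && n > 0 && n <= N && M <= N && m >= 0 && m <= min(n, M))) {
    stop("invalid enrichment counts: require 0 <= m <= min(n, M), ",
         "0 < n <= N, 0 < M <= N", call. = FALSE)
  }
  e_ratio <- (m / M) / (n / N)
  ## upper tail P(X >= m), X ~ Hypergeometric(N, M, n)
  p <- phyper(m - 1, M, N - M, n, lower.tail = FALSE)
  list(N = N, n = n, M = M, m = m, e_ratio = e_ratio, p = min(1, p))
}

## Shared engine for kinase/pathway enrichment over item -> unit edges.
enrich_units <- function(background, regulated, edges, unit_col, item_col,
                         alpha = 0.05, direction = NA_character_,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  bad <- setdiff(regulated, background)
  if (length(bad)) {
    stop("regulated items absent from background: ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  edges <- edges[edges[[item_col]] %in% background, , drop = FALSE]
  edges <- unique(edges[, c(unit_col, item_col)])
  N <- length(background)
  M <- length(regulated)
  units <- sort(unique(edges[[unit_col]]))
  rows <- lapply(units, function(u) {
    targets <- edges[[item_col]][edges[[unit_col]] == u]
    n <- length(targets)
    m <- length(intersect(targets, regulated))
    if (M == 0L) {
      return(data.frame(unit_id = u, direction = direction, N = N, n = n,
                        M = M, m = m, e_ratio = NA_real_, p = 1,
                        stringsAsFactors = FALSE))
    }
    h <- hypergeom_enrichment(N, n, M, m)
    data.frame(unit_id = u, direction = direction, N = N, n = n, M = M,
               m = m, e_ratio = h$e_ratio, p = h$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  ## significance rule: raw p < alpha and E-ratio > 1 (no multiplicity
  ## correction by default; BH available behind `adjust`)
  p_used <- if (adjust == "BH") out$p_adj else out$p
  out$significant <- !is.na(out$e_ratio) & out$e_ratio > 1 & p_used < alpha
  out <- out[order(out$p, -ifelse(is.na(out$e_ratio), 0, out$e_ratio)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kinase-substrate enrichment among regulated phosphosites
#'
#' One hypergeometric test per kinase (family) per regulation direction:
#' is the kinase's predicted substrate set over-represented among the
#' hyper- or hypo-phosphorylated sites relative to all identified
#' phosphosites? A kinase is flagged significant when p < alpha and
#' E-ratio > 1.
#'
#' @param all_sites character vector of background site ids (all
#'   identified phosphosites).
#' @param regulated data.frame (\code{site_id}, \code{direction}) with
#'   directions \code{"hyper"} / \code{"hypo"}.
#' @param kinase_edges data.frame (\code{kinase_family}, \code{site_id}).
#' @param alpha significance level (default 0.05).
#' @param adjust \code{"none"} (default, raw p rule) or \code{"BH"}.
#' @return data.frame of enrichment results, one row per kinase and
#'   direction: unit_id, direction, N, n, M, m, e_ratio, p, p_adj,
#'   significant.
#' @export
enrich_kinases <- function(all_sites, regulated, kinase_edges,
                           alpha = 0.05, adjust = "none") {
  out <- lapply(c("hyper", "hypo"), function(dir) {
    reg <- unique(regulated$site_id[regulated$direction == dir])
    enrich_units(all_sites, reg, kinase_edges,
                 unit_col = "kinase_family", item_col = "site_id",
                 alpha = alpha, direction = dir, adjust = adjust)
  })
  do.call(rbind, out)
}

#' Pathway enrichment among regulated genes
#'
#' Hypergeometric test per pathway of the regulated gene set against the
#' background gene universe; significant when p < alpha and E-ratio > 1.
#'
#' @param background_genes character vector of background gene ids.
#' @param regulated_genes character vector (subset of background).
#' @param gene_pathways data.frame (\code{pathway_id}, \code{gene_id}).
#' @param alpha significance level.
#' @param adjust \code{"none"} or \code{"BH"}.
#' @return data.frame as in [enrich_kinases()] (direction is NA).
#' @export
enrich_pathways <- function(background_genes, regulated_genes,
                            gene_pathways, alpha = 0.05, adjust = "none") {
  enrich_units(background_genes, unique(regulated_genes), gene_pathways,
               unit_col = "pathway_id", item_col = "gene_id",
               alpha = alpha, adjust = adjust)
}

#' Two-tailed Z-test for a score set against a population
#'
#' Tests whether the mean score of a category's items deviates from the
#' population mean, with the population standard deviation taken as
#' known: Z = (mean_items - mean_pop) / (sd_pop / sqrt(n)),
#' p = 2 * (1 - Phi(|Z|)). Used, e.g., for per-tissue expression-score
#' sets of regulated phosphoproteins against all genes.
#'
#' @param item_scores numeric scores of the category's items (n >= 1).
#' @param pop_mean,pop_sd population mean and standard deviation
#'   (sd > 0).
#' @return list: \code{z}, \code{p}, \code{n}, \code{mean}.
#' @export
score_set_ztest <- function(item_scores, pop_mean, pop_sd) {
  if (length(item_scores) < 1L) stop("empty score set", call. = FALSE)
  if (!is.finite(pop_sd) || pop_sd <= 0) {
    stop("population sd must be positive", call. = FALSE)
  }
  n <- length(item_scores)
  z <- (mean(item_scores) - pop_mean) / (pop_sd / sqrt(n))
  list(z = z, p = 2 * pnorm(-abs(z)), n = n, mean = mean(item_scores))
}
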