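## Differential phosphorylation calling from replicate 14N/15N ratios.
##
## The caller compares a test genotype against a control using the robust
## flexible filter: the spread of log2 fold changes across all eligible
## phosphoisoforms is summarized by the normalized interquartile range
## (NIQ = 0.7413 * IQ, a robust standard-deviation estimate), and an
## isoform is called regulated if its log2 fold change leaves the
## median +/- 1.5*NIQ band with one-tailed Wilcoxon p < alpha, or the
## median +/- NIQ band with two-tailed p < alpha.

#' Normalize raw ratios within one technical replicate
#'
#' Each technical replicate's ratio vector is divided by its own median, so
#' the per-replicate median becomes 1. This removes the systematic mixing
#' offset of the light/heavy channels within a run.
#'
#' @param ratios numeric vector of raw light/heavy ratios, all > 0.
#' @return normalized vector of the same length.
#' @export
#' @examples
#' normalize_replicate_ratios(c(1, 2, 3))
normalize_replicate_ratios <- function(ratios) {
  if (length(ratios) == 0L) stop("empty ratio vector", call. = FALSE)
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop("all ratios must be finite and > 0", call. = FALSE)
  }
  ratios / median(ratios)
}

#' Median-normalize a long quantitation table per technical replicate
#'
#' @param quant long-format data.frame with columns \code{isoform_id},
#'   \code{genotype}, \code{replicate}, \code{ratio}.
#' @return the table with \code{ratio} normalized within each
#'   (genotype, replicate) run.
#' @export
normalize_quant_table <- function(quant) {
  stopifnot(all(c("isoform_id", "genotype", "replicate", "ratio") %in%
                  names(quant)))
  key <- paste(quant$genotype, quant$replicate, sep = "\r")
  quant$ratio <- unsplit(lapply(split(quant$ratio, key),
                                normalize_replicate_ratios), key)
  quant
}

#' Assemble the control ratio vector for one isoform
#'
#' If the control genotype has at least \code{min_primary} confident
#' quantitations, those form the control ("control-1"). If it has fewer
#' (including none), the control genotype's measurements are pooled with
#' the auxiliary genotypes' ("control-2"). An isoform whose merged control
#' is empty is signalled by tier \code{"excluded"} rather than silently
#' dropped.
#'
#' @param ratios named list: genotype -> numeric vector of normalized
#'   ratios for this isoform.
#' @param control_genotype primary control label (e.g. \code{"WT"}).
#' @param auxiliary_genotypes genotypes pooled into control-2.
#' @param min_primary minimum control measurements for control-1
#'   (default 3, i.e. "more than two").
#' @return list with \code{control} (numeric vector) and \code{tier}
#'   (one of \code{"control-1"}, \code{"control-2"}, \code{"excluded"}).
#' @export
build_control <- function(ratios, control_genotype,
                          auxiliary_genotypes = character(0),
                          min_primary = 3L) {
  primary <- ratios[[control_genotype]] %||% numeric(0)
  if (length(primary) >= min_primary) {
    return(list(control = primary, tier = "control-1"))
  }
  aux <- unlist(ratios[intersect(auxiliary_genotypes, names(ratios))],
                use.names = FALSE)
  merged <- c(primary, aux)
  if (length(merged) == 0L) {
    return(list(control = numeric(0), tier = "excluded"))
  }
  list(control = merged, tier = "control-2")
}

#' Robust spread statistics of a log2 fold-change distribution
#'
#' Quartiles use linear interpolation between order statistics; the
#' normalized interquartile range NIQ = 0.7413 * (Q3 - Q1) estimates the
#' standard deviation robustly (0.7413 is approximately 1 / (2 * z[0.75])).
#'
#' @param log2fc numeric vector of log2 fold changes, length >= 4.
#' @return list of class \code{spread_stats}: \code{median}, \code{Q1},
#'   \code{Q3}, \code{IQ}, \code{NIQ}.
#' @export
#' @examples
#' robust_spread(c(1, 2, 3, 4, 5))  # NIQ = 1.4826
robust_spread <- function(log2fc) {
  log2fc <- log2fc[is.finite(log2fc)]
  if (length(log2fc) < 4L) {
    stop("need at least 4 finite log2 fold changes", call. = FALSE)
  }
  q <- quartiles(log2fc)
  iq <- q$Q3 - q$Q1
  structure(list(median = median(log2fc), Q1 = q$Q1, Q3 = q$Q3,
                 IQ = iq, NIQ = 0.7413 * iq),
            class = "spread_stats")
}

#' Wilcoxon rank-sum test
#'
#' Exact p-value from the null rank-sum distribution when the combined
#' sample is small (at most \code{exact_threshold} observations) and free
#' of ties; otherwise the normal approximation with tie correction and
#' continuity correction. Ties always force the corrected approximation,
#' so results are deterministic and well defined at every sample size.
#'
#' @param x,y numeric samples, each non-empty.
#' @param alternative \code{"two.sided"}, \code{"greater"} (x shifted
#'   above y) or \code{"less"}.
#' @param exact_threshold maximum combined sample size for the exact
#'   branch (default 20).
#' @return the p-value.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4), "less")  # 1/6
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater", "less"),
                              exact_threshold = 20L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  ## Mann-Whitney U for x: number of (x_i, y_j) pairs with x_i > y_j
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && (nx + ny) <= exact_threshold) {
    p <- switch(alternative,
      greater = pwilcox(W - 1, nx, ny, lower.tail = FALSE),
      less = pwilcox(W, nx, ny),
      two.sided = {
        if (W > nx * ny / 2) {
          min(1, 2 * pwilcox(W - 1, nx, ny, lower.tail = FALSE))
        } else if (W < nx * ny / 2) {
          min(1, 2 * pwilcox(W, nx, ny))
        } else 1
      })
    return(p)
  }
  ## normal approximation with tie and continuity corrections
  n <- nx + ny
  mu <- nx * ny / 2
  tie_tab <- table(r)
  sigma2 <- (nx * ny / 12) *
    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- W - mu
  cc <- switch(alternative,
               two.sided = sign(z) * 0.5,
               greater = 0.5,
               less = -0.5)
  z <- (z - cc) / sqrt(sigma2)
  switch(alternative,
         two.sided = min(1, 2 * pnorm(-abs(z))),
         greater = pnorm(z, lower.tail = FALSE),
         less = pnorm(z))
}

#' Apply the flexible regulation filter to one isoform
#'
#' An isoform is called hyper-phosphorylated when its log2 fold change
#' exceeds the spread median by more than 1.5 * NIQ with one-tailed
#' Wilcoxon p < alpha, or by more than NIQ with two-tailed p < alpha;
#' symmetrically for hypo-phosphorylation below the median. Either tier
#' suffices.
#'
#' @param log2fc the isoform's log2(median test / median control).
#' @param p_one_sided one-tailed Wilcoxon p-value in the direction of
#'   the observed shift.
#' @param p_two_sided two-tailed Wilcoxon p-value.
#' @param spread a [robust_spread()] result for the cohort.
#' @param alpha significance level (default 0.05).
#' @return direction string: \code{"hyper"}, \code{"hypo"} or \code{"none"}.
#' @export
call_regulated <- function(log2fc, p_one_sided, p_two_sided, spread,
                           alpha = 0.05) {
  stopifnot(inherits(spread, "spread_stats"))
  dev <- log2fc - spread$median
  tier1 <- abs(dev) > 1.5 * spread$NIQ && p_one_sided < alpha
  tier2 <- abs(dev) > spread$NIQ && p_two_sided < alpha
  if (tier1 || tier2) {
    if (dev > 0) "hyper" else "hypo"
  } else "none"
}

#' Call differentially phosphorylated isoforms
#'
#' Runs the full differential workflow on a long-format quantitation
#' table: isoforms quantified at least \code{min_quant} times in the test
#' genotype are compared against the control assembled by
#' [build_control()]; the cohort's log2 fold-change spread is summarized
#' by [robust_spread()]; each isoform gets Wilcoxon p-values and a
#' direction from [call_regulated()].
#'
#' @param quant long-format data.frame: \code{isoform_id},
#'   \code{genotype}, \code{replicate}, \code{ratio} (normalized).
#' @param test_genotype label of the test genotype.
#' @param control_genotype label of the primary control genotype.
#' @param auxiliary_genotypes genotypes merged into control-2 when the
#'   primary control is sparse.
#' @param min_quant minimum test-genotype quantitations (default 3).
#' @param alpha significance level for the flexible filter.
#' @return list with \code{calls} (data.frame: isoform_id, n_test,
#'   n_control, control_tier, log2fc, p_two_sided, p_one_sided,
#'   direction), \code{spread} (the [robust_spread()] statistics) and
#'   \code{excluded} (isoform ids with no usable control).
#' @export
call_differential <- function(quant, test_genotype, control_genotype,
                              auxiliary_genotypes = character(0),
                              min_quant = 3L, alpha = 0.05) {
  stopifnot(all(c("isoform_id", "genotype", "replicate", "ratio") %in%
                  names(quant)))
  by_iso <- split(quant, quant$isoform_id)
  rows <- list(); excluded <- character(0)
  for (iso in names(by_iso)) {
    d <- by_iso[[iso]]
    ratios <- split(d$ratio, d$genotype)
    test <- ratios[[test_genotype]] %||% numeric(0)
    if (length(test) < min_quant) next
    ctl <- build_control(ratios, control_genotype, auxiliary_genotypes)
    if (ctl$tier == "excluded") {
      excluded <- c(excluded, iso)
      next
    }
    log2fc <- log2(median(test) / median(ctl$control))
    rows[[iso]] <- data.frame(
      isoform_id = iso,
      n_test = length(test),
      n_control = length(ctl$control),
      control_tier = ctl$tier,
      log2fc = log2fc,
      p_two_sided = wilcoxon_rank_sum(test, ctl$control, "two.sided"),
      p_greater = wilcoxon_rank_sum(test, ctl$control, "greater"),
      p_less = wilcoxon_rank_sum(test, ctl$control, "less"),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    stop("no isoform passed the minimum quantitation filter", call. = FALSE)
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  spread <- robust_spread(calls$log2fc)
  dev <- calls$log2fc - spread$median
  calls$p_one_sided <- ifelse(dev > 0, calls$p_greater, calls$p_less)
  calls$direction <- vapply(seq_len(nrow(calls)), function(i) {
    call_regulated(calls$log2fc[i], calls$p_one_sided[i],
                   calls$p_two_sided[i], spread, alpha)
  }, character(1))
  calls$p_greater <- NULL
  calls$p_less <- NULL
  list(calls = calls, spread = spread, excluded = excluded)
}

#' Expand isoform-level regulation calls to phosphosites
#'
#' A site is regulated if any isoform containing it is regulated. A site
#' that is hyper-phosphorylated in one isoform and hypo-phosphorylated in
#' another is reported with both directions and a warning.
#'
#' @param calls the \code{calls} data.frame from [call_differential()].
#' @param isoform_sites data.frame mapping \code{isoform_id} to
#'   \code{site_id} (one row per isoform-site pair).
#' @return data.frame: \code{site_id}, \code{direction}, one row per
#'   site-direction combination with direction != "none".
#' @export
expand_regulated_sites <- function(calls, isoform_sites) {
  reg <- calls[calls$direction != "none", c("isoform_id", "direction")]
  m <- merge(reg, isoform_sites, by = "isoform_id")
  out <- unique(m[, c("site_id", "direction")])
  out <- out[order(out$site_id, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  conflicted <- out$site_id[duplicated(out$site_id)]
  if (length(conflicted)) {
    warning("sites regulated in opposite directions across isoforms: ",
            paste(unique(conflicted), collapse = ", "), call. = FALSE)
  }
  out
}
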