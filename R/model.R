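## Functional-site scorer: benchmark construction, ridge-stabilized
## logistic regression, stratified cross-validation, AUC with stratified
## bootstrap confidence intervals, fence-based score normalization, and
## top-fraction prioritization.

#' Build benchmark sets by negative sampling
#'
#' The positive class is fixed; each benchmark set draws
#' \code{ratio * n_positives} negatives from the negative pool without
#' replacement, independently per set, reproducibly from the seed.
#'
#' @param positives character vector of positive site ids.
#' @param negative_pool character vector of candidate negative site ids
#'   (disjoint from positives).
#' @param ratio negatives per positive (e.g. 1, 2, 5 or 10).
#' @param n_sets number of benchmark sets (default 10).
#' @param seed integer seed.
#' @return list of \code{n_sets} lists, each with \code{positives},
#'   \code{negatives}, \code{ratio}, \code{set_index}.
#' @export
build_benchmarks <- function(positives, negative_pool, ratio,
                             n_sets = 10L, seed) {
  if (length(intersect(positives, negative_pool))) {
    stop("positives and negative pool overlap", call. = FALSE)
  }
  n_neg <- ratio * length(positives)
  if (length(negative_pool) < n_neg) {
    stop("negative pool too small: need ", n_neg, ", have ",
         length(negative_pool), call. = FALSE)
  }
  with_seed(seed, lapply(seq_len(n_sets), function(i) {
    list(positives = positives,
         negatives = sample(negative_pool, n_neg, replace = FALSE),
         ratio = ratio, set_index = i)
  }))
}

#' Fit a binary logistic regression with a ridge penalty
#'
#' Newton (iteratively reweighted least squares) fit of
#' \eqn{P(y=1|x) = logit^{-1}(b + w'x)} with an L2 penalty
#' \code{l2 * ||w||^2 / 2} on the slopes only (the intercept is
#' unpenalized, so an intercept-only fit returns exactly
#' \code{log(n1/n0)}). The small default ridge keeps weights finite on
#' separable data without materially biasing estimates; the fit is
#' deterministic given its inputs. Features are used raw, with no
#' scaling, so coefficients are comparable across runs.
#'
#' @param features numeric matrix or data.frame of covariates (no
#'   missing values).
#' @param labels 0/1 vector (or logical), both classes present.
#' @param l2 ridge penalty (default 1e-8).
#' @param max_iter,tol Newton iteration controls.
#' @return list of class \code{trained_model}: \code{weights} (named),
#'   \code{intercept}, \code{converged}, \code{n_iter}, \code{meta}.
#' @export
fit_logistic <- function(features, labels, l2 = 1e-8,
                         max_iter = 100L, tol = 1e-10) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  if (anyNA(X)) stop("features contain missing values", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  Xd <- cbind(`(intercept)` = 1, X)
  pen <- c(0, rep(l2, p))  # intercept unpenalized
  beta <- c(log(mean(y) / (1 - mean(y))), rep(0, p))
  dev_old <- Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)) +
      sum(pen * beta^2)
    g <- drop(crossprod(Xd, y - mu)) - pen * beta
    W <- mu * (1 - mu)
    H <- crossprod(Xd * W, Xd) + diag(pen, p + 1L)
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-10, p + 1L), g)
    })
    beta_new <- beta + step
    if (abs(dev_old - dev) < tol * (abs(dev) + 1)) {
      converged <- TRUE
      break
    }
    beta <- beta_new
    dev_old <- dev
  }
  structure(list(weights = setNames(beta[-1L], colnames(X)),
                 intercept = beta[[1L]],
                 converged = converged, n_iter = it,
                 meta = list(l2 = l2, n = n)),
            class = "trained_model")
}

#' Raw model score (linear predictor) for a feature table
#'
#' @param model a \code{trained_model}.
#' @param features matrix/data.frame with the model's feature columns.
#' @return numeric vector of raw scores (log-odds scale).
#' @export
predict_raw_score <- function(model, features) {
  X <- as.matrix(features[, names(model$weights), drop = FALSE])
  drop(X %*% model$weights) + model$intercept
}

#' Area under the ROC curve
#'
#' Rank statistic: AUC = P(score+ > score-) + P(tie)/2, via the
#' Mann-Whitney identity on mid-ranks.
#'
#' @param scores numeric scores.
#' @param labels 0/1 or logical class labels; both classes present.
#' @return AUC in [0, 1].
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity from confusion counts
#'
#' Sn = TP / (TP + FN); Sp = TN / (TN + FP).
#'
#' @param TP,FP,TN,FN non-negative confusion counts; TP + FN > 0 and
#'   TN + FP > 0.
#' @return named numeric vector \code{c(Sn, Sp)}.
#' @export
sensitivity_specificity <- function(TP, FP, TN, FN) {
  if (TP + FN <= 0 || TN + FP <= 0) {
    stop("undefined: a class has no members", call. = FALSE)
  }
  c(Sn = TP / (TP + FN), Sp = TN / (TN + FP))
}

## Stratified fold assignment: within each class, a random permutation is
## dealt round-robin into k folds.
stratified_folds <- function(labels, k, seed) {
  y <- as.logical(labels)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- which(y == cls)
      if (length(idx) < k) {
        stop("class with ", length(idx),
             " members cannot be split into ", k, " folds", call. = FALSE)
      }
      fold[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the logistic scorer
#'
#' Folds are stratified by class; every sample is scored exactly once by
#' the model trained on the other folds; the cross-validated AUC is
#' computed on the pooled out-of-fold scores. Per-threshold sensitivity
#' and specificity are reported at every distinct score cut.
#'
#' @param features matrix/data.frame of covariates.
#' @param labels 0/1 labels; each class count >= \code{k}.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param l2 ridge penalty, passed to [fit_logistic()].
#' @return list: \code{scores} (pooled out-of-fold raw scores),
#'   \code{labels}, \code{fold}, \code{auc}, \code{roc} (data.frame:
#'   threshold, Sn, Sp).
#' @export
cross_validate <- function(features, labels, k = 10L, seed, l2 = 1e-8) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  fold <- stratified_folds(y, k, seed)
  scores <- numeric(length(y))
  for (f in seq_len(k)) {
    train <- fold != f
    m <- fit_logistic(X[train, , drop = FALSE], y[train], l2 = l2)
    scores[!train] <- predict_raw_score(m, X[!train, , drop = FALSE])
  }
  ## ROC by cumulative counts over descending score (one point per
  ## distinct threshold; predict positive when score >= threshold)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys == 1); fp <- cumsum(ys == 0)
  last <- !duplicated(ss, fromLast = TRUE)
  roc <- data.frame(threshold = ss[last],
                    Sn = tp[last] / sum(y == 1),
                    Sp = 1 - fp[last] / sum(y == 0))
  list(scores = scores, labels = y, fold = fold,
       auc = roc_auc(scores, y), roc = roc)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples scores with replacement within each class (so both classes
#' are present in every replicate) and returns the percentile interval of
#' the bootstrap AUC distribution.
#'
#' @param scores,labels as in [roc_auc()]; each class >= 2 members.
#' @param B bootstrap replicates (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return named numeric vector \code{c(lower, upper)}.
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 10000L, level = 0.95,
                             seed) {
  y <- as.logical(labels)
  pos <- scores[y]; neg <- scores[!y]
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("need at least 2 members per class", call. = FALSE)
  }
  aucs <- with_seed(seed, vapply(seq_len(B), function(b) {
    sp <- pos[sample.int(length(pos), replace = TRUE)]
    sn <- neg[sample.int(length(neg), replace = TRUE)]
    roc_auc(c(sp, sn), c(rep(1, length(sp)), rep(0, length(sn))))
  }, numeric(1)))
  alpha <- 1 - level
  q <- quantile(aucs, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  c(lower = q[[1L]], upper = q[[2L]])
}

#' Select the final model across benchmark sets
#'
#' Cross-validates the scorer on every benchmark set and refits on the
#' full benchmark whose cross-validated AUC is highest; ties break to the
#' lowest set index (with a warning).
#'
#' @param feature_table data.frame with \code{site_id} plus feature
#'   columns (as from [assemble_feature_table()]).
#' @param benchmarks list from [build_benchmarks()].
#' @param k folds for cross-validation.
#' @param seed integer seed (one fold-assignment seed is derived per set).
#' @param l2 ridge penalty.
#' @return list: \code{model} (the refit \code{trained_model}),
#'   \code{best_index}, \code{cv_auc} (vector over sets), \code{cv}
#'   (the winning set's [cross_validate()] result).
#' @export
select_final_model <- function(feature_table, benchmarks, k = 10L, seed,
                               l2 = 1e-8) {
  if (length(benchmarks) == 0L) stop("no benchmark sets", call. = FALSE)
  feat <- feature_table[, FEATURE_COLUMNS, drop = FALSE]
  rownames(feat) <- feature_table$site_id
  cvs <- lapply(seq_along(benchmarks), function(i) {
    b <- benchmarks[[i]]
    ids <- c(b$positives, b$negatives)
    y <- c(rep(1, length(b$positives)), rep(0, length(b$negatives)))
    X <- feat[ids, , drop = FALSE]
    cross_validate(X, y, k = k, seed = derive_seed(seed, i), l2 = l2)
  })
  auc <- vapply(cvs, `[[`, numeric(1), "auc")
  best <- which.max(auc)
  if (sum(auc == auc[best]) > 1L) {
    warning("cross-validated AUC tie; selecting lowest benchmark index ",
            best, call. = FALSE)
  }
  b <- benchmarks[[best]]
  ids <- c(b$positives, b$negatives)
  y <- c(rep(1, length(b$positives)), rep(0, length(b$negatives)))
  model <- fit_logistic(feat[ids, , drop = FALSE], y, l2 = l2)
  model$meta$benchmark_index <- best
  model$meta$ratio <- b$ratio
  list(model = model, best_index = best, cv_auc = auc, cv = cvs[[best]])
}

#' Fit the fence-based score normalizer
#'
#' From the raw score distribution: quartiles Q1/Q3 and IQ = Q3 - Q1;
#' lower fence Q1 - 3*IQ and upper fence Q3 + 3*IQ; S_min and S_max are
#' the extreme raw scores lying within the fences. Scores above the upper
#' fence normalize to 1, below the lower fence to 0, and in between to
#' (S - S_min) / (S_max - S_min).
#'
#' @param raw_scores numeric vector, length >= 4.
#' @return list of class \code{score_normalizer}: \code{Q1}, \code{Q3},
#'   \code{IQ}, \code{lower_fence}, \code{upper_fence}, \code{S_min},
#'   \code{S_max}, \code{degenerate}.
#' @export
fit_normalizer <- function(raw_scores) {
  raw_scores <- raw_scores[is.finite(raw_scores)]
  if (length(raw_scores) < 4L) {
    stop("need at least 4 raw scores", call. = FALSE)
  }
  q <- quartiles(raw_scores)
  iq <- q$Q3 - q$Q1
  lf <- q$Q1 - 3 * iq
  uf <- q$Q3 + 3 * iq
  inside <- raw_scores[raw_scores >= lf & raw_scores <= uf]
  degenerate <- length(inside) == 0L || max(inside) == min(inside)
  if (degenerate) {
    warning("degenerate score distribution; in-fence scores map to 0.5",
            call. = FALSE)
  }
  structure(list(Q1 = q$Q1, Q3 = q$Q3, IQ = iq,
                 lower_fence = lf, upper_fence = uf,
                 S_min = if (length(inside)) min(inside) else NA_real_,
                 S_max = if (length(inside)) max(inside) else NA_real_,
                 degenerate = degenerate),
            class = "score_normalizer")
}

#' Normalize raw scores to [0, 1]
#'
#' @param normalizer a [fit_normalizer()] result.
#' @param scores numeric raw scores.
#' @return numeric vector in [0, 1].
#' @export
normalize_scores <- function(normalizer, scores) {
  stopifnot(inherits(normalizer, "score_normalizer"))
  out <- numeric(length(scores))
  hi <- scores > normalizer$upper_fence
  lo <- scores < normalizer$lower_fence
  mid <- !hi & !lo
  out[hi] <- 1
  out[lo] <- 0
  if (normalizer$degenerate) {
    out[mid] <- 0.5
  } else {
    out[mid] <- pmin(1, pmax(0,
      (scores[mid] - normalizer$S_min) /
        (normalizer$S_max - normalizer$S_min)))
  }
  out
}

#' Select the top-scoring fraction of sites
#'
#' Returns the smallest site set containing at least
#' \code{ceiling(fraction * n)} sites such that no excluded site outscores
#' an included one; ties at the cut are all included.
#'
#' @param scores named numeric vector (names = site ids) or a data.frame
#'   with \code{site_id} and \code{score}.
#' @param fraction fraction of sites to keep, in (0, 1] (default 0.05).
#' @return character vector of prioritized site ids, highest score first.
#' @export
prioritize_top_fraction <- function(scores, fraction = 0.05) {
  if (is.data.frame(scores)) {
    scores <- setNames(scores$score, scores$site_id)
  }
  if (length(scores) == 0L) stop("empty score vector", call. = FALSE)
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  n_keep <- ceiling(fraction * length(scores))
  ord <- order(scores, decreasing = TRUE)
  cutoff <- scores[ord[n_keep]]
  keep <- ord[scores[ord] >= cutoff]
  names(scores)[keep]
}

#' Intersect prioritized and regulated sites
#'
#' The terminal prioritization step: sites that are both in the
#' top-scoring fraction and differentially regulated, with direction and
#' normalized score attached.
#'
#' @param prioritized character vector of top-fraction site ids.
#' @param regulated data.frame (\code{site_id}, \code{direction}) from
#'   [expand_regulated_sites()].
#' @param scores optional named numeric vector of normalized scores.
#' @return data.frame: \code{site_id}, \code{direction}, \code{score},
#'   sorted by decreasing score then site id.
#' @export
intersect_lirp <- function(prioritized, regulated, scores = NULL) {
  hit <- regulated[regulated$site_id %in% prioritized, , drop = FALSE]
  hit$score <- if (is.null(scores)) rep(NA_real_, nrow(hit)) else
    unname(scores[hit$site_id])
  hit <- hit[order(-ifelse(is.na(hit$score), -Inf, hit$score),
                   hit$site_id), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}
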