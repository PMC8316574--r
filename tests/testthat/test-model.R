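test_that("benchmark sets sample negatives reproducibly at the ratio", {
  pos <- sprintf("p%03d", 1:121)
  pool <- sprintf("n%05d", 1:3000)
  b <- build_benchmarks(pos, pool, ratio = 5, n_sets = 10, seed = 1)
  expect_length(b, 10L)
  for (s in b) {
    expect_length(s$negatives, 605L)
    expect_length(unique(s$negatives), 605L)
    expect_identical(s$positives, pos)
  }
  b2 <- build_benchmarks(pos, pool, ratio = 5, n_sets = 10, seed = 1)
  expect_identical(b, b2)
  expect_error(build_benchmarks(pos, pool[1:100], ratio = 5, seed = 1),
               "pool too small")
  expect_error(build_benchmarks(pos, c(pos[1], pool), 1, seed = 1),
               "overlap")
})

test_that("logistic fit recovers the intercept-only closed form", {
  y <- c(rep(1, 121), rep(0, 605))
  f <- fit_logistic(matrix(1, length(y), 1,
                           dimnames = list(NULL, "const")), y)
  expect_equal(f$intercept, log(121 / 605), tolerance = 0.01)
  expect_lt(abs(f$weights[["const"]]), 1e-6)
})

test_that("logistic fit matches glm on well-conditioned data", {
  set.seed(5)
  X <- cbind(a = rnorm(400), b = rnorm(400))
  y <- rbinom(400, 1, plogis(0.5 + X %*% c(1, -0.5)))
  f <- fit_logistic(X, y, l2 = 0)
  g <- glm(y ~ X, family = binomial)
  expect_equal(unname(f$intercept), unname(coef(g)[1]), tolerance = 1e-6)
  expect_equal(unname(f$weights), unname(coef(g)[-1]), tolerance = 1e-6)
})

test_that("ridge keeps separable fits finite and deterministic", {
  X <- matrix(c(-2, -1, 1, 2), ncol = 1, dimnames = list(NULL, "x"))
  y <- c(0, 0, 1, 1)
  f <- fit_logistic(X, y)
  expect_true(all(is.finite(c(f$weights, f$intercept))))
  f2 <- fit_logistic(X, y)
  expect_identical(f, f2)
  expect_error(fit_logistic(X, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC equals the pairwise counting oracle, ties included", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(9)
  for (i in 1:25) {
    n <- sample(4:200, 1)
    scores <- round(rnorm(n), sample(c(1, 3), 1))  # induce ties sometimes
    labels <- integer(n)
    labels[sample(n, sample(seq_len(n - 1), 1))] <- 1L
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC library", {
  set.seed(13)
  scores <- rnorm(150); labels <- rbinom(150, 1, 0.4)
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              levels = c(0, 1),
                                              direction = "<",
                                              quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("sensitivity and specificity are the exact count ratios", {
  expect_equal(sensitivity_specificity(TP = 9, FP = 10, TN = 0, FN = 1),
               c(Sn = 0.9, Sp = 0))
  expect_equal(sensitivity_specificity(5, 5, 5, 5), c(Sn = 0.5, Sp = 0.5))
  expect_error(sensitivity_specificity(0, 5, 5, 0), "undefined")
})

test_that("cross-validation scores each sample once, stratified", {
  set.seed(3)
  X <- matrix(c(rnorm(60, 3), rnorm(140, -3)), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- c(rep(1, 60), rep(0, 140))
  cv <- cross_validate(X, y, k = 10, seed = 42)
  expect_equal(cv$auc, 1)                      # separable
  expect_equal(length(cv$scores), 200L)
  expect_equal(sort(unique(cv$fold)), 1:10)
  ## strata balanced within one member
  expect_true(all(abs(table(cv$fold[y == 1]) - 6) <= 1))
  cv2 <- cross_validate(X, y, k = 10, seed = 42)
  expect_identical(cv$fold, cv2$fold)
  expect_error(cross_validate(X[1:15, , drop = FALSE],
                              c(rep(1, 5), rep(0, 10)), k = 10, seed = 1),
               "folds")

  ## shuffled labels give chance-level AUC (larger n for a tight null)
  Xn <- matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "x"))
  yn <- withr::with_seed(8, sample(rep(c(0, 1), 1000)))
  cvp <- cross_validate(Xn, yn, k = 10, seed = 42)
  expect_lt(abs(cvp$auc - 0.5), 0.08)

  ## ROC endpoints: Sn reaches 1 at the lowest threshold
  expect_equal(cv$roc$Sn[nrow(cv$roc)], 1)
})

test_that("stratified bootstrap CI behaves at the degenerate extremes", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(0, 0, 0, 1, 1, 1)
  ci <- bootstrap_auc_ci(scores, labels, B = 200, seed = 4)
  expect_equal(unname(ci), c(1, 1))
  ci2 <- bootstrap_auc_ci(rep(0.5, 8), c(0, 0, 0, 0, 1, 1, 1, 1),
                          B = 200, seed = 4)
  expect_equal(unname(ci2), c(0.5, 0.5))
  ci3 <- bootstrap_auc_ci(scores, labels, B = 200, seed = 4)
  expect_identical(ci, ci3)
})

test_that("model selection picks the benchmark with larger separation", {
  sim <- simulate_proteome(60, 4, 100, seed = 61)
  ids <- sim$sites$site_id
  pos <- ids[1:30]
  ## positives separated on rsa; benchmark 1's negatives are fully
  ## separated, half of benchmark 2's negatives overlap the positives
  feat <- data.frame(site_id = ids, ukf_count = 0, rcs = 0, idm_count = 0,
                     asc = 0, rsa = 0, ss_helix = 1/3, ss_strand = 1/3,
                     ss_coil = 1/3, stringsAsFactors = FALSE)
  feat$rsa[match(pos, ids)] <- 0.9
  feat$rsa[match(ids[91:120], ids)] <- 0.9
  benchmarks <- list(
    list(positives = pos, negatives = ids[31:90], ratio = 2, set_index = 1),
    list(positives = pos, negatives = ids[91:150], ratio = 2, set_index = 2))
  sel <- select_final_model(feat, benchmarks, k = 5, seed = 9)
  expect_equal(sel$best_index, 1L)
  expect_equal(sel$cv_auc[1], 1)
  expect_lt(sel$cv_auc[2], 1)
  expect_s3_class(sel$model, "trained_model")
})

test_that("the fence normalizer maps scores as specified", {
  nrm <- fit_normalizer(c(1, 2, 3, 4, 100))
  expect_equal(nrm$Q1, 2)
  expect_equal(nrm$Q3, 4)
  expect_equal(nrm$lower_fence, -4)
  expect_equal(nrm$upper_fence, 10)
  expect_equal(nrm$S_min, 1)
  expect_equal(nrm$S_max, 4)
  expect_equal(normalize_scores(nrm, 100), 1)    # above upper fence
  expect_equal(normalize_scores(nrm, -10), 0)    # below lower fence
  expect_equal(normalize_scores(nrm, 2), 1 / 3)
  expect_equal(normalize_scores(nrm, 1), 0)      # S_min endpoint
  expect_equal(normalize_scores(nrm, 4), 1)      # S_max endpoint

  expect_warning(nrm0 <- fit_normalizer(rep(2, 6)), "degenerate")
  expect_equal(normalize_scores(nrm0, 2), 0.5)

  ## monotone, image within [0,1]
  set.seed(17)
  raw <- rnorm(200, sd = 3)
  nrm2 <- fit_normalizer(raw)
  x <- sort(runif(100, min(raw) - 5, max(raw) + 5))
  v <- normalize_scores(nrm2, x)
  expect_true(all(diff(v) >= -1e-12))
  expect_true(all(v >= 0 & v <= 1))
})

test_that("top-fraction prioritization includes ties at the cut", {
  s <- setNames(c(100, 99, 98, 97, rep(96, 3), 93:1), paste0("s", 1:100))
  expect_length(prioritize_top_fraction(s, 0.05), 7L)  # 3-way tie at rank 5
  distinct <- setNames(1:100, paste0("d", 1:100))
  top <- prioritize_top_fraction(distinct, 0.05)
  expect_length(top, 5L)
  expect_setequal(top, paste0("d", 96:100))
  expect_length(prioritize_top_fraction(distinct, 1), 100L)
  expect_error(prioritize_top_fraction(distinct, 0), "fraction")
})

test_that("the prioritized/regulated intersection keeps direction and score", {
  regulated <- data.frame(site_id = c("a", "b", "c"),
                          direction = c("hyper", "hypo", "hyper"),
                          stringsAsFactors = FALSE)
  expect_equal(nrow(intersect_lirp(c("x", "y"), regulated)), 0L)
  out <- intersect_lirp(c("a", "c", "z"), regulated,
                        scores = c(a = 0.9, c = 0.95, z = 0.5))
  expect_equal(out$site_id, c("c", "a"))
  expect_equal(out$score, c(0.95, 0.9))
  expect_equal(out$direction, c("hyper", "hyper"))
  sub <- intersect_lirp(c("a", "b", "c"), regulated)
  expect_setequal(sub$site_id, regulated$site_id)
})
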