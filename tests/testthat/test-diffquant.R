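test_that("replicate normalization divides by the replicate median", {
  expect_equal(normalize_replicate_ratios(c(0.5, 1, 2)), c(0.5, 1, 2))
  expect_equal(normalize_replicate_ratios(c(1, 2, 3)), c(0.5, 1, 1.5))
  expect_equal(normalize_replicate_ratios(rep(3.7, 5)), rep(1, 5))
  expect_error(normalize_replicate_ratios(numeric(0)), "empty")
  expect_error(normalize_replicate_ratios(c(1, -2)), "> 0")
})

test_that("control assembly follows the control-1/control-2 rule", {
  r <- list(WT = c(1, 1.1, 0.9, 1.05), aux1 = c(1, 1), aux2 = c(1.2))
  c1 <- build_control(r, "WT", c("aux1", "aux2"))
  expect_equal(c1$tier, "control-1")
  expect_equal(c1$control, r$WT)

  r <- list(WT = c(1, 1.1), aux1 = c(1, 0.8, 1.2), aux2 = c(1.2, 0.9))
  c2 <- build_control(r, "WT", c("aux1", "aux2"))
  expect_equal(c2$tier, "control-2")
  expect_equal(length(c2$control), 7L)  # 2 + 3 + 2 pooled

  c3 <- build_control(list(mutant = c(1, 2, 3)), "WT", c("aux1"))
  expect_equal(c3$tier, "excluded")
})

test_that("robust spread reproduces the NIQ formula and is consistent", {
  s <- robust_spread(c(1, 2, 3, 4, 5))
  expect_equal(s$Q1, 2)
  expect_equal(s$Q3, 4)
  expect_equal(s$IQ, 2)
  expect_equal(s$NIQ, 1.4826)
  expect_equal(s$median, 3)

  s0 <- robust_spread(rep(2, 10))
  expect_equal(s0$IQ, 0)
  expect_equal(s0$NIQ, 0)

  expect_error(robust_spread(c(1, 2, 3)), "at least 4")

  ## NIQ estimates sigma on normal samples (0.7413 ~ 1 / (2 z_0.75))
  x <- withr::with_seed(11, rnorm(1e6, sd = 2))
  expect_lt(abs(robust_spread(x)$NIQ - 2) / 2, 0.01)
})

test_that("exact Wilcoxon p equals full enumeration for all small splits", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4), "less"), 1 / 6)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4), "two.sided"), 1 / 3)
  expect_gte(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3), "two.sided"), 0.99)

  for (n in 4:8) {
    vals <- seq_len(n)
    for (nx in 2:(n - 2)) {
      splits <- combn(n, nx)
      for (j in seq_len(ncol(splits))) {
        x <- vals[splits[, j]]; y <- vals[-splits[, j]]
        for (alt in c("less", "greater", "two.sided")) {
          expect_equal(wilcoxon_rank_sum(x, y, alt),
                       oracle_wilcoxon(x, y, alt),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("approximate Wilcoxon branch matches the corrected normal test", {
  set.seed(21)
  x <- rnorm(30); y <- rnorm(35, 0.5)
  for (alt in c("two.sided", "greater", "less")) {
    expect_equal(wilcoxon_rank_sum(x, y, alt),
                 wilcox.test(x, y, alternative = alt, exact = FALSE,
                             correct = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  ## ties force the corrected approximation even at small n
  xt <- c(1, 2, 2); yt <- c(2, 3, 4)
  expect_equal(wilcoxon_rank_sum(xt, yt, "two.sided"),
               suppressWarnings(
                 wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value),
               tolerance = 1e-10)
})

test_that("the flexible filter calls directions as specified", {
  spread <- structure(list(median = 0, Q1 = -0.1, Q3 = 0.1, IQ = 0.2,
                           NIQ = 0.2), class = "spread_stats")
  ## tier 1: beyond 1.5 NIQ with one-tailed support
  expect_equal(call_regulated(0.35, p_one_sided = 0.03,
                              p_two_sided = 0.2, spread), "hyper")
  ## tier 2: beyond 1 NIQ with two-tailed support
  expect_equal(call_regulated(0.25, p_one_sided = 0.2,
                              p_two_sided = 0.02, spread), "hyper")
  expect_equal(call_regulated(-0.25, p_one_sided = 0.2,
                              p_two_sided = 0.02, spread), "hypo")
  expect_equal(call_regulated(0, 0.5, 1, spread), "none")
  ## inside both bands: never called
  expect_equal(call_regulated(0.15, 0.001, 0.001, spread), "none")
})

test_that("swapping test and control negates log2fc and flips direction", {
  sim <- simulate_quant_table(n_isoforms = 60, fraction_regulated = 0.2,
                              fold = 3, sdlog = 0.1, seed = 31)
  fwd <- call_differential(sim$quant, "mutant", "WT", c("ctrlA", "ctrlB"))
  ## reverse roles: compare WT against mutant (aux genotypes unused)
  rev <- call_differential(sim$quant, "WT", "mutant", character(0))
  common <- intersect(fwd$calls$isoform_id, rev$calls$isoform_id)
  f <- fwd$calls[match(common, fwd$calls$isoform_id), ]
  r <- rev$calls[match(common, rev$calls$isoform_id), ]
  expect_equal(f$log2fc, -r$log2fc, tolerance = 1e-12)
  flip <- c(hyper = "hypo", hypo = "hyper", none = "none")
  called_both <- f$direction != "none" & r$direction != "none"
  expect_true(all(r$direction[called_both] ==
                    flip[f$direction[called_both]]))
})

test_that("isoform calls expand to sites, flagging direction conflicts", {
  calls <- data.frame(isoform_id = c("i1", "i2", "i3"),
                      direction = c("hyper", "hypo", "none"),
                      stringsAsFactors = FALSE)
  map <- data.frame(isoform_id = c("i1", "i1", "i2", "i3"),
                    site_id = c("s1", "s2", "s2", "s3"),
                    stringsAsFactors = FALSE)
  expect_warning(out <- expand_regulated_sites(calls, map),
                 "opposite directions")
  expect_equal(nrow(out), 3L)            # s1 hyper, s2 hyper + hypo
  expect_equal(sum(out$site_id == "s2"), 2L)
  expect_false("s3" %in% out$site_id)    # unregulated isoform
})
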