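test_that("generators are pure functions of their seed", {
  b1 <- simulate_benchmark(50, 100, mode = "gaussian", seed = 1)
  b2 <- simulate_benchmark(50, 100, mode = "gaussian", seed = 1)
  expect_identical(b1, b2)
  b3 <- simulate_benchmark(50, 100, mode = "gaussian", seed = 2)
  expect_false(identical(b1$features$x, b3$features$x))

  q1 <- simulate_quant_table(n_isoforms = 40, seed = 3)
  q2 <- simulate_quant_table(n_isoforms = 40, seed = 3)
  expect_identical(q1, q2)

  ## generators do not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_quant_table(n_isoforms = 5, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("gaussian benchmark attains the analytic population AUC", {
  ## AUC of N(d,1) vs N(0,1) is Phi(d / sqrt(2)); d = 1.19 -> 0.80
  b <- simulate_benchmark(20000, 20000, mode = "gaussian", d = 1.19,
                          seed = 5)
  expect_lt(abs(roc_auc(b$features$x, b$labels) - pnorm(1.19 / sqrt(2))),
            0.01)
  b0 <- simulate_benchmark(20000, 20000, mode = "gaussian", d = 0,
                           seed = 5)
  expect_lt(abs(roc_auc(b0$features$x, b0$labels) - 0.5), 0.01)
})

test_that("logistic benchmark labels follow the planted coefficients", {
  ## gaussian covariates: the well-posed recovery design
  b <- simulate_benchmark(n = 20000, mode = "logistic",
                          covariates = "gaussian", seed = 6)
  f <- fit_logistic(b$features[, names(b$beta)], b$labels, l2 = 1e-8)
  expect_lt(max(abs(f$weights - b$beta)), 0.1)
  expect_lt(abs(f$intercept - b$intercept), 0.1)
  ## realistic marginals: same model, wider sampling error on the
  ## low-information covariates
  br <- simulate_benchmark(n = 20000, mode = "logistic", seed = 6)
  fr <- fit_logistic(br$features[, names(br$beta)], br$labels, l2 = 1e-8)
  expect_lt(max(abs(fr$weights - br$beta)), 0.35)
})

test_that("quant tables plant folds only in the test genotype", {
  q <- simulate_quant_table(n_isoforms = 100, replicates = 4,
                            fraction_regulated = 0.2, fold = 4,
                            sdlog = 0.05, seed = 7)
  expect_true(all(q$quant$ratio > 0))
  expect_equal(sum(q$truth$direction != "none"), 20L)
  expect_equal(sum(q$truth$direction == "hyper"), 10L)
  hyper1 <- q$truth$isoform_id[q$truth$direction == "hyper"][1]
  d <- q$quant[q$quant$isoform_id == hyper1, ]
  expect_gt(median(d$ratio[d$genotype == "mutant"]),
            2 * median(d$ratio[d$genotype == "WT"]))
  ## fold 1 plants nothing
  q1 <- simulate_quant_table(n_isoforms = 30, fold = 1, seed = 8)
  expect_true(all(q1$truth$direction == "none"))
})

test_that("planted kinase enrichment carries the target excess exactly", {
  sim <- simulate_proteome(100, 4, 80, seed = 41)   # 400 sites
  reg <- sim$sites$site_id[1:40]
  ann <- simulate_annotations(sim$sites, sim$proteins, n_kinases = 10,
                              edges_per_kinase = 80,
                              regulated_sites = reg, e_target = 3,
                              seed = 42)
  expect_equal(ann$planted_kinase, "K_planted")
  edges <- ann$bundle$kinase_edges
  planted <- edges$site_id[edges$kinase_family == "K_planted"]
  m <- length(intersect(planted, reg))
  expect_equal(m, round(3 * 80 * 40 / 400))   # exact-count planting
  ## all edges reference existing sites
  expect_true(all(edges$site_id %in% sim$sites$site_id))
  ## excess 0 -> no planted kinase
  ann0 <- simulate_annotations(sim$sites, sim$proteins, e_target = 0,
                               seed = 43)
  expect_true(is.na(ann0$planted_kinase))
})

test_that("generated fixtures pass strict validation end to end", {
  td <- tempfile()
  fx <- simulate_fixture(td, fixture_config(seed = 11, n_proteins = 12,
                                            sites_per_protein = 3,
                                            n_positives = 6))
  tab <- read_site_table(file.path(td, "sites.tsv"))
  expect_equal(nrow(tab$sites), 36L)
  bundle <- read_annotation_bundle(td)
  v <- validate_annotations(bundle, tab$proteins, tab$sites, strict = TRUE)
  expect_true(v$ok)
  tree <- read_newick(file.path(td, "tree.nwk"))
  expect_equal(ape::Ntip(tree), 7L)
  ## every msa file parses and its reference ungaps to the protein
  for (acc in tab$proteins$accession[1:3]) {
    msa <- read_alignment(file.path(td, "msa", paste0(acc, ".fasta")),
                          "sp1")
    ref <- gsub("-", "", msa$sequences[["sp1"]])
    expect_equal(ref, tab$proteins$sequence[tab$proteins$accession == acc])
  }
})
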