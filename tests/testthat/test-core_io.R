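test_that("site tables are validated against their protein sequences", {
  p <- write_sites_fixture(list(list("P1", "MSTY", 2, "S"),
                                list("P1", "MSTY", 4, "Y"),
                                list("P2", "MSSA", 3, "S")))
  tab <- read_site_table(p)
  expect_equal(nrow(tab$sites), 3L)
  expect_equal(tab$sites$site_id, c("P1:S2", "P1:Y4", "P2:S3"))
  expect_equal(nrow(tab$proteins), 2L)  # P1 deduplicated

  expect_error(read_site_table(
    write_sites_fixture(list(list("P1", "MSTY", 3, "S")))),
    "does not match")
  expect_error(read_site_table(
    write_sites_fixture(list(list("P1", "MSTY", 9, "S")))),
    "beyond protein length")
  expect_error(read_site_table(
    write_sites_fixture(list(list("P1", "MSTY", 2, "S"),
                             list("P1", "MSTA", 2, "S")))),
    "conflicting sequences")
  expect_error(read_site_table(
    write_sites_fixture(list(list("P1", "MXTY", 2, "X")))),
    "residue must be one of")
})

test_that("site table round trip is lossless", {
  p <- write_sites_fixture(list(list("P1", "MSTY", 2, "S"),
                                list("P2", "MSSA", 3, "S")))
  tab <- read_site_table(p)
  p2 <- tempfile(fileext = ".tsv")
  write_site_table(tab$sites, tab$proteins, p2)
  tab2 <- read_site_table(p2)
  expect_identical(tab, tab2)
})

test_that("FASTA reading parses headers, uppercases, and round-trips", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">A some description", "mst", ">B", "MQW"), fa)
  prot <- read_fasta(fa)
  expect_equal(prot$accession, c("A", "B"))
  expect_equal(prot$sequence[1], "MST")  # uppercased, header to whitespace

  fa2 <- tempfile(fileext = ".fasta")
  write_fasta(prot, fa2)
  expect_identical(read_fasta(fa2), prot)

  writeLines(c(">A", "MST", ">A", "MQW"), fa)
  expect_error(read_fasta(fa), "duplicate accessions")
})

test_that("Newick reading validates branch lengths and labels", {
  nw <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,(C:1,D:3):1);", nw)
  tr <- read_newick(nw)
  expect_equal(ape::Ntip(tr), 4L)
  expect_equal(tree_path_distance(tr, "A", "B"), 2)

  writeLines("(A:0,B:0);", nw)
  expect_equal(tree_path_distance(read_newick(nw), "A", "B"), 0)

  writeLines("((A:1,B));", nw)
  expect_error(read_newick(nw), "branch length")

  writeLines("((A:1,A:1):1,B:1);", nw)
  expect_error(read_newick(nw), "duplicate leaf")
})

test_that("tree path distance is a symmetric metric on leaves", {
  for (s in 1:3) {
    tr <- simulate_tree(6, c(0.2, 1.5), seed = 100 + s)
    tips <- tr$tip.label
    for (a in tips) expect_equal(tree_path_distance(tr, a, a), 0)
    expect_equal(tree_path_distance(tr, tips[1], tips[4]),
                 tree_path_distance(tr, tips[4], tips[1]))
    expect_equal(tree_path_distance(tr, tips[2], tips[5]),
                 oracle_tree_distance(tr, tips[2], tips[5]))
  }
})

test_that("annotation validation flags bad rows and respects modes", {
  proteins <- data.frame(accession = "P1", sequence = "MSTYAAAA",
                         stringsAsFactors = FALSE)
  sites <- data.frame(site_id = "P1:S2", stringsAsFactors = FALSE)
  bundle <- annotation_bundle(
    acetyl_sites = data.frame(accession = "P1", position = c(3L, 99L)),
    ss_probs = data.frame(site_id = c("P1:S2", "P1:S2"),
                          p_helix = c(0.2, 0.5), p_strand = c(0.3, 0.5),
                          p_coil = c(0.5, 0.5)))
  expect_error(validate_annotations(bundle, proteins, sites,
                                    strict = TRUE),
               "position outside protein")
  ## the in-range acetyl row and the summing-to-one SS triple survive;
  ## the out-of-range position and the 1.5-sum triple are dropped
  bundle$ss_probs <- bundle$ss_probs[2:1, ]  # order must not matter
  v <- validate_annotations(bundle, proteins, sites, strict = FALSE)
  expect_false(v$ok)
  expect_equal(sum(v$report$n_dropped), 2L)
  expect_equal(v$bundle$acetyl_sites$position, 3L)
  expect_equal(v$bundle$ss_probs$p_coil, 0.5)
  expect_equal(v$bundle$ss_probs$p_helix, 0.2)
})

test_that("annotation bundle round-trips through a directory", {
  d <- tempfile()
  bundle <- annotation_bundle(
    kinase_edges = data.frame(kinase_family = c("CDK", "MAPK"),
                              site_id = c("P1:S2", "P1:S2"),
                              stringsAsFactors = FALSE),
    rsa = data.frame(site_id = "P1:S2", rsa = 0.5,
                     stringsAsFactors = FALSE))
  write_annotation_bundle(bundle, d)
  back <- read_annotation_bundle(d)
  expect_equal(back$kinase_edges, bundle$kinase_edges)
  expect_equal(back$rsa, bundle$rsa)
})
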