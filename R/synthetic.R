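## Seeded synthetic-data generators. Every generator is a pure function
## of its arguments and an explicit seed, and its output passes the
## package's strict validation, so each downstream stage can be tested
## against known ground truth without any external data.

#' Simulate a feature benchmark with known ground truth
#'
#' Two generative modes:
#' \describe{
#'   \item{\code{"gaussian"}}{a single feature drawn per class,
#'     N(d, 1) for positives and N(0, 1) for negatives, with fixed class
#'     counts. The population AUC is the closed form Phi(d / sqrt(2)),
#'     which makes this mode the analytic oracle for AUC checks.}
#'   \item{\code{"logistic"}}{the eight model features drawn either from
#'     realistic marginal distributions (counts, probabilities, a
#'     non-negative conservation score; \code{covariates = "realistic"})
#'     or as standard normals (\code{covariates = "gaussian"}, the
#'     well-posed design for coefficient-recovery checks), with labels
#'     drawn from the logistic model
#'     P(y=1|x) = logit^{-1}(intercept + x'beta); the true coefficients
#'     are returned for recovery tests.}
#' }
#'
#' @param n_pos,n_neg class sizes (gaussian mode).
#' @param n total sample size (logistic mode).
#' @param mode \code{"gaussian"} or \code{"logistic"}.
#' @param d class separation of the single gaussian feature.
#' @param beta named coefficient vector over the feature columns
#'   (logistic mode); defaults to a moderate effect on each feature.
#' @param intercept logistic-mode intercept.
#' @param covariates logistic-mode covariate design, \code{"realistic"}
#'   (default) or \code{"gaussian"}.
#' @param seed integer seed.
#' @return list: \code{features} (data.frame with \code{site_id} and
#'   feature columns), \code{labels} (0/1), \code{beta}, \code{intercept}.
#' @export
simulate_benchmark <- function(n_pos = 121L, n_neg = 605L, n = 2000L,
                               mode = c("gaussian", "logistic"),
                               d = 1.19,
                               beta = NULL, intercept = -2,
                               covariates = c("realistic", "gaussian"),
                               seed) {
  mode <- match.arg(mode)
  covariates <- match.arg(covariates)
  if (mode == "gaussian") {
    with_seed(seed, {
      x <- c(rnorm(n_pos, mean = d), rnorm(n_neg, mean = 0))
      labels <- c(rep(1L, n_pos), rep(0L, n_neg))
      features <- data.frame(
        site_id = sprintf("S%06d", seq_along(x)),
        x = x, stringsAsFactors = FALSE)
      list(features = features, labels = labels,
           beta = c(x = NA_real_), intercept = NA_real_, d = d)
    })
  } else {
    if (is.null(beta)) {
      beta <- c(ukf_count = 0.5, rcs = 0.3, idm_count = 0.2, asc = 0.8,
                rsa = 1.0, ss_helix = 0.4, ss_strand = -0.3,
                ss_coil = 0.1)
    }
    with_seed(seed, {
      X <- if (covariates == "gaussian") {
        as.data.frame(matrix(rnorm(n * length(beta)), ncol = length(beta),
                             dimnames = list(NULL, names(beta))))
      } else {
        ss_raw <- matrix(stats::rgamma(3L * n, shape = 2), ncol = 3L)
        ss <- ss_raw / rowSums(ss_raw)
        data.frame(
          ukf_count = stats::rpois(n, 1.5),
          rcs = stats::rexp(n, rate = 0.5),
          idm_count = stats::rpois(n, 1),
          asc = rbinom(n, 1L, 0.3),
          rsa = stats::rbeta(n, 2, 2),
          ss_helix = ss[, 1L], ss_strand = ss[, 2L], ss_coil = ss[, 3L])
      }
      eta <- intercept + as.matrix(X[, names(beta)]) %*% beta
      labels <- rbinom(n, 1L, plogis(drop(eta)))
      features <- cbind(data.frame(site_id = sprintf("S%06d", seq_len(n)),
                                   stringsAsFactors = FALSE), X)
      list(features = features, labels = labels, beta = beta,
           intercept = intercept)
    })
  }
}

#' Simulate a replicate isotope-ratio quantitation table
#'
#' Unregulated isoforms have light/heavy ratios lognormal around 1 in
#' every genotype; regulated isoforms have the test genotype's ratios
#' multiplied by the planted fold (hyper) or its reciprocal (hypo),
#' alternating. Multiplicative lognormal replicate noise mirrors the
#' error structure of isotope-ratio quantitation.
#'
#' @param n_isoforms number of phosphoisoforms (default 500).
#' @param replicates technical replicates per genotype (default 4).
#' @param fraction_regulated fraction of isoforms with a planted fold
#'   change (default 0.1).
#' @param fold planted fold change, > 0 (default 2; 1 plants nothing).
#' @param sdlog lognormal replicate noise, log scale (default 0.1).
#' @param test_genotype,control_genotype,auxiliary_genotypes genotype
#'   labels of the design.
#' @param seed integer seed.
#' @return list: \code{quant} (long data.frame: isoform_id, genotype,
#'   replicate, ratio), \code{truth} (data.frame: isoform_id, direction,
#'   planted_fold).
#' @export
simulate_quant_table <- function(n_isoforms = 500L, replicates = 4L,
                                 fraction_regulated = 0.1, fold = 2,
                                 sdlog = 0.1,
                                 test_genotype = "mutant",
                                 control_genotype = "WT",
                                 auxiliary_genotypes = c("ctrlA", "ctrlB"),
                                 seed) {
  stopifnot(n_isoforms >= 1L, replicates >= 1L, fold > 0,
            fraction_regulated >= 0, fraction_regulated <= 1)
  genotypes <- c(test_genotype, control_genotype, auxiliary_genotypes)
  iso_ids <- sprintf("iso%05d", seq_len(n_isoforms))
  n_reg <- if (fold == 1) 0L else round(fraction_regulated * n_isoforms)
  direction <- rep("none", n_isoforms)
  if (n_reg > 0L) {
    direction[seq_len(n_reg)] <- rep(c("hyper", "hypo"), length.out = n_reg)
  }
  mult <- ifelse(direction == "hyper", fold,
                 ifelse(direction == "hypo", 1 / fold, 1))
  quant <- with_seed(seed, {
    rows <- lapply(genotypes, function(g) {
      base <- if (g == test_genotype) mult else rep(1, n_isoforms)
      do.call(rbind, lapply(seq_len(replicates), function(r) {
        data.frame(isoform_id = iso_ids, genotype = g, replicate = r,
                   ratio = base * exp(rnorm(n_isoforms, 0, sdlog)),
                   stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows)
  })
  rownames(quant) <- NULL
  list(quant = quant,
       truth = data.frame(isoform_id = iso_ids, direction = direction,
                          planted_fold = mult, stringsAsFactors = FALSE))
}

#' Simulate a species tree
#'
#' Random topology with branch lengths drawn uniformly from
#' \code{branch_range}; leaf labels \code{sp1..spN} with \code{sp1}
#' conventionally the reference species.
#'
#' @param n_species number of leaves (>= 2).
#' @param branch_range length-2 numeric range of branch lengths.
#' @param seed integer seed.
#' @return a rooted \code{phylo} object.
#' @export
simulate_tree <- function(n_species = 7L, branch_range = c(0.1, 2),
                          seed) {
  with_seed(seed, {
    tr <- ape::rtree(n_species, rooted = TRUE,
                     tip.label = paste0("sp", seq_len(n_species)))
    tr$edge.length <- runif(nrow(tr$edge), branch_range[1L],
                            branch_range[2L])
    tr
  })
}

#' Simulate an ortholog alignment realizing a conservation pattern
#'
#' The reference row is the protein sequence itself (gap-free); every
#' other species gets a random background sequence over non-phospho
#' residues. At each listed site position, exactly the requested species
#' carry the site's phosphoacceptor residue; all other species carry a
#' non-phosphorylatable residue, so the conservation module's conserved
#' set equals the requested set by construction.
#'
#' @param sequence reference protein sequence (uppercase).
#' @param site_positions integer vector of phosphosite positions.
#' @param conserved list parallel to \code{site_positions}: for each
#'   site, the species (including the reference) conserving it.
#' @param species all species labels (rows of the alignment).
#' @param reference_species the reference row label.
#' @param seed integer seed.
#' @return an [ortholog_alignment()].
#' @export
simulate_msa <- function(sequence, site_positions, conserved, species,
                         reference_species, seed) {
  stopifnot(length(site_positions) == length(conserved))
  bad <- !vapply(conserved, function(s) reference_species %in% s &&
                   all(s %in% species), logical(1))
  if (any(bad)) {
    stop("each conserved set must contain the reference and only known ",
         "species", call. = FALSE)
  }
  L <- nchar(sequence)
  background <- setdiff(strsplit("ACDEFGHIKLMNPQRVW", "")[[1]], "")
  with_seed(seed, {
    rows <- lapply(species, function(sp) {
      if (sp == reference_species) return(sequence)
      chars <- sample(background, L, replace = TRUE)
      for (j in seq_along(site_positions)) {
        pos <- site_positions[j]
        res <- substr(sequence, pos, pos)
        chars[pos] <- if (sp %in% conserved[[j]]) res else "A"
      }
      paste(chars, collapse = "")
    })
    ortholog_alignment(setNames(unlist(rows), species), reference_species)
  })
}

#' Simulate annotation tables with planted structure
#'
#' Generates the full annotation bundle for a site table. Null kinases
#' draw their substrate edges uniformly from all sites. When a regulated
#' set and a target enrichment ratio are given, one planted kinase
#' ("K_planted") receives exactly \code{round(e_target * n_edges * M/N)}
#' of its edges from the regulated set (exact-count planting, so the
#' truth enrichment ratio equals the target). When a positive set and a
#' positive separation are given, positives receive extra kinase edges,
#' a higher chance of a nearby acetylation site, domain placement with
#' partner counts, and higher surface accessibility, so the feature
#' encoding separates the classes.
#'
#' @param sites data.frame (\code{accession}, \code{position},
#'   \code{residue}, \code{site_id}).
#' @param proteins data.frame (\code{accession}, \code{sequence}).
#' @param n_kinases number of null kinase families (default 20).
#' @param edges_per_kinase substrate edges per kinase (default 100,
#'   capped at the number of sites).
#' @param regulated_sites site ids of the regulated set (optional).
#' @param e_target planted enrichment ratio for the planted kinase
#'   (default 3; 0 or NULL plants nothing).
#' @param positives site ids of the positive class (optional).
#' @param separation strength of the positive/negative feature
#'   separation in [0, 1] scale units (default 1).
#' @param seed integer seed.
#' @return list: \code{bundle} (an [annotation_bundle()]),
#'   \code{planted_kinase} (label or NA).
#' @export
simulate_annotations <- function(sites, proteins, n_kinases = 20L,
                                 edges_per_kinase = 100L,
                                 regulated_sites = NULL, e_target = 3,
                                 positives = NULL, separation = 1,
                                 seed) {
  n_sites <- nrow(sites)
  edges_per_kinase <- min(edges_per_kinase, n_sites)
  plen <- setNames(nchar(proteins$sequence), proteins$accession)
  with_seed(seed, {
    ## --- kinase edges -------------------------------------------------
    edge_list <- lapply(seq_len(n_kinases), function(k) {
      data.frame(kinase_family = sprintf("K%03d", k),
                 site_id = sample(sites$site_id, edges_per_kinase),
                 stringsAsFactors = FALSE)
    })
    planted_kinase <- NA_character_
    if (!is.null(regulated_sites) && length(regulated_sites) &&
        !is.null(e_target) && e_target > 0) {
      planted_kinase <- "K_planted"
      M <- length(regulated_sites)
      m_target <- min(round(e_target * edges_per_kinase * M / n_sites),
                      M, edges_per_kinase)
      others <- setdiff(sites$site_id, regulated_sites)
      edge_list[[length(edge_list) + 1L]] <- data.frame(
        kinase_family = planted_kinase,
        site_id = c(sample(regulated_sites, m_target),
                    sample(others, edges_per_kinase - m_target)),
        stringsAsFactors = FALSE)
    }
    ## extra family edges onto positives (feature separation, UKF count)
    if (!is.null(positives) && length(positives) && separation > 0) {
      n_extra <- pmax(1L, stats::rpois(length(positives), 2 * separation))
      extra <- do.call(rbind, lapply(seq_along(positives), function(i) {
        data.frame(kinase_family = sprintf("K%03d",
                     sample(n_kinases, min(n_extra[i], n_kinases))),
                   site_id = positives[i], stringsAsFactors = FALSE)
      }))
      edge_list[[length(edge_list) + 1L]] <- extra
    }
    kinase_edges <- unique(do.call(rbind, edge_list))

    ## --- acetylation sites (near positives more often) ----------------
    p_acetyl <- ifelse(sites$site_id %in% positives,
                       0.1 + 0.5 * separation, 0.1)
    has_ac <- runif(n_sites) < p_acetyl
    acetyl <- if (any(has_ac)) {
      idx <- which(has_ac)
      pos <- pmin(pmax(sites$position[idx] +
                         sample(c(-10L:-1L, 1L:10L), length(idx),
                                replace = TRUE), 1L),
                  plen[sites$accession[idx]])
      data.frame(accession = sites$accession[idx], position = as.integer(pos),
                 stringsAsFactors = FALSE)
    } else empty_df("accession", "position")

    ## --- domains around a subset of sites ------------------------------
    p_dom <- ifelse(sites$site_id %in% positives,
                    0.2 + 0.4 * separation, 0.2)
    in_dom <- which(runif(n_sites) < p_dom)
    domains <- if (length(in_dom)) {
      data.frame(accession = sites$accession[in_dom],
                 start = pmax(1L, sites$position[in_dom] - 5L),
                 end = pmin(plen[sites$accession[in_dom]],
                            sites$position[in_dom] + 5L),
                 domain_id = sprintf("D%04d", seq_along(in_dom)),
                 stringsAsFactors = FALSE)
    } else empty_df("accession", "start", "end", "domain_id")
    partners <- if (nrow(domains)) {
      data.frame(domain_id = domains$domain_id,
                 n_partners = 1L + stats::rpois(nrow(domains), 2),
                 stringsAsFactors = FALSE)
    } else empty_df("domain_id", "n_partners")
    domains$start <- as.integer(domains$start)
    domains$end <- as.integer(domains$end)

    ## --- RSA and secondary structure -----------------------------------
    is_pos <- sites$site_id %in% positives
    rsa_val <- ifelse(is_pos,
                      stats::rbeta(n_sites, 2 + 3 * separation, 2),
                      stats::rbeta(n_sites, 2, 2))
    rsa <- data.frame(site_id = sites$site_id, rsa = rsa_val,
                      stringsAsFactors = FALSE)
    ss_raw <- matrix(stats::rgamma(3L * n_sites, shape = 2), ncol = 3L)
    ss_raw[is_pos, 3L] <- ss_raw[is_pos, 3L] * (1 + separation)
    ss <- ss_raw / rowSums(ss_raw)
    ss_probs <- data.frame(site_id = sites$site_id,
                           p_helix = ss[, 1L], p_strand = ss[, 2L],
                           p_coil = ss[, 3L], stringsAsFactors = FALSE)

    list(bundle = annotation_bundle(kinase_edges = kinase_edges,
                                    acetyl_sites = acetyl,
                                    domain_spans = domains,
                                    domain_partner_counts = partners,
                                    rsa = rsa, ss_probs = ss_probs),
         planted_kinase = planted_kinase)
  })
}

#' Simulate a random protein/site universe
#'
#' Random protein sequences with phosphosites planted at random S/T/Y
#' positions, one or more sites per protein.
#'
#' @param n_proteins number of proteins.
#' @param sites_per_protein sites per protein (recycled).
#' @param protein_length sequence length (recycled).
#' @param seed integer seed.
#' @return list: \code{sites}, \code{proteins} (as [read_site_table()]).
#' @export
simulate_proteome <- function(n_proteins = 50L, sites_per_protein = 4L,
                              protein_length = 200L, seed) {
  alphabet <- strsplit("ACDEFGHIKLMNPQRVW", "")[[1]]
  spp <- rep_len(sites_per_protein, n_proteins)
  plen <- rep_len(protein_length, n_proteins)
  with_seed(seed, {
    prot_rows <- list(); site_rows <- list()
    for (i in seq_len(n_proteins)) {
      acc <- sprintf("PROT%04d", i)
      chars <- sample(alphabet, plen[i], replace = TRUE)
      pos <- sort(sample(seq_len(plen[i]), spp[i]))
      res <- sample(c("S", "T", "Y"), spp[i], replace = TRUE,
                    prob = c(0.6, 0.3, 0.1))
      chars[pos] <- res
      prot_rows[[i]] <- data.frame(accession = acc,
                                   sequence = paste(chars, collapse = ""),
                                   stringsAsFactors = FALSE)
      site_rows[[i]] <- data.frame(accession = acc, position = pos,
                                   residue = res,
                                   site_id = make_site_id(acc, res, pos),
                                   stringsAsFactors = FALSE)
    }
    list(sites = do.call(rbind, site_rows),
         proteins = do.call(rbind, prot_rows))
  })
}

#' Default fixture configuration
#'
#' The defaults define the simulated study conditions used throughout
#' the package's tests: 200 sites on 50 proteins, 4 technical replicates
#' per genotype, lognormal replicate noise sdlog 0.1, planted fold 2,
#' 10\% of isoforms regulated, a 7-species tree, 20 null kinase families
#' of 100 edges plus one planted enriched kinase, 1:5 negative sampling
#' over 3 benchmark sets, 10-fold cross-validation, and top-5\%
#' prioritization.
#'
#' @param seed master integer seed (every stage derives its own).
#' @param ... overrides of any default listed above.
#' @return named list of class \code{fixture_config}.
#' @export
fixture_config <- function(seed, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_proteins = 50L, sites_per_protein = 4L, protein_length = 200L,
    replicates = 4L, fraction_regulated = 0.1, fold = 2, sdlog = 0.1,
    test_genotype = "mutant", control_genotype = "WT",
    auxiliary_genotypes = c("ctrlA", "ctrlB"),
    n_species = 7L, branch_range = c(0.1, 2),
    n_kinases = 20L, edges_per_kinase = 100L, e_target = 3,
    n_positives = 20L, separation = 1,
    ratio = 5L, n_sets = 3L, k = 10L, fraction = 0.05, alpha = 0.05,
    min_quant = 3L, reference_species = "sp1"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(modifyList(cfg, over), class = "fixture_config")
}

#' Write a complete synthetic fixture directory
#'
#' Generates and writes every input the pipeline consumes: site table,
#' protein FASTA, species tree, per-protein ortholog alignments,
#' annotation TSVs, the quantitation table, the positive-site list, the
#' isoform-to-site map, ground-truth tables, and a config snapshot.
#' Isoforms map 1:1 to sites. Positive sites are drawn from the
#' non-regulated pool plus a planted overlap with the regulated set so
#' the terminal intersection is non-trivial.
#'
#' @param dir output directory (created).
#' @param config a [fixture_config()].
#' @return invisibly, a list with the generated objects and \code{dir}.
#' @export
simulate_fixture <- function(dir, config) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  prot <- simulate_proteome(config$n_proteins, config$sites_per_protein,
                            config$protein_length,
                            seed = derive_seed(seed, 1))
  sites <- prot$sites
  n_sites <- nrow(sites)

  ## isoforms map 1:1 to sites
  iso_map <- data.frame(isoform_id = sprintf("iso%05d", seq_len(n_sites)),
                        site_id = sites$site_id, stringsAsFactors = FALSE)
  q <- simulate_quant_table(n_isoforms = n_sites,
                            replicates = config$replicates,
                            fraction_regulated = config$fraction_regulated,
                            fold = config$fold, sdlog = config$sdlog,
                            test_genotype = config$test_genotype,
                            control_genotype = config$control_genotype,
                            auxiliary_genotypes = config$auxiliary_genotypes,
                            seed = derive_seed(seed, 2))
  truth_sites <- merge(q$truth, iso_map, by = "isoform_id")
  regulated_true <- truth_sites$site_id[truth_sites$direction != "none"]

  ## positives: half from the regulated set (planted overlap), half not
  pos <- with_seed(derive_seed(seed, 3), {
    n_overlap <- min(length(regulated_true), config$n_positives %/% 2L)
    rest_pool <- setdiff(sites$site_id, regulated_true)
    c(sample(regulated_true, n_overlap),
      sample(rest_pool, config$n_positives - n_overlap))
  })

  ann <- simulate_annotations(sites, prot$proteins,
                              n_kinases = config$n_kinases,
                              edges_per_kinase = config$edges_per_kinase,
                              regulated_sites = regulated_true,
                              e_target = config$e_target,
                              positives = pos,
                              separation = config$separation,
                              seed = derive_seed(seed, 4))

  tree <- simulate_tree(config$n_species, config$branch_range,
                        seed = derive_seed(seed, 5))
  species <- tree$tip.label
  ref <- config$reference_species
  msa_dir <- file.path(dir, "msa")
  dir.create(msa_dir, showWarnings = FALSE)
  ## conservation pattern: positives conserved in more species
  with_seed(derive_seed(seed, 6), {
    for (acc in prot$proteins$accession) {
      s <- sites[sites$accession == acc, , drop = FALSE]
      conserved <- lapply(seq_len(nrow(s)), function(j) {
        k <- if (s$site_id[j] %in% pos) {
          sample(length(species) - 1L, 1L) # at least 1 extra species
        } else {
          sample(0:2, 1L)
        }
        union(ref, sample(setdiff(species, ref), k))
      })
      msa <- simulate_msa(
        prot$proteins$sequence[prot$proteins$accession == acc],
        s$position, conserved, species, ref,
        seed = derive_seed(seed, 7) + match(acc, prot$proteins$accession))
      fa <- data.frame(accession = names(msa$sequences),
                       sequence = unname(msa$sequences),
                       stringsAsFactors = FALSE)
      write_fasta(fa, file.path(msa_dir, paste0(acc, ".fasta")))
    }
  })

  ## write everything
  write_site_table(sites, prot$proteins, file.path(dir, "sites.tsv"))
  write_fasta(prot$proteins, file.path(dir, "proteins.fasta"))
  ape::write.tree(tree, file.path(dir, "tree.nwk"))
  write_annotation_bundle(ann$bundle, dir)
  write_tsv_table(q$quant, file.path(dir, "quant.tsv"))
  write_tsv_table(iso_map, file.path(dir, "isoform_sites.tsv"))
  writeLines(pos, file.path(dir, "positives.txt"))
  write_tsv_table(q$truth, file.path(dir, "truth_quant.tsv"))
  write_tsv_table(
    data.frame(site_id = sites$site_id,
               positive = as.integer(sites$site_id %in% pos),
               regulated = as.integer(sites$site_id %in% regulated_true),
               stringsAsFactors = FALSE),
    file.path(dir, "truth_sites.tsv"))
  cfg_snapshot <- unclass(config)
  write_json_sidecar(cfg_snapshot, file.path(dir, "config.json"))

  invisible(list(dir = dir, sites = sites, proteins = prot$proteins,
                 quant = q$quant, truth = q$truth, positives = pos,
                 bundle = ann$bundle, planted_kinase = ann$planted_kinase,
                 tree = tree, regulated_true = regulated_true))
}
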