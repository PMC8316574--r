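## Independent brute-force oracles used to check the package's
## statistics. These deliberately share no code with the implementation.

## Exact Wilcoxon rank-sum p by enumerating every assignment of the
## combined ranks to the x-sample (equally likely under the null).
oracle_wilcoxon <- function(x, y, alternative) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  all_w <- combn(n, nx, FUN = function(idx) sum(sort(r)[idx]))
  p_le <- mean(all_w <= w_obs)
  p_ge <- mean(all_w >= w_obs)
  switch(alternative,
         less = p_le,
         greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

## Upper hypergeometric tail by enumerating every size-n draw from a
## background of N items of which M are marked.
oracle_hypergeom_tail <- function(N, n, M, m) {
  draws <- combn(N, n)
  hits <- colSums(draws <= M)  # items 1..M are the marked ones
  mean(hits >= m)
}

## AUC by O(n^2) pairwise counting.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

## Leaf-to-leaf tree distance by walking node paths and summing edges
## (independent of cophenetic.phylo).
oracle_tree_distance <- function(tree, a, b) {
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  path <- ape::nodepath(tree, ia, ib)
  sum(vapply(seq_len(length(path) - 1L), function(i) {
    e <- which((tree$edge[, 1] == path[i] & tree$edge[, 2] == path[i + 1]) |
                 (tree$edge[, 2] == path[i] & tree$edge[, 1] == path[i + 1]))
    tree$edge.length[e]
  }, numeric(1)))
}

## Tiny in-memory fixture writers.
write_sites_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(accession = r[[1]], sequence = r[[2]],
               position = as.integer(r[[3]]), residue = r[[4]],
               stringsAsFactors = FALSE)
  }))
  write_tsv_table(df, path)
  path
}
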