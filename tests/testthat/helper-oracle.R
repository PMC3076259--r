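# Brute-force oracles for the exclusivity statistics, independent of the
# package's postorder traversal: enumerate subsets of ancient tips and test
# clade-hood via the MRCA's descendant tip set.

oracle_tips_under <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  sort(unlist(phangorn::Descendants(tree, node, type = "tips")))
}

oracle_exclusive_subsets <- function(tree) {
  ep <- sub("^.*\\|", "", tree$tip.label)
  anc <- which(ep == "ancient")
  out <- list()
  if (length(anc) < 2) return(out)
  for (size in 2:length(anc)) {
    for (S in utils::combn(anc, size, simplify = FALSE)) {
      m <- ape::getMRCA(tree, S)
      if (identical(oracle_tips_under(tree, m), sort(S))) out[[length(out) + 1]] <- S
    }
  }
  out
}

oracle_max_exclusive <- function(tree) {
  ep <- sub("^.*\\|", "", tree$tip.label)
  n_anc <- sum(ep == "ancient")
  if (n_anc == 0) return(0L)
  sizes <- lengths(oracle_exclusive_subsets(tree))
  max(1L, sizes, 0L)
}

oracle_pooled_exclusive <- function(tree) {
  subs <- oracle_exclusive_subsets(tree)
  if (!length(subs)) return(0L)
  maximal <- vapply(seq_along(subs), function(i) {
    !any(vapply(seq_along(subs), function(j) {
      i != j && all(subs[[i]] %in% subs[[j]])
    }, logical(1)))
  }, logical(1))
  sum(lengths(subs[maximal]))
}

# random epoch-labelled tree for property tests
random_labelled_tree <- function(ntips, p_ancient = 0.4) {
  tr <- ape::rtree(ntips)
  ep <- ifelse(stats::runif(ntips) < p_ancient, "ancient", "modern")
  tr$tip.label <- sprintf("t%d|%s", seq_len(ntips), ep)
  tr
}
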