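#' Epoch tags of a genealogy's tips
#'
#' @param tree a `phylo` whose tip labels end in `|modern` or `|ancient`
#'   (a `genealogy` object already carries `tip.epoch`).
#' @return Character vector of `"modern"` / `"ancient"`, one per tip.
#' @export
tip_epochs <- function(tree) {
  if (!is.null(tree$tip.epoch)) return(tree$tip.epoch)
  lab <- tree$tip.label
  has <- grepl("|", lab, fixed = TRUE)
  ep <- sub("^.*\\|", "", lab)
  if (any(!has) || any(!ep %in% c("modern", "ancient")))
    stop("every tip label must be tagged 'id|modern' or 'id|ancient'")
  ep
}

#' Largest ancient-exclusive clade
#'
#' The continuity test statistic: the maximum, over all nodes of the rooted
#' genealogy (tips included), of the number of tips the node subtends, taken
#' only over nodes that subtend no modern tip. A lone ancient tip is a clade
#' of size 1; a tree without ancient tips scores 0. Purely topological:
#' branch lengths play no role.
#'
#' @param tree a rooted binary `phylo`/`genealogy` with epoch-tagged tips.
#' @return Non-negative integer, at most the number of ancient tips.
#' @examples
#' tr <- ape::read.tree(text = "((a1|ancient,a2|ancient),(m1|modern,m2|modern));")
#' max_exclusive_ancient_clade(tr) # 2
#' @export
max_exclusive_ancient_clade <- function(tree) {
  ep <- tip_epochs(tree)
  n <- length(tree$tip.label)
  if (length(ep) != n) stop("epoch vector does not match tip count")
  if (n == 1L || nrow(tree$edge) == 0L)
    return(as.integer(sum(ep == "ancient")))
  m <- tree$Nnode
  anc <- integer(n + m)
  mod <- integer(n + m)
  anc[seq_len(n)] <- as.integer(ep == "ancient")
  mod[seq_len(n)] <- as.integer(ep == "modern")
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]
    ch <- edge[e, 2L]
    anc[p] <- anc[p] + anc[ch]
    mod[p] <- mod[p] + mod[ch]
  }
  vals <- anc[mod == 0L]
  if (length(vals)) max(vals) else 0L
}

#' Pooled count of ancient lineages sorting into exclusive clades
#'
#' The pooled variant of the continuity statistic: the total number of
#' ancient tips lying in *maximal* ancient-exclusive clades of size at least
#' two — that is, ancient lineages that coalesce with other ancient lineages
#' before any modern-descended lineage. Unlike
#' [max_exclusive_ancient_clade()], the sorted lineages need not form one
#' clade; singleton ancient tips never count (they have not coalesced with
#' anything to the exclusion of the moderns).
#'
#' @inheritParams max_exclusive_ancient_clade
#' @return Non-negative integer, at most the number of ancient tips.
#' @examples
#' tr <- ape::read.tree(text =
#'   "(((a1|ancient,a2|ancient),m1|modern),(a3|ancient,a4|ancient));")
#' pooled_exclusive_ancient_count(tr)  # 4 (two exclusive cherries)
#' max_exclusive_ancient_clade(tr)     # 2
#' @export
pooled_exclusive_ancient_count <- function(tree) {
  ep <- tip_epochs(tree)
  n <- length(tree$tip.label)
  if (length(ep) != n) stop("epoch vector does not match tip count")
  if (n == 1L || nrow(tree$edge) == 0L) return(0L)
  m <- tree$Nnode
  anc <- integer(n + m)
  mod <- integer(n + m)
  anc[seq_len(n)] <- as.integer(ep == "ancient")
  mod[seq_len(n)] <- as.integer(ep == "modern")
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]
    ch <- edge[e, 2L]
    anc[p] <- anc[p] + anc[ch]
    mod[p] <- mod[p] + mod[ch]
  }
  parent <- rep(NA_integer_, n + m)
  parent[edge[, 2L]] <- edge[, 1L]
  pure <- mod == 0L & anc >= 2L
  maximal <- pure & (is.na(parent) | !pure[ifelse(is.na(parent), 1L, parent)])
  as.integer(sum(anc[maximal]))
}

#' Evaluate the exclusivity statistic against a threshold
#'
#' Wraps [max_exclusive_ancient_clade()] with the "at least k ancient
#' lineages coalesce to the exclusion of all modern samples" indicator used
#' by the Monte-Carlo continuity tests (k = 8 of 13 in the headline setting).
#'
#' @inheritParams max_exclusive_ancient_clade
#' @param k positive integer threshold, at most the number of ancient tips.
#' @param statistic `"pooled"` ([pooled_exclusive_ancient_count()], the
#'   default used by the continuity tests) or `"single"`
#'   ([max_exclusive_ancient_clade()]).
#' @return An `exclusivity_result`: list with `max_exclusive_size` (the
#'   single-clade maximum), `pooled_exclusive_count`, `value` (the selected
#'   statistic), `indicator` (`value >= k`) and `threshold_k`.
#' @export
evaluate_statistic <- function(tree, k = 8,
                               statistic = c("pooled", "single")) {
  statistic <- match.arg(statistic)
  ep <- tip_epochs(tree)
  n_anc <- sum(ep == "ancient")
  if (!is.numeric(k) || k != round(k) || k < 1 || k > n_anc)
    stop("k must be an integer between 1 and the number of ancient tips (",
         n_anc, ")")
  s <- max_exclusive_ancient_clade(tree)
  pooled <- pooled_exclusive_ancient_count(tree)
  value <- if (statistic == "single") s else pooled
  structure(list(max_exclusive_size = as.integer(s),
                 pooled_exclusive_count = as.integer(pooled),
                 value = as.integer(value),
                 statistic = statistic,
                 indicator = value >= k,
                 threshold_k = as.integer(k)),
            class = "exclusivity_result")
}

#' @export
print.exclusivity_result <- function(x, ...) {
  cat("<exclusivity_result> largest exclusive clade =", x$max_exclusive_size,
      "| pooled sorted lineages =", x$pooled_exclusive_count,
      "|", x$statistic, ">=", x$threshold_k, ":",
      if (x$indicator) "yes" else "no", "\n")
  invisible(x)
}
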