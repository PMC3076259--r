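#' Simulate one serial coalescent genealogy
#'
#' Runs the continuous-time coalescent backward from the present under a
#' validated demographic configuration: within any interval where k lineages
#' share a deme of haploid size N, the waiting time to the next coalescence is
#' exponential with rate k(k-1)/(2N) per generation. The ancient sample joins
#' the process at its sampling age, the isolation-admixture model assigns
#' lineages to demes by a Bernoulli(c) draw at the split, and the expansion
#' model's growth epoch is sampled by exact inversion of the integrated rate.
#'
#' Reproducibility: the engine uses a self-contained xoshiro256** generator
#' with one substream per `(seed, replicate)` pair, so the same configuration,
#' seed and replicate index always give the identical genealogy.
#'
#' @param config a `continuity_config` from [validate_config()].
#' @param seed non-negative integer seed.
#' @param replicate replicate index (substream selector), default 0.
#' @return An object of classes `genealogy` and `phylo`: a rooted binary tree
#'   whose tip labels encode `id|epoch`, with extra components `node.time`
#'   (generations before present for every node, indexed by node id),
#'   `tip.epoch`, `node.deme` (deme of each coalescence: 0 = main/Old World,
#'   1 = New World), `seed` and `replicate`.
#' @examples
#' cfg <- validate_config(constant_model(1000),
#'                        sampling_scheme(5, 3, 1000), time_scale(2))
#' tr <- simulate_genealogy(cfg, seed = 1)
#' @export
simulate_genealogy <- function(config, seed, replicate = 0) {
  stopifnot(inherits(config, "continuity_config"))
  res <- sim_genealogy_cpp(config$cpp, check_seed(seed), replicate)
  build_genealogy(res, config, seed, replicate)
}

build_genealogy <- function(res, config, seed, replicate) {
  n_mod <- config$cpp$n_modern
  n_anc <- config$cpp$n_ancient
  ntip <- n_mod + n_anc
  epochs <- rep(c("modern", "ancient"), c(n_mod, n_anc))
  labels <- c(if (n_mod) sprintf("m%d|modern", seq_len(n_mod)),
              if (n_anc) sprintf("a%d|ancient", seq_len(n_anc)))
  tip_time <- rep(c(0, config$cpp$t_anc), c(n_mod, n_anc))
  m <- length(res$node_time)
  if (m == 0L) {
    tr <- structure(list(edge = matrix(integer(0), 0, 2), Nnode = 0L,
                         tip.label = labels, edge.length = numeric(0)),
                    class = c("genealogy", "phylo"))
    tr$node.time <- tip_time
    tr$tip.epoch <- epochs
    tr$node.deme <- integer(0)
    tr$seed <- seed
    tr$replicate <- replicate
    return(tr)
  }
  # internal nodes were created in increasing time order; the root (last
  # created) must become node ntip + 1 under the phylo convention
  remap <- function(id) ifelse(id <= ntip, id, ntip + (m - (id - ntip) + 1L))
  parent <- remap(res$parent)
  child <- remap(res$child)
  node_time <- c(tip_time, rev(res$node_time))
  node_deme <- rev(res$node_deme)
  edge <- cbind(parent, child, deparse.level = 0)
  tr <- structure(list(edge = edge, Nnode = m, tip.label = labels,
                       edge.length = node_time[parent] - node_time[child]),
                  class = c("genealogy", "phylo"))
  tr <- ape::reorder.phylo(tr, "cladewise")
  class(tr) <- c("genealogy", "phylo")
  tr$node.time <- node_time
  tr$tip.epoch <- epochs
  tr$node.deme <- node_deme
  tr$seed <- seed
  tr$replicate <- replicate
  tr
}

#' @export
print.genealogy <- function(x, ...) {
  ep <- table(x$tip.epoch)
  cat("<genealogy> ", length(x$tip.label), " tips (",
      paste(names(ep), ep, sep = ": ", collapse = ", "), "), TMRCA ",
      format(max(x$node.time), digits = 6), " generations\n", sep = "")
  invisible(x)
}

#' Simulate a batch of genealogies
#'
#' Generates `reps` independent genealogies, optionally reducing each to a
#' summary via `FUN` so trees can be discarded as they stream by. Replicate
#' `i` of a batch is identical to
#' `simulate_genealogy(config, seed, replicate_offset + i - 1)`.
#'
#' @inheritParams simulate_genealogy
#' @param reps positive integer number of replicates.
#' @param FUN optional function applied to each `genealogy`; if `NULL` the
#'   full list of trees is returned.
#' @param replicate_offset first replicate index, default 0.
#' @return A list of length `reps` (trees, or values of `FUN`).
#' @export
simulate_batch <- function(config, reps, seed, FUN = NULL,
                           replicate_offset = 0) {
  stopifnot(reps >= 1)
  lapply(seq_len(reps) - 1L, function(i) {
    tr <- simulate_genealogy(config, seed, replicate_offset + i)
    if (is.null(FUN)) tr else FUN(tr)
  })
}

#' Expected number of ancestral lineages (Tavaré's series)
#'
#' Exact expectation of the number of ancestors of `n` sampled lineages after
#' `t` generations in a constant-size haploid population, computed in log
#' space from the classical series for the pure-death coalescent chain. Used
#' as a validation oracle for the simulator.
#'
#' @param n positive integer sample size.
#' @param ne positive constant haploid population size.
#' @param t non-negative time in generations.
#' @return The expected ancestor count, a number in `[1, n]`.
#' @examples
#' expected_ancestor_count(2, 1000, 0)     # 2
#' expected_ancestor_count(2, 1000, 1e9)   # 1
#' @export
expected_ancestor_count <- function(n, ne, t) {
  stopifnot(n >= 1, n == round(n), ne > 0, t >= 0)
  if (t == 0 || n == 1) return(as.numeric(n))
  tau <- t / ne
  i <- seq_len(n)
  # log of falling(n, i) / rising(n, i)
  lr <- (lgamma(n + 1) - lgamma(n - i + 1)) - (lgamma(n + i) - lgamma(n))
  terms <- exp(-i * (i - 1) * tau / 2 + log(2 * i - 1) + lr)
  sum(terms)
}

#' Number of lineages crossing a time point
#'
#' Counts the genealogy's branches alive `t` generations before present
#' (sampled tips whose ancestors have not yet coalesced away).
#'
#' @param tree a `genealogy`.
#' @param t non-negative time in generations.
#' @return Integer lineage count.
#' @export
lineages_at <- function(tree, t) {
  nt <- tree$node.time
  if (is.null(nt)) stop("tree carries no node times")
  if (nrow(tree$edge) == 0L)
    return(sum(nt <= t))
  cross <- sum(nt[tree$edge[, 1]] > t & nt[tree$edge[, 2]] <= t)
  if (t >= max(nt)) 1L else as.integer(cross)
}

#' Time to the most recent common ancestor
#'
#' @param tree a `genealogy`.
#' @return TMRCA in generations before present.
#' @export
tmrca <- function(tree) max(tree$node.time)

#' Write and read genealogies as Newick
#'
#' Tip labels encode `id|epoch`; branch lengths are in generations. On
#' reading, node times are reconstructed from root-to-node path lengths
#' (most recent tip at time zero).
#'
#' @param trees a `genealogy` or list of them.
#' @param file path to a Newick file.
#' @return `write_genealogies()` returns `file` invisibly;
#'   `read_genealogies()` returns a list of `genealogy` objects.
#' @export
write_genealogies <- function(trees, file) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = file)
  invisible(file)
}

#' @rdname write_genealogies
#' @export
read_genealogies <- function(file) {
  trees <- ape::read.tree(file)
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(trees, as_genealogy)
}

#' Attach genealogy metadata to a phylo tree
#'
#' Derives epoch tags from `id|epoch` tip labels and node times from branch
#' lengths (deepest tip-to-root distance defines the present).
#'
#' @param tree a `phylo` with `id|epoch` tip labels.
#' @return A `genealogy`.
#' @export
as_genealogy <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  depth <- ape::node.depth.edgelength(tree)
  nt <- max(depth) - depth
  tr <- tree
  class(tr) <- c("genealogy", "phylo")
  tr$node.time <- nt
  tr$tip.epoch <- tip_epochs(tree)
  tr
}
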