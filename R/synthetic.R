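#' Finite-sites mutation model
#'
#' Equal-rates single-nucleotide replacement over a fixed number of sites:
#' each branch of a genealogy receives a Poisson(`branch length * mu * sites`)
#' number of mutations, each hitting a uniform site and replacing its base by
#' a uniform different base. The defaults are the 425-bp mtDNA control-region
#' fragment at 2.13e-7 mutations per site per generation.
#'
#' @param mu positive mutation rate per site per generation.
#' @param sites positive integer sequence length.
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(mu = 2.13e-7, sites = 425) {
  if (!is.numeric(mu) || mu < 0) stop("mu must be non-negative")
  if (!is.numeric(sites) || sites < 1 || sites != round(sites))
    stop("sites must be a positive integer")
  structure(list(mu = mu, sites = as.integer(sites)),
            class = "mutation_model")
}

# evaluate `code` under a temporary R RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Drop mutations on a genealogy
#'
#' Evolves sequences down a genealogy under a [mutation_model()]: the root
#' sequence is drawn uniformly, mutations are placed on each branch with
#' Poisson counts proportional to its length in generations, and tip
#' sequences are emitted with their epoch tags.
#'
#' @param tree a `genealogy` (or `phylo` with `id|epoch` tip labels and
#'   branch lengths in generations).
#' @param model a [mutation_model()].
#' @param seed optional integer seed (R RNG, restored afterwards).
#' @return A [dna_alignment()] of the tip sequences.
#' @export
drop_mutations <- function(tree, model = mutation_model(), seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "mutation_model"))
  ep <- tip_epochs(tree)
  ids <- sub("\\|.*$", "", tree$tip.label)
  n <- length(tree$tip.label)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    L <- model$sites
    if (n == 1L || nrow(tree$edge) == 0L) {
      s <- sample.int(4L, L, replace = TRUE)
      return(dna_alignment(paste(bases[s], collapse = ""), ids = ids,
                           epoch = ep))
    }
    seqs <- vector("list", n + tree$Nnode)
    root <- n + 1L
    seqs[[root]] <- sample.int(4L, L, replace = TRUE)
    edge <- ape::reorder.phylo(tree, "cladewise")$edge # parents before children
    elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (e in seq_len(nrow(edge))) {
      s <- seqs[[edge[e, 1L]]]
      nm <- stats::rpois(1L, elen[e] * model$mu * L)
      if (nm > 0L) {
        pos <- sample.int(L, nm, replace = TRUE)
        shift <- sample.int(3L, nm, replace = TRUE)
        if (anyDuplicated(pos)) {
          for (i in seq_len(nm))  # sequential so multiple hits compose
            s[pos[i]] <- ((s[pos[i]] - 1L + shift[i]) %% 4L) + 1L
        } else {
          s[pos] <- ((s[pos] - 1L + shift) %% 4L) + 1L
        }
      }
      seqs[[edge[e, 2L]]] <- s
    }
    out <- vapply(seqs[seq_len(n)],
                  function(s) paste(bases[s], collapse = ""), "")
    dna_alignment(out, ids = ids, epoch = ep)
  })
}

#' Generate a complete synthetic data set
#'
#' One [simulate_genealogy()] call plus [drop_mutations()]: a sequence data
#' set with the statistical structure the continuity analysis assumes, along
#' with its generating truth (the genealogy, TMRCA and the true distinct
#' sequence count) for testing.
#'
#' @param config a `continuity_config`.
#' @param model a [mutation_model()].
#' @param seed non-negative integer seed (drives both the genealogy substream
#'   and the mutation RNG).
#' @param replicate replicate index.
#' @return A `synthetic_dataset`: list with `alignment`, `tree` and `truth`
#'   (`n_haplotypes`, `tmrca`).
#' @export
generate_dataset <- function(config, model = mutation_model(), seed = 1,
                             replicate = 0) {
  tree <- simulate_genealogy(config, seed, replicate)
  aln <- drop_mutations(tree, model, seed = check_seed(seed) + replicate)
  structure(list(alignment = aln, tree = tree,
                 truth = list(n_haplotypes = length(unique(aln$seq)),
                              tmrca = tmrca(tree)),
                 seed = seed, replicate = replicate),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  print(x$alignment)
  cat("  truth:", x$truth$n_haplotypes, "distinct sequences, TMRCA",
      format(x$truth$tmrca, digits = 6), "generations\n")
  invisible(x)
}

#' Write a synthetic data set to disk
#'
#' Emits `<prefix>.fasta`, `<prefix>_meta.tsv` and `<prefix>_tree.nwk`.
#'
#' @param ds a `synthetic_dataset`.
#' @param prefix output path prefix.
#' @return The three file paths, invisibly.
#' @export
write_dataset <- function(ds, prefix) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, "_meta.tsv")
  nwk <- paste0(prefix, "_tree.nwk")
  write_fasta_alignment(ds$alignment, fa, meta = tsv)
  write_genealogies(ds$tree, nwk)
  invisible(c(fasta = fa, meta = tsv, tree = nwk))
}

#' Hand-built genealogy fixtures with known statistic values
#'
#' A deterministic set of small Newick trees shipped with the package,
#' each with its largest ancient-exclusive clade size recorded at fixture
#' build time (the randomized 12-tip batch was scored by exhaustive
#' subset enumeration).
#'
#' @return A named list of `genealogy` objects; the expected statistic values
#'   (columns `max_exclusive`, `pooled_exclusive`) are in
#'   `attr(, "expected")`.
#' @export
fixture_genealogies <- function() {
  path <- system.file("extdata", "fixture_genealogies.tsv",
                      package = "serialcoal", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  trees <- lapply(tab$newick, function(s) as_genealogy(ape::read.tree(text = s)))
  names(trees) <- tab$name
  attr(trees, "expected") <- tab[, c("name", "max_exclusive", "pooled_exclusive")]
  trees
}
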