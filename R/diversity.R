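#' Aligned DNA sequences with sample metadata
#'
#' A light container for pre-aligned, equal-length DNA sequences (alphabet
#' `A C G T N -`) with one id, epoch tag (`modern`/`ancient`) and optional
#' region tag per sequence. The region tag supports metadata-driven
#' geographic subsetting (e.g. excluding samples collected north of Mexico).
#'
#' @param sequences character vector of equal-length sequences.
#' @param ids unique sample identifiers (defaults to the names of
#'   `sequences`).
#' @param epoch `"modern"` or `"ancient"`, recycled if length 1.
#' @param region optional region tag, recycled if length 1.
#' @return An object of class `dna_alignment` with elements `seq` (named,
#'   uppercase) and `meta` (data frame `id`, `epoch`, `region`).
#' @export
dna_alignment <- function(sequences, ids = names(sequences),
                          epoch = "modern", region = NA_character_) {
  if (!is.character(sequences) || !length(sequences))
    stop("sequences must be a non-empty character vector")
  if (is.null(ids)) ids <- paste0("s", seq_along(sequences))
  if (anyDuplicated(ids) || anyNA(ids)) stop("sequence ids must be unique")
  len <- unique(nchar(sequences))
  if (length(len) != 1)
    stop("all sequences must have the same length (got lengths ",
         paste(len, collapse = ", "), ")")
  seqs <- toupper(sequences)
  if (any(grepl("[^ACGTN-]", seqs)))
    stop("sequences may only contain A, C, G, T, N and -")
  epoch <- rep_len(epoch, length(seqs))
  if (any(!epoch %in% c("modern", "ancient")))
    stop("epoch must be 'modern' or 'ancient'")
  region <- rep_len(region, length(seqs))
  names(seqs) <- ids
  structure(list(seq = seqs,
                 meta = data.frame(id = ids, epoch = epoch, region = region,
                                   stringsAsFactors = FALSE)),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("<dna_alignment>", length(x$seq), "sequences x", nchar(x$seq[1]),
      "sites (", sum(x$meta$epoch == "modern"), "modern,",
      sum(x$meta$epoch == "ancient"), "ancient )\n")
  invisible(x)
}

#' @export
length.dna_alignment <- function(x) length(x$seq)

#' Read an alignment from FASTA (plus optional metadata sidecar)
#'
#' The FASTA may be wrapped or single-line. The sidecar is a TSV with columns
#' `id`, `epoch` and optionally `region`; sequences without metadata default
#' to epoch `"modern"`.
#'
#' @param fasta path to a FASTA file.
#' @param meta optional path to a TSV metadata file.
#' @return A [dna_alignment()].
#' @export
read_fasta_alignment <- function(fasta, meta = NULL) {
  dn <- ape::read.FASTA(fasta)
  seqs <- vapply(as.character(dn), paste, "", collapse = "")
  ids <- names(dn)
  epoch <- rep("modern", length(ids))
  region <- rep(NA_character_, length(ids))
  if (!is.null(meta)) {
    md <- utils::read.delim(meta, stringsAsFactors = FALSE)
    if (!all(c("id", "epoch") %in% names(md)))
      stop("metadata must have columns 'id' and 'epoch'")
    hit <- match(ids, md$id)
    if (anyNA(hit)) stop("metadata is missing ids: ",
                         paste(ids[is.na(hit)], collapse = ", "))
    epoch <- md$epoch[hit]
    if ("region" %in% names(md)) region <- md$region[hit]
  }
  dna_alignment(seqs, ids = ids, epoch = epoch, region = region)
}

#' Write an alignment to FASTA (plus optional metadata sidecar)
#'
#' @param aln a [dna_alignment()].
#' @param fasta output FASTA path (single-line records).
#' @param meta optional output TSV path for the `id`/`epoch`/`region` table.
#' @return `fasta`, invisibly.
#' @export
write_fasta_alignment <- function(aln, fasta, meta = NULL) {
  stopifnot(inherits(aln, "dna_alignment"))
  writeLines(paste0(">", names(aln$seq), "\n", unname(aln$seq)), fasta)
  if (!is.null(meta))
    utils::write.table(aln$meta, meta, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(fasta)
}

#' Subset an alignment by metadata
#'
#' @param aln a [dna_alignment()].
#' @param keep logical or integer index over sequences, or `NULL`.
#' @param epoch optional epoch to keep.
#' @param exclude_region optional region tags to drop (metadata filter for
#'   geographic subsetting).
#' @return The filtered [dna_alignment()].
#' @export
subset_alignment <- function(aln, keep = NULL, epoch = NULL,
                             exclude_region = NULL) {
  stopifnot(inherits(aln, "dna_alignment"))
  sel <- rep(TRUE, length(aln$seq))
  if (!is.null(keep)) sel <- sel & seq_along(aln$seq) %in% seq_along(aln$seq)[keep]
  if (!is.null(epoch)) sel <- sel & aln$meta$epoch %in% epoch
  if (!is.null(exclude_region))
    sel <- sel & !(aln$meta$region %in% exclude_region)
  if (!any(sel)) stop("no sequences left after subsetting")
  dna_alignment(aln$seq[sel], ids = aln$meta$id[sel],
                epoch = aln$meta$epoch[sel], region = aln$meta$region[sel])
}

#' Collapse an alignment into haplotypes
#'
#' Groups sequences by exact (uppercased) string identity, in order of first
#' occurrence, and flags each haplotype as novel when it is absent from a
#' reference panel of previously described haplotype strings. `N` is treated
#' as a literal character (with a warning), so sequences differing only by
#' missing data are distinct haplotypes.
#'
#' @param aln a [dna_alignment()].
#' @param reference character vector of known haplotype sequences.
#' @return A `haplotype_table` (data frame): `haplotype`, `sequence`,
#'   `count`, `novel`, with member ids per haplotype in `attr(, "members")`.
#' @export
collapse_haplotypes <- function(aln, reference = character()) {
  stopifnot(inherits(aln, "dna_alignment"))
  seqs <- aln$seq
  if (any(grepl("N", seqs, fixed = TRUE)))
    warning("sequences contain N; treated as a literal character for haplotype identity")
  hap <- seqs[!duplicated(seqs)]
  idx <- match(seqs, hap)
  counts <- tabulate(idx, nbins = length(hap))
  members <- split(aln$meta$id, factor(idx, levels = seq_along(hap)))
  out <- data.frame(haplotype = paste0("H", seq_along(hap)),
                    sequence = unname(hap), count = counts,
                    novel = !(hap %in% toupper(reference)),
                    row.names = NULL, stringsAsFactors = FALSE)
  names(members) <- out$haplotype
  attr(out, "members") <- members
  class(out) <- c("haplotype_table", "data.frame")
  out
}

#' Novel-haplotype summary
#'
#' @param tab a `haplotype_table`.
#' @return List with `n_haplotypes`, `n_novel` and `percent_novel`
#'   (one decimal, e.g. 23 novel of 40 gives 57.5).
#' @export
novel_fraction <- function(tab) {
  stopifnot(inherits(tab, "haplotype_table"))
  n <- nrow(tab)
  nn <- sum(tab$novel)
  list(n_haplotypes = n, n_novel = nn,
       percent_novel = round(100 * nn / n, 1))
}

#' Express a count as a percentage
#'
#' @param count,total non-negative numbers, `total > 0`.
#' @param digits decimal places (default 0, i.e. 8 of 13 gives 62).
#' @return `round(100 * count / total, digits)`.
#' @export
percent <- function(count, total, digits = 0) {
  stopifnot(total > 0, count >= 0)
  round(100 * count / total, digits)
}

#' Nucleotide diversity per site
#'
#' The average proportion of differing sites over all unordered sequence
#' pairs. Under `deletion = "complete"` (the default) every column containing
#' a gap or an ambiguous base in any sequence is removed before comparison;
#' `"pairwise"` drops such sites per pair instead.
#'
#' @param aln a [dna_alignment()] with at least two sequences.
#' @param deletion `"complete"` or `"pairwise"` treatment of gap/N columns.
#' @return Nucleotide diversity per site, with the number of sites used as
#'   attribute `sites_used` (`NA` for pairwise deletion).
#' @examples
#' a <- dna_alignment(c(s1 = "ACGT", s2 = "ACGA"))
#' nucleotide_diversity(a) # 0.25
#' @export
nucleotide_diversity <- function(aln, deletion = c("complete", "pairwise")) {
  stopifnot(inherits(aln, "dna_alignment"))
  deletion <- match.arg(deletion)
  if (length(aln$seq) < 2)
    stop("nucleotide diversity needs at least 2 sequences")
  mat <- do.call(rbind, strsplit(tolower(aln$seq), ""))
  rownames(mat) <- aln$meta$id
  if (deletion == "complete") {
    good <- colSums(matrix(mat %in% c("a", "c", "g", "t"), nrow(mat))) == nrow(mat)
    if (!any(good)) stop("no usable sites after complete deletion")
    mat <- mat[, good, drop = FALSE]
    sites <- sum(good)
  } else {
    sites <- NA_integer_
  }
  d <- ape::dist.dna(ape::as.DNAbin(mat), model = "raw",
                     pairwise.deletion = (deletion == "pairwise"))
  theta <- mean(d)
  if (!is.finite(theta)) stop("no usable sites in some pair")
  structure(theta, sites_used = sites)
}

#' Effective population size from nucleotide diversity
#'
#' For a haploid, maternally inherited locus the expected nucleotide
#' diversity is `theta_pi = 2 * Ne * mu`, so `Ne = theta_pi / (2 * mu)`.
#' The default mutation rate, 2.13e-7 per site per generation, is the
#' conservative dog control-region calibration (wolf-coyote divergence at
#' 2 Mya).
#'
#' @param theta_pi non-negative per-site nucleotide diversity.
#' @param mu positive mutation rate per site per generation.
#' @return The effective size estimate `theta_pi / (2 * mu)` (unrounded).
#' @examples
#' effective_size_from_diversity(0.017) # ~39906, displays as 40000
#' @seealso [display_ne()]
#' @export
effective_size_from_diversity <- function(theta_pi, mu = 2.13e-7) {
  if (!is.numeric(mu) || any(mu <= 0)) stop("mu must be positive")
  if (!is.numeric(theta_pi) || any(theta_pi < 0))
    stop("theta_pi must be non-negative")
  as.numeric(theta_pi) / (2 * mu)
}

#' Display rounding for effective sizes
#'
#' Reported effective sizes are conventionally rounded to the nearest
#' thousand (0.017 diversity gives 39,906, displayed as 40,000).
#'
#' @param ne numeric effective size(s).
#' @return `ne` rounded to the nearest 1000.
#' @export
display_ne <- function(ne) round(ne / 1000) * 1000

#' Diversity-based effective-size estimate for an alignment
#'
#' Bundles [nucleotide_diversity()] and [effective_size_from_diversity()].
#'
#' @inheritParams nucleotide_diversity
#' @param mu mutation rate per site per generation.
#' @return A `diversity_estimate`: `theta_pi`, `mu`, `ne_estimate`,
#'   `ne_display`, `sites_used`, `n_sequences`.
#' @export
diversity_estimate <- function(aln, mu = 2.13e-7,
                               deletion = c("complete", "pairwise")) {
  theta <- nucleotide_diversity(aln, deletion)
  ne <- effective_size_from_diversity(as.numeric(theta), mu)
  structure(list(theta_pi = as.numeric(theta), mu = mu, ne_estimate = ne,
                 ne_display = display_ne(ne),
                 sites_used = attr(theta, "sites_used"),
                 n_sequences = length(aln$seq)),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("<diversity_estimate> theta_pi = %.4g over %s sites (n = %d)\n",
              x$theta_pi, format(x$sites_used), x$n_sequences))
  cat(sprintf("  Ne = theta_pi / (2 mu) = %.0f (displayed %s) at mu = %.3g\n",
              x$ne_estimate, format(x$ne_display, big.mark = ","), x$mu))
  invisible(x)
}
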