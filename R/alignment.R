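#' Multi-gene alignment input and site compression
#'
#' Genes are read one file per gene (FASTA or sequential PHYLIP), encoded
#' over the 5-letter code alphabet {A,C,G,T,unknown} = {0,1,2,3,4}, and
#' full-site compressed: duplicate alignment columns are collapsed to one
#' column carrying a repeat weight.  This classic compression is the
#' baseline on top of which the per-node subtree pattern compression of
#' the likelihood engine operates.
#'
#' @name alignment_io
NULL

new_gene_alignment <- function(name, taxa, seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("gene '", name, "': ragged alignment rows")
  if (anyDuplicated(taxa)) stop("gene '", name, "': duplicate taxa")
  structure(list(name = name, taxa = as.character(taxa),
                 seqs = toupper(as.character(seqs)), length = lens[[1]]),
            class = "gene_alignment")
}

#' Read one or more gene alignments
#'
#' @param paths character vector of file paths, one gene per file.
#' @param format `"fasta"` or `"phylip"` (sequential).
#' @return list of `gene_alignment` objects (fields: name, taxa, seqs,
#'   length); gene names are the file base names.
#' @export
read_alignments <- function(paths, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  lapply(paths, function(p) {
    if (file.size(p) == 0) stop("empty alignment file: ", p)
    x <- ape::read.dna(p, format = if (format == "fasta") "fasta"
                                   else "sequential",
                       as.character = TRUE, as.matrix = TRUE)
    seqs <- apply(x, 1L, paste0, collapse = "")
    new_gene_alignment(sub("\\.[^.]*$", "", basename(p)),
                       rownames(x), unname(seqs))
  })
}

#' Write a gene alignment as FASTA
#' @param aln a `gene_alignment`.
#' @param path output path.
#' @export
write_alignment_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$taxa)) {
    writeLines(paste0(">", aln$taxa[i]), con)
    writeLines(aln$seqs[i], con)
  }
  invisible(path)
}

# A,C,G,T -> 0..3; everything else (gaps, N, IUPAC ambiguity, U->T aside) -> 4
.code_lookup <- local({
  lk <- rep(4L, 256)
  for (pair in list(c("A", 0L), c("C", 1L), c("G", 2L), c("T", 3L),
                    c("U", 3L))) {
    lk[utf8ToInt(pair[[1]]) + 1L] <- as.integer(pair[[2]])
    lk[utf8ToInt(tolower(pair[[1]])) + 1L] <- as.integer(pair[[2]])
  }
  lk
})

#' Encode a gene over the 5-letter code alphabet
#'
#' Rows are laid out in the tree's leaf order; tree leaves absent from the
#' gene become all-unknown rows (an unknown contributes a factor of one to
#' every partial likelihood, so this is equivalent to pruning the taxon
#' from the gene).
#'
#' @param aln a `gene_alignment`.
#' @param tree_leaves character vector of all tree leaf labels, in tree
#'   leaf order.
#' @return an `encoded_gene`: list with `codes` (integer matrix
#'   leaf x site, values 0..4), `name`, and empty compression slots
#'   (`kept_sites`, `site_weights`) until [full_site_compress()] runs.
#' @export
encode_gene <- function(aln, tree_leaves) {
  missing_in_tree <- setdiff(aln$taxa, tree_leaves)
  if (length(missing_in_tree))
    stop("gene '", aln$name, "' has taxa not in the tree: ",
         paste(missing_in_tree, collapse = ", "))
  codes <- matrix(4L, nrow = length(tree_leaves), ncol = aln$length,
                  dimnames = list(tree_leaves, NULL))
  for (i in seq_along(aln$taxa)) {
    codes[aln$taxa[i], ] <- .code_lookup[utf8ToInt(aln$seqs[i]) + 1L]
  }
  structure(list(name = aln$name, codes = codes, n_sites = aln$length,
                 kept_sites = NULL, site_weights = NULL),
            class = "encoded_gene")
}

#' Classic full-site compression
#'
#' Collapses duplicate alignment columns; the first occurrence of each
#' pattern is kept (original order preserved) with a weight equal to its
#' multiplicity.  `sum(site_weights)` always equals the original length.
#'
#' @param enc an `encoded_gene` from [encode_gene()].
#' @return the `encoded_gene` with `codes` reduced to unique columns and
#'   `kept_sites` / `site_weights` filled.
#' @export
full_site_compress <- function(enc) {
  s <- ncol(enc$codes)
  key <- apply(enc$codes, 2L, paste0, collapse = "")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  w <- tabulate(grp, nbins = sum(first))
  enc$kept_sites <- which(first)
  enc$site_weights <- w
  enc$codes <- enc$codes[, first, drop = FALSE]
  stopifnot(sum(w) == s)
  enc
}

# empirical base frequencies over all genes (unknown codes ignored);
# uniform fallback when a gene set is all-unknown
empirical_base_freqs <- function(encs) {
  cnt <- numeric(4)
  for (e in encs) {
    w <- if (is.null(e$site_weights)) rep(1L, ncol(e$codes)) else e$site_weights
    for (b in 0:3) cnt[b + 1] <- cnt[b + 1] +
        sum((e$codes == b) %*% w)
  }
  if (sum(cnt) == 0) return(rep(0.25, 4))
  cnt / sum(cnt)
}
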