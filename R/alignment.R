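# Alignments are stored as integer state matrices (taxa x sites, values
# 1..S, NA for gaps/ambiguities, which the likelihood marginalizes as fully
# uncertain states).

NT_STATES <- c("a", "c", "g", "t")
NT_AMBIG <- c("r", "y", "s", "w", "k", "m", "b", "d", "h", "v", "n", "-", "?", ".", "u", "x")
AA_STATES <- c("a", "r", "n", "d", "c", "q", "e", "g", "h", "i",
               "l", "k", "m", "f", "p", "s", "t", "w", "y", "v")
AA_AMBIG <- c("b", "z", "j", "x", "-", "?", "*", ".")

#' Construct an alignment from a character matrix
#'
#' @param x character matrix (taxa x sites) of residues.
#' @param taxa taxon labels (unique).
#' @param alphabet `"nt"` or `"aa"`.
#' @export
alignment <- function(x, taxa = rownames(x), alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (is.null(taxa)) stop("taxon labels required")
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  states <- if (alphabet == "nt") NT_STATES else AA_STATES
  ambig <- if (alphabet == "nt") NT_AMBIG else AA_AMBIG
  xl <- tolower(x)
  bad <- setdiff(unique(as.vector(xl)), c(states, ambig))
  if (length(bad)) stop("unknown symbols outside declared alphabet: ",
                        paste(bad, collapse = " "))
  m <- matrix(match(xl, states), nrow = nrow(x))
  rownames(m) <- taxa
  structure(list(taxa = taxa, x = m, alphabet = alphabet,
                 n_sites = ncol(m)),
            class = "chrono_alignment")
}

#' @export
print.chrono_alignment <- function(x, ...) {
  cat("alignment:", length(x$taxa), "taxa x", x$n_sites, "sites (",
      x$alphabet, ")\n")
  invisible(x)
}

#' Read a sequence alignment
#'
#' FASTA and sequential/relaxed PHYLIP are supported; the two encodings of
#' the same data yield identical alignments. Rows must all have the same
#' length; gaps and ambiguity codes are flagged and treated as missing.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"`.
#' @param alphabet `"nt"` or `"aa"`.
#' @return a [alignment] object, taxa in file order.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip"),
                           alphabet = c("nt", "aa")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    seqs <- ape::read.FASTA(path, type = if (alphabet == "nt") "DNA" else "AA")
    if (length(seqs) == 0) stop("no sequences in ", path)
    lens <- lengths(seqs)
    if (length(unique(lens)) != 1)
      stop("unequal lengths: sequences range ", min(lens), "-", max(lens))
    m <- do.call(rbind, as.character(seqs))
    rownames(m) <- names(seqs)
  } else {
    ph <- phangorn::read.phyDat(path, format = "phylip",
                                type = if (alphabet == "nt") "DNA" else "AA")
    m <- as.character(ph)
  }
  alignment(m, taxa = rownames(m), alphabet = alphabet)
}

#' Write an alignment
#'
#' @param aln a [alignment].
#' @param path output path.
#' @param format `"fasta"` or `"phylip"`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  states <- if (aln$alphabet == "nt") NT_STATES else AA_STATES
  chars <- matrix(toupper(states)[aln$x], nrow = nrow(aln$x))
  chars[is.na(chars)] <- "-"
  seqs <- apply(chars, 1, paste, collapse = "")
  if (format == "fasta") {
    writeLines(as.vector(rbind(paste0(">", aln$taxa), seqs)), path)
  } else {
    writeLines(c(paste(length(aln$taxa), aln$n_sites),
                 paste(formatC(aln$taxa, width = 10, flag = "-"), seqs)), path)
  }
  invisible(path)
}

# site-pattern compression for the likelihood kernels
aln_patterns <- function(aln) {
  key <- apply(aln$x, 2, paste, collapse = ",")
  idx <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[idx])))
  list(tipstates = aln$x[, idx, drop = FALSE], weights = w)
}

# empirical state frequencies (missing ignored), with a pseudocount so no
# frequency is exactly zero
empirical_freqs <- function(aln) {
  S <- if (aln$alphabet == "nt") 4L else 20L
  tab <- tabulate(aln$x[!is.na(aln$x)], nbins = S) + 0.5
  tab / sum(tab)
}

# subset and reorder taxa
subset_alignment <- function(aln, taxa) {
  keep <- match(taxa, aln$taxa)
  if (anyNA(keep)) stop("taxa not in alignment: ",
                        paste(taxa[is.na(keep)], collapse = ", "))
  structure(list(taxa = aln$taxa[keep], x = aln$x[keep, , drop = FALSE],
                 alphabet = aln$alphabet, n_sites = aln$n_sites),
            class = "chrono_alignment")
}

#' Concatenate gene alignments
#'
#' Genes may cover different taxon subsets; absent taxa are filled with
#' missing states, which the likelihood marginalizes.
#'
#' @param genes list of [alignment] objects over a shared alphabet.
#' @export
concat_alignments <- function(genes) {
  stopifnot(length(genes) >= 1)
  ab <- unique(vapply(genes, function(g) g$alphabet, ""))
  if (length(ab) != 1) stop("mixed alphabets")
  taxa <- unique(unlist(lapply(genes, function(g) g$taxa)))
  blocks <- lapply(genes, function(g) {
    m <- matrix(NA_integer_, length(taxa), g$n_sites)
    m[match(g$taxa, taxa), ] <- g$x
    m
  })
  x <- do.call(cbind, blocks)
  rownames(x) <- taxa
  structure(list(taxa = taxa, x = x, alphabet = ab, n_sites = ncol(x)),
            class = "chrono_alignment")
}
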