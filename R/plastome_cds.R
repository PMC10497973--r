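# Plastid CDS utilities: pseudogene classification (intact / premature
# stop / large deletion), the 50%-gap alignment column filter, and
# supermatrix concatenation with a partition table.

STOP_CODONS <- c("TAA", "TAG", "TGA")  # translation table 11 (plastid)

check_nucleotides <- function(seq, what, allow_gap = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop(what, " sequence is empty")
  pat <- if (allow_gap) "^[ACGTNacgtn-]+$" else "^[ACGTNacgtn]+$"
  if (!grepl(pat, seq))
    stop(what, " sequence contains non-nucleotide characters")
  toupper(seq)
}

#' Classify a plastid CDS as intact, premature stop, or large deletion
#'
#' Decision rule: a query shorter than `deletion_threshold` times the
#' reference CDS length is a `large_deletion`; otherwise the query is
#' scanned codon-by-codon in frame 1 and a stop codon (TAA/TAG/TGA,
#' translation table 11) strictly before the final codon makes it a
#' `premature_stop`; else `intact`. A missing stop at the final codon is
#' tolerated (edge-trimmed annotations). Queries must be ungapped
#' extractions; codons containing N are never called as stops.
#'
#' @param query Ungapped nucleotide sequence of the gene in one sample.
#' @param reference Reference CDS; length must be a positive multiple
#'   of 3.
#' @param deletion_threshold Fraction of the reference length below which
#'   the gene is called a large deletion (default 0.5).
#' @param gene,sample Optional identifiers carried into the result.
#' @return An object of class `cds_status`: `gene`, `sample`, `status`
#'   (one of `"intact"`, `"premature_stop"`, `"large_deletion"`) and
#'   `detail` (1-based codon index of the first premature stop, or the
#'   query/reference length fraction for a deletion, else `NA`).
#' @examples
#' classify_cds("ATGAAATAA", "ATGAAATAA")$status          # intact
#' classify_cds("ATGTAAAAA", "ATGAAATAA")$status          # premature_stop
#' @export
classify_cds <- function(query, reference, deletion_threshold = 0.5,
                         gene = NA_character_, sample = NA_character_) {
  query <- check_nucleotides(query, "query")
  reference <- check_nucleotides(reference, "reference")
  if (nchar(reference) %% 3L != 0L)
    stop("reference length must be a positive multiple of 3")
  frac <- nchar(query) / nchar(reference)
  if (nchar(query) < deletion_threshold * nchar(reference))
    return(new_cds_status(gene, sample, "large_deletion", frac))
  n_codons <- nchar(query) %/% 3L
  if (n_codons >= 2L) {
    starts <- seq(1L, by = 3L, length.out = n_codons - 1L)
    codons <- substring(query, starts, starts + 2L)
    hit <- which(codons %in% STOP_CODONS)
    if (length(hit))
      return(new_cds_status(gene, sample, "premature_stop", hit[1L]))
  }
  new_cds_status(gene, sample, "intact", NA_real_)
}

new_cds_status <- function(gene, sample, status, detail) {
  structure(list(gene = gene, sample = sample, status = status,
                 detail = detail),
            class = "cds_status")
}

#' @export
print.cds_status <- function(x, ...) {
  extra <- switch(x$status,
    premature_stop = sprintf(" (first stop at codon %d)", as.integer(x$detail)),
    large_deletion = sprintf(" (%.0f%% of reference length)", 100 * x$detail),
    "")
  cat(sprintf("<cds_status %s/%s: %s%s>\n", x$gene, x$sample, x$status, extra))
  invisible(x)
}

#' Classify a set of genes across samples
#'
#' @param queries Named list: one element per gene, each a named
#'   character vector of per-sample ungapped CDS sequences.
#' @param references Named character vector of reference CDS, one per
#'   gene in `queries`.
#' @param deletion_threshold Passed to [classify_cds()].
#' @return A long-format data frame (`gene`, `sample`, `status`,
#'   `detail`), one row per gene/sample pair.
#' @export
classify_cds_set <- function(queries, references, deletion_threshold = 0.5) {
  stopifnot(is.list(queries), !is.null(names(queries)))
  missing_ref <- setdiff(names(queries), names(references))
  if (length(missing_ref))
    stop("no reference for gene(s): ", paste(missing_ref, collapse = ", "))
  rows <- list()
  for (g in names(queries)) {
    for (s in names(queries[[g]])) {
      st <- classify_cds(queries[[g]][[s]], references[[g]],
                         deletion_threshold, gene = g, sample = s)
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, sample = s, status = st$status,
                   detail = st$detail, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a genes x samples status matrix as TSV
#'
#' Mirrors the gene-status figure convention: one row per gene, one
#' column per sample, cell values `intact` / `premature_stop` /
#' `large_deletion` (or `NA` if unscanned).
#'
#' @param status_df Output of [classify_cds_set()].
#' @param path Output TSV path.
#' @export
write_status_matrix <- function(status_df, path) {
  genes <- unique(status_df$gene)
  samples <- unique(status_df$sample)
  m <- matrix(NA_character_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(status_df$gene, genes), match(status_df$sample, samples))] <-
    status_df$status
  df <- data.frame(gene = genes, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an alignment object
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   over `A,C,G,T,N,-` (case-insensitive; stored uppercase).
#' @param gene Gene name recorded as the provenance of every column.
#' @return An object of class `cds_alignment` with fields `seqs` and
#'   `provenance` (data frame `gene`, `column`: source gene and 1-based
#'   source column of each alignment column).
#' @export
alignment <- function(seqs, gene = NA_character_) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named by sample")
  if (anyDuplicated(names(seqs))) stop("duplicate sample names")
  seqs <- vapply(seqs, check_nucleotides, character(1), what = "aligned",
                 allow_gap = TRUE)
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("aligned sequences must have equal length")
  structure(list(seqs = seqs,
                 provenance = data.frame(
                   gene = rep(gene, len),
                   column = seq_len(len))),
            class = "cds_alignment")
}

#' @export
print.cds_alignment <- function(x, ...) {
  cat(sprintf("<cds_alignment: %d samples x %d columns (%d gene(s))>\n",
              length(x$seqs), nrow(x$provenance),
              length(unique(x$provenance$gene))))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path FASTA file of equal-length sequences.
#' @param gene Gene name for column provenance (defaults to the file name
#'   without extension).
#' @return A `cds_alignment`.
#' @export
read_fasta_alignment <- function(path, gene = NULL) {
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(path))
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
  alignment(setNames(toupper(seqs), names(dna)), gene = gene)
}

#' Write an alignment (or any named sequence set) as FASTA
#'
#' @param x A `cds_alignment` or named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "cds_alignment")) x$seqs else x
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
}

#' Filter alignment columns by gap fraction
#'
#' Removes every column in which the fraction of gap characters (`-`)
#' across samples is greater than or equal to `max_gap_fraction`; the
#' published rule "gaps in 50% or more of the samples" is inclusive, so a
#' column with exactly half gaps is removed at the default threshold.
#' Column provenance is carried through; row order is preserved.
#'
#' @param aln A `cds_alignment`.
#' @param max_gap_fraction Inclusive gap-fraction threshold (default 0.5).
#' @return The filtered `cds_alignment` (possibly with zero columns).
#' @export
filter_alignment_columns <- function(aln, max_gap_fraction = 0.5) {
  stopifnot(inherits(aln, "cds_alignment"))
  m <- alignment_matrix(aln)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac < max_gap_fraction
  out <- aln
  out$seqs <- setNames(
    vapply(seq_len(nrow(m)),
           function(i) paste(m[i, keep, drop = FALSE], collapse = ""),
           character(1)),
    names(aln$seqs))
  out$provenance <- aln$provenance[keep, , drop = FALSE]
  rownames(out$provenance) <- NULL
  out
}

#' Concatenate gene alignments into a supermatrix
#'
#' Gene blocks are concatenated in list order. Samples missing from a
#' gene are padded with all-gap rows (and reported via a message). The
#' partition table gives 1-based inclusive column ranges per gene, the
#' convention of RAxML/IQ-Tree partition files.
#'
#' @param gene_alignments Named list of `cds_alignment`s (names are the
#'   gene names; duplicate names are an error).
#' @return A list with `alignment` (the supermatrix `cds_alignment`,
#'   per-column provenance preserved) and `partitions` (data frame
#'   `gene`, `start`, `end`).
#' @export
concatenate_alignments <- function(gene_alignments) {
  stopifnot(is.list(gene_alignments), length(gene_alignments) >= 1L)
  genes <- names(gene_alignments)
  if (is.null(genes) || any(!nzchar(genes)))
    stop("gene alignments must be named")
  if (anyDuplicated(genes))
    stop("duplicate gene names: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  samples <- unique(unlist(lapply(gene_alignments, function(a) names(a$seqs))))
  blocks <- vector("list", length(gene_alignments))
  prov <- vector("list", length(gene_alignments))
  starts <- integer(length(gene_alignments))
  ends <- integer(length(gene_alignments))
  pos <- 0L
  for (i in seq_along(gene_alignments)) {
    a <- gene_alignments[[i]]
    stopifnot(inherits(a, "cds_alignment"))
    len <- nrow(a$provenance)
    absent <- setdiff(samples, names(a$seqs))
    if (length(absent))
      message(sprintf("gene %s: padding %d absent sample(s) with gaps",
                      genes[i], length(absent)))
    block <- setNames(rep(strrep("-", len), length(samples)), samples)
    block[names(a$seqs)] <- a$seqs
    blocks[[i]] <- block
    p <- a$provenance
    p$gene <- rep(genes[i], len)
    prov[[i]] <- p
    starts[i] <- pos + 1L
    ends[i] <- pos + len
    pos <- pos + len
  }
  seqs <- setNames(
    vapply(samples,
           function(s) paste(vapply(blocks, `[[`, character(1), s),
                             collapse = ""),
           character(1)),
    samples)
  super <- structure(list(seqs = seqs, provenance = do.call(rbind, prov)),
                     class = "cds_alignment")
  rownames(super$provenance) <- NULL
  list(alignment = super,
       partitions = data.frame(gene = genes, start = starts, end = ends))
}

#' Write a RAxML-style partition file
#'
#' One line per gene: `DNA, <gene> = <start>-<end>`.
#'
#' @param partitions Partition data frame from
#'   [concatenate_alignments()].
#' @param path Output path.
#' @export
write_partitions <- function(partitions, path) {
  writeLines(sprintf("DNA, %s = %d-%d", partitions$gene,
                     partitions$start, partitions$end), path)
  invisible(path)
}
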