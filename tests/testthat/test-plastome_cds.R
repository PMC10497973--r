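test_that("classify_cds applies the deletion / stop / intact rule", {
  ref <- paste0(random_orf(19, seed = 1), "TAA")   # 20 codons, ends in stop

  expect_equal(classify_cds(ref, ref)$status, "intact")

  # codon 5 mutated to TAA: premature stop at codon 5
  q <- replace_codon(ref, 5, "TAA")
  st <- classify_cds(q, ref)
  expect_equal(st$status, "premature_stop")
  expect_equal(st$detail, 5)

  # first stop wins
  q2 <- replace_codon(q, 12, "TGA")
  expect_equal(classify_cds(q2, ref)$detail, 5)

  # 40% of reference length: large deletion, detail = fraction
  q3 <- substr(ref, 1, 24)   # 8 of 20 codons
  st3 <- classify_cds(q3, ref)
  expect_equal(st3$status, "large_deletion")
  expect_equal(st3$detail, 0.4)

  # exactly at the threshold: not a deletion (rule is strictly less-than)
  q4 <- substr(ref, 1, 30)
  expect_false(classify_cds(q4, ref)$status == "large_deletion")

  # terminal stop alone never flags a gene; missing terminal stop tolerated
  expect_equal(classify_cds(substr(ref, 1, 57), ref)$status, "intact")

  # codons containing N are never stops
  qn <- replace_codon(ref, 5, "TNA")
  expect_equal(classify_cds(qn, ref)$status, "intact")

  expect_error(classify_cds("", ref), "empty")
  expect_error(classify_cds("ATGXXX", ref), "non-nucleotide")
  expect_error(classify_cds(ref, substr(ref, 1, 58)), "multiple of 3")
})

test_that("planted statuses are recovered exactly across a gene set", {
  set.seed(33)
  genes <- paste0("gene", 1:6)
  samples <- paste0("s", 1:8)
  refs <- setNames(vapply(seq_along(genes), function(i)
    paste0(random_orf(30, seed = 100 + i), "TAA"), character(1)), genes)
  truth <- list(); queries <- list()
  for (g in genes) {
    qs <- character(0)
    for (s in samples) {
      kind <- sample(c("intact", "premature_stop", "large_deletion"), 1)
      if (kind == "intact") {
        qs[s] <- refs[[g]]
        truth[[paste(g, s)]] <- list(status = "intact", detail = NA_real_)
      } else if (kind == "premature_stop") {
        pos <- sample(2:29, 1)
        qs[s] <- replace_codon(refs[[g]], pos, sample(c("TAA", "TAG", "TGA"), 1))
        truth[[paste(g, s)]] <- list(status = "premature_stop", detail = pos)
      } else {
        keep <- sample(5:40, 1)   # < 50% of 93 bases
        qs[s] <- substr(refs[[g]], 1, keep)
        truth[[paste(g, s)]] <- list(status = "large_deletion",
                                     detail = keep / nchar(refs[[g]]))
      }
    }
    queries[[g]] <- qs
  }
  df <- classify_cds_set(queries, refs)
  expect_equal(nrow(df), length(genes) * length(samples))
  for (i in seq_len(nrow(df))) {
    key <- paste(df$gene[i], df$sample[i])
    expect_equal(df$status[i], truth[[key]]$status)
    if (df$status[i] != "intact")
      expect_equal(df$detail[i], truth[[key]]$detail)
  }

  # the status matrix round-trips through TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  write_status_matrix(df, path)
  m <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  expect_equal(dim(m), c(length(genes), length(samples) + 1L))
  expect_equal(m[m$gene == "gene2", "s3"],
               df$status[df$gene == "gene2" & df$sample == "s3"])
})

test_that("gap-fraction filtering is inclusive at the threshold", {
  aln <- alignment(c(s1 = "ACGTAC",
                     s2 = "A-GTA-",
                     s3 = "A-G-AC",
                     s4 = "ACGTA-"), gene = "g1")
  # gap fractions by column: 0, 0.5, 0, 0.25, 0, 0.5
  out <- filter_alignment_columns(aln)
  expect_equal(unname(out$seqs),
               c("AGTA", "AGTA", "AG-A", "AGTA"))
  expect_equal(out$provenance$column, c(1L, 3L, 4L, 5L))

  # gap-free alignment unchanged; all-gap column removed
  clean <- alignment(c(a = "ACGT", b = "TGCA"))
  expect_identical(filter_alignment_columns(clean)$seqs, clean$seqs)
  gappy <- alignment(c(a = "A-C", b = "T-G"))
  expect_equal(nchar(filter_alignment_columns(gappy)$seqs[["a"]]), 2L)

  # threshold is a parameter: nothing reaches 0.6, so all columns survive
  expect_equal(nrow(filter_alignment_columns(aln, 0.6)$provenance), 6L)
  # and a strict-zero threshold removes every column with any gap
  expect_equal(filter_alignment_columns(aln, 0.25)$provenance$column,
               c(1L, 3L, 5L))
})

test_that("concatenation builds the supermatrix and partition table", {
  g1 <- alignment(c(s1 = "ACGTACGTA", s2 = "ACGTACGTA"), gene = "g1")   # 9
  g2 <- alignment(c(s1 = "TTTTTTTTTTTT", s2 = "GGGGGGGGGGGG"), gene = "g2") # 12
  res <- concatenate_alignments(list(g1 = g1, g2 = g2))
  expect_equal(nchar(res$alignment$seqs[["s1"]]), 21L)
  expect_equal(res$partitions,
               data.frame(gene = c("g1", "g2"), start = c(1L, 10L),
                          end = c(9L, 21L)))

  # single gene: identity
  solo <- concatenate_alignments(list(g1 = g1))
  expect_identical(solo$alignment$seqs, g1$seqs)

  # absent sample padded with gaps
  g3 <- alignment(c(s1 = "AAAA"), gene = "g3")
  expect_message(res2 <- concatenate_alignments(list(g1 = g1, g3 = g3)),
                 "padding")
  expect_equal(substr(res2$alignment$seqs[["s2"]], 10, 13), "----")

  expect_error(concatenate_alignments(list(g1 = g1, g1 = g1)), "duplicate")

  # partition file format
  path <- withr::local_tempfile(fileext = ".txt")
  write_partitions(res$partitions, path)
  expect_equal(readLines(path), c("DNA, g1 = 1-9", "DNA, g2 = 10-21"))
})

test_that("column filtering commutes with concatenation", {
  set.seed(77)
  mk <- function(gene, len) {
    seqs <- vapply(1:6, function(i)
      paste(sample(c("A", "C", "G", "T", "-"), len, replace = TRUE,
                   prob = c(0.2, 0.2, 0.2, 0.2, 0.2)), collapse = ""),
      character(1))
    alignment(setNames(seqs, paste0("s", 1:6)), gene = gene)
  }
  gs <- list(gA = mk("gA", 30), gB = mk("gB", 45))
  a <- filter_alignment_columns(concatenate_alignments(gs)$alignment)
  b <- concatenate_alignments(lapply(gs, filter_alignment_columns))$alignment
  expect_identical(a$seqs, b$seqs)
  expect_identical(a$provenance$gene, b$provenance$gene)
  expect_identical(a$provenance$column, b$provenance$column)
})

test_that("FASTA alignments round-trip through disk", {
  aln <- alignment(c(s1 = "ACGT-ACG", s2 = "ACGTTACG", s3 = "AC-TTACG"),
                   gene = "rbcL")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(aln, path)
  back <- read_fasta_alignment(path, gene = "rbcL")
  expect_identical(back$seqs, aln$seqs)
  expect_identical(back$provenance, aln$provenance)
})
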