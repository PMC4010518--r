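test_that("loaded fixture references carry the anchor at its mRNA coordinate", {
  expect_named(fix_refs, c("NM_006766.3", "NM_004380.2"))
  expect_equal(substr(ref_subseq(crebbp, 290, 290), 1, 1), "A")
  expect_equal(ref_subseq(crebbp, 290, 309), ANCHOR)
  expect_equal(ref_subseq(kat6a, 3756, 3764), "ATGCTGATG")
  expect_equal(ref_window(kat6a), c(3686L, 3764L))
  expect_equal(ref_window(crebbp), c(212L, 380L))
})

test_that("load_references validates inputs and tolerates an empty FASTA", {
  tmp <- withr::local_tempdir()
  fa <- file.path(tmp, "refs.fa")
  ann <- file.path(tmp, "ann.tsv")
  writeLines(character(0), fa)
  writeLines(paste("accession", "gene", "coord_offset", "exon_label",
                   "exon_start", "exon_end", "cds_start", "cytoband",
                   sep = "\t"), ann)
  expect_length(load_references(fa, ann), 0)

  writeLines(c(">ACC1 toy", paste(rep("ACGT", 30), collapse = "")), fa)
  expect_error(load_references(fa, ann), "ACC1")

  ok_rows <- c("ACC1\tTOY\t1\t1\t1\t50\t\t", "ACC1\tTOY\t1\t2\t51\t120\t\t")
  writeLines(c(readLines(ann)[1], ok_rows), ann)
  refs <- load_references(fa, ann)
  expect_equal(nrow(refs$ACC1$exons), 2)

  bad_rows <- c("ACC1\tTOY\t1\t1\t1\t50\t\t", "ACC1\tTOY\t1\t2\t45\t120\t\t")
  writeLines(c(readLines(ann)[1], bad_rows), ann)
  expect_error(load_references(fa, ann), "overlap")

  writeLines(c(readLines(ann)[1], "ACC1\tTOY\t1\t1\t1\tfifty\t\t"), ann)
  expect_error(load_references(fa, ann), "exon_end")
})

test_that("subseq is exact-length and concatenation reconstructs the window", {
  w <- ref_window(crebbp)
  expect_equal(ref_subseq(crebbp, w[1], w[1]), substr(crebbp$sequence, 1, 1))
  expect_error(ref_subseq(crebbp, 100, 150), "212\\.\\.380")
  set.seed(71)
  for (i in 1:25) {
    s <- sample(w[1]:w[2], 1)
    e <- sample(s:w[2], 1)
    expect_equal(nchar(ref_subseq(crebbp, s, e)), e - s + 1)
    if (e < w[2]) {
      cut <- sample(s:e, 1)
      joined <- if (cut < e) {
        paste0(ref_subseq(crebbp, s, cut), ref_subseq(crebbp, cut + 1, e))
      } else ref_subseq(crebbp, s, e)
      expect_equal(joined, ref_subseq(crebbp, s, e))
    }
  }
})

test_that("consensus from the packaged reads reproduces the shipped fixtures", {
  reads <- published_reads()
  anchored <- scan_reads(reads)
  cl <- classify_reads(anchored, fix_refs["NM_006766.3"], crebbp)

  wt <- cl$category == "WILDTYPE"
  cons <- consensus_from_anchored_reads(anchored$oriented_sequence[wt],
                                        anchored$anchor_start[wt],
                                        anchor_start = 290, side = "full")
  expect_equal(cons$coord_offset, 212)
  expect_equal(cons$sequence, crebbp$sequence)

  fus <- cl$category == "FUSION"
  up <- consensus_from_anchored_reads(anchored$oriented_sequence[fus],
                                      anchored$anchor_start[fus],
                                      anchor_start = 3765, side = "upstream")
  expect_equal(up$coord_offset, 3686)
  expect_equal(up$sequence, kat6a$sequence)

  # independent per-column counting oracle over the same reads
  seqs <- anchored$oriented_sequence[wt]
  starts <- 290L - (anchored$anchor_start[wt] - 1L)
  lo <- min(starts)
  width <- max(starts + nchar(seqs) - 1L) - lo + 1L
  counts <- matrix(0L, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1]]
    for (j in seq_along(ch)) {
      col <- starts[i] - lo + j
      if (ch[j] %in% rownames(counts)) {
        counts[ch[j], col] <- counts[ch[j], col] + 1L
      }
    }
  }
  naive <- paste(rownames(counts)[apply(counts, 2, which.max)], collapse = "")
  expect_equal(cons$sequence, naive)
})

test_that("consensus handles single reads, ties, and degenerate input", {
  one <- consensus_from_anchored_reads("GGTT", 3L, anchor_start = 100,
                                       side = "full")
  expect_equal(one$sequence, "GGTT")
  expect_equal(one$coord_offset, 98)
  expect_length(one$low_confidence, 0)

  tie <- consensus_from_anchored_reads(c("TAAA", "GAAA"), c(2L, 2L),
                                       anchor_start = 50, side = "full")
  expect_equal(substr(tie$sequence, 1, 1), "G")  # lexicographic G < T
  expect_equal(tie$low_confidence, 49L)

  expect_error(consensus_from_anchored_reads(character(0), integer(0), 1),
               "no reads")
  # N casts no vote
  n_vote <- consensus_from_anchored_reads(c("NAAA", "CAAA"), c(2L, 2L),
                                          anchor_start = 10, side = "full")
  expect_equal(substr(n_vote$sequence, 1, 1), "C")
})

test_that("consensus of error-free generated reads is idempotent", {
  set.seed(5)
  tpl <- random_dna(160)
  anchor_at <- 61L
  reads <- character(30)
  pos <- integer(30)
  for (i in 1:30) {
    s <- sample(1:55, 1)
    e <- sample((anchor_at + 25):160, 1)
    reads[i] <- substr(tpl, s, e)
    pos[i] <- anchor_at - s + 1L
  }
  cons <- consensus_from_anchored_reads(reads, pos, anchor_start = anchor_at,
                                        side = "full")
  lo <- cons$coord_offset
  expect_equal(cons$sequence,
               substr(tpl, lo, lo + nchar(cons$sequence) - 1L))
})

test_that("fusion transcript construction concatenates exact windows", {
  fus <- build_fusion_transcript(kat6a, 3764, crebbp, 290)
  expect_equal(nchar(fus), 79 + 91)
  expect_equal(attr(fus, "junction_at"), 79)
  expect_equal(substr(fus, 80, 99), ANCHOR, ignore_attr = TRUE)
  for (k in c(1, 5, 10, 20)) {
    expect_equal(substr(fus, 80 - k, 79 + k),
                 paste0(ref_subseq(kat6a, 3764 - k + 1, 3764),
                        ref_subseq(crebbp, 290, 290 + k - 1)),
                 ignore_attr = TRUE)
  }
  stub <- build_fusion_transcript(kat6a, 3686, crebbp, 290)
  expect_equal(nchar(stub), 1 + 91)
  expect_error(build_fusion_transcript(kat6a, 4000, crebbp, 290), "window")
})
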