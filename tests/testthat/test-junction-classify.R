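params_default <- classifier_params()
spec_default <- anchor_spec()

test_that("upstream flanks place on the donor reference at the breakpoint", {
  hit <- match_flank_suffix("AAGAAGAAGATGAAGAGTCAGATGATGCTGATG", kat6a)
  expect_equal(hit$end, 3764)
  expect_equal(hit$mismatches, 0)

  genomic <- "GTAAAGGTTGCTTAGTTTCTCATTTCCATTTCTGTTTAATTTCTAG"
  expect_null(match_flank_suffix(genomic, kat6a))
  expect_null(match_flank_suffix(genomic, crebbp))

  tail10 <- substr(kat6a$sequence, 70, 79)
  expect_equal(match_flank_suffix(tail10, kat6a)$end, 3764)
  expect_null(match_flank_suffix(strrep("A", 200), kat6a))
})

test_that("downstream extension handles mismatches, adapters and trailing runs", {
  # exact copy, no adapter
  exact <- ref_subseq(crebbp, 310, 347)
  r <- match_flank_prefix(exact, crebbp, 310)
  expect_equal(r[c("end", "mismatches", "adapter_clipped", "trailing_trimmed")],
               list(end = 347L, mismatches = 0L, adapter_clipped = 0L,
                    trailing_trimmed = 0L))

  # one internal substitution, no clipping
  r11 <- "TTGGAAAATGATCTTCCTGATGAGCTGATACCCAATGTAGGA"
  r <- match_flank_prefix(r11, crebbp, 310)
  expect_equal(r$end, 351)
  expect_equal(r$mismatches, 1)
  expect_equal(r$adapter_clipped, 0)

  # 5-nt adapter prefix clipped after an exact 32-base extension
  r13 <- "TTGGAAAATGATCTTCCTGATGAGCTGATACCAGATC"
  r <- match_flank_prefix(r13, crebbp, 310)
  expect_equal(r$end, 341)
  expect_equal(r$adapter_clipped, 5)
  expect_equal(r$mismatches, 0)

  # the first adapter base coincides with the reference: the longer exact
  # extension wins and the tail is a trailing-mismatch run, not adapter
  r22 <- "TTGGAAAATGATCTTCCTGATGAGCTGATACCCAGATC"
  r <- match_flank_prefix(r22, crebbp, 310)
  expect_equal(r$end, 343)
  expect_equal(r$adapter_clipped, 0)
  expect_equal(r$trailing_trimmed, 4)

  # long adapter read-through, including bases past the adapter itself
  r05 <- "TTGGAAAATGATCTTCCTGATGAGCTGATACCCAATGGAGGAGAATTAAGATCGGAAGAGCGTCGTGTAGGG"
  r <- match_flank_prefix(r05, crebbp, 310)
  expect_equal(r$end, 357)
  expect_equal(r$adapter_clipped, 24)

  # adapter clip plus a two-base trailing mismatch run before it
  r14 <- "TTGGAAAATGATCTTCCTGATGAGCTGATACCCAATGGAGGGCAGATCGGAAG"
  r <- match_flank_prefix(r14, crebbp, 310)
  expect_equal(r$end, 350)
  expect_equal(r$adapter_clipped, 10)
  expect_equal(r$trailing_trimmed, 2)

  # empty flank: the anchor alone
  r <- match_flank_prefix("", crebbp, 310)
  expect_equal(r$end, 309)
  expect_equal(r$matched, 0)
})

test_that("classification reproduces the published categories for key reads", {
  reads <- published_reads()
  anchored <- scan_reads(reads)
  cl <- classify_reads(anchored, fix_refs["NM_006766.3"], crebbp)

  expect_equal(sort(unique(cl$category)), c("FUSION", "OTHER", "WILDTYPE"))
  expect_equal(sum(cl$category == "FUSION"), 11)
  expect_equal(sum(cl$category == "WILDTYPE"), 14)
  expect_equal(sum(cl$category == "OTHER"), 1)

  r01 <- cl[cl$read_id == "read_01", ]
  expect_equal(r01$category, "WILDTYPE")
  expect_equal(c(r01$donor_start, r01$acceptor_end), c(238, 338))

  r05 <- cl[cl$read_id == "read_05", ]
  expect_equal(r05$category, "FUSION")
  expect_equal(c(r05$donor_start, r05$donor_end), c(3756, 3764))
  expect_equal(r05$adapter_clipped, 24)

  r25 <- cl[cl$read_id == "read_25", ]
  expect_equal(r25$category, "OTHER")
  expect_equal(c(r25$acceptor_start, r25$acceptor_end), c(290, 344))
})

test_that("reported spans reconstruct each read up to recorded mismatches", {
  anchored <- scan_reads(published_reads())
  cl <- classify_reads(anchored, fix_refs["NM_006766.3"], crebbp)
  for (i in which(cl$category %in% c("FUSION", "WILDTYPE"))) {
    r <- cl[i, ]
    donor_ref <- fix_refs[[r$donor_accession]]
    up_ref <- ref_subseq(donor_ref, r$donor_start, r$donor_end)
    down_ref <- ref_subseq(crebbp, r$acceptor_start, r$acceptor_end)
    read <- anchored$oriented_sequence[anchored$read_id == r$read_id]
    up_len <- r$donor_end - r$donor_start + 1L
    down_len <- r$acceptor_end - r$acceptor_start + 1L
    expect_equal(up_len + down_len + r$adapter_clipped + r$trailing_trimmed,
                 nchar(read))
    expect_equal(hamming_chars(substr(read, 1, up_len), up_ref),
                 r$upstream_mismatches)
    expect_equal(hamming_chars(substr(read, up_len + 1,
                                      up_len + down_len), down_ref),
                 r$downstream_mismatches)
  }
})

test_that("short upstream flanks are uninformative; corrupt input is fatal", {
  short_read <- paste0("ACGTA", ANCHOR, ref_subseq(crebbp, 310, 340))
  an <- data.frame(read_id = "s", orientation = "forward", anchor_start = 6L,
                   multiple_hits = FALSE, oriented_sequence = short_read,
                   stringsAsFactors = FALSE)
  cl <- classify_reads(an, fix_refs["NM_006766.3"], crebbp)
  expect_equal(cl$category, "UNINFORMATIVE")
  expect_equal(cl$acceptor_end, 340)

  an$anchor_start <- 7L
  expect_error(classify_reads(an, fix_refs["NM_006766.3"], crebbp), "corrupt")
})

test_that("wild-type/fusion ties follow the tie-break policy", {
  # a decoy donor that ends exactly like CREBBP exon 1 ties the hypotheses
  decoy <- transcript_reference("DECOY.1", "DECOY",
                                paste0("GGGTTTCCC", ref_subseq(crebbp, 280, 289)),
                                coord_offset = 1000)
  read <- paste0(ref_subseq(crebbp, 280, 289), ANCHOR,
                 ref_subseq(crebbp, 310, 340))
  an <- scan_reads(c(tie = read))
  cl <- classify_reads(an, list(decoy), crebbp)
  expect_equal(cl$category, "WILDTYPE")
  cl2 <- classify_reads(an, list(decoy), crebbp,
                        params = classifier_params(tie_break = "ambiguous"))
  expect_equal(cl2$category, "AMBIGUOUS")
})

test_that("categories partition any classified input", {
  set.seed(311)
  reads <- vapply(1:40, function(i) {
    u <- random_dna(sample(0:60, 1))
    paste0(u, ANCHOR, random_dna(101 - 20 - nchar(u)))
  }, "")
  names(reads) <- sprintf("p%02d", 1:40)
  an <- scan_reads(reads)
  cl <- classify_reads(an, fix_refs["NM_006766.3"], crebbp)
  expect_equal(nrow(cl), nrow(an))
  expect_true(all(cl$category %in% c("FUSION", "WILDTYPE", "OTHER",
                                     "UNINFORMATIVE", "AMBIGUOUS")))
  expect_equal(sum(table(cl$category)), nrow(an))
})

test_that("junction calls group fusion reads by breakpoint with support", {
  anchored <- scan_reads(published_reads())
  cl <- classify_reads(anchored, fix_refs["NM_006766.3"], crebbp)
  calls <- call_junctions(cl, fix_refs)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$donor_end, 3764)
  expect_equal(calls$acceptor_start, 290)
  expect_equal(calls$supporting_reads, 11)
  expect_equal(calls$donor_gene, "KAT6A")

  expect_equal(nrow(call_junctions(cl[cl$category == "WILDTYPE", ])), 0)

  # two planted junctions: supports aggregate per breakpoint, ordered by size
  fus2 <- build_fusion_transcript(kat6a, 3750, crebbp, 290)
  mk_read <- function(tpl, s) substr(tpl, s, s + 100)
  fus1 <- build_fusion_transcript(kat6a, 3764, crebbp, 290)
  reads <- c(a1 = mk_read(fus1, 30), a2 = mk_read(fus1, 40),
             a3 = mk_read(fus1, 50), b1 = mk_read(fus2, 30),
             b2 = mk_read(fus2, 40))
  an <- scan_reads(reads)
  cl2 <- classify_reads(an, fix_refs["NM_006766.3"], crebbp)
  calls2 <- call_junctions(cl2, fix_refs)
  expect_equal(calls2$donor_end, c(3764, 3750))
  expect_equal(calls2$supporting_reads, c(3, 2))
})

test_that("frame determination follows codon arithmetic on both sides", {
  # codon-boundary join is in frame by construction
  dref <- transcript_reference("D.1", "D", random_dna(60), coord_offset = 1,
                               cds_start = 10)
  aref <- transcript_reference("A.1", "A", random_dna(60), coord_offset = 1,
                               cds_start = 7)
  fr <- frame_check(dref, aref, donor_end = 10 + 29, acceptor_start = 7 + 27)
  expect_equal(fr$frame, "in_frame")
  expect_equal(fr$donor_codon, 10)
  expect_equal(fr$acceptor_codon, 10)

  # the published junction: in frame, last donor codon 1117, first acceptor 29
  fr <- frame_check(kat6a, crebbp, 3764, 290)
  expect_equal(fr$frame, "in_frame")
  expect_equal(fr$donor_codon, 1117)
  expect_equal(fr$acceptor_codon, 29)

  # the same donor joined inside acceptor codon 267 is out of frame
  fr2 <- frame_check(kat6a, crebbp, 3764, 1005)
  expect_equal(fr2$frame, "out_of_frame")
  expect_equal(fr2$acceptor_codon, 267)

  no_cds <- transcript_reference("N.1", "N", random_dna(30))
  expect_equal(frame_check(no_cds, crebbp, 10, 290)$frame, "unknown")
  expect_warning(out <- frame_check(dref, aref, donor_end = 5,
                                    acceptor_start = 40), "upstream")
  expect_equal(out$frame, "unknown")
})

test_that("classifier agrees with the exhaustive brute-force scorer", {
  set.seed(77)
  donor_small <- transcript_reference("DS.1", "DS", random_dna(150),
                                      coord_offset = 501)
  acc_seq <- paste0(random_dna(80), ANCHOR, random_dna(90))
  acc_small <- transcript_reference("AS.1", "AS", acc_seq, coord_offset = 101)
  sp <- anchor_spec(acceptor_accession = "AS.1", acceptor_start = 181L)
  pr <- classifier_params()
  for (case in 1:60) {
    u_kind <- sample(c("donor", "wt", "random"), 1)
    u_len <- sample(0:60, 1)
    u <- if (u_len == 0) "" else switch(
      u_kind,
      donor = substr(donor_small$sequence, 151 - u_len, 150),
      wt = substr(acc_seq, 80 - min(u_len, 80) + 1, 80),
      random = random_dna(u_len))
    if (nchar(u) > 2 && runif(1) < 0.5) {
      u <- mutate_dna(u, sample(nchar(u), sample(1:2, 1)))
    }
    d_len <- sample(0:40, 1)
    dflank <- if (d_len == 0) "" else substr(acc_seq, 101, 100 + d_len)
    if (nchar(dflank) > 2 && runif(1) < 0.4) {
      dflank <- mutate_dna(dflank, sample(nchar(dflank), 1))
    }
    if (runif(1) < 0.4) {
      dflank <- paste0(dflank, substr(pr$adapter, 1, sample(5:13, 1)))
    }
    read <- paste0(u, ANCHOR, dflank)
    an <- data.frame(read_id = "case", orientation = "forward",
                     anchor_start = nchar(u) + 1L, multiple_hits = FALSE,
                     oriented_sequence = read, stringsAsFactors = FALSE)
    got <- classify_reads(an, list(donor_small), acc_small, sp, pr)
    expect_equal(got$category,
                 oracle_classify(read, nchar(u) + 1L, list(donor_small),
                                 acc_small, sp, pr),
                 info = paste("case", case))
    want_dn <- oracle_prefix(dflank, acc_small, 181L + 20L, pr)
    if (!is.null(want_dn)) {
      expect_equal(got$acceptor_end, want_dn$end, info = paste("case", case))
      expect_equal(got$adapter_clipped, want_dn$clip,
                   info = paste("case", case))
    }
  }
})
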