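# Shared fixtures and independent oracles for the test suite.

ANCHOR <- "ATTTTGGATCATTGTTTGAC"

fix_refs <- fixture_references()
kat6a <- fix_refs[["NM_006766.3"]]
crebbp <- fix_refs[["NM_004380.2"]]

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Published per-read expectations for the packaged 26-read set: category and
# coordinate spans exactly as printed (en dash), frozen from the source table.
d <- "\u2013"
expected_read_table <- data.frame(
  read_id = sprintf("read_%02d", 1:26),
  category = c("WILDTYPE", "WILDTYPE", "FUSION", "WILDTYPE", "FUSION",
               "FUSION", "FUSION", "FUSION", "WILDTYPE", "WILDTYPE",
               "WILDTYPE", "WILDTYPE", "WILDTYPE", "FUSION", "WILDTYPE",
               "FUSION", "WILDTYPE", "WILDTYPE", "FUSION", "WILDTYPE",
               "WILDTYPE", "WILDTYPE", "FUSION", "FUSION", "OTHER",
               "FUSION"),
  donor_span = c("", "", paste0("3732", d, "3764 (exon 16)"), "",
                 paste0("3756", d, "3764 (exon 16)"),
                 paste0("3748", d, "3764 (exon 16)"),
                 paste0("3744", d, "3764 (exon 16)"),
                 paste0("3745", d, "3764 (exon 16)"), "", "", "", "", "",
                 paste0("3737", d, "3764 (exon 16)"), "",
                 paste0("3692", d, "3764 (exon 16)"), "", "",
                 paste0("3701", d, "3764 (exon 16)"), "", "", "",
                 paste0("3686", d, "3764 (exon 16)"),
                 paste0("3753", d, "3764 (exon 16)"), "",
                 paste0("3752", d, "3764 (exon 16)")),
  acceptor_span = c(
    paste0("238", d, "338 (exon 1", d, "2)"),
    paste0("272", d, "372 (exon 1", d, "2)"),
    paste0("290", d, "357 (exon 2)"),
    paste0("215", d, "315 (exon 1", d, "2)"),
    paste0("290", d, "357 (exon 2)"),
    paste0("290", d, "373 (exon 2)"),
    paste0("290", d, "369 (exon 2)"),
    paste0("290", d, "370 (exon 2)"),
    paste0("212", d, "312 (exon 1", d, "2)"),
    paste0("280", d, "380 (exon 1", d, "2)"),
    paste0("251", d, "351 (exon 1", d, "2)"),
    paste0("220", d, "320 (exon 1", d, "2)"),
    paste0("246", d, "341 (exon 1", d, "2)"),
    paste0("290", d, "350 (exon 2)"),
    paste0("247", d, "347 (exon 1", d, "2)"),
    paste0("290", d, "317 (exon 2)"),
    paste0("216", d, "316 (exon 1", d, "2)"),
    paste0("242", d, "342 (exon 1", d, "2)"),
    paste0("290", d, "326 (exon 2)"),
    paste0("247", d, "347 (exon 1", d, "2)"),
    paste0("241", d, "341 (exon 1", d, "2)"),
    paste0("247", d, "343 (exon 1", d, "2)"),
    paste0("290", d, "311 (exon 2)"),
    paste0("290", d, "359 (exon 2)"),
    paste0("290", d, "344 (exon 2)"),
    paste0("290", d, "377 (exon 2)")),
  stringsAsFactors = FALSE)
rm(d)

# --- independent oracles (naive, character-by-character) -------------------

hamming_chars <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- 0L
  for (i in seq_along(ca)) if (ca[i] != cb[i]) n <- n + 1L
  n
}

oracle_scan <- function(seqs, anchor) {
  names(seqs)[vapply(seqs, function(s) {
    found <- FALSE
    if (nchar(s) >= nchar(anchor)) {
      for (i in 1:(nchar(s) - nchar(anchor) + 1L)) {
        if (substr(s, i, i + nchar(anchor) - 1L) == anchor) { found <- TRUE; break }
      }
    }
    found
  }, TRUE)]
}

# Exhaustive suffix placement: every end position, fewest mismatches, tie to
# the largest end.
oracle_suffix <- function(flank, ref, rate, forced_end = NULL) {
  m <- nchar(flank)
  w <- ref_window(ref)
  ends <- if (is.null(forced_end)) seq(w[1] + m - 1L, w[2]) else forced_end
  ends <- ends[ends - m + 1L >= w[1] & ends <= w[2]]
  best <- NULL
  for (e in ends) {
    mm <- hamming_chars(flank, ref_subseq(ref, e - m + 1L, e))
    if (mm > ceiling(rate * m)) next
    if (is.null(best) || mm < best$mm || (mm == best$mm && e > best$end)) {
      best <- list(end = e, mm = mm)
    }
  }
  best
}

# Exhaustive downstream scoring over every adapter clip point.
oracle_prefix <- function(flank, ref, start, params) {
  len <- nchar(flank)
  if (len == 0L) {
    return(list(end = start - 1L, mm = 0L, clip = 0L, trail = 0L))
  }
  w <- ref_window(ref)
  adapter <- params$adapter
  best <- NULL
  for (i in seq_len(len + 1L)) {     # clip start; len + 1 means no clip
    kept <- i - 1L
    tail_len <- len - kept
    if (tail_len > 0L) {
      if (tail_len < params$adapter_min_overlap) next
      k <- min(nchar(adapter), tail_len)
      if (substr(flank, i, i + k - 1L) != substr(adapter, 1L, k)) next
    }
    avail <- max(0L, w[2] - start + 1L)
    cmp <- min(kept, avail)
    matched <- 0L; mm <- 0L
    if (cmp > 0L) {
      ok <- logical(cmp)
      for (j in seq_len(cmp)) {
        ok[j] <- substr(flank, j, j) ==
          substr(ref$sequence, start - w[1] + j, start - w[1] + j)
      }
      matched <- if (any(ok)) max(which(ok)) else 0L
      if (matched > 0L) mm <- sum(!ok[seq_len(matched)])
    }
    if (mm > ceiling(params$max_mismatch_rate * matched)) next
    cand <- list(end = start + matched - 1L, mm = mm, clip = len - kept,
                 trail = (cmp - matched) + (kept - cmp))
    if (is.null(best) || cand$mm < best$mm ||
        (cand$mm == best$mm && cand$end > best$end) ||
        (cand$mm == best$mm && cand$end == best$end && cand$clip > best$clip)) {
      best <- cand
    }
  }
  best
}

oracle_classify <- function(oriented, anchor_start, donor_refs, acceptor_ref,
                            spec, params) {
  alen <- nchar(spec$anchor)
  upstream <- substr(oriented, 1L, anchor_start - 1L)
  if (nchar(upstream) < params$min_upstream_flank) return("UNINFORMATIVE")
  wt <- oracle_suffix(upstream, acceptor_ref, params$max_mismatch_rate,
                      forced_end = spec$acceptor_start - 1L)
  fus <- NULL
  for (dref in donor_refs) {
    cand <- oracle_suffix(upstream, dref, params$max_mismatch_rate)
    if (is.null(cand)) next
    if (is.null(fus) || cand$mm < fus$mm ||
        (cand$mm == fus$mm && cand$end > fus$end)) fus <- cand
  }
  if (is.null(wt) && is.null(fus)) "OTHER"
  else if (is.null(fus)) "WILDTYPE"
  else if (is.null(wt)) "FUSION"
  else if (fus$mm < wt$mm) "FUSION"
  else if (fus$mm > wt$mm) "WILDTYPE"
  else if (params$tie_break == "prefer_wildtype") "WILDTYPE" else "AMBIGUOUS"
}

# Synthetic extended reference pair encoding the published in-silico PCR
# geometry (forward primer 5' end at donor coordinate 3558; reverse site
# ending at acceptor coordinate 434). These windows are synthetic stand-ins
# for the full GenBank mRNAs, which are not redistributable here; only the
# primer sites and the junction-proximal windows are faithful.
synthetic_pcr_refs <- function(seed = 4242) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  fwd <- "GAGGCCAATGCCAAGATTAGAAC"  # MOZ-3558F
  rev <- "GTTGATACTAGAGCCGCTGCCTC"  # CBP-431R
  donor_seq <- withr_seed({
    paste0(fwd, random_dna(3764 - 3558 + 1 - nchar(fwd) - 79),
           kat6a$sequence)
  })
  acceptor_seq <- paste0(crebbp$sequence, random_dna(434 - 380 - 23),
                         as.character(Biostrings::reverseComplement(
                           Biostrings::DNAString(rev))))
  donor <- transcript_reference("SYN_NM_006766.3", "KAT6A", donor_seq,
                                coord_offset = 3558,
                                exons = data.frame(label = "16", start = 3686,
                                                   end = 3764),
                                cds_start = 414, cytoband = "8p11")
  acceptor <- transcript_reference("SYN_NM_004380.2", "CREBBP", acceptor_seq,
                                   coord_offset = 212,
                                   exons = data.frame(label = c("1", "2"),
                                                      start = c(212, 290),
                                                      end = c(289, 434)),
                                   cds_start = 206, cytoband = "16p13")
  list(donor = donor, acceptor = acceptor,
       primers = primer_pair(fwd, rev, "MOZ-3558F", "CBP-431R"))
}
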