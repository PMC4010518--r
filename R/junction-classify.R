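#' Classification tolerances
#'
#' Parameters governing how the flanks of an anchored read are matched
#' against the donor and acceptor references. The defaults reproduce every
#' coordinate span of the printed 26-read set: up to 10% mismatches per
#' matched flank, Illumina TruSeq 3'-adapter stem `AGATCGGAAGAGC` recognised
#' from 5 nt of overlap, at least 6 nt of upstream flank required before a
#' read is informative, and ties between the wild-type and fusion hypotheses
#' resolved in favour of wild type (parsimony: no rearrangement).
#'
#' @param max_mismatch_rate Maximum mismatch fraction per matched flank,
#'   applied as `ceiling(rate * matched_length)`.
#' @param adapter 3' adapter sequence sequenced into on short inserts.
#' @param adapter_min_overlap Minimum adapter prefix length recognised at the
#'   read 3' end.
#' @param min_upstream_flank Minimum bases upstream of the anchor needed to
#'   classify a read (shorter reads are `UNINFORMATIVE`).
#' @param tie_break `"prefer_wildtype"` or `"ambiguous"`: what to do when the
#'   wild-type and fusion hypotheses tie on mismatches.
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(max_mismatch_rate = 0.10,
                              adapter = "AGATCGGAAGAGC",
                              adapter_min_overlap = 5L,
                              min_upstream_flank = 6L,
                              tie_break = c("prefer_wildtype", "ambiguous")) {
  tie_break <- match.arg(tie_break)
  assert_dna(adapter, "adapter")
  stopifnot(max_mismatch_rate >= 0, max_mismatch_rate < 0.5,
            adapter_min_overlap >= 3L, min_upstream_flank >= 1L)
  structure(list(max_mismatch_rate = max_mismatch_rate, adapter = adapter,
                 adapter_min_overlap = as.integer(adapter_min_overlap),
                 min_upstream_flank = as.integer(min_upstream_flank),
                 tie_break = tie_break),
            class = "classifier_params")
}

mismatch_budget <- function(params, matched_length) {
  as.integer(ceiling(params$max_mismatch_rate * matched_length))
}

#' Best suffix placement of a flank on a reference
#'
#' Finds the mRNA end coordinate `e` such that the reference bases
#' `e - |flank| + 1 .. e` match the flank with at most
#' `ceiling(max_mismatch_rate * |flank|)` mismatches, the flank lying fully
#' inside the stored window. The best placement has the fewest mismatches;
#' ties go to the largest `e`. Used for the upstream (donor-side) flank of an
#' anchored read. `N` counts as a mismatch.
#'
#' @param flank Non-empty DNA string.
#' @param ref A [transcript_reference()].
#' @param params A [classifier_params()].
#' @param forced_end Optional mRNA coordinate: only consider the placement
#'   ending exactly there (the wild-type hypothesis pins the upstream flank
#'   to the base immediately before the anchor).
#' @return `list(end, mismatches)`, or `NULL` when no placement qualifies.
#' @export
match_flank_suffix <- function(flank, ref, params = classifier_params(),
                               forced_end = NULL) {
  stopifnot(nzchar(flank))
  m <- nchar(flank)
  L <- nchar(ref$sequence)
  if (m > L) return(NULL)
  w <- ref_window(ref)
  subject <- Biostrings::DNAString(ref$sequence)
  pat <- Biostrings::DNAString(flank)
  if (!is.null(forced_end)) {
    at <- forced_end - m + 1L - w[1] + 1L # stored-sequence start position
    if (at < 1L || forced_end > w[2]) return(NULL)
    starts <- at
  } else {
    starts <- seq_len(L - m + 1L)
  }
  ed <- Biostrings::neditStartingAt(pat, subject, starting.at = starts,
                                    with.indels = FALSE, fixed = TRUE)
  ok <- ed <= mismatch_budget(params, m)
  if (!any(ok)) return(NULL)
  best_mm <- min(ed[ok])
  best_at <- max(starts[ok & ed == best_mm]) # largest end on ties
  list(end = w[1] + best_at - 1L + m - 1L, mismatches = as.integer(best_mm))
}

# All positions where the read tail can be explained as adapter: 1-based clip
# starts i such that flank[i .. i+k-1] equals the adapter prefix of length
# k = min(|adapter|, |flank| - i + 1) >= min_overlap. Bases beyond the
# adapter (read-through past the adapter) are clipped along with it.
adapter_clip_points <- function(flank, params) {
  len <- nchar(flank)
  alen <- nchar(params$adapter)
  pts <- integer(0)
  if (len >= params$adapter_min_overlap) {
    for (i in seq_len(len - params$adapter_min_overlap + 1L)) {
      k <- min(alen, len - i + 1L)
      if (substr(flank, i, i + k - 1L) == substr(params$adapter, 1L, k)) {
        pts <- c(pts, i)
      }
    }
  }
  pts
}

#' Extend the downstream flank along the acceptor reference
#'
#' Matches the read bases after the anchor against the reference from a fixed
#' start coordinate, handling Illumina 3'-adapter read-through. Every
#' qualifying adapter clip point (including "no clip") is scored by extending
#' base-by-base from `start`, trimming the maximal trailing run of contiguous
#' mismatches, and requiring the remaining mismatches to fit the budget
#' `ceiling(max_mismatch_rate * matched_length)`. The best interpretation has
#' the fewest mismatches; ties prefer the longest match, then the larger
#' adapter clip. This ranking — rather than an unconditional leftmost clip —
#' is what reproduces printed spans in which the first adapter base happens
#' to coincide with the reference base at that position.
#'
#' @param flank DNA string after the anchor (may be empty).
#' @param ref The acceptor [transcript_reference()].
#' @param start mRNA coordinate the flank extends from (first base after the
#'   anchor).
#' @param params A [classifier_params()].
#' @return `list(end, mismatches, adapter_clipped, trailing_trimmed,
#'   matched)`, where `end = start + matched - 1`, or `NULL` when no
#'   interpretation fits the mismatch budget.
#' @export
match_flank_prefix <- function(flank, ref, start, params = classifier_params()) {
  w <- ref_window(ref)
  start <- as.integer(start)
  stopifnot(start >= w[1])
  len <- nchar(flank)
  if (len == 0L) {
    return(list(end = start - 1L, mismatches = 0L, adapter_clipped = 0L,
                trailing_trimmed = 0L, matched = 0L))
  }
  avail <- max(0L, w[2] - start + 1L)
  ref_chars <- if (avail > 0L) {
    seq_chars(ref_subseq(ref, start, min(w[2], start + len - 1L)))
  } else character(0)
  flank_chars <- seq_chars(flank)
  clip_at <- c(adapter_clip_points(flank, params), len + 1L)
  best <- NULL
  for (i in clip_at) {
    kept <- i - 1L
    clipped <- len - kept
    cmp_len <- min(kept, length(ref_chars))
    overflow <- kept - cmp_len # read bases past the reference window
    if (cmp_len > 0L) {
      match_vec <- flank_chars[seq_len(cmp_len)] == ref_chars[seq_len(cmp_len)]
      last_match <- if (any(match_vec)) max(which(match_vec)) else 0L
    } else {
      last_match <- 0L
    }
    matched <- last_match
    trailing <- (cmp_len - last_match) + overflow
    mism <- if (matched > 0L) sum(!match_vec[seq_len(matched)]) else 0L
    if (mism > mismatch_budget(params, matched)) next
    cand <- list(end = start + matched - 1L, mismatches = as.integer(mism),
                 adapter_clipped = as.integer(clipped),
                 trailing_trimmed = as.integer(trailing),
                 matched = as.integer(matched))
    if (is.null(best) ||
        cand$mismatches < best$mismatches ||
        (cand$mismatches == best$mismatches && cand$end > best$end) ||
        (cand$mismatches == best$mismatches && cand$end == best$end &&
         cand$adapter_clipped > best$adapter_clipped)) {
      best <- cand
    }
  }
  best
}

classify_one <- function(oriented_sequence, anchor_start, read_id, donor_refs,
                         acceptor_ref, spec, params) {
  alen <- nchar(spec$anchor)
  if (substr(oriented_sequence, anchor_start, anchor_start + alen - 1L) !=
      spec$anchor) {
    stop("corrupt anchored read ", read_id,
         ": anchor not found at the recorded offset", call. = FALSE)
  }
  upstream <- substr(oriented_sequence, 1L, anchor_start - 1L)
  downstream <- substr(oriented_sequence, anchor_start + alen,
                       nchar(oriented_sequence))
  res <- list(read_id = read_id, category = NA_character_,
              donor_accession = NA_character_, donor_start = NA_integer_,
              donor_end = NA_integer_, donor_exons = NA_character_,
              acceptor_accession = acceptor_ref$accession,
              acceptor_start = spec$acceptor_start,
              acceptor_end = NA_integer_, acceptor_exons = NA_character_,
              upstream_mismatches = NA_integer_,
              downstream_mismatches = NA_integer_,
              adapter_clipped = NA_integer_, trailing_trimmed = NA_integer_)

  dn <- match_flank_prefix(downstream, acceptor_ref,
                           spec$acceptor_start + alen, params)
  if (is.null(dn)) { # nothing downstream fits: keep the anchor itself
    dn <- list(end = spec$acceptor_start + alen - 1L, mismatches = 0L,
               adapter_clipped = 0L, trailing_trimmed = nchar(downstream),
               matched = 0L)
  }
  res$acceptor_end <- dn$end
  res$downstream_mismatches <- dn$mismatches
  res$adapter_clipped <- dn$adapter_clipped
  res$trailing_trimmed <- dn$trailing_trimmed
  res$acceptor_exons <- exon_label(acceptor_ref, spec$acceptor_start, dn$end)

  if (nchar(upstream) < params$min_upstream_flank) {
    res$category <- "UNINFORMATIVE"
    return(res)
  }

  wt <- match_flank_suffix(upstream, acceptor_ref, params,
                           forced_end = spec$acceptor_start - 1L)
  fus <- NULL
  fus_ref <- NULL
  for (dref in donor_refs) {
    if (identical(dref$accession, acceptor_ref$accession)) next
    cand <- match_flank_suffix(upstream, dref, params)
    if (is.null(cand)) next
    if (is.null(fus) || cand$mismatches < fus$mismatches ||
        (cand$mismatches == fus$mismatches && cand$end > fus$end)) {
      fus <- cand
      fus_ref <- dref
    }
  }

  pick <- if (is.null(wt) && is.null(fus)) "OTHER"
  else if (is.null(fus)) "WILDTYPE"
  else if (is.null(wt)) "FUSION"
  else if (fus$mismatches < wt$mismatches) "FUSION"
  else if (fus$mismatches > wt$mismatches) "WILDTYPE"
  else if (params$tie_break == "prefer_wildtype") "WILDTYPE" else "AMBIGUOUS"

  res$category <- pick
  if (pick == "FUSION") {
    res$donor_accession <- fus_ref$accession
    res$donor_end <- fus$end
    res$donor_start <- fus$end - nchar(upstream) + 1L
    res$donor_exons <- exon_label(fus_ref, res$donor_start, res$donor_end)
    res$upstream_mismatches <- fus$mismatches
  } else if (pick == "WILDTYPE") {
    res$donor_accession <- acceptor_ref$accession
    res$donor_end <- wt$end
    res$donor_start <- wt$end - nchar(upstream) + 1L
    res$donor_exons <- exon_label(acceptor_ref, res$donor_start, res$donor_end)
    res$upstream_mismatches <- wt$mismatches
  }
  res
}

#' Classify anchored reads as fusion, wild type, or other
#'
#' For each anchored read, the bases upstream of the anchor are matched as a
#' suffix of (a) the acceptor reference ending immediately before the anchor
#' (wild-type hypothesis) and (b) each donor reference at any position
#' (fusion hypothesis); the hypothesis with fewer mismatches wins, ties being
#' resolved by `tie_break`. Reads fitting neither are `OTHER` (e.g. genomic
#' sequence containing the anchored exon); reads with less upstream sequence
#' than `min_upstream_flank` are `UNINFORMATIVE`. The downstream flank is
#' always extended along the acceptor from the anchor with adapter
#' read-through handling, so every classified read carries an acceptor span
#' beginning at the anchor.
#'
#' @param anchored An `anchored_reads` data.frame from [scan_reads()].
#' @param donor_refs List of candidate donor [transcript_reference()]s (the
#'   acceptor itself is skipped).
#' @param acceptor_ref The acceptor [transcript_reference()].
#' @param spec The [anchor_spec()] used for retrieval.
#' @param params A [classifier_params()].
#' @return A `data.frame` of class `classified_reads`, one row per anchored
#'   read, with donor/acceptor spans in mRNA coordinates, exon labels, and
#'   mismatch/adapter bookkeeping. Categories partition the input.
#' @export
classify_reads <- function(anchored, donor_refs, acceptor_ref,
                           spec = anchor_spec(),
                           params = classifier_params()) {
  if (inherits(donor_refs, "transcript_reference")) donor_refs <- list(donor_refs)
  rows <- lapply(seq_len(nrow(anchored)), function(i) {
    as.data.frame(
      classify_one(anchored$oriented_sequence[i], anchored$anchor_start[i],
                   anchored$read_id[i], donor_refs, acceptor_ref, spec,
                   params),
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(classify_one(paste0("A", spec$anchor), 2L, "x",
                               donor_refs, acceptor_ref, spec,
                               params))[0, ]
  rownames(out) <- NULL
  class(out) <- c("classified_reads", "data.frame")
  out
}

#' Tabulate classified reads in printed-table style
#'
#' One row per read with the donor and acceptor spans rendered as
#' `"start-end (exon ...)"` strings (en dash). Wild-type reads, whose
#' upstream flank continues the acceptor's own upstream exon, are rendered as
#' a single merged span across the anchor, as such reads are conventionally
#' printed.
#'
#' @param classified A `classified_reads` data.frame.
#' @param acceptor_ref The acceptor [transcript_reference()] (for merged
#'   wild-type exon labels).
#' @return A `data.frame` with columns `read_id`, `category`, `donor_span`,
#'   `acceptor_span`.
#' @export
format_read_table <- function(classified, acceptor_ref) {
  span <- function(s, e, lab) {
    ifelse(is.na(s), "",
           sprintf("%d%s%d%s", s, EN_DASH, e,
                   ifelse(is.na(lab) | lab == "", "", paste0(" (", lab, ")"))))
  }
  donor <- character(nrow(classified))
  acceptor <- character(nrow(classified))
  for (i in seq_len(nrow(classified))) {
    r <- classified[i, ]
    if (identical(r$category, "WILDTYPE")) {
      lab <- exon_label(acceptor_ref, r$donor_start, r$acceptor_end)
      donor[i] <- ""
      acceptor[i] <- span(r$donor_start, r$acceptor_end, lab)
    } else {
      donor[i] <- span(r$donor_start, r$donor_end, r$donor_exons)
      acceptor[i] <- span(r$acceptor_start, r$acceptor_end, r$acceptor_exons)
    }
  }
  data.frame(read_id = classified$read_id, category = classified$category,
             donor_span = donor, acceptor_span = acceptor,
             stringsAsFactors = FALSE)
}

#' Aggregate fusion reads into junction calls
#'
#' Groups `FUSION`-classified reads by donor accession and donor breakpoint
#' coordinate; each group becomes one junction call with its supporting read
#' count. Calls are ordered by support (descending), then breakpoint.
#'
#' @param classified A `classified_reads` data.frame.
#' @param refs Optional named list of [transcript_reference()]s used to fill
#'   in gene symbols and exon labels.
#' @return A `data.frame` of class `junction_calls` with columns
#'   `donor_accession`, `donor_gene`, `donor_end`, `donor_exons`,
#'   `acceptor_accession`, `acceptor_gene`, `acceptor_start`,
#'   `supporting_reads`. Empty input yields an empty table.
#' @export
call_junctions <- function(classified, refs = NULL) {
  fus <- classified[classified$category == "FUSION", , drop = FALSE]
  gene_of <- function(acc) {
    if (!is.null(refs) && acc %in% names(refs)) refs[[acc]]$gene
    else NA_character_
  }
  if (nrow(fus) == 0L) {
    out <- data.frame(donor_accession = character(0), donor_gene = character(0),
                      donor_end = integer(0), donor_exons = character(0),
                      acceptor_accession = character(0),
                      acceptor_gene = character(0),
                      acceptor_start = integer(0),
                      supporting_reads = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("junction_calls", "data.frame")
    return(out)
  }
  key <- paste(fus$donor_accession, fus$donor_end, sep = "\r")
  groups <- split(fus, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(donor_accession = g$donor_accession[1L],
               donor_gene = gene_of(g$donor_accession[1L]),
               donor_end = g$donor_end[1L],
               donor_exons = g$donor_exons[1L],
               acceptor_accession = g$acceptor_accession[1L],
               acceptor_gene = gene_of(g$acceptor_accession[1L]),
               acceptor_start = g$acceptor_start[1L],
               supporting_reads = nrow(g), stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$supporting_reads, out$donor_end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("junction_calls", "data.frame")
  out
}

#' Reading-frame determination for a junction
#'
#' With `L_d = donor_end - cds_start(donor) + 1` coding donor bases and the
#' acceptor joined at CDS offset `L_a = acceptor_start - cds_start(acceptor)`,
#' the acceptor's reading frame is preserved — the fusion is in frame — if
#' and only if `L_d` and `L_a` are congruent modulo 3: the acceptor base at
#' CDS offset `L_a` comes to lie at fusion CDS offset `L_d`. A junction
#' joining a donor codon boundary to an acceptor codon boundary is therefore
#' in frame. Codon numbers are reported as `ceiling(L_d / 3)` for the last
#' donor codon and `floor(L_a / 3) + 1` for the first acceptor codon.
#'
#' @param donor_ref,acceptor_ref [transcript_reference()]s with `cds_start`
#'   set; when either is missing the frame is `"unknown"`.
#' @param donor_end Donor breakpoint (last retained donor mRNA coordinate).
#' @param acceptor_start First retained acceptor mRNA coordinate.
#' @return `list(frame, donor_codon, acceptor_codon)` with `frame` one of
#'   `"in_frame"`, `"out_of_frame"`, `"unknown"`.
#' @export
frame_check <- function(donor_ref, acceptor_ref, donor_end, acceptor_start) {
  unknown <- list(frame = "unknown", donor_codon = NA_integer_,
                  acceptor_codon = NA_integer_)
  if (is.null(donor_ref$cds_start) || is.null(acceptor_ref$cds_start)) {
    return(unknown)
  }
  L_d <- donor_end - donor_ref$cds_start + 1L
  L_a <- acceptor_start - acceptor_ref$cds_start
  if (L_d < 1L) {
    warning("donor breakpoint upstream of the CDS start; frame unknown")
    return(unknown)
  }
  if (L_a < 0L) {
    warning("acceptor junction upstream of the CDS start; frame unknown")
    return(unknown)
  }
  list(frame = if (L_d %% 3L == L_a %% 3L) "in_frame" else "out_of_frame",
       donor_codon = as.integer(ceiling(L_d / 3)),
       acceptor_codon = as.integer(L_a %/% 3L + 1L))
}

#' Annotate junction calls with frame information
#'
#' @param calls A `junction_calls` data.frame.
#' @param refs Named list of [transcript_reference()]s keyed by accession.
#' @return `calls` with `frame`, `donor_codon`, `acceptor_codon` columns.
#' @export
annotate_frames <- function(calls, refs) {
  calls$frame <- rep(NA_character_, nrow(calls))
  calls$donor_codon <- rep(NA_integer_, nrow(calls))
  calls$acceptor_codon <- rep(NA_integer_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    d <- refs[[calls$donor_accession[i]]]
    a <- refs[[calls$acceptor_accession[i]]]
    if (is.null(d) || is.null(a)) {
      calls$frame[i] <- "unknown"
      next
    }
    fr <- frame_check(d, a, calls$donor_end[i], calls$acceptor_start[i])
    calls$frame[i] <- fr$frame
    calls$donor_codon[i] <- fr$donor_codon
    calls$acceptor_codon[i] <- fr$acceptor_codon
  }
  calls
}
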