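#' Transcript reference in mRNA coordinates
#'
#' A `transcript_reference` stores an mRNA sequence (or a window of one)
#' together with its coordinate system: all positions are 1-based inclusive
#' coordinates of the accessioned mRNA, never genomic coordinates.
#' `coord_offset` is the mRNA coordinate of the first stored base, so partial
#' windows reconstructed from reads (e.g. a KAT6A window 3686-3764) keep the
#' accession's own numbering.
#'
#' @param accession Text identifier, e.g. `"NM_006766.3"`.
#' @param gene Gene symbol, e.g. `"KAT6A"`.
#' @param sequence Uppercase DNA string over `{A,C,G,T,N}`.
#' @param coord_offset 1-based mRNA coordinate of the first stored base.
#' @param exons Optional `data.frame` with columns `label`, `start`, `end`
#'   (1-based inclusive mRNA coordinates); exons must be non-overlapping and
#'   ascending, and each must intersect the stored window.
#' @param cds_start Optional 1-based mRNA coordinate of the first CDS base.
#'   It may lie outside the stored window (only the coordinate is needed for
#'   reading-frame arithmetic).
#' @param cytoband Optional chromosome band, e.g. `"8p11"`.
#'
#' @return An object of class `transcript_reference`.
#' @export
transcript_reference <- function(accession, gene, sequence, coord_offset = 1L,
                                 exons = NULL, cds_start = NULL,
                                 cytoband = NULL) {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession))
  sequence <- toupper(sequence)
  assert_dna(sequence, "sequence", allow_n = TRUE)
  if (nchar(sequence) == 0L) stop("sequence must be non-empty", call. = FALSE)
  coord_offset <- as.integer(coord_offset)
  if (is.na(coord_offset) || coord_offset < 1L) {
    stop("coord_offset must be a positive integer", call. = FALSE)
  }
  w_end <- coord_offset + nchar(sequence) - 1L
  if (!is.null(exons)) {
    exons <- as.data.frame(exons)
    stopifnot(all(c("label", "start", "end") %in% names(exons)))
    exons$start <- as.integer(exons$start)
    exons$end <- as.integer(exons$end)
    if (anyNA(exons$start) || anyNA(exons$end) || any(exons$start > exons$end)) {
      stop("malformed exon boundaries for ", accession, call. = FALSE)
    }
    if (nrow(exons) > 1L) {
      if (is.unsorted(exons$start, strictly = TRUE) ||
          any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
        stop("exon intervals of ", accession,
             " must be ascending and non-overlapping", call. = FALSE)
      }
    }
    if (any(exons$end < coord_offset | exons$start > w_end)) {
      stop("exon interval outside the stored window of ", accession,
           call. = FALSE)
    }
  }
  if (!is.null(cds_start)) {
    cds_start <- as.integer(cds_start)
    if (is.na(cds_start) || cds_start < 1L) {
      stop("cds_start must be a positive integer", call. = FALSE)
    }
  }
  structure(
    list(accession = accession, gene = gene, sequence = sequence,
         coord_offset = coord_offset, exons = exons,
         cds_start = cds_start, cytoband = cytoband),
    class = "transcript_reference"
  )
}

#' @export
print.transcript_reference <- function(x, ...) {
  w <- ref_window(x)
  cat(sprintf("<transcript_reference> %s (%s), window %d%s%d (%d nt)\n",
              x$accession, x$gene %||% "?", w[1], EN_DASH, w[2],
              nchar(x$sequence)))
  if (!is.null(x$exons)) {
    cat("  exons:", paste(sprintf("%s:%d%s%d", x$exons$label, x$exons$start,
                                  EN_DASH, x$exons$end), collapse = ", "), "\n")
  }
  if (!is.null(x$cds_start)) cat("  cds_start:", x$cds_start, "\n")
  invisible(x)
}

#' mRNA coordinate window covered by a reference
#'
#' @param ref A [transcript_reference()].
#' @return Integer vector `c(start, end)`, 1-based inclusive.
#' @export
ref_window <- function(ref) {
  c(ref$coord_offset, ref$coord_offset + nchar(ref$sequence) - 1L)
}

#' Extract a subsequence by mRNA coordinates
#'
#' @param ref A [transcript_reference()].
#' @param start,end 1-based inclusive mRNA coordinates; must lie within the
#'   stored window.
#' @return A DNA string of exactly `end - start + 1` bases.
#' @export
ref_subseq <- function(ref, start, end) {
  w <- ref_window(ref)
  start <- as.integer(start); end <- as.integer(end)
  if (start > end || start < w[1] || end > w[2]) {
    stop(sprintf("coordinates %d..%d outside the stored window %d..%d of %s",
                 start, end, w[1], w[2], ref$accession), call. = FALSE)
  }
  substr(ref$sequence, start - w[1] + 1L, end - w[1] + 1L)
}

#' Exon label for a coordinate span
#'
#' Returns the printed-style exon annotation for a span, e.g. `"exon 2"` for a
#' span inside one exon or `"exon 1-2"` (with an en dash) for a span crossing
#' the boundary between labelled exons.
#'
#' @param ref A [transcript_reference()] with an exon table.
#' @param start,end 1-based inclusive mRNA coordinates.
#' @return A character scalar, or `NA_character_` when no exon table is
#'   available or the span touches no annotated exon.
#' @export
exon_label <- function(ref, start, end) {
  if (is.null(ref$exons)) return(NA_character_)
  hit <- ref$exons$end >= start & ref$exons$start <= end
  if (!any(hit)) return(NA_character_)
  labs <- ref$exons$label[hit]
  if (length(labs) == 1L) paste("exon", labs)
  else paste0("exon ", labs[1L], EN_DASH, labs[length(labs)])
}

#' Load transcript references from FASTA plus an annotation table
#'
#' The FASTA records are keyed by the first word of each header (the
#' accession). The annotation TSV has one exon per row with the header
#' `accession, gene, coord_offset, exon_label, exon_start, exon_end,
#' cds_start, cytoband`; `cds_start` and `cytoband` are repeated on each row
#' of an accession or left blank.
#'
#' @param fasta_path Path to the reference FASTA (wrapped or unwrapped).
#' @param annotation_path Path to the annotation TSV.
#' @return A named list of [transcript_reference()] objects, keyed by
#'   accession. An empty FASTA yields an empty list.
#' @export
load_references <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ann <- utils::read.delim(annotation_path, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("accession", "gene", "coord_offset", "exon_label", "exon_start",
            "exon_end")
  if (!all(need %in% names(ann))) {
    stop("annotation table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (length(seqs) == 0L) return(structure(list(), names = character(0)))
  acc <- sub("\\s.*$", "", names(seqs))
  out <- vector("list", length(seqs))
  names(out) <- acc
  for (i in seq_along(seqs)) {
    rows <- ann[ann$accession == acc[i], , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop("no annotation rows for FASTA record ", acc[i], call. = FALSE)
    }
    num <- function(col, row_idx) {
      v <- suppressWarnings(as.integer(rows[[col]][row_idx]))
      if (anyNA(v)) {
        stop(sprintf("malformed %s in annotation row %d for %s", col,
                     row_idx[which(is.na(v))[1L]], acc[i]), call. = FALSE)
      }
      v
    }
    exons <- data.frame(label = rows$exon_label,
                        start = num("exon_start", seq_len(nrow(rows))),
                        end = num("exon_end", seq_len(nrow(rows))),
                        stringsAsFactors = FALSE)
    cds <- rows$cds_start[1L] %||% ""
    cds <- if (is.null(cds) || is.na(cds) || !nzchar(cds)) NULL else num("cds_start", 1L)
    cyto <- rows$cytoband[1L] %||% ""
    cyto <- if (is.null(cyto) || is.na(cyto) || !nzchar(cyto)) NULL else cyto
    out[[i]] <- transcript_reference(
      accession = acc[i], gene = rows$gene[1L],
      sequence = as.character(seqs[[i]]),
      coord_offset = num("coord_offset", 1L),
      exons = exons, cds_start = cds, cytoband = cyto)
  }
  out
}

#' Majority-rule consensus from reads sharing an anchor k-mer
#'
#' Aligns reads on their common anchor occurrence and takes a per-column
#' majority base, reconstructing the transcript window the reads cover. This
#' is how the packaged partial references were rebuilt from the printed read
#' set. Ties are broken lexicographically (`A < C < G < T`) and flagged as
#' low confidence; `N` casts no vote; columns with no votes become `N`.
#'
#' @param sequences Character vector of read sequences (anchor sense).
#' @param anchor_pos Integer vector, 1-based position of the anchor's first
#'   base within each read.
#' @param anchor_start 1-based mRNA coordinate of the anchor's first base.
#' @param side `"full"` aligns whole reads left-anchored at the anchor;
#'   `"upstream"` uses only the bases before the anchor, right-justified at
#'   `anchor_start - 1` (used to rebuild the donor side of a junction).
#' @return A list with `sequence` (the consensus), `coord_offset` (mRNA
#'   coordinate of its first base), and `low_confidence` (mRNA coordinates of
#'   tied columns).
#' @export
consensus_from_anchored_reads <- function(sequences, anchor_pos, anchor_start,
                                          side = c("full", "upstream")) {
  side <- match.arg(side)
  if (length(sequences) == 0L) stop("no reads to build a consensus from",
                                    call. = FALSE)
  anchor_pos <- as.integer(anchor_pos)
  stopifnot(length(anchor_pos) == length(sequences), all(anchor_pos >= 1L))
  if (side == "upstream") {
    sequences <- substr(sequences, 1L, anchor_pos - 1L)
    starts <- anchor_start - nchar(sequences)
  } else {
    starts <- anchor_start - (anchor_pos - 1L)
  }
  keep <- nchar(sequences) > 0L
  sequences <- sequences[keep]; starts <- starts[keep]
  if (length(sequences) == 0L) stop("no informative bases for consensus",
                                    call. = FALSE)
  lo <- min(starts)
  hi <- max(starts + nchar(sequences) - 1L)
  ncol <- hi - lo + 1L
  votes <- matrix(0L, nrow = 4L, ncol = ncol,
                  dimnames = list(DNA_BASES, NULL))
  for (i in seq_along(sequences)) {
    ch <- seq_chars(sequences[i])
    cols <- (starts[i] - lo) + seq_along(ch)
    for (b in DNA_BASES) {
      idx <- cols[ch == b]
      if (length(idx)) votes[b, idx] <- votes[b, idx] + 1L
    }
  }
  top <- apply(votes, 2L, max)
  n_top <- colSums(votes == rep(top, each = 4L)) # ties share the max count
  base <- DNA_BASES[apply(votes, 2L, which.max)] # which.max is lexicographic
  base[top == 0L] <- "N"
  tied <- which(n_top > 1L & top > 0L)
  list(sequence = paste(base, collapse = ""),
       coord_offset = lo,
       low_confidence = as.integer(lo + tied - 1L))
}

#' Construct a fusion transcript sequence
#'
#' Concatenates the donor transcript up to and including `donor_end` with the
#' acceptor transcript from `acceptor_start` onward, both in their own mRNA
#' coordinates. The result carries the junction position (last donor base,
#' 1-based within the fusion sequence) as attribute `junction_at`.
#'
#' @param donor,acceptor [transcript_reference()] objects.
#' @param donor_end Last donor mRNA coordinate retained (the breakpoint).
#' @param acceptor_start First acceptor mRNA coordinate retained.
#' @return A DNA string with attribute `junction_at`.
#' @export
build_fusion_transcript <- function(donor, donor_end, acceptor,
                                    acceptor_start) {
  dw <- ref_window(donor); aw <- ref_window(acceptor)
  d <- ref_subseq(donor, dw[1], donor_end)
  a <- ref_subseq(acceptor, acceptor_start, aw[2])
  structure(paste0(d, a), junction_at = nchar(d))
}
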