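#' Primer pair for in-silico PCR
#'
#' Both primers are written 5' to 3' as conventionally ordered: the forward
#' primer in the sense of the template, the reverse primer on the antisense
#' strand (so its binding site on the template is the reverse complement of
#' the given sequence).
#'
#' @param fwd,rev Primer sequences, `A/C/G/T` only, at least 15 nt.
#' @param name_fwd,name_rev Optional primer names.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(fwd, rev, name_fwd = "fwd", name_rev = "rev") {
  assert_dna(fwd, "forward primer")
  assert_dna(rev, "reverse primer")
  if (nchar(fwd) < 15L || nchar(rev) < 15L) {
    stop("primers must be at least 15 nt", call. = FALSE)
  }
  structure(list(fwd = fwd, rev = rev, name_fwd = name_fwd,
                 name_rev = name_rev), class = "primer_pair")
}

#' Locate primer binding sites on a template
#'
#' The forward primer is matched as a (near-)exact substring of the template;
#' the reverse primer as the exact substring equal to its reverse complement.
#' All ordered pairings with the forward site starting before the reverse
#' site ends are returned.
#'
#' @param template DNA string (e.g. a fusion transcript).
#' @param primers A [primer_pair()].
#' @param max_mismatch Mismatches tolerated per primer site (default 0,
#'   i.e. exact binding).
#' @return A `data.frame` with columns `fwd_start`, `fwd_end`, `rev_start`,
#'   `rev_end` (1-based template positions); zero rows when either site is
#'   absent.
#' @export
find_primer_sites <- function(template, primers, max_mismatch = 0L) {
  stopifnot(nzchar(template))
  subject <- Biostrings::DNAString(template)
  hits <- function(p) {
    m <- Biostrings::matchPattern(p, subject, max.mismatch = max_mismatch,
                                  with.indels = FALSE, fixed = TRUE)
    data.frame(start = Biostrings::start(m), end = Biostrings::end(m))
  }
  f <- hits(primers$fwd)
  r <- hits(revcomp(primers$rev))
  if (nrow(f) == 0L || nrow(r) == 0L) {
    return(data.frame(fwd_start = integer(0), fwd_end = integer(0),
                      rev_start = integer(0), rev_end = integer(0)))
  }
  pairs <- expand.grid(fi = seq_len(nrow(f)), ri = seq_len(nrow(r)))
  out <- data.frame(fwd_start = f$start[pairs$fi], fwd_end = f$end[pairs$fi],
                    rev_start = r$start[pairs$ri], rev_end = r$end[pairs$ri])
  out <- out[out$fwd_start < out$rev_end, , drop = FALSE]
  out <- out[order(out$fwd_start, out$rev_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute the PCR amplicon
#'
#' Requires exactly one forward/reverse site pairing on the template; the
#' amplicon runs from the forward primer's first base through the last base
#' of the reverse primer's binding site, inclusive.
#'
#' @inheritParams find_primer_sites
#' @return `list(length, sequence, fwd_start, rev_end)`.
#' @export
pcr_amplicon <- function(template, primers, max_mismatch = 0L) {
  sites <- find_primer_sites(template, primers, max_mismatch)
  if (nrow(sites) != 1L) {
    stop(sprintf(
      "expected exactly one primer-site pair, found %d (%s/%s)%s",
      nrow(sites), primers$name_fwd, primers$name_rev,
      if (nrow(sites) > 1L) {
        paste0(": ", paste(sprintf("[%d..%d]", sites$fwd_start, sites$rev_end),
                           collapse = " "))
      } else ""), call. = FALSE)
  }
  len <- sites$rev_end - sites$fwd_start + 1L
  list(length = len,
       sequence = substr(template, sites$fwd_start, sites$rev_end),
       fwd_start = sites$fwd_start, rev_end = sites$rev_end)
}
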