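#' Simulation source template
#'
#' A transcript a simulated library draws fragments from. A source carrying a
#' junction (a fusion transcript) records the position of the last donor base
#' within the template so the truth ledger can flag junction-spanning reads.
#' The output of [build_fusion_transcript()] can be passed directly: its
#' `junction_at` attribute is picked up automatically.
#'
#' @param label Source label recorded in the truth ledger.
#' @param sequence Template DNA string (plain, or the result of
#'   [build_fusion_transcript()]).
#' @param weight Non-negative sampling weight among background sources.
#' @param junction_at 1-based template position of the last donor base, or
#'   `NULL` for a wild-type template.
#' @return An object of class `sim_source`.
#' @export
sim_source <- function(label, sequence, weight = 1, junction_at = NULL) {
  junction_at <- junction_at %||% attr(sequence, "junction_at")
  sequence <- as.character(sequence)
  assert_dna(sequence, "template sequence")
  stopifnot(weight >= 0)
  structure(list(label = label, sequence = sequence, weight = weight,
                 junction_at = if (is.null(junction_at)) NA_integer_
                               else as.integer(junction_at)),
            class = "sim_source")
}

#' Configuration of a synthetic sequencing library
#'
#' Emulates a short-read transcriptome library: fixed-length single-end reads
#' drawn from weighted transcript templates, i.i.d. substitution errors, a
#' normal fragment-length distribution truncated to the template, and
#' Illumina 3'-adapter read-through whenever the fragment is shorter than the
#' read (the remainder of the read is filled with the adapter, then padded).
#' Junction-spanning fusion reads enter at rate `fusion_fraction`. The
#' defaults mirror the library the packaged read set came from: 101-nt reads
#' and a low substitution rate; `fusion_fraction` defaults to trace abundance
#' and is a free parameter of any experiment.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param sources List of background [sim_source()]s (weights are normalised).
#' @param fusion Optional [sim_source()] carrying the junction.
#' @param fusion_fraction Probability a read originates from `fusion`.
#' @param n_reads Number of reads to emit.
#' @param read_length Read length in nt.
#' @param substitution_rate Per-base substitution probability (template bases
#'   only; appended adapter bases are never mutated).
#' @param insert_mean,insert_sd Fragment length distribution (nt), truncated
#'   to `[min_insert, template length]` by redrawing.
#' @param min_insert Smallest fragment length retained.
#' @param adapter Adapter sequence read into on short fragments.
#' @param anchor Anchor k-mer whose position in each template is recorded so
#'   the truth ledger can flag anchor-covering reads.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed, sources, fusion = NULL,
                              fusion_fraction = 2e-4,
                              n_reads = 100000L, read_length = 101L,
                              substitution_rate = 0.005,
                              insert_mean = 160, insert_sd = 40,
                              min_insert = 25L,
                              adapter = "AGATCGGAAGAGC",
                              anchor = "ATTTTGGATCATTGTTTGAC") {
  if (inherits(sources, "sim_source")) sources <- list(sources)
  stopifnot(length(sources) >= 1L || !is.null(fusion),
            fusion_fraction >= 0, fusion_fraction <= 1,
            substitution_rate >= 0, substitution_rate < 1,
            n_reads >= 0L, read_length >= nchar(anchor) + 12L,
            min_insert >= 1L)
  assert_dna(adapter, "adapter")
  w <- vapply(sources, function(s) s$weight, 1)
  if (length(sources) && sum(w) <= 0) {
    stop("source weights must be normalizable (sum > 0)", call. = FALSE)
  }
  locate <- function(s) {
    p <- regexpr(anchor, s$sequence, fixed = TRUE)
    if (p > 0L) as.integer(p) else NA_integer_
  }
  for (i in seq_along(sources)) sources[[i]]$anchor_at <- locate(sources[[i]])
  if (!is.null(fusion)) fusion$anchor_at <- locate(fusion)
  structure(list(seed = as.integer(seed), sources = sources, fusion = fusion,
                 fusion_fraction = fusion_fraction,
                 n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 substitution_rate = substitution_rate,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 min_insert = as.integer(min_insert), adapter = adapter,
                 anchor = anchor),
            class = "simulation_config")
}

draw_fragment <- function(tpl_len, cfg) {
  for (try in 1:1000) {
    L <- as.integer(round(stats::rnorm(1L, cfg$insert_mean, cfg$insert_sd)))
    L <- max(L, cfg$min_insert)
    if (L <= tpl_len) return(L)
  }
  stop("cannot draw a fragment shorter than the template (length ",
       tpl_len, ")", call. = FALSE)
}

#' Simulate a sequencing library with a ground-truth ledger
#'
#' Deterministic given `cfg$seed` (the function seeds R's default
#' Mersenne-Twister generator). Each read picks a source (the fusion template
#' with probability `fusion_fraction`, otherwise a background source by
#' weight), draws a truncated-normal fragment and a uniform start, copies up
#' to `read_length` template bases, injects substitutions, and fills any
#' remainder with adapter sequence (padded with `A` past the adapter, as on
#' a sequencer reading past the ligated adapter).
#'
#' @param cfg A [simulation_config()].
#' @return A list with `reads` (named character vector, ids `sim_000001`...)
#'   and `truth`, a `data.frame` with one row per read: `read_id`, `source`,
#'   `tpl_start`, `frag_len`, `copied`, `covers_junction` (fragment contains
#'   the junction with at least one copied base on each side),
#'   `junction_overhang_5p` (copied bases on the donor side; 0 when not
#'   spanning), `covers_anchor` (the copied interval contains the full
#'   anchor), `n_errors`, `adapter_bases`.
#' @export
simulate_library <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_reads
  pool <- cfg$sources
  w <- vapply(pool, function(s) s$weight, 1)
  has_fusion <- !is.null(cfg$fusion)
  from_fusion <- if (has_fusion) {
    stats::runif(n) < cfg$fusion_fraction
  } else rep(FALSE, n)
  src_idx <- integer(n)
  if (any(!from_fusion)) {
    if (length(pool) == 0L) stop("no background sources", call. = FALSE)
    src_idx[!from_fusion] <- sample.int(length(pool), sum(!from_fusion),
                                        replace = TRUE, prob = w / sum(w))
  }
  alen <- nchar(cfg$anchor)
  fill_src <- paste0(cfg$adapter, strrep("A", cfg$read_length))
  ids <- sprintf("sim_%06d", seq_len(n))
  reads <- character(n)
  src_lab <- character(n)
  tpl_start <- integer(n); frag_len <- integer(n); copied <- integer(n)
  covers_junction <- logical(n); overhang <- integer(n)
  covers_anchor <- logical(n); n_err <- integer(n); adp <- integer(n)
  for (i in seq_len(n)) {
    s <- if (from_fusion[i]) cfg$fusion else pool[[src_idx[i]]]
    tlen <- nchar(s$sequence)
    L <- draw_fragment(tlen, cfg)
    st <- as.integer(1L + floor(stats::runif(1L) * (tlen - L + 1L)))
    cp <- min(L, cfg$read_length)
    seq <- substr(s$sequence, st, st + cp - 1L)
    ne <- 0L
    if (cfg$substitution_rate > 0) {
      err <- which(stats::runif(cp) < cfg$substitution_rate)
      ne <- length(err)
      if (ne > 0L) {
        ch <- seq_chars(seq)
        for (j in err) {
          ch[j] <- sample(setdiff(DNA_BASES, ch[j]), 1L)
        }
        seq <- paste(ch, collapse = "")
      }
    }
    ab <- cfg$read_length - cp
    if (ab > 0L) seq <- paste0(seq, substr(fill_src, 1L, ab))
    reads[i] <- seq
    src_lab[i] <- s$label
    tpl_start[i] <- st; frag_len[i] <- L; copied[i] <- cp
    j_at <- s$junction_at
    cj <- !is.na(j_at) && st <= j_at && (st + cp - 1L) >= (j_at + 1L)
    covers_junction[i] <- cj
    overhang[i] <- if (cj) j_at - st + 1L else 0L
    a_at <- s$anchor_at
    covers_anchor[i] <- !is.na(a_at) && st <= a_at &&
      (st + cp - 1L) >= (a_at + alen - 1L)
    n_err[i] <- ne; adp[i] <- ab
  }
  names(reads) <- ids
  truth <- data.frame(read_id = ids, source = src_lab, tpl_start = tpl_start,
                      frag_len = frag_len, copied = copied,
                      covers_junction = covers_junction,
                      junction_overhang_5p = overhang,
                      covers_anchor = covers_anchor,
                      n_errors = n_err, adapter_bases = adp,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Write simulated reads as FASTQ
#'
#' Constant base quality (`I`), as qualities are ignored downstream.
#'
#' @param sim Output of [simulate_library()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  q <- strrep("I", nchar(sim$reads))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", names(sim$reads)),
                             unname(sim$reads), "+", q)), con)
  invisible(path)
}

#' Detection metrics against the simulator's truth ledger
#'
#' Quantifies how much junction evidence an exact-anchor retrieval plus
#' split-read classification recovers from a library. Retrieval sensitivity
#' is measured on reads whose copied bases contain the full anchor (an
#' anchor hit is lost whenever a substitution falls inside the anchor, so
#' with substitution rate `r` the expectation is `(1 - r)^k` for a k-mer
#' anchor). Fusion sensitivity is measured on junction-spanning reads with
#' the full anchor and at least `min_upstream_flank` donor-side bases.
#'
#' @param truth Truth ledger from [simulate_library()].
#' @param classified A `classified_reads` data.frame for the anchored reads.
#' @param anchored_ids Read ids retrieved by [scan_reads()]; defaults to
#'   `classified$read_id`.
#' @param calls Optional `junction_calls` for coordinate accuracy.
#' @param planted_junction Optional `c(donor_end, acceptor_start)` the
#'   library was built around.
#' @param min_upstream_flank Minimum donor overhang for a read to count as
#'   recoverable (matches [classifier_params()]).
#' @return A list of metrics: `n_anchor_covering`, `retrieval_sensitivity`,
#'   `n_junction_recoverable`, `fusion_sensitivity`, `false_positives`,
#'   and (when `calls` and `planted_junction` are given) `n_calls` and
#'   `junction_accuracy` (fraction of calls at the planted coordinates).
#' @export
evaluate_detection <- function(truth, classified, anchored_ids = NULL,
                               calls = NULL, planted_junction = NULL,
                               min_upstream_flank = 6L) {
  anchored_ids <- anchored_ids %||% classified$read_id
  if (!all(classified$read_id %in% truth$read_id)) {
    stop("classified read ids not found in the truth ledger", call. = FALSE)
  }
  anchored <- truth$read_id %in% anchored_ids
  cov <- truth$covers_anchor
  fus_ids <- classified$read_id[classified$category == "FUSION"]
  eligible <- truth$covers_junction & truth$covers_anchor &
    truth$junction_overhang_5p >= min_upstream_flank
  fp <- sum(!truth$covers_junction[match(fus_ids, truth$read_id)])
  out <- list(
    n_anchor_covering = sum(cov),
    retrieval_sensitivity = if (any(cov)) mean(anchored[cov]) else NA_real_,
    n_junction_recoverable = sum(eligible),
    fusion_sensitivity = if (any(eligible)) {
      mean(truth$read_id[eligible] %in% fus_ids)
    } else NA_real_,
    false_positives = fp)
  if (!is.null(calls) && !is.null(planted_junction)) {
    out$n_calls <- nrow(calls)
    out$junction_accuracy <- if (nrow(calls)) {
      mean(calls$donor_end == planted_junction[1] &
             calls$acceptor_start == planted_junction[2])
    } else NA_real_
  }
  out
}
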