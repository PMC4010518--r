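#' Gene locus with a cytoband address
#'
#' @param gene Gene symbol.
#' @param cytoband Band of the form `<chrom><arm><band>`, e.g. `"8p11"` or
#'   `"16p13.3"` (chromosome 1-22, X or Y; arm p or q).
#' @return An object of class `gene_locus`.
#' @export
gene_locus <- function(gene, cytoband) {
  parse_cytoband(cytoband) # validates
  structure(list(gene = gene, cytoband = cytoband), class = "gene_locus")
}

#' Parse a cytoband string
#'
#' @param x Character vector of cytobands, e.g. `c("8p11", "16p13.3")`.
#' @return A `data.frame` with columns `chrom`, `arm`, `band`, and `rank`
#'   (chromosome sort order: 1-22, then X, then Y).
#' @export
parse_cytoband <- function(x) {
  m <- regmatches(x, regexec("^(2[0-2]|1[0-9]|[1-9]|X|Y)([pq])([0-9]+(\\.[0-9]+)?)$", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("cannot parse cytoband(s): ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  }
  chrom <- vapply(m, `[`, "", 2L)
  rank <- match(chrom, c(as.character(1:22), "X", "Y"))
  data.frame(chrom = chrom, arm = vapply(m, `[`, "", 3L),
             band = vapply(m, `[`, "", 4L), rank = rank,
             stringsAsFactors = FALSE)
}

#' Load a gene-to-cytoband table
#'
#' @param path TSV with header columns `gene` and `cytoband`. A small table
#'   covering the genes used in the worked examples ships with the package
#'   (`system.file("extdata", "gene_cytobands.tsv", package = "anchorfusion")`).
#' @return A named list of [gene_locus()] objects keyed by gene symbol.
#' @export
load_gene_loci <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "cytoband") %in% names(tab)))
  loci <- lapply(seq_len(nrow(tab)),
                 function(i) gene_locus(tab$gene[i], tab$cytoband[i]))
  names(loci) <- tab$gene
  loci
}

#' Parse a generic fusion-caller output table
#'
#' Reads the TSV/CSV output of any fusion caller into a uniform record
#' layout. The gene pair may be given as one combined column (split on the
#' last hyphen, so symbols containing hyphens survive as 5' partner) or as
#' two columns; the mapping from logical to actual column names is supplied
#' by the caller of this function.
#'
#' @param path Path to the caller output (`.csv` is comma-separated,
#'   everything else tab-separated).
#' @param column_map Named list mapping logical names to actual column names:
#'   either `pair`, or `gene5` and `gene3`; optionally `rank` and `score`.
#'   When `rank` is absent, file order is used.
#' @return A `data.frame` with columns `gene5`, `gene3`, `rank`, `score`,
#'   followed by all remaining input columns, in file order.
#' @export
parse_caller_table <- function(path, column_map = list(pair = "FusionGene",
                                                       rank = "Rank")) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  get_col <- function(logical_name) {
    actual <- column_map[[logical_name]]
    if (is.null(actual)) return(NULL)
    if (!actual %in% names(tab)) {
      stop("mapped column not found in table: ", actual, call. = FALSE)
    }
    tab[[actual]]
  }
  if (!is.null(column_map$pair)) {
    pair <- as.character(get_col("pair"))
    gene5 <- sub("-[^-]*$", "", pair)
    gene3 <- sub("^.*-", "", pair)
  } else {
    gene5 <- as.character(get_col("gene5"))
    gene3 <- as.character(get_col("gene3"))
    if (is.null(gene5) || is.null(gene3)) {
      stop("column_map must provide either 'pair' or both 'gene5' and 'gene3'",
           call. = FALSE)
    }
  }
  n <- nrow(tab)
  if (n > 0L && any(!nzchar(gene5) | !nzchar(gene3))) {
    stop("empty gene symbol in caller table", call. = FALSE)
  }
  rank <- get_col("rank")
  rank <- if (is.null(rank)) seq_len(n) else as.integer(rank)
  if (anyDuplicated(rank)) {
    stop("duplicate rank in caller table", call. = FALSE)
  }
  score <- get_col("score")
  score <- if (is.null(score)) rep(NA_real_, n) else as.numeric(score)
  used <- unlist(column_map, use.names = FALSE)
  extra <- tab[, setdiff(names(tab), used), drop = FALSE]
  out <- data.frame(gene5 = gene5, gene3 = gene3, rank = rank, score = score,
                    stringsAsFactors = FALSE)
  cbind(out, extra)
}

normalize_symbol <- function(x, aliases) {
  if (length(aliases) == 0L) return(x)
  hit <- match(x, names(aliases))
  ifelse(is.na(hit), x, unname(unlist(aliases))[hit])
}

#' Check whether a caller table contains a target gene pair
#'
#' Orientation-invariant lookup of a gene pair, with alias translation (e.g.
#' `KAT6A` is reported as `MYST3` by some callers, `CREBBP` as `CBP`).
#'
#' @param records Output of [parse_caller_table()].
#' @param gene_a,gene_b Gene symbols of the target pair.
#' @param aliases Named character vector or list translating symbols to the
#'   caller's vocabulary, e.g. `c(KAT6A = "MYST3")`.
#' @return `list(present, best_rank, matches)`; `best_rank` is `NA` when the
#'   pair is absent.
#' @export
audit_target_pair <- function(records, gene_a, gene_b, aliases = character(0)) {
  a <- normalize_symbol(gene_a, aliases)
  b <- normalize_symbol(gene_b, aliases)
  g5 <- normalize_symbol(records$gene5, aliases)
  g3 <- normalize_symbol(records$gene3, aliases)
  hit <- (g5 == a & g3 == b) | (g5 == b & g3 == a)
  list(present = any(hit),
       best_rank = if (any(hit)) min(records$rank[hit]) else NA_integer_,
       matches = records[hit, , drop = FALSE])
}

band_matches <- function(locus_band, band) {
  locus_band == band | startsWith(locus_band, paste0(band, ".")) |
    startsWith(band, paste0(locus_band, "."))
}

#' Filter caller records by karyotype breakpoint cytobands
#'
#' Keeps candidate fusions whose partner genes map to the chromosome bands
#' rearranged in the karyotype — the way a short list of cytogenetically
#' plausible candidates is culled from hundreds of caller outputs. Sub-band
#' resolution is tolerated in either direction (`16p13.3` matches `16p13`).
#'
#' @param records Output of [parse_caller_table()].
#' @param loci Named list of [gene_locus()] objects (see [load_gene_loci()]).
#' @param bands Character vector of cytobands of interest.
#' @param mode `"any"` keeps records with at least one partner in `bands`;
#'   `"both"` requires both partners.
#' @param aliases Optional symbol translation applied before locus lookup.
#' @return The filtered records; the number of records dropped because a
#'   partner gene had no locus is attached as attribute `n_unresolved` (a
#'   warning is also raised).
#' @export
cytoband_filter <- function(records, loci, bands, mode = c("any", "both"),
                            aliases = character(0)) {
  mode <- match.arg(mode)
  band_of <- function(sym) {
    sym <- normalize_symbol(sym, aliases)
    vapply(sym, function(s) {
      # accept loci keyed by either the caller's or the canonical symbol
      l <- loci[[s]]
      if (is.null(l)) NA_character_ else l$cytoband
    }, "")
  }
  b5 <- band_of(records$gene5)
  b3 <- band_of(records$gene3)
  unresolved <- is.na(b5) | is.na(b3)
  if (any(unresolved)) {
    warning(sum(unresolved), " record(s) dropped: gene(s) without a locus")
  }
  in_bands <- function(bb) {
    vapply(bb, function(x) {
      !is.na(x) && any(band_matches(x, bands))
    }, TRUE)
  }
  keep <- if (mode == "any") {
    !unresolved & (in_bands(b5) | in_bands(b3))
  } else {
    !unresolved & in_bands(b5) & in_bands(b3)
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unresolved") <- sum(unresolved)
  out
}

#' Format a reciprocal translocation in ISCN notation
#'
#' Renders `t(c1;c2)(b1;b2)` for two loci on different chromosomes, with
#' chromosomes ordered 1-22 then X then Y, and the band list ordered to
#' correspond positionally to the chromosome list. Symmetric in its
#' arguments.
#'
#' @param locus_a,locus_b [gene_locus()] objects or plain cytoband strings.
#' @return ISCN string such as `"t(3;8)(q21;p11)"`.
#' @export
iscn_translocation <- function(locus_a, locus_b) {
  band_str <- function(l) if (inherits(l, "gene_locus")) l$cytoband else l
  p <- parse_cytoband(c(band_str(locus_a), band_str(locus_b)))
  if (p$chrom[1] == p$chrom[2]) {
    stop("intrachromosomal rearrangement not expressible as t()",
         call. = FALSE)
  }
  o <- order(p$rank)
  sprintf("t(%s;%s)(%s%s;%s%s)", p$chrom[o[1]], p$chrom[o[2]],
          p$arm[o[1]], p$band[o[1]], p$arm[o[2]], p$band[o[2]])
}
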