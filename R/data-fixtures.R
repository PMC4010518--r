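af_extdata <- function(file) {
  path <- system.file("extdata", file, package = "anchorfusion",
                      mustWork = FALSE)
  if (!nzchar(path)) stop("packaged data file not found: ", file,
                          call. = FALSE)
  path
}

#' Packaged anchored read set
#'
#' The 26 published 101-nt read sequences retrieved from a patient's RNA-seq
#' library by exact search for the first 20 nt of CREBBP exon 2: 11 reads
#' span a KAT6A-CREBBP junction, 14 are wild-type CREBBP exon 1-2, and one is
#' genomic sequence containing the anchored exon. They serve both as a worked
#' example and as the material the fixture references are reconstructed from.
#'
#' @return Named character vector of 26 read sequences (`read_01` ...
#'   `read_26`, in published order).
#' @export
published_reads <- function() {
  read_sequences(af_extdata("published_reads.fasta"))
}

#' Packaged partial transcript references
#'
#' KAT6A (NM_006766.3) and CREBBP (NM_004380.2) windows reconstructed by
#' majority consensus from the packaged read set ([published_reads()]): KAT6A
#' mRNA 3686-3764 (the donor side of the junction, exon 16) and CREBBP mRNA
#' 212-380 (exon 1 tail plus the start of exon 2). Coordinates, exon
#' boundaries and CDS starts follow the accessions' own mRNA numbering; the
#' CDS start coordinates are annotation metadata, the coordinate itself lying
#' upstream of the reconstructed windows.
#'
#' @return Named list of two [transcript_reference()] objects keyed by
#'   accession.
#' @export
fixture_references <- function() {
  load_references(af_extdata("fixture_refs.fasta"),
                  af_extdata("fixture_refs_annotation.tsv"))
}
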