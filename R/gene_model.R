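#' Construct a transcript isoform from an ordered exon table
#'
#' A transcript isoform is an ordered list of exons; its mature sequence is
#' the concatenation of the exon sequences in order. Exon identifiers are
#' treated as opaque labels (numbering conventions differ between references)
#' and only their order within an isoform carries meaning.
#'
#' @param isoform_id single string naming the isoform (e.g. `"JMa/CYT-1"`).
#' @param exons either a named character vector (names = exon ids, values =
#'   sequences) or a data.frame with columns `exon_id` and `sequence`.
#'   Sequences are case-normalized to upper case and must be non-empty
#'   strings over the DNA alphabet `A, C, G, T`.
#' @return an object of class `transcript_isoform`: a list with elements
#'   `isoform_id`, `exon_id` (character), `sequence` (character, one entry
#'   per exon, same order).
#' @seealso [enumerate_junctions()], [design_probes()], [read_gene_model()]
#' @export
#' @examples
#' iso <- transcript_isoform("toy", c(E1 = "ACGTACGTAC", E2 = "GGGTTTAAAC"))
#' transcript_seq(iso)
transcript_isoform <- function(isoform_id, exons) {
  stopifnot(is.character(isoform_id), length(isoform_id) == 1L, nzchar(isoform_id))
  if (is.data.frame(exons)) {
    stopifnot(all(c("exon_id", "sequence") %in% names(exons)))
    ids <- as.character(exons$exon_id)
    seqs <- as.character(exons$sequence)
  } else {
    stopifnot(is.character(exons), !is.null(names(exons)))
    ids <- names(exons)
    seqs <- unname(exons)
  }
  if (length(ids) < 1L) stop("isoform must contain at least one exon")
  if (anyDuplicated(ids)) stop("exon_ids must be unique within an isoform")
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) stop("exon sequences must be non-empty")
  if (any(grepl("[^ACGT]", seqs)))
    stop("exon sequences must contain only A, C, G, T")
  structure(list(isoform_id = isoform_id, exon_id = ids, sequence = seqs),
            class = "transcript_isoform")
}

#' @export
print.transcript_isoform <- function(x, ...) {
  cat("Transcript isoform:", x$isoform_id, "\n")
  cat(sprintf("  %d exon(s), %d nt total\n",
              length(x$exon_id), sum(nchar(x$sequence))))
  for (i in seq_along(x$exon_id)) {
    s <- x$sequence[i]
    shown <- if (nchar(s) > 40) paste0(substr(s, 1, 37), "...") else s
    cat(sprintf("  %-8s %5d nt  %s\n", x$exon_id[i], nchar(s), shown))
  }
  invisible(x)
}

#' Mature transcript sequence of an isoform
#'
#' @param isoform a [transcript_isoform()].
#' @return single string: concatenation of exon sequences in order.
#' @export
transcript_seq <- function(isoform) {
  stopifnot(inherits(isoform, "transcript_isoform"))
  paste(isoform$sequence, collapse = "")
}

# cumulative exon end positions (1-based, inclusive) in transcript coordinates
exon_ends <- function(isoform) cumsum(nchar(isoform$sequence))

#' Reverse-complement an isoform
#'
#' Reverses the exon order and reverse-complements every exon sequence, so
#' the mature transcript of the result is the reverse complement of the
#' original mature transcript. Exon ids are retained.
#'
#' @param isoform a [transcript_isoform()].
#' @return a `transcript_isoform` on the opposite strand.
#' @export
revcomp_isoform <- function(isoform) {
  stopifnot(inherits(isoform, "transcript_isoform"))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rev(isoform$sequence))))
  transcript_isoform(isoform$isoform_id,
                     stats::setNames(rc, rev(isoform$exon_id)))
}

#' Read a multi-isoform gene model
#'
#' Two plain-text layouts are accepted:
#' \describe{
#'   \item{TSV}{columns `isoform_id`, `exon_id`, `sequence`; exon order within
#'     an isoform is file order.}
#'   \item{FASTA}{one record per exon with headers of the form
#'     `isoform|exon`; record order within an isoform is file order.}
#' }
#'
#' @param path file path.
#' @param format `"tsv"`, `"fasta"`, or `"auto"` (by file extension).
#' @return named list of [transcript_isoform()] objects.
#' @export
read_gene_model <- function(path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             comment.char = "#")
    stopifnot(all(c("isoform_id", "exon_id", "sequence") %in% names(tab)))
  } else {
    ss <- Biostrings::readDNAStringSet(path)
    hdr <- strsplit(names(ss), "|", fixed = TRUE)
    if (any(lengths(hdr) != 2L))
      stop("FASTA headers must have the form 'isoform|exon'")
    tab <- data.frame(isoform_id = vapply(hdr, `[`, "", 1L),
                      exon_id = vapply(hdr, `[`, "", 2L),
                      sequence = as.character(ss),
                      stringsAsFactors = FALSE)
  }
  lapply(split(tab, factor(tab$isoform_id, unique(tab$isoform_id))),
         function(d) transcript_isoform(d$isoform_id[1L],
                                        stats::setNames(d$sequence, d$exon_id)))
}

#' Write a gene model as TSV
#'
#' @param gene_model list of [transcript_isoform()] objects.
#' @param path output file.
#' @export
write_gene_model <- function(gene_model, path) {
  rows <- do.call(rbind, lapply(gene_model, function(iso)
    data.frame(isoform_id = iso$isoform_id, exon_id = iso$exon_id,
               sequence = iso$sequence, stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Miniature four-isoform example gene model
#'
#' A compact ErbB4-like gene model used throughout the documentation and
#' tests. Four isoforms arise from two alternative-splicing events: mutually
#' exclusive juxtamembrane exons (`E16a`, 45 nt, JMb-like; `E16b`, 75 nt,
#' JMa-like) and the inclusion (CYT-1-like) or exclusion (CYT-2-like) of a
#' 48 nt cytoplasmic exon `E26`. Exon boundary contexts around every
#' designed-probe junction reproduce published single-pair probe target
#' sequences for this receptor; the exon interiors away from those contexts
#' are synthetic filler, and exons between the junction-bearing ones are
#' omitted, so the model is a miniature, not the real gene.
#'
#' @return named list of four [transcript_isoform()] objects
#'   (`JMa/CYT-1`, `JMa/CYT-2`, `JMb/CYT-1`, `JMb/CYT-2`).
#' @export
#' @examples
#' gm <- example_gene_model()
#' enumerate_junctions(gm[["JMb/CYT-2"]])
example_gene_model <- function() {
  # junction-context segments (sense strand) with synthetic filler between
  fill1 <- "GATTACACCGGTTCAACTGG"
  fill2 <- "TTCACCGATCGATGGCCATA"
  e1  <- paste0(fill1, "TCTCAGTCAG")                     # ...E1]
  e2  <- paste0("TGTGCGCAGGAACAGAGAACAAACTGAGCTCTCTCT",  # [E2...
                fill2,
                "GAGCACAACCGGGACCTCTCCTTCCTGCGG")         # ...E2]
  e3  <- paste0("TCTATCCGAG", fill1)                      # [E3...
  e15 <- paste0(fill2, "CCCAGGG")                         # ...E15]
  # 45 nt juxtamembrane exon (JMb-like)
  e16a <- "GTGCATAGGTTCAAGCATTGAAGACTGCATCGGCCTGACGGATAG"
  # 75 nt juxtamembrane exon (JMa-like)
  e16b <- paste0("GTGTAACGGTCCCACTAGTCATGACTGCATTTACTACCC", "CA",
                 "GGACGGGCCATTCCACTTTACCACAACACGCTAG")
  e17 <- paste0("AACTCCAC", fill1)                        # [E17...
  e25 <- paste0(fill2, "CCATCTACACATCCAGAACAAGAATTGACTCCAATAGG")
  # 48 nt cytoplasmic exon (CYT-1-like): 13 + 24 + 11 nt
  e26 <- paste0("AGTGAAATTGGAC", "TTGGCACCAGATTCCGAAGGTCAT", "CCATGTCGGGA")
  e27 <- paste0("AATCAGTTTGTGTACCAAGATGGGGGCTTT", fill2,
                "GCATGACAAGCCCAAACAAG")
  e28 <- paste0("AATATCTGAATCCTGTGGAAGAGAACC", fill1)
  stopifnot(nchar(e16a) == 45L, nchar(e16b) == 75L, nchar(e26) == 48L)
  common5 <- c(E1 = e1, E2 = e2, E3 = e3, E15 = e15)
  common3 <- c(E17 = e17, E25 = e25)
  tail3 <- c(E27 = e27, E28 = e28)
  list(
    "JMa/CYT-1" = transcript_isoform("JMa/CYT-1",
      c(common5, E16b = e16b, common3, E26 = e26, tail3)),
    "JMa/CYT-2" = transcript_isoform("JMa/CYT-2",
      c(common5, E16b = e16b, common3, tail3)),
    "JMb/CYT-1" = transcript_isoform("JMb/CYT-1",
      c(common5, E16a = e16a, common3, E26 = e26, tail3)),
    "JMb/CYT-2" = transcript_isoform("JMb/CYT-2",
      c(common5, E16a = e16a, common3, tail3)))
}
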