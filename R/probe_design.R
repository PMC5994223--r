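#' Enumerate exon-exon junctions of an isoform
#'
#' Returns one junction per consecutive exon pair, in transcript order. The
#' junction position is given in 0-based transcript coordinates as the
#' offset of the first base of the downstream exon, i.e. the cumulative
#' length of all upstream exons.
#'
#' @param isoform a [transcript_isoform()].
#' @return data.frame with columns `isoform_id`, `upstream_exon_id`,
#'   `downstream_exon_id`, `junction_pos`. A single-exon isoform yields a
#'   zero-row frame (there is no junction; this is not an error).
#' @export
#' @examples
#' gm <- example_gene_model()
#' enumerate_junctions(gm[["JMa/CYT-2"]])
enumerate_junctions <- function(isoform) {
  stopifnot(inherits(isoform, "transcript_isoform"))
  k <- length(isoform$exon_id)
  if (k < 2L)
    return(data.frame(isoform_id = character(), upstream_exon_id = character(),
                      downstream_exon_id = character(),
                      junction_pos = integer(), stringsAsFactors = FALSE))
  ends <- exon_ends(isoform)
  data.frame(isoform_id = isoform$isoform_id,
             upstream_exon_id = isoform$exon_id[-k],
             downstream_exon_id = isoform$exon_id[-1L],
             junction_pos = as.integer(ends[-k]),
             stringsAsFactors = FALSE)
}

gc_fraction <- function(s) {
  v <- strsplit(s, "")[[1]]
  mean(v %in% c("G", "C"))
}

empty_probe_frame <- function() {
  data.frame(name = character(), isoform_id = character(),
             upstream_exon_id = character(), downstream_exon_id = character(),
             junction_pos = integer(), side = character(),
             span_start = integer(), span_end = integer(),
             adj_start = integer(), adj_end = integer(),
             gc_span = numeric(), gc_adj = numeric(),
             target_sequence = character(), stringsAsFactors = FALSE)
}

as_probe_set <- function(df) {
  class(df) <- c("single_pair_probes", "data.frame")
  df
}

#' Design single-pair probes for one exon junction
#'
#' A single-pair probe consists of two 18-25 nt oligos targeting adjacent
#' mRNA sequence: one oligo spans the exon-exon junction (with at least
#' `min_overhang` bases in each exon, which is what confers junction
#' specificity) and the second lies immediately adjacent, with no gap and no
#' overlap, either upstream or downstream of the spanning oligo. All
#' placements satisfying the length, overhang and GC constraints are
#' enumerated, for both adjacent-upstream and adjacent-downstream layouts,
#' and returned in deterministic order (spanning-oligo start, then spanning
#' length, then side, then adjacent length).
#'
#' Coordinates are 0-based, half-open, transcript-relative, on the sense
#' strand; the physical hybridization probes are the reverse complements
#' (anti-sense) of the reported target sequences.
#'
#' @param isoform a [transcript_isoform()].
#' @param junction one row of [enumerate_junctions()] output (or a list with
#'   the same fields); must belong to `isoform`.
#' @param min_overhang minimum number of bases of the spanning oligo on each
#'   side of the junction. Default 4 nt.
#' @param oligo_len_range allowed oligo lengths, default `c(18, 25)`.
#' @param gc_range allowed GC fraction per oligo, default `c(0.3, 0.7)`;
#'   a heuristic bound, not taken from any assay documentation.
#' @param junction_offset optional integer restricting the number of
#'   spanning-oligo bases upstream of the junction to exactly this value
#'   (commercial designs may fix it); `NULL` (default) allows all offsets.
#' @param max_probes keep at most this many probes (after ordering).
#' @param marker junction marker character inserted into `target_sequence`.
#' @return a `single_pair_probes` data.frame (possibly zero rows, with a
#'   warning when the junction is too close to a transcript end to host both
#'   oligos). Columns: `name`, junction fields, `side`
#'   (`"adjacent-upstream"` or `"adjacent-downstream"`), half-open
#'   coordinates `span_start`/`span_end` and `adj_start`/`adj_end`, per-oligo
#'   GC fractions, and `target_sequence` (covered transcript substring with
#'   the marker at the junction).
#' @export
#' @examples
#' gm <- example_gene_model()
#' iso <- gm[["JMa/CYT-2"]]
#' j <- enumerate_junctions(iso)
#' pr <- design_probes(iso, j[j$upstream_exon_id == "E25", ], max_probes = 2)
#' pr$target_sequence
design_probes <- function(isoform, junction, min_overhang = 4L,
                          oligo_len_range = c(18L, 25L),
                          gc_range = c(0.3, 0.7), junction_offset = NULL,
                          max_probes = Inf, marker = "/") {
  stopifnot(inherits(isoform, "transcript_isoform"),
            min_overhang >= 1L, oligo_len_range[1L] <= oligo_len_range[2L])
  junction <- as.list(junction)
  jp <- as.integer(junction$junction_pos)
  ends <- exon_ends(isoform)
  k <- match(junction$upstream_exon_id, isoform$exon_id)
  if (is.na(k) || k >= length(isoform$exon_id) ||
      isoform$exon_id[k + 1L] != junction$downstream_exon_id ||
      ends[k] != jp)
    stop("junction does not belong to this isoform")
  txp <- transcript_seq(isoform)
  L <- nchar(txp)
  lens <- seq.int(oligo_len_range[1L], oligo_len_range[2L])

  rows <- list()
  for (sl in lens) {
    # upstream bases of the spanning oligo: between min_overhang and
    # sl - min_overhang, optionally pinned to junction_offset
    ups <- seq.int(min_overhang, sl - min_overhang)
    if (length(ups) == 0L || min_overhang > sl - min_overhang) next
    if (!is.null(junction_offset)) ups <- intersect(ups, junction_offset)
    for (up in ups) {
      s0 <- jp - up                       # 0-based span start
      e0 <- s0 + sl
      if (s0 < 0L || e0 > L) next
      span_seq <- substr(txp, s0 + 1L, e0)
      gs <- gc_fraction(span_seq)
      if (gs < gc_range[1L] || gs > gc_range[2L]) next
      for (al in lens) {
        for (side in c("adjacent-upstream", "adjacent-downstream")) {
          if (side == "adjacent-upstream") {
            a0 <- s0 - al; a1 <- s0
          } else {
            a0 <- e0; a1 <- e0 + al
          }
          if (a0 < 0L || a1 > L) next
          adj_seq <- substr(txp, a0 + 1L, a1)
          ga <- gc_fraction(adj_seq)
          if (ga < gc_range[1L] || ga > gc_range[2L]) next
          cov0 <- min(s0, a0); cov1 <- max(e0, a1)
          tgt <- paste0(substr(txp, cov0 + 1L, jp), marker,
                        substr(txp, jp + 1L, cov1))
          rows[[length(rows) + 1L]] <- data.frame(
            name = sprintf("%s:%s/%s:span%d-%d:adj%d-%d",
                           isoform$isoform_id, junction$upstream_exon_id,
                           junction$downstream_exon_id, s0, e0, a0, a1),
            isoform_id = isoform$isoform_id,
            upstream_exon_id = junction$upstream_exon_id,
            downstream_exon_id = junction$downstream_exon_id,
            junction_pos = jp, side = side,
            span_start = s0, span_end = e0, adj_start = a0, adj_end = a1,
            gc_span = gs, gc_adj = ga, target_sequence = tgt,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    warning(sprintf("no probe placement fits junction %s/%s (junction too close to a transcript end, or constraints unsatisfiable)",
                    junction$upstream_exon_id, junction$downstream_exon_id))
    return(as_probe_set(empty_probe_frame()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$span_start, out$span_end - out$span_start,
                   out$side, out$adj_end - out$adj_start), , drop = FALSE]
  rownames(out) <- NULL
  if (is.finite(max_probes) && nrow(out) > max_probes)
    out <- out[seq_len(max_probes), , drop = FALSE]
  as_probe_set(out)
}

#' Design one probe per junction across a whole isoform
#'
#' Convenience wrapper calling [design_probes()] on every junction of the
#' isoform and keeping the first `per_junction` placements of each.
#'
#' @inheritParams design_probes
#' @param per_junction probes kept per junction (default 1).
#' @param ... passed to [design_probes()].
#' @return a `single_pair_probes` data.frame.
#' @export
design_probes_all <- function(isoform, per_junction = 1L, ...) {
  js <- enumerate_junctions(isoform)
  out <- lapply(seq_len(nrow(js)), function(i)
    design_probes(isoform, js[i, ], max_probes = per_junction, ...))
  as_probe_set(do.call(rbind, c(list(empty_probe_frame()), out)))
}

#' @export
print.single_pair_probes <- function(x, ...) {
  cat(sprintf("Single-pair probes: %d placement(s) (sense-strand targets; physical probes are anti-sense)\n",
              nrow(x)))
  if (nrow(x) > 0L)
    print.data.frame(x[, c("name", "side", "span_start", "span_end",
                           "adj_start", "adj_end", "target_sequence")],
                     right = FALSE)
  invisible(x)
}

# sequence of the junction-spanning oligo of one probe row, on sense strand
span_oligo_seq <- function(probe, gene_model) {
  iso <- gene_model[[probe$isoform_id]]
  substr(transcript_seq(iso), probe$span_start + 1L, probe$span_end)
}

#' Screen a probe for isoform specificity
#'
#' Exact-substring screening of the junction-spanning oligo against every
#' isoform of a gene model: the oligo sequence is searched (sense strand) in
#' each isoform's mature transcript. Isoforms that contain the oligo but lack
#' the targeted exon junction (the same upstream/downstream exon pair,
#' consecutive) are off-target; a probe is specific when there are none.
#' This formalizes why a probe spanning a skipping junction (e.g. an
#' E25/E27 junction of an exon-26-excluded isoform) does not detect
#' exon-26-included transcripts. No hybridization thermodynamics are
#' modelled.
#'
#' @param probe one row of a `single_pair_probes` frame.
#' @param gene_model named list of [transcript_isoform()] objects containing
#'   the probe's own isoform.
#' @return object of class `specificity_report`: list with `probe_name`,
#'   `oligo` (spanning oligo sense-strand sequence), `occurs_in_isoforms`,
#'   `off_target_isoforms`, `specific`.
#' @export
#' @examples
#' gm <- example_gene_model()
#' iso <- gm[["JMa/CYT-2"]]
#' j <- enumerate_junctions(iso)
#' pr <- design_probes(iso, j[j$upstream_exon_id == "E25", ], max_probes = 1)
#' check_specificity(pr[1, ], gm)
check_specificity <- function(probe, gene_model) {
  probe <- as.list(probe)
  if (is.null(gene_model[[probe$isoform_id]]))
    stop("gene_model must contain the probe's isoform: ", probe$isoform_id)
  oligo <- span_oligo_seq(probe, gene_model)
  hits <- vapply(gene_model, function(iso)
    Biostrings::countPattern(oligo,
                             Biostrings::DNAString(transcript_seq(iso))) > 0L,
    logical(1L))
  has_junction <- vapply(gene_model, function(iso) {
    js <- enumerate_junctions(iso)
    any(js$upstream_exon_id == probe$upstream_exon_id &
          js$downstream_exon_id == probe$downstream_exon_id)
  }, logical(1L))
  occurs <- names(gene_model)[hits]
  off <- names(gene_model)[hits & !has_junction]
  structure(list(probe_name = probe$name, oligo = oligo,
                 occurs_in_isoforms = occurs, off_target_isoforms = off,
                 specific = length(off) == 0L),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("Specificity report for", x$probe_name, "\n")
  cat("  spanning oligo:", x$oligo, "\n")
  cat("  occurs in:", paste(x$occurs_in_isoforms, collapse = ", "), "\n")
  cat("  off-target:",
      if (length(x$off_target_isoforms)) paste(x$off_target_isoforms, collapse = ", ") else "(none)",
      "\n")
  cat("  specific:", x$specific, "\n")
  invisible(x)
}

#' Export designed probes
#'
#' @param probes a non-empty `single_pair_probes` frame.
#' @param path output file.
#' @param format `"tsv"` (full records, round-trippable with
#'   [read_probes()]), `"fasta"` (two records per probe: the spanning and the
#'   adjacent oligo, sense-strand target sequences), or `"bed"` (half-open
#'   transcript-coordinate intervals, one line per oligo, chrom =
#'   isoform id).
#' @param gene_model required for `"fasta"`: the model the probes were
#'   designed against.
#' @return `path`, invisibly.
#' @export
export_probes <- function(probes, path, format = c("tsv", "fasta", "bed"),
                          gene_model = NULL) {
  format <- match.arg(format)
  if (nrow(probes) == 0L) stop("no probes to export")
  if (format == "tsv") {
    utils::write.table(probes, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "fasta") {
    if (is.null(gene_model))
      stop("FASTA export needs the gene_model to extract oligo sequences")
    seqs <- character(0L); nms <- character(0L)
    for (i in seq_len(nrow(probes))) {
      p <- probes[i, ]
      tx <- transcript_seq(gene_model[[p$isoform_id]])
      nms <- c(nms, paste0(p$name, "|span"), paste0(p$name, "|adjacent"))
      seqs <- c(seqs, substr(tx, p$span_start + 1L, p$span_end),
                substr(tx, p$adj_start + 1L, p$adj_end))
    }
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(seqs, nms)), path)
  } else {
    bed <- data.frame(
      chrom = rep(probes$isoform_id, each = 2L),
      start = as.vector(rbind(probes$span_start, probes$adj_start)),
      end = as.vector(rbind(probes$span_end, probes$adj_end)),
      name = as.vector(rbind(paste0(probes$name, "|span"),
                             paste0(probes$name, "|adjacent"))))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Re-read a TSV probe export
#'
#' @param path file written by [export_probes()] with `format = "tsv"`.
#' @return a `single_pair_probes` data.frame.
#' @export
read_probes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  # accept "-" as junction marker on input; "/" is canonical
  df$target_sequence <- sub("-", "/", df$target_sequence, fixed = TRUE)
  int_cols <- c("junction_pos", "span_start", "span_end",
                "adj_start", "adj_end")
  df[int_cols] <- lapply(df[int_cols], as.integer)
  as_probe_set(df)
}
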