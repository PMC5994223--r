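test_that("isoform construction validates and normalizes input", {
  iso <- transcript_isoform("x", c(E1 = "acgt", E2 = "TTAA"))
  expect_equal(transcript_seq(iso), "ACGTTTAA")
  expect_error(transcript_isoform("x", c(E1 = "ACGT", E1 = "TTTT")),
               "unique")
  expect_error(transcript_isoform("x", c(E1 = "ACGN")), "A, C, G, T")
  expect_error(transcript_isoform("x", c(E1 = "")), "non-empty")
})

test_that("junction enumeration matches cumulative exon lengths", {
  # brute-force oracle: cumulative sums over a toy 4-exon model
  set.seed(11)
  lens <- c(13L, 27L, 8L, 40L)
  seqs <- vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    "")
  iso <- transcript_isoform("t4", stats::setNames(seqs, paste0("E", 1:4)))
  js <- enumerate_junctions(iso)
  expect_equal(nrow(js), 3L)
  expect_equal(js$junction_pos, cumsum(lens)[1:3])
  expect_equal(js$upstream_exon_id, c("E1", "E2", "E3"))
  expect_equal(js$downstream_exon_id, c("E2", "E3", "E4"))

  # single-exon isoform has no junction (empty, not an error)
  one <- transcript_isoform("solo", c(E1 = "ACGTACGTAC"))
  expect_equal(nrow(enumerate_junctions(one)), 0L)

  # invariant: enumeration depends on exon order/length, not on labels
  iso2 <- transcript_isoform("t4b", stats::setNames(seqs, paste0("X", 4:1)))
  expect_equal(enumerate_junctions(iso2)$junction_pos, js$junction_pos)
})

test_that("skipping junctions of the example model match published contexts", {
  gm <- example_gene_model()
  js <- enumerate_junctions(gm[["JMa/CYT-2"]])
  # exon-26-excluded isoform has a direct E25/E27 junction
  expect_true(any(js$upstream_exon_id == "E25" &
                    js$downstream_exon_id == "E27"))
  # exon-26-included isoform does not
  js1 <- enumerate_junctions(gm[["JMa/CYT-1"]])
  expect_false(any(js1$upstream_exon_id == "E25" &
                     js1$downstream_exon_id == "E27"))
  # the skipping-junction context on the transcript
  iso <- gm[["JMb/CYT-2"]]
  j <- js[js$upstream_exon_id == "E25", ]
  tx <- transcript_seq(iso)
  expect_match(tx, "CCAATAGGAATCAGTTTGT", fixed = TRUE)
})

test_that("designed probes satisfy all pair constraints", {
  gm <- example_gene_model()
  for (iso in gm[c("JMa/CYT-1", "JMb/CYT-2")]) {
    js <- enumerate_junctions(iso)
    for (i in seq_len(nrow(js))) {
      pr <- design_probes(iso, js[i, ])
      expect_gt(nrow(pr), 0L)
      sl <- pr$span_end - pr$span_start
      al <- pr$adj_end - pr$adj_start
      expect_true(all(sl >= 18 & sl <= 25))
      expect_true(all(al >= 18 & al <= 25))
      # spanning oligo straddles the junction with >= 4 nt overhang
      expect_true(all(pr$junction_pos - pr$span_start >= 4))
      expect_true(all(pr$span_end - pr$junction_pos >= 4))
      # adjacent oligo abuts the spanning oligo: gap 0, no overlap
      up <- pr$side == "adjacent-upstream"
      expect_true(all(pr$adj_end[up] == pr$span_start[up]))
      expect_true(all(pr$adj_start[!up] == pr$span_end[!up]))
      # the two oligos tile a contiguous interval
      expect_true(all((pmax(pr$span_end, pr$adj_end) -
                         pmin(pr$span_start, pr$adj_start)) == sl + al))
      expect_true(all(pr$gc_span >= 0.3 & pr$gc_span <= 0.7))
      # target sequence = covered substring with exactly one marker
      expect_true(all(lengths(gregexpr("/", pr$target_sequence,
                                       fixed = TRUE)) == 1L))
      expect_true(all(nchar(pr$target_sequence) == sl + al + 1L))
    }
  }
})

test_that("designer equals exhaustive brute-force enumeration on a toy transcript", {
  iso <- toy_isoform()
  j <- enumerate_junctions(iso)[1, ]
  pr <- design_probes(iso, j)
  oracle <- brute_force_probes(iso, j)
  got <- unique(as.matrix(pr[, c("span_start", "span_end", "adj_start",
                                 "adj_end")]))
  dimnames(got) <- NULL
  dimnames(oracle) <- NULL
  expect_equal(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
               oracle)
})

test_that("impossible placements give an empty set with a warning", {
  iso <- transcript_isoform("short", c(E1 = "ACG", E2 = paste(rep("ACGT", 15),
                                                              collapse = "")))
  j <- enumerate_junctions(iso)[1, ]
  # upstream exon of length 3 cannot host a 4 nt overhang
  expect_warning(pr <- design_probes(iso, j, min_overhang = 4), "no probe")
  expect_equal(nrow(pr), 0L)
})

test_that("junction probe targets reproduce published junction contexts", {
  gm <- example_gene_model()
  iso <- gm[["JMa/CYT-2"]]
  js <- enumerate_junctions(iso)
  pr <- design_probes(iso, js[js$upstream_exon_id == "E25", ])
  # every placement carries at least the minimum-overhang junction core,
  # and placements with enough overhang carry the full published context
  expect_true(all(grepl("TAGG/AATC", pr$target_sequence, fixed = TRUE)))
  expect_true(any(grepl("CCAATAGG/AATCAGTTTGT", pr$target_sequence,
                        fixed = TRUE)))
  # the first-ranked placement covers the full context
  expect_match(pr$target_sequence[1], "CCAATAGG/AATCAGTTTGT", fixed = TRUE)
})

test_that("specificity screening distinguishes skipping junctions from shared exons", {
  gm <- example_gene_model()
  iso <- gm[["JMa/CYT-2"]]
  js <- enumerate_junctions(iso)
  pr <- design_probes(iso, js[js$upstream_exon_id == "E25", ],
                      max_probes = 5)
  for (i in seq_len(nrow(pr))) {
    rep_i <- check_specificity(pr[i, ], gm)
    # exon-26-included isoforms must not contain the skipping oligo
    expect_false(any(grepl("CYT-1", rep_i$occurs_in_isoforms)))
    expect_true(rep_i$specific)
  }
  # a probe over a junction present in all isoforms occurs in all of them
  prall <- design_probes(iso, js[js$upstream_exon_id == "E1", ],
                         max_probes = 1)
  repall <- check_specificity(prall[1, ], gm)
  expect_setequal(repall$occurs_in_isoforms, names(gm))
  expect_true(repall$specific)  # all carriers share the junction

  # vacuous exclusion: gene model containing only the probe's own isoform
  rep1 <- check_specificity(pr[1, ], gm["JMa/CYT-2"])
  expect_true(rep1$specific)
})

test_that("design on the reverse-complemented model mirrors coordinates and sequences", {
  iso <- toy_isoform(seed = 21)
  L <- nchar(transcript_seq(iso))
  j <- enumerate_junctions(iso)[1, ]
  pr <- design_probes(iso, j)

  rc <- revcomp_isoform(iso)
  jrc <- enumerate_junctions(rc)[1, ]
  expect_equal(jrc$junction_pos, L - j$junction_pos)
  prc <- design_probes(rc, jrc)
  expect_equal(nrow(prc), nrow(pr))
  # mirrored span coordinates
  expect_setequal(paste(L - prc$span_end, L - prc$span_start),
                  paste(pr$span_start, pr$span_end))
  # target sequences are reverse complements (marker position mirrors)
  rc_targets <- vapply(prc$target_sequence, function(s) {
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    rcp <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(rev(parts))))
    paste(rcp, collapse = "/")
  }, "", USE.NAMES = FALSE)
  expect_setequal(rc_targets, pr$target_sequence)
})

test_that("probe export round-trips through TSV and writes FASTA/BED", {
  gm <- example_gene_model()
  iso <- gm[["JMb/CYT-2"]]
  pr <- design_probes_all(iso, per_junction = 1L)
  tsv <- tempfile(fileext = ".tsv")
  export_probes(pr, tsv)
  back <- read_probes(tsv)
  expect_equal(as.data.frame(back), as.data.frame(pr))

  # one probe -> header + one row
  one <- tempfile(fileext = ".tsv")
  export_probes(pr[1, ], one)
  expect_length(readLines(one), 2L)

  fa <- tempfile(fileext = ".fa")
  export_probes(pr, fa, format = "fasta", gene_model = gm)
  ss <- Biostrings::readDNAStringSet(fa)
  expect_length(ss, 2L * nrow(pr))
  # FASTA oligos match the transcript substrings
  tx <- transcript_seq(iso)
  expect_equal(unname(as.character(ss[[1]])),
               substr(tx, pr$span_start[1] + 1, pr$span_end[1]))

  bed <- tempfile(fileext = ".bed")
  export_probes(pr, bed, format = "bed")
  btab <- read.delim(bed, header = FALSE)
  expect_equal(nrow(btab), 2L * nrow(pr))
  expect_true(all(btab$V3 > btab$V2))

  expect_error(export_probes(pr, tempfile(), format = "xlsx"))
  expect_error(export_probes(pr[0, ], tempfile()), "no probes")
})

test_that("a dash junction marker is accepted on input and canonicalized", {
  gm <- example_gene_model()
  pr <- design_probes_all(gm[["JMb/CYT-1"]], per_junction = 1L)
  tsv <- tempfile(fileext = ".tsv")
  dashed <- pr
  dashed$target_sequence <- sub("/", "-", dashed$target_sequence, fixed = TRUE)
  export_probes(dashed, tsv)
  back <- read_probes(tsv)
  expect_equal(back$target_sequence, pr$target_sequence)
})

test_that("gene models round-trip through TSV and FASTA readers", {
  gm <- example_gene_model()
  tsv <- tempfile(fileext = ".tsv")
  write_gene_model(gm, tsv)
  back <- read_gene_model(tsv)
  expect_setequal(names(back), names(gm))
  expect_equal(transcript_seq(back[["JMa/CYT-1"]]),
               transcript_seq(gm[["JMa/CYT-1"]]))

  fa <- tempfile(fileext = ".fa")
  iso <- gm[["JMb/CYT-2"]]
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(
    stats::setNames(iso$sequence, paste0(iso$isoform_id, "|", iso$exon_id))),
    fa)
  back2 <- read_gene_model(fa)
  expect_equal(transcript_seq(back2[[1]]), transcript_seq(iso))
})
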