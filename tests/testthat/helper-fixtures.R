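# shared fixtures: small, fast simulation settings for unit tests
small_params <- function(...) {
  sim_params(image_shape = c(256L, 256L), n_nuclei = 30L, ...)
}

# deterministic two-exon toy isoform for designer oracles
toy_isoform <- function(seed = 7, len1 = 50L, len2 = 50L) {
  set.seed(seed)
  transcript_isoform("toy", c(
    EA = paste(sample(c("A", "C", "G", "T"), len1, replace = TRUE),
               collapse = ""),
    EB = paste(sample(c("A", "C", "G", "T"), len2, replace = TRUE),
               collapse = "")))
}

# independent brute-force enumeration of all valid single-pair placements
brute_force_probes <- function(isoform, junction, min_overhang = 4L,
                               len_range = c(18L, 25L),
                               gc_range = c(0.3, 0.7)) {
  txp <- transcript_seq(isoform)
  L <- nchar(txp)
  jp <- junction$junction_pos
  gc <- function(s) {
    v <- strsplit(s, "")[[1]]
    mean(v %in% c("G", "C"))
  }
  out <- list()
  for (s0 in 0:(L - 1)) for (e0 in (s0 + 1):L) {
    sl <- e0 - s0
    if (sl < len_range[1] || sl > len_range[2]) next
    if (jp - s0 < min_overhang || e0 - jp < min_overhang) next
    g1 <- gc(substr(txp, s0 + 1, e0))
    if (g1 < gc_range[1] || g1 > gc_range[2]) next
    for (al in len_range[1]:len_range[2]) for (side in c("up", "down")) {
      if (side == "up") { a0 <- s0 - al; a1 <- s0 } else { a0 <- e0; a1 <- e0 + al }
      if (a0 < 0 || a1 > L) next
      g2 <- gc(substr(txp, a0 + 1, a1))
      if (g2 < gc_range[1] || g2 > gc_range[2]) next
      out[[length(out) + 1]] <- c(s0, e0, a0, a1)
    }
  }
  m <- do.call(rbind, out)
  if (is.null(m)) m <- matrix(numeric(0), ncol = 4)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}
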