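## Independent oracles used by the tests.  Each is a deliberately naive,
## brute-force computation kept separate from the package implementation.

# score one complete gapped alignment: substitution scores on residue
# columns, each gap run costs open + len * ext
score_alignment_oracle <- function(arow, brow, mat, open, ext) {
  s <- 0
  resid <- arow != "-" & brow != "-"
  if (any(resid)) s <- s + sum(mat[cbind(arow[resid], brow[resid])])
  for (g in list(arow == "-", brow == "-")) {
    if (any(g)) {
      r <- rle(g)
      s <- s - sum(open + ext * r$lengths[r$values])
    }
  }
  s
}

# exhaustively enumerate every global alignment of a and b, return best score
enumerate_alignment_oracle <- function(a, b, mat, open, ext) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  best <- -Inf
  rec <- function(i, j, arow, brow) {
    if (i > n && j > m) {
      best <<- max(best, score_alignment_oracle(arow, brow, mat, open, ext))
      return(invisible(NULL))
    }
    if (i <= n && j <= m) rec(i + 1L, j + 1L, c(arow, ac[i]), c(brow, bc[j]))
    if (i <= n) rec(i + 1L, j, c(arow, ac[i]), c(brow, "-"))
    if (j <= m) rec(i, j + 1L, c(arow, "-"), c(brow, bc[j]))
  }
  rec(1L, 1L, character(), character())
  best
}

# per-codon translation via direct genetic-code lookup
codon_lookup_oracle <- function(dna, frame = 1L) {
  gc_tab <- Biostrings::GENETIC_CODE
  s <- substr(dna, frame, nchar(dna))
  n_cod <- nchar(s) %/% 3L
  out <- character(n_cod)
  for (k in seq_len(n_cod)) {
    cod <- substr(s, 3L * k - 2L, 3L * k)
    out[k] <- if (grepl("[^ACGT]", cod)) "X" else unname(gc_tab[cod])
  }
  paste(out, collapse = "")
}

# exhaustive six-frame ORF scan: every ATG paired with its first in-frame
# stop; longest peptide wins, ties broken + strand first then smallest start
orf_scan_oracle <- function(dna) {
  L <- nchar(dna)
  rc <- paste(rev(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
                         strsplit(dna, "")[[1]])), collapse = "")
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else rc
    for (off in 0:2) {
      idx <- seq(1L + off, L - 2L, by = 3L)
      if (!length(idx)) next
      codons <- substring(s, idx, idx + 2L)
      for (a in which(codons == "ATG")) {
        stops <- which(codons %in% c("TAA", "TAG", "TGA"))
        stops <- stops[stops > a]
        if (!length(stops)) next
        k <- stops[1L]
        len <- k - a
        lo <- idx[a]; hi <- idx[k] + 2L
        if (strand == "+") { st <- lo; en <- hi } else { st <- L - hi + 1L; en <- L - lo + 1L }
        rank <- if (strand == "+") 0L else 1L
        if (is.null(best) || len > best$len ||
            (len == best$len && rank < best$rank) ||
            (len == best$len && rank == best$rank && st < best$st))
          best <- list(len = len, rank = rank, st = st, en = en, strand = strand)
      }
    }
  }
  best
}

# brute-force degenerate-primer matcher: expand every degeneracy to concrete
# primers, slide each over both strands, min mismatches per placement
iupac_expansions <- function(seq) {
  sets <- slc6tools:::IUPAC_DNA[strsplit(seq, "")[[1]]]
  do.call(paste0, expand.grid(sets, stringsAsFactors = FALSE))
}

expansion_match_oracle <- function(primer_seq, template, max_mm, anchor) {
  k <- nchar(primer_seq)
  tch <- strsplit(template, "")[[1]]
  L <- length(tch)
  exps <- iupac_expansions(primer_seq)
  hits <- list()
  for (strand in c("+", "-")) {
    for (p in seq_len(L - k + 1L)) {
      win <- substr(template, p, p + k - 1L)
      best_mm <- Inf; ok_anchor <- FALSE
      for (ex in exps) {
        laid <- if (strand == "+") ex else paste(rev(slc6tools:::IUPAC_COMPLEMENT[strsplit(ex, "")[[1]]]), collapse = "")
        cmp <- strsplit(laid, "")[[1]] == strsplit(win, "")[[1]]
        # anchor = primer 3' end: right end of footprint on +, left end on -
        anc <- if (strand == "+") utils::tail(cmp, anchor) else utils::head(cmp, anchor)
        if (!all(anc)) next
        mm <- sum(!cmp)
        if (mm < best_mm) { best_mm <- mm; ok_anchor <- TRUE }
      }
      if (ok_anchor && best_mm <= max_mm) {
        pos5 <- if (strand == "+") p else p + k - 1L
        hits[[length(hits) + 1L]] <- data.frame(pos_5prime = pos5, strand = strand,
                                                mismatches = best_mm)
      }
    }
  }
  if (!length(hits)) return(data.frame(pos_5prime = integer(), strand = character(),
                                       mismatches = integer()))
  out <- do.call(rbind, hits)
  left <- ifelse(out$strand == "+", out$pos_5prime, out$pos_5prime - k + 1L)
  out <- out[order(left, out$strand), ]
  rownames(out) <- NULL
  out
}

# rule-table oracle for the ion-dependence classification
ion_rule_oracle <- function(na1_status, na2_status, cl_status) {
  na_call <- if (any(na1_status == "unaligned")) "undetermined"
    else if (all(na1_status %in% c("identical", "similar"))) "dependent"
    else "undetermined"
  cl_call <- if (any(cl_status == "unaligned")) "undetermined"
    else if (all(cl_status == "identical")) "dependent"
    else "independent_candidate"
  list(na_call = na_call, cl_call = cl_call)
}

# residue pairs realizing each conservation status under BLOSUM62
status_residue_pair <- function(status) {
  switch(status,
    identical = c("A", "A"),
    similar   = c("S", "T"),   # BLOSUM62 S/T = +1
    divergent = c("D", "W"),   # BLOSUM62 D/W = -4
    unaligned = c("A", NA))
}

random_protein <- function(n, alphabet = slc6tools:::AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
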