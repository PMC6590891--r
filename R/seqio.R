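## Sequence IO, translation, ORF scanning, reverse complement.
## All coordinates anywhere in the package are 1-based inclusive.

# internal validated 1-based inclusive interval
.interval <- function(start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L,
            start >= 1L, end >= start, strand %in% c("+", "-"))
  list(start = start, end = end, strand = strand)
}

#' Read sequences from a FASTA file
#'
#' Multi-record FASTA, wrapped or unwrapped.  Residues are uppercased and
#' validated against the record alphabet; gap characters and any symbol
#' outside the IUPAC DNA / protein alphabets raise a parse error naming the
#' offending line.
#'
#' @param path path to a FASTA file
#' @param alphabet `"auto"` (classify each record: all-IUPAC-DNA residues =>
#'   dna, otherwise protein), `"dna"` or `"protein"`
#' @return List of [SeqRecord-class] objects, input order preserved.
#' @export
readFasta <- function(path, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^;", lines)]
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("FASTA parse error: file is empty: ", path)
  hdr_at <- grep("^>", lines)
  first_content <- which(nzchar(trimws(lines)))[1L]
  if (!length(hdr_at) || !startsWith(lines[first_content], ">"))
    stop("FASTA parse error: line ", first_content,
         " does not start a record ('>') in ", path)

  out <- vector("list", length(hdr_at))
  bounds <- c(hdr_at, length(lines) + 1L)
  for (k in seq_along(hdr_at)) {
    hdr <- sub("^>", "", lines[hdr_at[k]])
    id <- sub("\\s.*$", "", hdr)
    desc <- sub("^\\S+\\s*", "", hdr)
    if (!nzchar(id))
      stop("FASTA parse error: empty record id at line ", hdr_at[k])
    body_idx <- seq(hdr_at[k] + 1L, bounds[k + 1L] - 1L)
    body_idx <- body_idx[body_idx <= length(lines) & body_idx > hdr_at[k]]
    body <- if (length(body_idx)) lines[body_idx] else character()
    for (i in body_idx) {
      bad <- regmatches(lines[i], regexpr("[^A-Za-z \t]", lines[i]))
      if (length(bad) && nzchar(bad))
        stop("FASTA parse error: illegal character '", bad, "' at line ", i)
    }
    residues <- toupper(gsub("[ \t]", "", paste(body, collapse = "")))
    if (!nzchar(residues))
      stop("FASTA parse error: record '", id, "' (line ", hdr_at[k], ") has no residues")
    ab <- alphabet
    if (ab == "auto")
      ab <- if (.is_valid_dna(.chars(residues))) "dna" else "protein"
    rec <- try(SeqRecord(id, residues, ab, desc), silent = TRUE)
    if (inherits(rec, "try-error"))
      stop("FASTA parse error in record '", id, "' (line ", hdr_at[k], "): ",
           attr(rec, "condition")$message)
    out[[k]] <- rec
  }
  out
}

#' Write SeqRecords to FASTA
#'
#' @param records list of [SeqRecord-class] (or a single record)
#' @param path output path
#' @param width line-wrap width
#' @return `path`, invisibly.
#' @export
writeFasta <- function(records, path, width = 70L) {
  if (is(records, "SeqRecord")) records <- list(records)
  con <- file(path, "w"); on.exit(close(con))
  for (r in records) {
    hdr <- if (nzchar(r@description)) paste(r@id, r@description) else r@id
    writeLines(paste0(">", hdr), con)
    n <- nchar(r@residues)
    starts <- seq(1L, n, by = width)
    writeLines(substring(r@residues, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Translate a DNA record
#'
#' Standard genetic code; frames 1..3 on the given strand of the record.
#' Codons containing ambiguity codes translate to `X` (the cloned-library
#' context makes Ns plausible, so they are not an error); stop codons are
#' written `*` unless `to_first_stop` truncates at the first stop.  A
#' trailing incomplete codon is dropped.
#'
#' @param dna a DNA [SeqRecord-class]
#' @param frame 1, 2 or 3 (offset from the 5' end)
#' @param to_first_stop if TRUE, return the peptide up to (excluding) the
#'   first stop codon
#' @return A protein [SeqRecord-class].
#' @examples
#' translateDna(SeqRecord("x", "ATGTAA", "dna"), to_first_stop = TRUE)
#' @export
translateDna <- function(dna, frame = 1L, to_first_stop = FALSE) {
  stopifnot(is(dna, "SeqRecord"))
  if (dna@alphabet != "dna") stop("translateDna requires a DNA record")
  frame <- as.integer(frame)
  if (length(frame) != 1L || is.na(frame) || frame < 1L || frame > 3L)
    stop("frame must be 1, 2 or 3")
  s <- substr(dna@residues, frame, nchar(dna@residues))
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) stop("no complete codon in frame ", frame)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(substr(s, 1, n)),
                                           if.fuzzy.codon = "X",
                                           no.init.codon = TRUE))
  if (to_first_stop) {
    stop_at <- regexpr("*", aa, fixed = TRUE)
    if (stop_at > 0L) aa <- substr(aa, 1L, stop_at - 1L)
    if (!nzchar(aa)) stop("translation is empty: stop codon at frame start")
  }
  new("SeqRecord", id = paste0(dna@id, "_translation"),
      description = sprintf("frame %d translation of %s", frame, dna@id),
      alphabet = "protein", residues = aa)
}

#' Reverse complement of a DNA record
#'
#' IUPAC-aware (R<->Y, K<->M, B<->V, D<->H; S, W, N self-complementary).
#' An involution: applying it twice recovers the input.
#'
#' @param dna a DNA [SeqRecord-class]
#' @return A DNA [SeqRecord-class].
#' @export
revComp <- function(dna) {
  stopifnot(is(dna, "SeqRecord"))
  if (dna@alphabet != "dna") stop("revComp requires a DNA record")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna@residues)))
  new("SeqRecord", id = dna@id, description = dna@description,
      alphabet = "dna", residues = rc)
}

# reverse complement for plain character strings (internal)
.revcomp_chr <- function(x) {
  paste(rev(IUPAC_COMPLEMENT[.chars(x)]), collapse = "")
}

#' Locate the longest open reading frame
#'
#' Scans all six frames for ATG..stop ORFs (stop codon required and included
#' in the reported interval).  Ties on amino-acid length are broken by strand
#' (+ before -) and then by smallest interval start on the forward
#' coordinates.  Degenerate codons translate to X and never count as start or
#' stop.
#'
#' @param dna a DNA [SeqRecord-class], length >= 3
#' @return `NULL` when no ORF exists; otherwise a list with `interval`
#'   (start, end, strand; 1-based inclusive, forward coordinates) and
#'   `protein` (a protein [SeqRecord-class], stop codon not translated).
#' @examples
#' findLongestOrf(SeqRecord("x", "ATGAAATAG", "dna"))
#' @export
findLongestOrf <- function(dna) {
  stopifnot(is(dna, "SeqRecord"))
  if (dna@alphabet != "dna") stop("findLongestOrf requires a DNA record")
  L <- nchar(dna@residues)
  if (L < 3L) stop("sequence shorter than one codon")
  stops <- c("TAA", "TAG", "TGA")

  best <- NULL  # list(len, strand_rank, start, end, strand, peptide)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna@residues else .revcomp_chr(dna@residues)
    for (frame in 1:3) {
      n_cod <- (L - frame + 1L) %/% 3L
      if (n_cod < 2L) next
      cod_start <- frame + 3L * (seq_len(n_cod) - 1L)
      codons <- substring(s, cod_start, cod_start + 2L)
      is_stop <- codons %in% stops
      is_atg <- codons == "ATG"
      prev_stop <- 0L
      for (k in which(is_stop)) {
        cand <- which(is_atg[seq.int(prev_stop + 1L, k)]) + prev_stop
        prev_stop <- k
        if (!length(cand)) next
        a <- cand[1L]                       # earliest ATG => longest ORF to this stop
        aa_len <- k - a                     # codons excluding the stop
        if (aa_len < 1L) next
        lo <- cod_start[a]; hi <- cod_start[k] + 2L  # coords on strand s
        if (strand == "+") { start <- lo; end <- hi }
        else { start <- L - hi + 1L; end <- L - lo + 1L }
        strand_rank <- if (strand == "+") 0L else 1L
        better <- is.null(best) ||
          aa_len > best$len ||
          (aa_len == best$len && strand_rank < best$strand_rank) ||
          (aa_len == best$len && strand_rank == best$strand_rank && start < best$start)
        if (better) {
          pep <- as.character(Biostrings::translate(
            Biostrings::DNAString(substr(s, lo, cod_start[k] - 1L)),
            if.fuzzy.codon = "X", no.init.codon = TRUE))
          best <- list(len = aa_len, strand_rank = strand_rank,
                       start = start, end = end, strand = strand, peptide = pep)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(interval = .interval(best$start, best$end, best$strand),
       protein = new("SeqRecord", id = paste0(dna@id, "_orf"),
                     description = sprintf("longest ORF of %s (%s strand)",
                                           dna@id, best$strand),
                     alphabet = "protein", residues = best$peptide))
}
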