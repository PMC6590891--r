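## Seeded synthetic-data generators: protein families on trees with invariant
## (planted) binding-site columns, membrane proteins with planted TM/sequon
## features, and DNA templates with planted primer sites.  Every generator is
## a pure function of its seed.

# residue pools chosen so the Kyte-Doolittle window mean crosses the classic
# 1.6 threshold within about one window-centre of a true TM boundary:
# TM pool KD >= 3.8 (mean ~4.17), loop pool mean KD ~ -0.93
.TM_POOL <- c("I", "V", "L")
.LOOP_POOL <- c("T", "S", "W", "Y")

#' Random bifurcating tree
#'
#' Coalescent-style construction: starting from the tips, joins a uniformly
#' random pair of lineages until one remains; every branch length is drawn
#' from an exponential with mean `length_scale` (expected substitutions per
#' site).  Deterministic per seed.
#'
#' @param n_taxa number of tips (>= 3); labels t1..tn
#' @param seed RNG seed
#' @param length_scale mean branch length
#' @return An ape `phylo`.
#' @export
randomTree <- function(n_taxa, seed = 1L, length_scale = 0.1) {
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 3L) stop("need at least 3 taxa")
  set.seed(seed)
  nodes <- paste0("t", seq_len(n_taxa))
  repeat {
    if (length(nodes) == 1L) break
    pick <- sort(sample.int(length(nodes), 2L))
    bl <- rexp(2L, rate = 1 / length_scale)
    merged <- sprintf("(%s:%.8f,%s:%.8f)", nodes[pick[1L]], bl[1L],
                      nodes[pick[2L]], bl[2L])
    nodes <- c(nodes[-pick], merged)
  }
  ape::read.tree(text = paste0(nodes, ";"))
}

#' Simulate a protein family on a tree
#'
#' Evolves a root sequence down the tree under a uniform-replacement model:
#' on a branch of length b each mutable site differs from its parent with
#' probability 1 - exp(-b), the replacement drawn uniformly from the other 19
#' residues (so the observed per-branch substitution fraction has closed form
#' 1 - exp(-b)).  Planted invariant columns never substitute - they emulate
#' the conservation structure of binding-site residues.
#'
#' @param tree an ape `phylo` (default: `randomTree(n_taxa, seed)`)
#' @param n_taxa used only when `tree` is NULL
#' @param root_seq root protein string; default random uniform over the 20
#'   residues of length `length`
#' @param length root sequence length when `root_seq` is NULL
#' @param invariant_columns integer positions never substituted
#' @param seed RNG seed
#' @param length_scale passed to [randomTree()] when `tree` is NULL
#' @return list: `records` (protein [SeqRecord-class] per tip, tip order) and
#'   `truth` (tree, root_seq, invariant_columns).
#' @export
simulateFamily <- function(tree = NULL, n_taxa = 8L, root_seq = NULL,
                           length = 200L, invariant_columns = integer(),
                           seed = 1L, length_scale = 0.1) {
  if (is.null(tree)) tree <- randomTree(n_taxa, seed, length_scale)
  set.seed(seed + 1L)
  if (is.null(root_seq))
    root_seq <- paste(sample(AA20, length, replace = TRUE), collapse = "")
  root_seq <- toupper(root_seq)
  L <- nchar(root_seq)
  invariant_columns <- as.integer(invariant_columns)
  if (any(invariant_columns < 1L | invariant_columns > L))
    stop("invariant column outside the sequence")
  mutable <- setdiff(seq_len(L), invariant_columns)

  phy <- stats::reorder(tree, "cladewise")
  n_tip <- ape::Ntip(phy)
  seqs <- vector("list", n_tip + phy$Nnode)
  seqs[[n_tip + 1L]] <- .chars(root_seq)
  for (e in seq_len(nrow(phy$edge))) {
    parent <- phy$edge[e, 1L]; child <- phy$edge[e, 2L]
    b <- phy$edge.length[e]
    s <- seqs[[parent]]
    if (length(mutable) && b > 0) {
      hit <- mutable[runif(length(mutable)) < 1 - exp(-b)]
      for (p in hit) s[p] <- sample(setdiff(AA20, s[p]), 1L)
    }
    seqs[[child]] <- s
  }
  records <- lapply(seq_len(n_tip), function(i)
    SeqRecord(phy$tip.label[i], paste(seqs[[i]], collapse = ""), "protein"))
  list(records = records,
       truth = list(tree = phy, root_seq = root_seq,
                    invariant_columns = invariant_columns))
}

#' Generate a membrane protein with planted features
#'
#' Tiles the chain as loop1, TM1, loop2, ..., TMn, loop(n+1).  TM regions are
#' drawn from strongly hydrophobic residues (I/V/L, KD >= 3.8), loops from
#' hydrophilic ones (T/S/W/Y); sequons (N-X-\[S/T\]) and cysteines are spliced
#' at the requested loop positions.  Defaults emulate the canonical SLC6
#' architecture: 12 TM segments of 21 residues and an enlarged loop between
#' TM3 and TM4 carrying two sequons and three cysteines.  Planted point
#' features should sit >= 12 residues from a TM boundary so they cannot
#' perturb the hydropathy windows that call the segment edges.
#'
#' @param n_tm number of TM segments
#' @param tm_len TM length (residues)
#' @param loop_lens lengths of the n_tm + 1 loops; default 25 everywhere
#'   except a 60-residue loop between TM3 and TM4 (when n_tm >= 4)
#' @param sequon_positions start positions for planted sequons; NULL =
#'   automatic placement in the largest loop
#' @param cys_positions positions for planted cysteines; NULL = automatic
#' @param seed RNG seed
#' @return list: `record` (protein [SeqRecord-class]) and `truth` (tm,
#'   sequons, cysteines data.frames/vectors, loops).
#' @export
makeMembraneProtein <- function(n_tm = 12L, tm_len = 21L, loop_lens = NULL,
                                sequon_positions = NULL, cys_positions = NULL,
                                seed = 1L) {
  n_tm <- as.integer(n_tm); tm_len <- as.integer(tm_len)
  if (is.null(loop_lens)) {
    loop_lens <- rep(25L, n_tm + 1L)
    if (n_tm >= 4L) loop_lens[4L] <- 60L  # EL2-like enlarged loop after TM3
  }
  loop_lens <- as.integer(loop_lens)
  if (length(loop_lens) != n_tm + 1L)
    stop("loop_lens must have n_tm + 1 entries")
  set.seed(seed)

  tm <- data.frame(start = integer(n_tm), end = integer(n_tm))
  chunks <- character(0)
  pos <- 1L
  for (k in seq_len(n_tm + 1L)) {
    chunks <- c(chunks, paste(sample(.LOOP_POOL, loop_lens[k], replace = TRUE),
                              collapse = ""))
    pos <- pos + loop_lens[k]
    if (k <= n_tm) {
      tm$start[k] <- pos
      chunks <- c(chunks, paste(sample(.TM_POOL, tm_len, replace = TRUE),
                                collapse = ""))
      pos <- pos + tm_len
      tm$end[k] <- pos - 1L
    }
  }
  chars <- .chars(paste(chunks, collapse = ""))
  L <- length(chars)

  biggest <- which.max(loop_lens)
  loop_start <- if (biggest == 1L) 1L else tm$end[biggest - 1L] + 1L
  if (is.null(sequon_positions))
    sequon_positions <- if (loop_lens[biggest] >= 40L)
      c(loop_start + 15L, loop_start + 24L) else integer()
  if (is.null(cys_positions))
    cys_positions <- if (loop_lens[biggest] >= 40L)
      c(loop_start + 12L, loop_start + 33L, loop_start + 34L) else integer()

  in_tm <- function(p) any(p >= tm$start & p <= tm$end)
  for (p in sequon_positions) {
    if (any(vapply(p:(p + 2L), in_tm, logical(1))))
      stop("sequon at ", p, " overlaps a TM region")
    chars[p] <- "N"
    chars[p + 1L] <- sample(setdiff(.LOOP_POOL, "P"), 1L)
    chars[p + 2L] <- sample(c("S", "T"), 1L)
  }
  for (p in cys_positions) {
    if (in_tm(p)) stop("cysteine at ", p, " lies inside a TM region")
    chars[p] <- "C"
  }
  list(record = SeqRecord(sprintf("synthetic_mp_seed%d", seed),
                          paste(chars, collapse = ""), "protein"),
       truth = list(tm = tm,
                    sequons = data.frame(start = as.integer(sequon_positions),
                                         end = as.integer(sequon_positions + 2L)),
                    cysteines = sort(as.integer(cys_positions)),
                    loops = loop_lens, length = L))
}

#' Generate a DNA template with planted primer sites
#'
#' Random ACGT background; each insert splices one concrete realization of
#' its (possibly degenerate) primer at the requested 5' coordinate and
#' strand, degeneracies resolved uniformly at random and recorded in the
#' truth list so downstream mismatch counts are exact.  For a - strand
#' insert, `pos` is the template coordinate of the primer's 5' base, i.e. the
#' rightmost base of the footprint.
#'
#' @param length template length
#' @param inserts list of `list(primer = <Primer>, pos = <int>, strand =
#'   "+"/"-")`; footprints must not overlap
#' @param seed RNG seed
#' @return list: `record` (DNA [SeqRecord-class]) and `truth` (data.frame
#'   name, pos, strand, realization).
#' @export
makeTemplateWithPrimers <- function(length, inserts = list(), seed = 1L) {
  L <- as.integer(length)
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  occupied <- integer()
  truth <- list()
  for (ins in inserts) {
    p <- ins$primer; stopifnot(inherits(p, "Primer"))
    k <- nchar(p$seq)
    span <- if (ins$strand == "+") ins$pos:(ins$pos + k - 1L)
            else (ins$pos - k + 1L):ins$pos
    if (min(span) < 1L || max(span) > L)
      stop("insert footprint outside template")
    if (any(span %in% occupied)) stop("overlapping primer inserts")
    occupied <- c(occupied, span)
    real <- vapply(.chars(p$seq),
                   function(cc) { exp_ <- IUPAC_DNA[[cc]]
                                  if (length(exp_) == 1L) exp_ else sample(exp_, 1L) },
                   character(1))
    real <- paste(real, collapse = "")
    laid <- if (ins$strand == "+") real else .revcomp_chr(real)
    chars[span] <- .chars(laid)
    truth[[length(truth) + 1L]] <- data.frame(
      name = p$name, pos = as.integer(ins$pos), strand = ins$strand,
      realization = real, stringsAsFactors = FALSE)
  }
  list(record = SeqRecord(sprintf("synthetic_template_seed%d", seed),
                          paste(chars, collapse = ""), "dna"),
       truth = if (length(truth)) do.call(rbind, truth)
               else data.frame(name = character(), pos = integer(),
                               strand = character(), realization = character()))
}
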