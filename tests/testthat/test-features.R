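test_that("hydropathy profile equals the windowed-mean oracle", {
  expect_equal(unname(kdProfile(SeqRecord("r", strrep("R", 19), "protein"))@scores),
               -4.5)
  expect_equal(unname(kdProfile(SeqRecord("i", strrep("I", 19), "protein"))@scores),
               4.5)
  expect_error(kdProfile(SeqRecord("x", strrep("A", 30), "protein"), window = 10),
               "odd")
  expect_error(kdProfile(SeqRecord("x", "AAAA", "protein"), window = 19), "length")

  set.seed(5)
  p <- random_protein(100)
  kd <- slc6tools:::KD_SCALE
  for (w in c(7L, 19L)) {
    prof <- kdProfile(SeqRecord("p", p, "protein"), window = w)
    vals <- kd[strsplit(p, "")[[1]]]
    want <- vapply(seq_len(100 - w + 1L), function(i) mean(vals[i:(i + w - 1L)]),
                   numeric(1))
    expect_equal(unname(prof@scores), want)
    expect_equal(as.integer(names(prof@scores)[1]), (w %/% 2L) + 1L)
  }
})

test_that("TM segment calling finds planted blocks and is threshold-monotone", {
  allr <- kdProfile(SeqRecord("r", strrep("R", 60), "protein"))
  expect_equal(nrow(callTmSegments(allr)), 0L)

  blocks <- paste0(strrep("D", 15), strrep("L", 21), strrep("D", 15),
                   strrep("L", 21), strrep("D", 15), strrep("L", 21),
                   strrep("D", 15))
  prof <- kdProfile(SeqRecord("b", blocks, "protein"))
  seg <- callTmSegments(prof)
  expect_equal(nrow(seg), 3L)
  # planted blocks span 16-36, 52-72, 88-108: each call lies inside its
  # block and covers the block centre (strong D/L contrast narrows the run)
  expect_true(all(seg$start >= c(16, 52, 88) & seg$end <= c(36, 72, 108)))
  expect_true(all(seg$start <= c(26, 62, 98) & seg$end >= c(26, 62, 98)))

  set.seed(9)
  mp <- makeMembraneProtein(seed = 31)
  prof2 <- kdProfile(mp$record)
  thresholds <- c(0.5, 1.0, 1.6, 2.2, 2.8)
  counts <- vapply(thresholds, function(th)
    nrow(callTmSegments(prof2, threshold = th)), integer(1))
  runs <- lapply(thresholds, function(th) callTmSegments(prof2, threshold = th))
  # raising the threshold never adds a segment position
  for (k in seq_along(thresholds)[-1]) {
    hi <- runs[[k]]; lo <- runs[[k - 1]]
    hi_pos <- unlist(mapply(seq, hi$start, hi$end, SIMPLIFY = FALSE))
    lo_pos <- unlist(mapply(seq, lo$start, lo$end, SIMPLIFY = FALSE))
    expect_true(all(hi_pos %in% lo_pos))
  }
})

test_that("topology alternates sides from the N-terminus", {
  seg12 <- data.frame(start = seq(30, by = 50, length.out = 12),
                      end = seq(50, by = 50, length.out = 12))
  topo <- assignTopology(seg12, 650, "in")
  expect_equal(topo$c_term_side, "in")
  # loop between TM3 and TM4 is extracellular
  l34 <- topo$loops[topo$loops$start == seg12$end[3] + 1L, ]
  expect_equal(l34$side, "out")

  topo0 <- assignTopology(data.frame(start = integer(), end = integer()),
                          100, "in")
  expect_equal(nrow(topo0$loops), 1L)
  expect_equal(topo0$loops$side, "in")

  topo1 <- assignTopology(data.frame(start = 40, end = 60), 100, "in")
  expect_equal(topo1$c_term_side, "out")
})

test_that("largest out loop is identified (EL2 analogue)", {
  seg <- data.frame(start = c(20, 60, 100, 220), end = c(40, 80, 120, 240))
  topo <- assignTopology(seg, 300, "in")
  big <- topo$loops[topo$largest_out_loop, ]
  expect_equal(big$side, "out")
  expect_equal(c(big$start, big$end), c(121, 219))
})

test_that("sequon scan excludes proline, restricts to regions, ignores suffixes", {
  expect_equal(nrow(findSequons(SeqRecord("x", "MNPSA", "protein"))), 0L)
  sq <- findSequons(SeqRecord("x", "ANLSD", "protein"))
  expect_equal(sq$start, 2L)
  expect_equal(sq$end, 4L)

  p <- SeqRecord("x", "MMNLSDAANLTR", "protein")
  all_sq <- findSequons(p)
  expect_equal(all_sq$start, c(3L, 9L))
  expect_equal(findSequons(p, region = c(1, 5))$start, 3L)

  set.seed(21)
  base <- random_protein(60)
  suffix <- paste(sample(setdiff(slc6tools:::AA20, "N"), 20, replace = TRUE),
                  collapse = "")
  expect_equal(findSequons(SeqRecord("a", base, "protein"))$start,
               findSequons(SeqRecord("b", paste0(base, suffix), "protein"))$start)
})

test_that("average mass matches an independent residue-mass summation", {
  expect_equal(averageMass(SeqRecord("g", "G", "protein")), 75.07,
               tolerance = 0.01 / 75.07)
  masses <- c(A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155,
              F = 147.1766, G = 57.0519, H = 137.1411, I = 113.1594,
              K = 128.1741)
  expect_equal(averageMass(SeqRecord("x", "ACDEFGHIK", "protein")),
               sum(masses) + 18.0153, tolerance = 1e-6)
  expect_error(averageMass(SeqRecord("x", "AXA", "protein")), "ambiguous")
})

test_that("cysteine inventory equals a linear scan", {
  expect_equal(cysteinesInRegion(SeqRecord("x", "CACA", "protein"), c(1, 4)),
               c(1L, 3L))
  set.seed(13)
  p <- random_protein(200)
  expect_equal(cysteinesInRegion(SeqRecord("p", p, "protein")),
               which(strsplit(p, "")[[1]] == "C"))
})
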