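test_that("MSA distances match a direct column scan", {
  msa <- c(a = "MKVLW", b = "MKVLW")
  expect_equal(unname(msaDistances(msa)["a", "b"]), 0)

  r1 <- paste(rep("A", 100), collapse = "")
  r2 <- paste(c(rep("A", 95), rep("C", 5)), collapse = "")
  D <- msaDistances(c(x = r1, y = r2), model = "p_distance")
  expect_equal(unname(D["x", "y"]), 0.05)
  Dp <- msaDistances(c(x = r1, y = r2))
  expect_equal(unname(Dp["x", "y"]), -log(0.95))

  set.seed(31)
  rows <- setNames(replicate(5, random_protein(80)), paste0("s", 1:5))
  # punch some gaps
  rows[2] <- paste0("----", substr(rows[2], 5, 80))
  D2 <- msaDistances(rows, model = "p_distance")
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  for (i in 1:4) for (j in (i + 1):5) {
    both <- mat[i, ] != "-" & mat[j, ] != "-"
    expect_equal(unname(D2[i, j]), sum(mat[i, both] != mat[j, both]) / sum(both))
  }

  sat <- c(a = strrep("A", 10), b = strrep("C", 10))
  expect_error(msaDistances(sat), "saturated")
  expect_error(msaDistances(c(a = "A-", b = "-A"), "p_distance"), "overlap")
})

test_that("three-taxon NJ uses the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  st <- njTree(D)
  phy <- asPhylo(st)
  # v_A = (3+4-5)/2 = 1, v_B = (3+5-4)/2 = 2, v_C = (4+5-3)/2 = 3
  bl <- setNames(phy$edge.length, phy$tip.label[phy$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 2, 3))
  expect_error(njTree(D[1:2, 1:2]), "3 taxa")
})

test_that("NJ recovers the generating topology from additive distances", {
  set.seed(35)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.2, 1))
    D <- ape::cophenetic.phylo(tr)
    D <- D[tr$tip.label, tr$tip.label]
    st <- njTree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), asPhylo(st)), 0,
                 ignore_attr = TRUE)
    # independent cross-check: agrees with ape's NJ topology
    expect_equal(ape::dist.topo(ape::nj(D), asPhylo(st)), 0, ignore_attr = TRUE)
  }
})

test_that("total tree length is invariant under taxon reordering", {
  set.seed(37)
  tr <- ape::rtree(8, br = function(k) runif(k, 0.2, 1))
  D <- ape::cophenetic.phylo(tr)
  perm <- sample(rownames(D))
  st1 <- njTree(D)
  st2 <- njTree(D[perm, perm])
  expect_equal(sum(asPhylo(st1)$edge.length), sum(asPhylo(st2)$edge.length))
})

test_that("bootstrap gives full support to an unambiguous deep split", {
  blockA <- strrep("A", 60); blockB <- strrep("W", 60)
  msa <- c(a1 = blockA, a2 = blockA, a3 = blockA,
           b1 = blockB, b2 = blockB, b3 = blockB)
  # identical-within-block rows make within-block distances 0; add signal
  msa["a3"] <- paste0(strrep("A", 58), "CC")
  msa["b3"] <- paste0(strrep("W", 58), "CC")
  st <- bootstrapSupport(msa, n_reps = 50, seed = 7, model = "p_distance")
  sup <- supportValues(st)
  expect_true(any(sup[!is.na(sup)] == 1))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 1))
})

test_that("single-replicate bootstrap supports are 0 or 1 and runs are seeded", {
  fam <- simulateFamily(n_taxa = 6, length = 150, seed = 41, length_scale = 0.2)
  msa <- progressiveMsa(fam$records)
  st1 <- bootstrapSupport(msa, n_reps = 1, seed = 9)
  sup <- supportValues(st1)
  expect_true(all(sup[!is.na(sup)] %in% c(0, 1)))
  st2 <- bootstrapSupport(msa, n_reps = 25, seed = 10)
  st3 <- bootstrapSupport(msa, n_reps = 25, seed = 10)
  expect_identical(supportValues(st2), supportValues(st3))
})

test_that("outgroup rooting places the root on the separating edge", {
  phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  st <- new("SupportedTree", tree = ape::unroot(phy),
            supports = rep(NA_real_, ape::unroot(phy)$Nnode), rooted = FALSE)
  rooted <- rootByOutgroup(st, c("C", "D"))
  expect_true(ape::is.rooted(asPhylo(rooted)))
  expect_true(ape::is.monophyletic(asPhylo(rooted), c("C", "D")))
  expect_true(ape::is.monophyletic(asPhylo(rooted), c("A", "B")))

  single <- rootByOutgroup(st, "D")
  expect_true(ape::is.rooted(asPhylo(single)))

  # rooting never changes the bipartition set
  expect_equal(ape::dist.topo(ape::unroot(asPhylo(rooted)), asPhylo(st)), 0,
               ignore_attr = TRUE)

  bad <- ape::unroot(ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);"))
  stbad <- new("SupportedTree", tree = bad,
               supports = rep(NA_real_, bad$Nnode), rooted = FALSE)
  expect_error(rootByOutgroup(stbad, c("C", "D")), "monophyletic")
  expect_error(rootByOutgroup(st, c("Z")), "absent")
})

test_that("cluster assignment labels the query by its smallest labelled clade", {
  # query nested inside an all-NAT clade
  phy <- ape::read.tree(text = "(((query:1,nat1:1):1,nat2:1):1,(gaba1:1,(out1:1,out2:1):1):1);")
  labels <- c(query = "query", nat1 = "NAT", nat2 = "NAT",
              gaba1 = "NTT-GABAT", out1 = "outgroup", out2 = "outgroup")
  st <- new("SupportedTree", tree = phy, supports = rep(NA_real_, phy$Nnode),
            rooted = TRUE)
  res <- clusterAssignment(st, labels)
  expect_equal(res$query_cluster_label, "NAT")
  expect_true(res$is_nested)
  expect_true("nat1" %in% res$sister_taxa)

  # query sister to a mixed clade: majority label, not nested
  phy2 <- ape::read.tree(text = "((query:1,((n1:1,n2:1):1,(n3:1,g1:1):1):1):1,(o1:1,o2:1):1);")
  labels2 <- c(query = "query", n1 = "NAT", n2 = "NAT", n3 = "NAT",
               g1 = "NTT-GABAT", o1 = "outgroup", o2 = "outgroup")
  st2 <- new("SupportedTree", tree = phy2, supports = rep(NA_real_, phy2$Nnode),
             rooted = TRUE)
  res2 <- clusterAssignment(st2, labels2)
  expect_equal(res2$query_cluster_label, "NAT")
  expect_false(res2$is_nested)
  expect_setequal(res2$sister_taxa, c("n1", "n2", "n3", "g1"))

  expect_error(clusterAssignment(st, labels[-1]), "query")
})

test_that("Newick round-trip preserves supports and branch lengths", {
  fam <- simulateFamily(n_taxa = 5, length = 100, seed = 43)
  msa <- progressiveMsa(fam$records)
  st <- bootstrapSupport(msa, n_reps = 10, seed = 3)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeSupportedTree(st, f)
  back <- readSupportedTree(f)
  expect_equal(sort(asPhylo(back)$tip.label), sort(asPhylo(st)$tip.label))
  expect_equal(sum(asPhylo(back)$edge.length), sum(asPhylo(st)$edge.length),
               tolerance = 1e-6)
  got <- supportValues(back)
  want <- supportValues(st)
  expect_equal(got[!is.na(got)], want[!is.na(want)], tolerance = 0.005,
               ignore_attr = TRUE)
})
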