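make_aln <- function(a, b) new("GlobalAlignment", a_id = "T", b_id = "Q",
                               a_aln = a, b_aln = b, score = 0,
                               gap_open = 10, gap_extend = 0.5)

test_that("position mapping walks alignment columns correctly", {
  ident <- make_aln("MKVLW", "MKVLW")
  expect_equal(mapPositions(ident, 1:5), 1:5)

  # template ABD vs query ACD aligned as AB-D / A-CD
  aln <- make_aln("AB-D", "A-CD")
  expect_equal(mapPositions(aln, 1L), 1L)
  expect_true(is.na(mapPositions(aln, 2L)))
  expect_equal(mapPositions(aln, 3L), 3L)
  expect_error(mapPositions(aln, 9L), "out of range")

  # order-preserving and injective on aligned positions
  set.seed(22)
  for (rep in 1:10) {
    a <- SeqRecord("a", random_protein(40), "protein")
    b <- SeqRecord("b", random_protein(35), "protein")
    al <- globalAlign(a, b)
    m <- mapPositions(al, 1:40)
    m <- m[!is.na(m)]
    expect_true(all(diff(m) > 0))
  }
})

test_that("projecting a template onto itself is 100% identical for all fixtures", {
  sites <- loadTemplateSites()
  set.seed(24)
  for (tid in unique(sites$template_id)) {
    sub <- sites[sites$template_id == tid, ]
    # synthetic template realizing the fixture residues at the fixture positions
    L <- max(sub$pos) + 10L
    chars <- sample(slc6tools:::AA20, L, replace = TRUE)
    chars[sub$pos] <- sub$residue
    tmpl <- paste(chars, collapse = "")
    aln <- make_aln(tmpl, tmpl)
    proj <- projectSites(sub, aln)
    expect_true(all(projectionTable(proj)$status == "identical"))
  }
})

test_that("template residue check catches a mis-numbered template", {
  sites <- data.frame(site = "Na1", pos = c(2L, 4L), residue = c("A", "G"))
  aln <- make_aln("MAKGW", "MAKGW")
  expect_silent(projectSites(sites, aln))
  bad <- data.frame(site = "Na1", pos = 2L, residue = "W")
  expect_error(projectSites(bad, aln), "mismatch at 2")
})

test_that("status assignment distinguishes identical, similar, divergent, unaligned", {
  # template ASDW, query A T W -; S->T similar (+1), D->W divergent (-4)
  aln <- make_aln("ASDW", "ATW-")
  sites <- data.frame(site = "s", pos = 1:4, residue = c("A", "S", "D", "W"))
  st <- projectionTable(projectSites(sites, aln))$status
  expect_equal(st, c("identical", "similar", "divergent", "unaligned"))
})

test_that("ion-dependence call matches the rule-table oracle on all status combinations", {
  statuses <- c("identical", "similar", "divergent")
  combos <- expand.grid(na1_1 = statuses, na1_2 = statuses, na2_1 = statuses,
                        cl_1 = statuses, cl_2 = statuses,
                        stringsAsFactors = FALSE)
  build_proj <- function(sts, sites_grp) {
    rows <- lapply(seq_along(sts), function(k) {
      pr <- status_residue_pair(sts[k])
      data.frame(site = sites_grp[k], template_pos = 10L * k,
                 template_res = pr[1], query_pos = 10L * k,
                 query_res = pr[2], status = sts[k],
                 stringsAsFactors = FALSE)
    })
    new("SiteProjection", template_id = "T", query_id = "Q",
        entries = do.call(rbind, rows))
  }
  grp <- c("Na1", "Na1", "Na2", "Cl", "Cl")
  for (i in seq_len(nrow(combos))) {
    sts <- unlist(combos[i, ], use.names = FALSE)
    call <- classifyIonDependence(build_proj(sts, grp))
    want <- ion_rule_oracle(sts[1:2], sts[3], sts[4:5])
    expect_equal(call@na_call, want$na_call, info = paste(sts, collapse = ","))
    expect_equal(call@cl_call, want$cl_call, info = paste(sts, collapse = ","))
  }

  # unaligned entries degrade the affected call to undetermined
  sts <- c("identical", "unaligned", "identical", "identical", "identical")
  call <- classifyIonDependence(build_proj(sts, grp))
  expect_equal(call@na_call, "undetermined")
  expect_equal(call@cl_call, "dependent")
  sts <- c("identical", "identical", "identical", "unaligned", "identical")
  call <- classifyIonDependence(build_proj(sts, grp))
  expect_equal(call@cl_call, "undetermined")
})

test_that("the call is invariant under permutation of projection entries", {
  sts <- c("identical", "similar", "divergent", "identical", "similar")
  grp <- c("Na1", "Na1", "Na2", "Cl", "Cl")
  rows <- lapply(seq_along(sts), function(k) {
    pr <- status_residue_pair(sts[k])
    data.frame(site = grp[k], template_pos = 10L * k, template_res = pr[1],
               query_pos = 10L * k, query_res = pr[2], status = sts[k],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  base <- classifyIonDependence(new("SiteProjection", template_id = "T",
                                    query_id = "Q", entries = df))
  set.seed(26)
  for (rep in 1:5) {
    perm <- df[sample(nrow(df)), ]
    # restore ascending positions per site so the object stays valid while
    # the status-to-position assignment is permuted
    for (s in unique(perm$site)) {
      sel <- perm$site == s
      perm$template_pos[sel] <- sort(perm$template_pos[sel])
      perm$query_pos[sel] <- sort(perm$query_pos[sel])
    }
    call <- classifyIonDependence(new("SiteProjection", template_id = "T",
                                      query_id = "Q", entries = perm))
    expect_equal(call@na_call, base@na_call)
    expect_equal(call@cl_call, base@cl_call)
    expect_equal(call@cl_conserved, base@cl_conserved)
  }
})

test_that("a serine-to-threonine chloride site is flagged in the rationale", {
  aln <- make_aln("YSNS", "YTNS")
  sites <- data.frame(site = "Cl", pos = 1:4, residue = c("Y", "S", "N", "S"))
  proj <- projectSites(sites, aln)
  # fake Na sites so the classifier runs
  e <- projectionTable(proj)
  na <- data.frame(site = c("Na1", "Na2"), template_pos = c(100L, 101L),
                   template_res = "A", query_pos = c(100L, 101L),
                   query_res = "A", status = "identical")
  proj2 <- new("SiteProjection", template_id = "T", query_id = "Q",
               entries = rbind(e, na))
  call <- classifyIonDependence(proj2)
  expect_equal(call@cl_call, "independent_candidate")
  expect_equal(call@cl_conserved, 3L)
  expect_match(call@rationale, "threonine")
})

test_that("pocket conservation reports full agreement for identical sequences", {
  msa <- setNames(rep("MKGLFWSYAA", 4), c("T", "a", "b", "c"))
  sites <- data.frame(site = "pocket", pos = c(3L, 5L, 7L),
                      residue = c("G", "F", "S"))
  rep_ <- pocketConservationReport(sites, msa, "T")
  expect_true(all(rep_$per_sequence$matches == 3L))
  expect_true(all(rep_$columns$conservation == 1))
  expect_error(pocketConservationReport(sites, msa, "absent"), "absent")
})

test_that("planted invariant pocket columns score full size at every leaf", {
  pocket <- data.frame(site = "pocket", pos = c(25L, 60L, 104L, 141L, 180L),
                       residue = c("G", "L", "F", "S", "Y"))
  set.seed(28)
  root <- sample(slc6tools:::AA20, 200, replace = TRUE)
  root[pocket$pos] <- pocket$residue
  fam <- simulateFamily(n_taxa = 7, root_seq = paste(root, collapse = ""),
                        invariant_columns = pocket$pos, seed = 29)
  recs <- c(fam$records,
            SeqRecord("SYN_TEMPLATE", fam$truth$root_seq, "protein"))
  msa <- progressiveMsa(recs)
  rep_ <- pocketConservationReport(pocket, msa, "SYN_TEMPLATE")
  expect_true(all(rep_$per_sequence$matches == nrow(pocket)))
})

test_that("the bundled synthetic pocket fixture loads and is flagged synthetic", {
  path <- system.file("extdata", "pocket_sites_synthetic.tsv",
                      package = "slc6tools")
  pocket <- loadTemplateSites(path)
  expect_equal(unique(pocket$template_id), "SYN_TEMPLATE")
  expect_true(any(grepl("SYNTHETIC", readLines(path))))
})
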