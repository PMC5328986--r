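test_that("pairwise distances follow the gap-excluded mismatch convention", {
  d0 <- pairwise_distances(c(a = "ACGT", b = "ACGT"))
  expect_equal(d0["a", "b"], 0)

  s1 <- strrep("A", 458)
  s2 <- paste0(strrep("A", 453), "CCCCC")
  d <- pairwise_distances(c(x = s1, y = s2))
  expect_equal(d["x", "y"], 5 / 458, tolerance = 1e-12)

  dg <- pairwise_distances(c(g = "A---", h = "AAAA"))
  expect_equal(dg["g", "h"], 0) # only one comparable position, matching

  expect_error(pairwise_distances(c("ACG", "ACGT")), "same")
})

test_that("average-neighbor clustering matches hand-run and brute-force results", {
  # identical pair -> one OTU
  d0 <- pairwise_distances(c(a = "ACGT", b = "ACGT"))
  expect_equal(length(unique(cluster_average_neighbor(d0, 0.03))), 1)

  # hand-run of average linkage: {A,B} merge at 0.02; C stays (avg 0.04 > 0.03)
  d <- matrix(c(0, 0.02, 0.04, 0.02, 0, 0.04, 0.04, 0.04, 0),
              3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- cluster_average_neighbor(d, 0.03)
  expect_equal(cl[["A"]], cl[["B"]])
  expect_false(cl[["C"]] == cl[["A"]])

  # cutoff zero: OTUs = distinct sequences
  seqs <- c(a = "AAAA", b = "AAAA", c = "AAAT", d = "GGGG")
  cl0 <- cluster_average_neighbor(pairwise_distances(seqs), 0)
  expect_equal(length(unique(cl0)), 3)
  expect_equal(cl0[["a"]], cl0[["b"]])

  # brute-force oracle agreement on random matrices of up to 6 sequences
  withr::with_seed(7, {
    for (rep in 1:60) {
      n <- sample(2:6, 1)
      d <- matrix(0, n, n)
      d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, 0.12)
      d <- d + t(d)
      dimnames(d) <- list(letters[1:n], letters[1:n])
      cutoff <- runif(1, 0.01, 0.1)
      got <- cluster_average_neighbor(d, cutoff)
      want <- oracle_average_neighbor(d, cutoff)
      expect_true(same_partition(as.integer(factor(got)), want))
    }
  })
})

test_that("Shannon index evaluates the entropy formula in nats", {
  expect_equal(shannon_index(c(50, 50)), log(2))
  expect_equal(shannon_index(100), 0)
  expect_equal(shannon_index(c(1, 2, 3)), 1.0114, tolerance = 1e-4)
  expect_error(shannon_index(c(0, 0)), "positive")
})

test_that("Chao1 uses the bias-corrected singleton/doubleton formula", {
  expect_equal(chao1_index(c(2, 2, 3))$chao1, 3)
  ch <- chao1_index(c(1, 1, 1, 1, 2, 2, 5))
  expect_equal(ch$chao1, 9) # 7 + 4*3 / (2*3)
  expect_equal(ch$n1, 4)
  expect_equal(ch$n2, 2)
  r <- 2
  expect_equal(ch$se, sqrt(2 * (r^2 / 2 + r^3 + r^4 / 4)))
  one <- chao1_index(10)
  expect_equal(one$chao1, 1)
  expect_equal(one$se, 0)

  # chao1 >= S_obs over 1,000 random abundance vectors; equality iff n1 <= 1
  withr::with_seed(11, {
    for (i in 1:1000) {
      counts <- rpois(sample(3:40, 1), sample(1:5, 1))
      counts <- counts[counts > 0]
      if (length(counts) == 0) next
      ch <- chao1_index(counts)
      expect_gte(ch$chao1, ch$s_obs)
      if (ch$n1 <= 1) expect_equal(ch$chao1, ch$s_obs)
      else expect_gt(ch$chao1, ch$s_obs)
    }
  })
})

test_that("analytic rarefaction matches enumeration and Monte-Carlo", {
  counts <- c(5, 3, 2)
  expect_equal(rarefaction_expected(counts, sum(counts)), 3)
  expect_equal(rarefaction_expected(c(2, 2), 1), 1)
  # counts [3,1], depth 2: 6 subsamples, 3 contain both OTUs -> E = 1.5
  expect_equal(rarefaction_expected(c(3, 1), 2), 1.5)
  expect_error(rarefaction_expected(c(3, 1), 5), "depth")

  # non-decreasing in depth
  rc <- rarefaction_expected(c(10, 5, 2, 1, 1), 1:19)
  expect_true(all(diff(rc) >= -1e-12))

  # Monte-Carlo agreement within 3 SE at several depths
  counts <- c(12, 7, 4, 2, 1, 1, 1)
  for (depth in c(3, 9, 18)) {
    mc <- oracle_rarefaction_mc(counts, depth, n_rep = 10000, seed = depth)
    expect_lt(abs(rarefaction_expected(counts, depth) - mc["mean"]),
              3 * mc["se"])
  }
})

test_that("even resampling drops shallow pools and hits the target depth", {
  tab <- rbind(EGL_vnfD = c(o1 = 60, o2 = 50, o3 = 10),
               SM_vnfD = c(o1 = 9, o2 = 2, o3 = 0))
  rs <- resample_table(tab, 100, seed = 5)
  expect_equal(rs$dropped, "SM_vnfD")
  expect_equal(unname(rowSums(rs$table)), 100)
  expect_identical(rs$table, resample_table(tab, 100, seed = 5)$table)

  exact <- rbind(pool = c(a = 60, b = 40))
  rs2 <- resample_table(exact, 100, seed = 1)
  expect_equal(unname(rs2$table["pool", c("a", "b")]), c(60, 40))
})

test_that("site overlap reproduces brute-force Venn regions", {
  disjoint <- site_overlap(list(EGL = c("o1", "o2"), EGS = "o3", SM = "o4"))
  expect_equal(sum(disjoint[grepl("&", names(disjoint))]), 0)
  expect_equal(sum(disjoint), 4)

  shared <- site_overlap(list(EGL = "o1", EGS = "o1", SM = c("o1", "o2")))
  expect_equal(unname(shared[["EGL&EGS&SM"]]), 1)

  withr::with_seed(3, {
    for (rep in 1:20) {
      sets <- lapply(1:3, function(i) sample(sprintf("o%02d", 1:12),
                                             sample(0:8, 1)))
      names(sets) <- c("EGL", "EGS", "SM")
      got <- site_overlap(sets)
      u <- unique(unlist(sets))
      inx <- vapply(sets, function(s) u %in% s, logical(length(u)))
      if (length(u) == 1) inx <- matrix(inx, nrow = 1)
      # brute-force region counts via set algebra
      expect_equal(unname(got[["EGL&EGS&SM"]]), sum(rowSums(inx) == 3))
      expect_equal(unname(got[["EGL"]]),
                   sum(inx[, 1] & !inx[, 2] & !inx[, 3]))
      expect_equal(sum(got), length(u))
    }
  })
  expect_error(site_overlap(list(a = "x")), "2 or 3")
})

test_that("internal-standard clustering estimates the spurious-OTU rate", {
  refs <- fixture_refs()
  isd <- refs$dna[refs$isozyme == "internal_standard"]
  tpl <- refs[refs$isozyme == "internal_standard", c("id", "isozyme", "dna")]

  clean <- simulate_ccs_reads(tpl, c(internal_standard = 15), no_error_rates,
                              chimera_rate = 0, internal_standard_fraction = 0,
                              seed = 3)
  r0 <- spurious_otu_rate(clean, isd, cutoff = 0.03)
  expect_equal(r0$otus_observed, 1)
  expect_equal(r0$spurious_per_read, 0)

  noisy <- simulate_ccs_reads(
    tpl, c(internal_standard = 15),
    list(substitution = 0.05, homopolymer_extension = 0, ambiguity = 0),
    chimera_rate = 0, internal_standard_fraction = 0, seed = 4
  )
  r5 <- spurious_otu_rate(noisy, isd, cutoff = 0.03)
  expect_gt(r5$spurious_per_read, 0)

  # rate is non-increasing as the cutoff loosens
  rates <- vapply(c(0.01, 0.03, 0.05, 0.10), function(cut) {
    spurious_otu_rate(noisy, isd, cutoff = cut)$spurious_per_read
  }, numeric(1))
  expect_true(all(diff(rates) <= 1e-12))

  expect_error(spurious_otu_rate(read_df(character(0)), isd), "undefined")
})

test_that("percentage shares reproduce the published table rows", {
  egl <- isozyme_share_percent(c(nifD = 566, anfD = 34, vnfD = 108))
  expect_equal(as.character(egl), c("80", "5", "15"))

  egl_chao <- isozyme_share_percent(c(nifD = 2822, anfD = 126, vnfD = 378))
  expect_equal(as.character(egl_chao), c("85", "4", "11"))

  sm <- isozyme_share_percent(c(nifD = 289, anfD = 31, vnfD = 2))
  expect_equal(as.character(sm), c("90", "10", "<1"))

  expect_error(isozyme_share_percent(c(a = 0, b = 0)), "positive")
})

test_that("OTU counts are non-increasing in the clustering cutoff", {
  refs <- fixture_refs()
  tpl <- fixture_templates()
  nit <- tpl[tpl$isozyme != "internal_standard", ]
  reads <- simulate_ccs_reads(
    nit, stats::setNames(rep(6L, nrow(nit)), nit$id),
    list(substitution = 0.01, homopolymer_extension = 0, ambiguity = 0),
    chimera_rate = 0, internal_standard_fraction = 0, seed = 12
  )
  anf_ids <- nit$id[nit$isozyme == "anfD"]
  seqs <- reads$dna[reads$source_ref_id %in% anf_ids]
  dm <- pairwise_distances(seqs, sprintf("s%02d", seq_along(seqs)))
  n_otus <- vapply(c(0, 0.03, 0.05, 0.10), function(cut) {
    length(unique(cluster_average_neighbor(dm, cut)))
  }, numeric(1))
  expect_true(all(diff(n_otus) <= 0))
})
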