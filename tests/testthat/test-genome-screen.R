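# Independent re-statement of the minimum-gene-set rules used as an oracle
# for the exhaustive classifier check.
oracle_classify <- function(present) {
  has <- function(g) g %in% present
  h <- has("NifH") || has("AnfH") || has("VnfH")
  core <- has("NifH") && has("NifD") && has("NifK") && has("NifB")
  list(
    mo = core,
    fe = has("AnfD") && has("AnfK") && has("AnfG") && h,
    v = has("VnfD") && has("VnfK") && has("VnfG") && h,
    flag = core && !(has("NifE") && has("NifN"))
  )
}

test_that("proteome screening credits self-hits and rejects noise", {
  refs <- fixture_refs()
  anf_prot <- refs$protein[refs$isozyme == "anfD"][1]
  vnf_prot <- refs$protein[refs$isozyme == "vnfD"][1]
  queries <- data.frame(gene = c("AnfD", "VnfD"),
                        protein = c(anf_prot, vnf_prot),
                        stringsAsFactors = FALSE)

  proteome <- data.frame(id = c("p1", "p2"),
                         protein = c(anf_prot, random_protein(300, 4)),
                         stringsAsFactors = FALSE)
  suite <- screen_proteome(proteome, queries, genome_id = "g1")
  expect_lt(suite$AnfD, 1e-20)
  expect_true(is.na(suite$VnfD) || suite$VnfD > 1e-20)

  junk <- data.frame(id = sprintf("j%d", 1:3),
                     protein = vapply(1:3, function(i) random_protein(350, i), ""),
                     stringsAsFactors = FALSE)
  empty <- screen_proteome(junk, queries, genome_id = "g0")
  vals <- unlist(empty[gene_suite_vocabulary()])
  expect_true(all(is.na(vals) | vals > 1e-20))

  expect_error(screen_proteome(junk[0, ], queries), "non-empty")
  expect_error(screen_proteome(junk, queries[0, ]), "non-empty")
})

test_that("Bch-like proteins are not credited as nitrogenase genes", {
  refs <- fixture_refs()
  anf_prot <- refs$protein[refs$isozyme == "anfD"][1]
  # a decoy proteome protein identical to the Bch query but also similar to
  # the nitrogenase query: best hit goes to Bch, nitrogenase is confounded
  queries <- data.frame(gene = c("AnfD", "BchN"),
                        protein = c(anf_prot, anf_prot),
                        stringsAsFactors = FALSE)
  proteome <- data.frame(id = "p1", protein = anf_prot, stringsAsFactors = FALSE)
  suite <- screen_proteome(proteome, queries, genome_id = "gBch")
  # equal scores: which.min keeps the first query (AnfD); make Bch strictly
  # better by extending the decoy with Bch-only context
  bch_prot <- paste0(anf_prot, "WWWWWWWWWW")
  queries2 <- data.frame(gene = c("AnfD", "BchN"),
                         protein = c(anf_prot, bch_prot),
                         stringsAsFactors = FALSE)
  proteome2 <- data.frame(id = "p1", protein = bch_prot, stringsAsFactors = FALSE)
  suite2 <- screen_proteome(proteome2, queries2, genome_id = "gBch2")
  expect_lt(suite2$BchN, 1e-20)
  expect_true(is.na(suite2$AnfD))
  expect_true("AnfD" %in% attr(suite2, "bch_confounded"))
  cl <- classify_suites(suite2)
  expect_false(cl$has_Fe_only)
  expect_match(cl$bch_confounded, "AnfD")
})

test_that("classifier reproduces the minimum-gene-set calls", {
  full <- simulate_gene_suites(list(list(
    genome_id = "all16",
    genes_present = setdiff(gene_suite_vocabulary(),
                            c("BchL", "BchN", "BchX", "BchY"))
  )))
  cl <- classify_suites(full)
  expect_true(cl$has_Mo && cl$has_Fe_only && cl$has_V)

  noG <- simulate_gene_suites(list(list(
    genome_id = "noAnfG",
    genes_present = c("NifH", "AnfD", "AnfK")
  )))
  expect_false(classify_suites(noG)$has_Fe_only)

  dagger <- simulate_gene_suites(list(list(
    genome_id = "dagger",
    genes_present = c("NifH", "NifD", "NifK", "NifB",
                      "AnfH", "AnfD", "AnfK", "AnfG")
  )))
  cld <- classify_suites(dagger)
  expect_true(cld$has_Fe_only)
  expect_true(cld$incomplete_nif_flag)

  noB <- simulate_gene_suites(list(list(
    genome_id = "noNifB",
    genes_present = c("NifH", "NifD", "NifK", "NifE", "NifN")
  )))
  expect_false(classify_suites(noB)$has_Mo)
})

test_that("classifier agrees with the oracle on every gene pattern and is monotone", {
  genes <- setdiff(gene_suite_vocabulary(), c("BchL", "BchN", "BchX", "BchY"))
  n <- length(genes) # 14 -> exhaustive over all 2^14 patterns
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  names(patterns) <- genes
  suite <- as.data.frame(lapply(patterns, function(col)
    ifelse(col, 1e-50, NA_real_)))
  suite$genome_id <- sprintf("g%05d", seq_len(nrow(suite)))
  got <- classify_suites(suite)
  want <- lapply(seq_len(nrow(patterns)), function(i)
    oracle_classify(genes[unlist(patterns[i, ])]))
  expect_equal(got$has_Mo, vapply(want, `[[`, TRUE, "mo"))
  expect_equal(got$has_Fe_only, vapply(want, `[[`, TRUE, "fe"))
  expect_equal(got$has_V, vapply(want, `[[`, TRUE, "v"))
  expect_equal(got$incomplete_nif_flag, vapply(want, `[[`, TRUE, "flag"))

  # monotonicity: adding genes never turns a true call false
  withr::with_seed(13, {
    for (i in 1:200) {
      base <- genes[runif(n) < 0.5]
      more <- union(base, genes[runif(n) < 0.3])
      a <- oracle_classify(base)
      b <- oracle_classify(more)
      expect_true(!a$mo || b$mo)
      expect_true(!a$fe || b$fe)
      expect_true(!a$v || b$v)
    }
  })

  # purity: repeated calls and column permutation give identical output
  expect_identical(classify_suites(suite), got)
  expect_identical(classify_suites(suite[, rev(names(suite))]), got)
})

test_that("nearest-reference assignment labels queries and finds ambiguity", {
  refs <- fixture_refs()
  labeled <- refs[refs$isozyme %in% c("nifD", "anfD", "vnfD"),
                  c("isozyme", "protein")]
  anf_q <- refs$protein[refs$isozyme == "anfD"][1]
  hit <- nearest_reference_isozyme(anf_q, labeled)
  expect_equal(hit$label, "anfD")
  expect_equal(hit$distance, 0)
  expect_gt(hit$margin, 0)

  # equidistant constructed query -> ambiguous
  two <- data.frame(isozyme = c("anfD", "vnfD"),
                    protein = c("AAAAAAAAAA", "CCCCCCCCCC"),
                    stringsAsFactors = FALSE)
  mid <- nearest_reference_isozyme("AAAAACCCCC", two)
  expect_equal(mid$label, "ambiguous")

  # noise-free simulated anfD amplicon translations are always labeled anfD
  tpl <- fixture_templates()
  anf_tpl <- tpl[tpl$isozyme == "anfD", ]
  reads <- simulate_ccs_reads(anf_tpl,
                              stats::setNames(rep(2L, nrow(anf_tpl)), anf_tpl$id),
                              no_error_rates, chimera_rate = 0,
                              internal_standard_fraction = 0, seed = 10)
  amp_refs <- fixture_amps()
  amp_labeled <- data.frame(isozyme = amp_refs$isozyme,
                            protein = vapply(amp_refs$dna, translate_dna, ""),
                            stringsAsFactors = FALSE)
  labels <- vapply(reads$dna, function(d) {
    nearest_reference_isozyme(translate_dna(d), amp_labeled)$label
  }, character(1), USE.NAMES = FALSE)
  expect_true(all(labels == "anfD"))

  expect_error(nearest_reference_isozyme("AAA", labeled[0, ]), "references")
})
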