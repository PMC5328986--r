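test_that("reference sets have the expected composition and are deterministic", {
  r0 <- generate_reference_set(0, seed = 1)
  expect_equal(nrow(r0), 1)
  expect_equal(r0$isozyme, "internal_standard")

  r1 <- generate_reference_set(2, seed = 7)
  r2 <- generate_reference_set(2, seed = 7)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 7)
  expect_equal(sum(r1$isozyme == "nifD"), 2)
  expect_equal(sum(r1$isozyme == "internal_standard"), 1)

  expect_error(generate_reference_set(-1, seed = 1), "non-negative")
})

test_that("references respect divergence bands, the internal standard its spec", {
  refs <- fixture_refs()
  for (iso in c("nifD", "anfD", "vnfD")) {
    fam <- refs$dna[refs$isozyme == iso]
    expect_lte(hamming_frac(fam[1], fam[2]), 0.15)
    expect_gt(hamming_frac(fam[1], fam[2]), 0)
  }
  anf <- refs$dna[refs$isozyme == "anfD"][1]
  vnf <- refs$dna[refs$isozyme == "vnfD"][1]
  expect_gte(hamming_frac(anf, vnf), 0.30)

  isd <- refs$dna[refs$isozyme == "internal_standard"]
  expect_equal(nchar(isd), 600)
  gc <- mean(strsplit(isd, "")[[1]] %in% c("G", "C"))
  expect_gte(gc, 0.58)
  expect_lte(gc, 0.62)
  expect_equal(refs$protein[refs$isozyme == "internal_standard"], "")

  # protein field is the frame-1 translation of the gene
  nif <- refs[refs$isozyme == "nifD", ][1, ]
  expect_equal(nif$protein, translate_dna(nif$dna))
  expect_false(grepl("*", nif$protein, fixed = TRUE))
})

test_that("generated anfD/vnfD references carry the 13-residue motif window", {
  refs <- generate_reference_set(3, seed = 3)
  amps <- reference_amplicons(refs)
  alt <- amps[amps$isozyme %in% c("anfD", "vnfD"), ]
  prot <- data.frame(id = alt$id, protein = vapply(alt$dna, translate_dna, ""),
                     stringsAsFactors = FALSE)
  expect_true(all(grepl("CAR", prot$protein)))
  mw <- extract_motif_windows(prot)
  found <- c(mw$windows$source_id, mw$removed_singletons$source_id)
  expect_setequal(found, alt$id)
  expect_length(mw$removed_incomplete, 0)
})

test_that("in-silico PCR reproduces the published amplicon geometry", {
  refs <- fixture_refs()
  p <- nitrogenase_primers()
  nif <- refs$dna[refs$isozyme == "nifD"][1]
  anf <- refs$dna[refs$isozyme == "anfD"][1]

  # nested amplicons: 1331 - 820 + 1 = 512 and 1291 - 548 + 1 = 744
  expect_equal(nchar(insilico_pcr(nif, p$nifD$outer, p$nifD$inner)), 512)
  expect_equal(nchar(insilico_pcr(anf, p$anfvnfD$outer, p$anfvnfD$inner)), 744)

  # first-round products span to the outer reverse primer
  expect_equal(nchar(insilico_pcr(nif, p$nifD$outer)), 1389 - 820 + 1)

  # no forward match -> no amplicon
  expect_null(insilico_pcr(random_dna(800, 5), p$nifD$inner))

  # a duplicated forward site is ambiguous and names the positions
  amp <- insilico_pcr(nif, p$nifD$outer)
  dup <- paste0(substr(nif, 1, 1389), substr(nif, 760, 1389))
  expect_error(insilico_pcr(dup, p$nifD$outer), "multiple positions")
})

test_that("read simulation honours its rates and records truth", {
  tpl <- fixture_templates()
  nif_ids <- tpl$id[tpl$isozyme == "nifD"]

  clean <- simulate_ccs_reads(tpl, c(nifD_ref_01 = 5), no_error_rates,
                              chimera_rate = 0, internal_standard_fraction = 0,
                              seed = 1)
  expect_equal(nrow(clean), 5)
  expect_true(all(clean$dna == tpl$dna[tpl$id == "nifD_ref_01"]))
  expect_true(all(clean$n_errors == 0))

  rd <- simulate_ccs_reads(tpl, c(nifD_ref_01 = 500, anfD_ref_01 = 500),
                           no_error_rates, chimera_rate = 0.1,
                           internal_standard_fraction = 0, seed = 9)
  p <- 0.1
  sd3 <- 3 * sqrt(p * (1 - p) * 1000)
  expect_lt(abs(sum(rd$is_chimera) - 1000 * p), sd3)
  # chimera parents recorded, distinct, and drawn from the same primer pool
  ch <- rd[rd$is_chimera, ]
  expect_true(all(ch$parent_a != ch$parent_b))
  pool <- function(id) ifelse(tpl$isozyme[match(id, tpl$id)] == "nifD", "nifD", "anfvnf")
  expect_true(all(pool(ch$parent_a) == pool(ch$parent_b)))

  rd2 <- simulate_ccs_reads(tpl, c(nifD_ref_01 = 10000), no_error_rates,
                            chimera_rate = 0, internal_standard_fraction = 0.01,
                            seed = 4)
  expect_lt(abs(sum(rd2$is_internal_standard) - 100),
            3 * sqrt(0.01 * 0.99 * 10000))

  expect_identical(rd, simulate_ccs_reads(tpl, c(nifD_ref_01 = 500, anfD_ref_01 = 500),
                                          no_error_rates, chimera_rate = 0.1,
                                          internal_standard_fraction = 0, seed = 9))
  expect_error(
    simulate_ccs_reads(tpl, integer(0), no_error_rates, 0.1, 0.01, seed = 1),
    "empty composition"
  )
})

test_that("isotope simulation hits the mixing line exactly at zero noise", {
  em <- endmembers()
  s0 <- simulate_isotope_samples(0, "Fe", em, delta_acetylene = -24,
                                 noise_sd = 0, n = 3, seed = 1)
  expect_equal(epsilon_ar(s0), rep(em$eps_Mo, 3))

  s1 <- simulate_isotope_samples(1, "Fe", em, noise_sd = 0, n = 3, seed = 1)
  expect_equal(epsilon_ar(s1), rep(em$eps_Fe, 3))

  s5 <- simulate_isotope_samples(0.5, "V", em, noise_sd = 0, n = 1, seed = 1)
  expect_equal(epsilon_ar(s5), (13.8 + 7.9) / 2) # 10.85

  expect_error(simulate_isotope_samples(1.2, "Fe", em, seed = 1), "f_alt_true")
})

test_that("time-course simulation is linear and refittable", {
  tc <- simulate_ara_timecourse(2, c(0, 15, 18), noise_sd = 0, seed = 1)
  expect_equal(tc$ethylene_ppmv, c(0, 30, 36))
  tc0 <- simulate_ara_timecourse(0, c(0, 15, 18), noise_sd = 0, seed = 1)
  expect_equal(tc0$ethylene_ppmv, c(0, 0, 0))
  expect_error(simulate_ara_timecourse(1, c(0, 15), noise_sd = 0, seed = 1),
               "3 time points")

  tc2 <- simulate_ara_timecourse(1.5, c(0, 5, 10, 15, 20, 25), noise_sd = 0.1,
                                 seed = 8)
  fit <- fit_ara_rate(tc2, n_points = 6)
  expect_lt(abs(fit$slope - 1.5), 0.1)
})

test_that("gene-suite simulation validates names and feeds the classifier", {
  full <- simulate_gene_suites(list(list(
    genome_id = "azoto",
    genes_present = c("NifH", "NifD", "NifK", "NifE", "NifN", "NifB",
                      "AnfH", "AnfD", "AnfK", "AnfG",
                      "VnfH", "VnfD", "VnfK", "VnfG")
  )))
  cl <- classify_suites(full)
  expect_true(cl$has_Mo && cl$has_Fe_only && cl$has_V)
  expect_false(cl$incomplete_nif_flag)

  none <- simulate_gene_suites(list(list(genome_id = "empty",
                                         genes_present = character(0))))
  cl0 <- classify_suites(none)
  expect_false(any(cl0$has_Mo, cl0$has_Fe_only, cl0$has_V))

  noE <- simulate_gene_suites(list(list(
    genome_id = "noE",
    genes_present = c("NifH", "NifD", "NifK", "NifN", "NifB",
                      "AnfH", "AnfD", "AnfK", "AnfG")
  )))
  clE <- classify_suites(noE)
  expect_true(clE$incomplete_nif_flag)
  expect_true(clE$has_Fe_only)

  expect_error(simulate_gene_suites(list(list(genome_id = "x",
                                              genes_present = "NifZ"))),
               "unknown gene")
})
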