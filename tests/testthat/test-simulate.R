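test_that("reference construction guarantees ORF structure", {
  cfg <- simConfig(n_orfs = 1, orf_len_codons = 50, seed = 3)
  ref <- simulateReference(cfg)
  expect_length(ref$reference, 1)
  expect_equal(nrow(ref$orfs), 1)
  expect_equal(ref$orfs$end - ref$orfs$start, 3 * 51)   # 150 coding nt + stop
  coding <- as.character(Biostrings::subseq(
    ref$reference[[1]], ref$orfs$start + 1, ref$orfs$end))
  codons <- substring(coding, seq(1, 153, 3), seq(3, 153, 3))
  expect_equal(codons[1], "ATG")
  expect_true(all(GC[codons[1:50]] != "*"))     # no internal stop
  expect_true(GC[codons[51]] == "*")            # terminal stop
  # determinism
  ref2 <- simulateReference(cfg)
  expect_identical(as.character(ref$reference), as.character(ref2$reference))
})

test_that("coding map dimensions follow the configuration arithmetic", {
  ref <- simulateReference(simConfig(n_orfs = 200, orf_len_codons = 60,
                                     seed = 1))
  expect_equal(nrow(ref$orfs), 200)
  expect_equal(nrow(ref$coding), 36000)      # 200 x 60 x 3 coding nt
})

test_that("with all rates zero the VCF is empty and individuals match the reference", {
  cfg <- simConfig(n_orfs = 5, d_fix = 0, theta = 0, mu = 0, lambda_loh = 0,
                   clones = list(cloneSpec("F1", "ET", 0, 1)), seed = 2)
  sim <- simulateComplex(cfg)
  expect_equal(nSites(genotypes(sim)), 0)
  expect_equal(nrow(simTruth(sim)$sites), 0)
})

test_that("planted fixed differences per species pair follow d_fix", {
  # an E-T difference is a fixed substitution on either branch; aggregate
  # over replicates so the check has power against miscalibration
  n_rep <- 5
  n_pair <- vapply(seq_len(n_rep), function(s) {
    cfg <- simConfig(n_orfs = 200, orf_len_codons = 60, d_fix = 0.01,
                     theta = 0, clones = list(), seed = 16 + s)
    tr <- simTruth(simulateComplex(cfg))$sites
    sum(tr$class == "interspecific_fixed" & tr$focal %in% c("E", "T"))
  }, 0L)
  ci <- qbinom(c(0.025, 0.975), n_rep * 2 * 36000, 0.005)
  expect_gte(sum(n_pair), ci[1]); expect_lte(sum(n_pair), ci[2])
})

test_that("selection shift drives nonsynonymous variants towards rarity", {
  cfg <- simConfig(n_orfs = 120, theta = 0.01, sel_shift = 2, d_fix = 0,
                   clones = list(), seed = 23)
  sim <- simulateComplex(cfg)
  tr <- simTruth(sim)$sites
  seg <- tr[tr$class == "intraspecific", ]
  m_non <- mean(seg$freq_count[seg$syn_planted == "non"] /
                seg$n_chrom[seg$syn_planted == "non"])
  m_syn <- mean(seg$freq_count[seg$syn_planted == "syn"] /
                seg$n_chrom[seg$syn_planted == "syn"])
  expect_lt(m_non, m_syn)
})

test_that("an F1 clone has no private mutations, no LOH, and full diagnostic heterozygosity", {
  sim <- tinySim()   # default clones include a tau = 0 F1
  tr <- simTruth(sim)
  expect_false(any(tr$private$clone_id == "F1"))
  expect_false(any(tr$loh$sample_id %in% c("F1_1", "F1_2")))
  tab <- tr$sites
  gt <- genotypes(sim)
  et_diag <- which(tab$emitted & tab$class == "interspecific_fixed" &
                   tab$focal %in% c("E", "T"))
  rows <- match(paste(tab$contig, tab$pos)[et_diag],
                paste(siteInfo(gt)$contig, siteInfo(gt)$pos))
  f1 <- genotypes(gt)[rows, "F1_1"]
  n_allele <- vapply(strsplit(f1, "/"), function(a) length(unique(a)), 0L)
  expect_true(all(n_allele == 2))   # heterozygous at every E/T fixed diff
})

test_that("private-mutation counts follow the Poisson clock", {
  cfg <- simConfig(n_orfs = 200, orf_len_codons = 60, mu = 1e-7,
                   theta = 0, d_fix = 0.002, lambda_loh = 0,
                   clones = list(cloneSpec("c", "EN", 1e5, 1)), seed = 31)
  sim <- simulateComplex(cfg)
  n_priv <- sum(simTruth(sim)$private$sample_id == "c_1")
  ci <- qpois(c(0.025, 0.975), 1e-7 * 36000 * 1e5)   # mean 360
  expect_gte(n_priv, ci[1]); expect_lte(n_priv, ci[2])
  # lambda_loh = 0: every private allele stays heterozygous
  expect_true(all(simTruth(sim)$private$state == "het"))
})

test_that("truth covers every emitted variant exactly once", {
  sim <- tinySim()
  tr <- simTruth(sim)$sites
  expect_false(anyDuplicated(paste(tr$contig, tr$pos)) > 0)
  gt_keys <- paste(siteInfo(genotypes(sim))$contig,
                   siteInfo(genotypes(sim))$pos)
  expect_true(all(gt_keys %in% paste(tr$contig, tr$pos)))
  expect_setequal(gt_keys, paste(tr$contig, tr$pos)[tr$emitted])
})

test_that("VCF round trip preserves allele multisets and ploidy", {
  sim <- tinySim()
  dir <- withr::local_tempdir()
  writeSimOutputs(sim, dir)
  back <- readGenotypeTable(file.path(dir, "variants.vcf"),
                            file.path(dir, "samples.tsv"))
  expect_identical(genotypes(back), genotypes(genotypes(sim)))
  # triploid samples carry three alleles in the VCF
  vcf <- readLines(file.path(dir, "variants.vcf"))
  hdr <- strsplit(grep("^#CHROM", vcf, value = TRUE), "\t")[[1]]
  tri_col <- which(hdr == "c9_1")
  row1 <- strsplit(vcf[length(grep("^#", vcf)) + 1L], "\t")[[1]]
  expect_length(strsplit(row1[tri_col], "/")[[1]], 3)
  expect_true(validateSimOutputs(dir))
})

test_that("a VCF site missing from the truth ledger fails validation", {
  sim <- tinySim()
  dir <- withr::local_tempdir()
  writeSimOutputs(sim, dir)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth$sites <- truth$sites[-1, ]
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, na = "null")
  expect_error(validateSimOutputs(dir), "absent from the truth")
})

test_that("phenotype generator: determinism and a clean null", {
  null_ef <- list(gsi_old = 1, fec_old = 1,
                  oocyte_size_old = c(spring = 1, fall = 1))
  ph1 <- simulatePhenotypes(n_per_group = 30, effects = null_ef, seed = 9)
  ph2 <- simulatePhenotypes(n_per_group = 30, effects = null_ef, seed = 9)
  expect_identical(ph1, ph2)
  # null: group GSI means differ only by sampling noise
  ind <- computeIndices(ph1$specimens)
  sp <- ind[ind$season == "spring", ]
  tt <- welchT(sp$GSI[sp$age_class == "old"],
               sp$GSI[sp$age_class == "young"])
  expect_gt(tt$p_value, 0.001)
  expect_error(simulatePhenotypes(params = list(organ_cv = -1)), "positive")
})
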