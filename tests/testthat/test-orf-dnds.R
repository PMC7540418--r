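test_that("ORF eligibility counts intact codons with an inclusive threshold", {
  sim <- tinySim()
  cls <- tinyCls()
  gt <- genotypes(sim)
  orfs <- orfTable(sim)
  elig <- eligibleOrfs(gt, cls, orfs, min_codons = 50)
  intact <- attr(elig, "intact")
  tab <- classificationTable(cls)
  # manual recount for one ORF with masked sites, if any
  bad <- tab$coding & tab$masked
  for (oid in utils::head(orfs$orf_id, 5)) {
    manual <- 60 - length(unique(tab$codon_index[bad & tab$orf_id == oid]))
    expect_equal(unname(intact[oid]), manual)
  }
  # boundary: eligibility flips exactly at the threshold
  o1 <- orfs$orf_id[1]
  expect_true(orfEligible(gt, cls, orfs, o1, min_codons = intact[o1]))
  expect_false(orfEligible(gt, cls, orfs, o1, min_codons = intact[o1] + 1L))
  # a missing call makes that codon unresolved for everyone
  g2 <- genotypes(gt)
  site1 <- which(tab$orf_id == o1 & tab$coding & !tab$masked)[1]
  row1 <- match(paste(tab$contig, tab$pos)[site1],
                paste(siteInfo(gt)$contig, siteInfo(gt)$pos))
  g2[row1, 1] <- NA
  gt2 <- genotypeTable(siteInfo(gt), g2, sampleMeta(gt))
  expect_equal(unname(attr(eligibleOrfs(gt2, cls, orfs), "intact")[o1]),
               unname(intact[o1]) - 1L)
})

test_that("within-individual dN/dS of an F1 equals the parental pairwise value", {
  cfg <- simConfig(n_orfs = 25, theta = 0, mu = 0,
                   clones = list(cloneSpec("F1", "ET", 0, 1)), seed = 8)
  sim <- simulateComplex(cfg)
  gt <- genotypes(sim)
  cls <- classifySites(gt, referenceSeqs(sim), orfTable(sim))
  # theta = 0: each sexual individual IS the species haplotype, so the
  # between-individual estimate is deterministic
  pair <- betweenIndividualDnDs(gt, cls, referenceSeqs(sim), orfTable(sim),
                                "EE_1", "TT_1", seed = 99)
  for (oid in pair$orf_id) {
    w <- withinIndividualDnDs("F1_1", oid, gt, cls, referenceSeqs(sim),
                              orfTable(sim))
    p <- pair[pair$orf_id == oid, ]
    expect_identical(w$Nd, p$Nd); expect_identical(w$Sd, p$Sd)
    expect_identical(w$ratio, p$ratio)
  }
})

test_that("a fully homozygous individual yields ratio exactly 1", {
  sim <- tinySim()
  cls <- tinyCls()
  # outgroup LL carries only homozygous fixed differences
  w <- withinIndividualDnDs("LL_1", orfTable(sim)$orf_id[1], genotypes(sim),
                            cls, referenceSeqs(sim), orfTable(sim))
  expect_identical(w$ratio, 1)
  expect_identical(w$Nd + w$Sd, 0)
})

test_that("triploid codons with two distinct alleles count one difference", {
  reference <- Biostrings::DNAStringSet(c(c1 = "ATGTTTTAA"))
  orfs <- data.frame(orf_id = "o1", contig = "c1", start = 0L, end = 9L,
                     n_codons = 2L)
  samples <- data.frame(sample_id = "EEN_1", genomotype = "EEN", ploidy = 3L,
                        category = "old_clone", clone_id = "x")
  gt <- genotypeTable(
    data.frame(contig = "c1", pos = 5L, ref = "T", alt = "A"),
    matrix("A/T/T", 1, 1), samples)
  tab <- data.frame(contig = "c1", pos = 5L, ref = "T", alt = "A",
                    orf_id = "o1", codon_index = 1L, codon_pos = 2L,
                    coding = TRUE, masked = FALSE, category = "private_asexual",
                    stringsAsFactors = FALSE)
  cls <- new("SnpClassification", table = tab, removed = list(),
             params = list())
  w <- withinIndividualDnDs("EEN_1", "o1", gt, cls, reference, orfs)
  expect_identical(w$Nd + w$Sd, 1)   # {T,T,A} -> one TTT/TTA difference
  expect_identical(w$Nd, 1)          # Phe -> Leu
})

test_that("the simulated-hybrid null enumerates all cross-species pairs", {
  sim <- tinySim()
  cls <- tinyCls()
  nul <- simulatedHybridNull(genotypes(sim), cls, referenceSeqs(sim),
                             orfTable(sim), "E", "N", min_codons = 50,
                             seed = 4)
  n_orf <- length(unique(nul$orf_id))
  expect_equal(nrow(nul), n_orf * 8 * 4)    # 8 E x 4 N individuals
  expect_error(simulatedHybridNull(genotypes(sim), cls, referenceSeqs(sim),
                                   orfTable(sim), "E", "Q"),
               "at least one")
})

test_that("monomorphic species give identical ratios across pairs", {
  cfg <- simConfig(n_orfs = 10, theta = 0, mu = 0, clones = list(), seed = 12)
  sim <- simulateComplex(cfg)
  gt <- genotypes(sim)
  cls <- classifySites(gt, referenceSeqs(sim), orfTable(sim))
  nul <- simulatedHybridNull(gt, cls, referenceSeqs(sim), orfTable(sim),
                             "E", "T", seed = 5)
  spread <- tapply(nul$ratio, nul$orf_id, function(r) diff(range(r)))
  expect_true(all(spread == 0))
})
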