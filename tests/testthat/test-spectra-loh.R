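test_that("the recovered SFS matches the planted frequency classes exactly", {
  sim <- tinySim()
  cls <- tinyCls()
  tr <- simTruth(sim)$sites
  tab <- classificationTable(cls)
  for (sp in c("E", "T")) {
    sfs <- siteFrequencySpectrum(genotypes(sim), cls, sp)
    # conservation: bins sum to the polarised site count
    expect_equal(sum(sfs$count), attr(sfs, "n_polarized"))
    # planted derived counts, restricted to polarised unmasked strata
    m <- match(paste(tab$contig, tab$pos), paste(tr$contig, tr$pos))
    pol <- tab$category == "intraspecific" & tab$focal == sp &
      !is.na(tab$derived) & tab$synonymity %in%
      c("synonymous", "nonsynonymous", "stop_gain")
    planted <- sort(tr$freq_count[m][pol])
    recovered <- sort(rep(sfs$k, sfs$count))
    expect_equal(recovered, planted)
  }
})

test_that("clone sharing spectra separate trunk from tip mutations", {
  cfg <- simConfig(n_orfs = 60, theta = 0, d_fix = 0.002, mu = 5e-8,
                   lambda_loh = 0,
                   clones = list(cloneSpec("c", "EN", 2e5, 4)), seed = 19)
  sim <- simulateComplex(cfg)
  cls <- classifySites(genotypes(sim), referenceSeqs(sim), orfTable(sim))
  sp <- cloneSharingSpectrum(genotypes(sim), cls, "c")
  expect_setequal(unique(sp$k), c(1L, 4L))   # singletons and full sharing only
  tr <- simTruth(sim)$private
  n_trunk_sites <- length(unique(tr$g[tr$scope == "trunk"]))
  n_tip_sites <- length(unique(tr$g[tr$scope != "trunk"]))
  expect_equal(sum(sp$count[sp$k == 4]), n_trunk_sites)
  expect_equal(sum(sp$count[sp$k == 1]), n_tip_sites)
  expect_warning(cloneSharingSpectrum(
    subsetGenotypes(genotypes(sim),
                    samples = !(sampleMeta(genotypes(sim))$sample_id %in%
                                paste0("c_", 2:4))), cls, "c"),
    "degenerate")
})

test_that("heterozygosity: hybrids above sexuals, homozygotes at zero", {
  sim <- tinySim()
  gt <- genotypes(sim)
  het <- heterozygosity(gt)
  meta <- sampleMeta(gt)
  expect_gt(min(het[meta$category %in% c("F1", "old_clone", "young_clone")]),
            max(het[meta$category == "sexual"]))
  # the LL outgroup is fixed for its own alleles: zero heterozygosity
  expect_equal(unname(het["LL_1"]), 0)
})

test_that("LOH calls follow the diploid/triploid rules on a toy hybrid", {
  samples <- data.frame(
    sample_id = c("EE_1", "NN_1", "TT_1", "EN_1", "EEN_1"),
    genomotype = c("EE", "NN", "TT", "EN", "EEN"),
    ploidy = c(2L, 2L, 2L, 2L, 3L),
    category = c("sexual", "sexual", "sexual", "old_clone", "old_clone"),
    clone_id = c(NA, NA, NA, "a", "b"), stringsAsFactors = FALSE)
  # site1: E=A, N=G diagnostic; site2: same but hybrid intact
  geno <- rbind(c("A/A", "G/G", "A/A", "A/A", "G/G/G"),
                c("A/A", "G/G", "A/A", "A/G", "A/A/G"))
  colnames(geno) <- samples$sample_id
  gt <- toyTable(geno, pos = c(0L, 1L), samples = samples)
  tab <- cbind(siteInfo(gt), classifySiteCategories(gt))
  cls <- new("SnpClassification", table = tab, removed = list(),
             params = list())
  prof <- callLOH(gt, cls)
  en <- prof[prof$sample_id == "EN_1", ]
  expect_equal(en$n_informative, 2)
  expect_equal(en$n_loh, 1)              # homozygous A/A at site1
  expect_equal(en$retained_E, 1)
  een <- prof[prof$sample_id == "EEN_1", ]
  expect_equal(een$n_loh, 1)             # G/G/G: all alleles from N
  expect_equal(een$retained_N, 1)
  expect_error(callLOH(gt, cls, samples = "EE_1"), "not a hybrid")
})

test_that("F1 hybrids show zero LOH and zero homozygous private fraction", {
  sim <- tinySim()
  cls <- tinyCls()
  prof <- callLOH(genotypes(sim), cls)
  expect_equal(prof$proportion[prof$sample_id %in% c("F1_1", "F1_2")], c(0, 0))
  # lambda = 0 clones: private alleles all heterozygous
  cfg <- simConfig(n_orfs = 40, mu = 1e-7, lambda_loh = 0,
                   clones = list(cloneSpec("c", "EN", 1e5, 2)), seed = 27)
  sim0 <- simulateComplex(cfg)
  cls0 <- classifySites(genotypes(sim0), referenceSeqs(sim0), orfTable(sim0))
  hp <- homozygousPrivateFraction(genotypes(sim0), cls0, c("c_1", "c_2"))
  expect_equal(unname(hp), c(0, 0))
})

test_that("private-SNP proportions increase with clone age", {
  cfg <- simConfig(n_orfs = 80, mu = 5e-8,
                   clones = list(cloneSpec("young", "EN", 2e4, 3),
                                 cloneSpec("mid", "EN", 1e5, 3),
                                 cloneSpec("old", "EN", 3e5, 3)),
                   seed = 37)
  sim <- simulateComplex(cfg)
  cls <- classifySites(genotypes(sim), referenceSeqs(sim), orfTable(sim))
  meta <- sampleMeta(genotypes(sim))
  pp <- privateSnpProportion(genotypes(sim), cls)
  means <- tapply(pp[!is.na(meta$clone_id)],
                  meta$clone_id[!is.na(meta$clone_id)], mean)
  expect_true(means[["young"]] < means[["mid"]])
  expect_true(means[["mid"]] < means[["old"]])
})

test_that("quadratic fits: exact line, exact parabola, constraint behaviour", {
  x <- seq(0, 1, length.out = 10)
  lin <- fitLohVsPrivate(x, 2 + 3 * x)
  expect_lt(abs(lin$unconstrained$a2), 1e-8)
  expect_equal(lin$constrained$a1, lin$unconstrained$a1, tolerance = 1e-8)
  par <- fitLohVsPrivate(x, x^2)
  expect_equal(par$unconstrained$a2, 1, tolerance = 1e-8)
  expect_equal(par$constrained$a2, 1, tolerance = 1e-8)
  # concave data: the constrained fit collapses to the boundary line
  set.seed(2)
  y <- 1 + x - 2 * x^2 + rnorm(10, sd = 0.05)
  con <- fitLohVsPrivate(x, y)
  expect_lt(con$unconstrained$a2, 0)
  expect_identical(con$constrained$a2, 0)
  expect_gte(con$constrained$rss, con$unconstrained$rss)
  expect_error(fitLohVsPrivate(1:3, 1:3), "at least 4")
})
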