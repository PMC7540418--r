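# toy metadata panel: 2 individuals each of EE/TT/NN, one LL outgroup, one
# EN diploid hybrid
.panel <- function() {
  data.frame(
    sample_id = c("EE_1", "EE_2", "TT_1", "TT_2", "NN_1", "NN_2", "LL_1",
                  "EN_h1"),
    genomotype = c("EE", "EE", "TT", "TT", "NN", "NN", "LL", "EN"),
    ploidy = 2L,
    category = c(rep("sexual", 6), "outgroup", "old_clone"),
    clone_id = c(rep(NA, 7), "h"), stringsAsFactors = FALSE)
}

.gtFromRows <- function(rows, ...) {
  geno <- do.call(rbind, rows)
  colnames(geno) <- .panel()$sample_id
  toyTable(geno, samples = .panel(), ...)
}

test_that("site filtering enforces biallelism and the inclusive 80% rule", {
  het <- "A/G"; ref <- "A/A"; alt <- "G/G"
  rows <- list(
    rep(ref, 8),                                        # monomorphic, kept
    c("A/C", ref, "A/G", ref, ref, ref, ref, ref),      # 3 alleles: A,C,G
    c(het, ref, ref, ref, ref, ref, ref, ref),          # biallelic, kept
    c(NA, ref, ref, ref, ref, ref, ref, het))           # 6/7 ingroup = 86%
  gt <- .gtFromRows(rows)
  ft <- filterSites(gt, min_called_fraction = 0.8)
  expect_equal(nSites(ft), 3)
  expect_equal(attr(ft, "removed")$multiallelic, 1)
  # called fraction is inclusive at the boundary: 4/5 kept, 3/5 dropped
  m5 <- .panel()[1:5, ]
  g5 <- rbind(c(NA, het, het, het, het), c(NA, NA, het, het, het))
  colnames(g5) <- m5$sample_id
  ft5 <- filterSites(toyTable(g5, samples = m5), min_called_fraction = 0.8)
  expect_equal(nSites(ft5), 1)
  expect_equal(attr(ft5, "removed")$undercalled, 1)
  expect_warning(filterSites(toyTable(g5[2, , drop = FALSE], samples = m5)),
                 "no sites remain")
})

test_that("toy table: 10 sites, 2 triallelic and 1 undercalled leave 7", {
  het <- "A/G"; ref <- "A/A"
  rows <- c(replicate(7, rep(ref, 8), simplify = FALSE),
            list(c("A/C", "A/G", ref, ref, ref, ref, ref, ref),
                 c("C/T", "A/A", ref, ref, ref, ref, ref, ref),
                 c(NA, NA, NA, ref, ref, ref, ref, ref)))  # 4/7 called
  ft <- filterSites(.gtFromRows(rows), min_called_fraction = 0.8)
  expect_equal(nSites(ft), 7)
})

test_that("paralog flagging requires shared heterozygosity incl. the outgroup", {
  het <- "A/G"; ref <- "A/A"
  rows <- list(
    c(het, ref, het, ref, het, ref, het, ref),   # het in EE, TT, NN and LL
    c(het, het, ref, ref, ref, ref, ref, ref),   # het only within EE
    c(het, ref, het, ref, het, ref, ref, ref))   # het ingroup, not outgroup
  gt <- .gtFromRows(rows)
  flagged <- flagParalogContigs(gt, min_shared_het_sites = 1)
  expect_identical(as.character(flagged), "c1")
  expect_identical(attr(flagged, "spurious_sites"), 1L)
  expect_length(flagParalogContigs(gt, min_shared_het_sites = 2), 0)
  no_out <- subsetGenotypes(gt, samples = 1:6)
  expect_error(flagParalogContigs(no_out), "outgroup")
})

test_that("multi-variant codons are masked, singles analysed", {
  orfs <- data.frame(orf_id = "o1", contig = "c1", start = 0L, end = 33L,
                     n_codons = 10L)
  # 5 SNPs in 4 codons; codon 2 holds two of them
  sites <- data.frame(contig = "c1", pos = c(0L, 6L, 8L, 12L, 15L))
  cmap <- mapSitesToCodons(sites, orfs)
  expect_equal(cmap$codon_index, c(0L, 2L, 2L, 4L, 5L))
  mask <- maskMultiVariantCodons(cmap)
  expect_equal(sum(mask), 2)
  expect_equal(which(mask), c(2L, 3L))
  # stop codon span and flanks are noncoding
  nc <- mapSitesToCodons(data.frame(contig = "c1", pos = c(30L, 40L)), orfs)
  expect_false(any(nc$coding))
})

test_that("category assignment follows the sexual-species rules", {
  het <- "A/G"; refA <- "A/A"; refG <- "G/G"
  rows <- list(
    c(het, refA, refA, refA, refA, refA, refA, refA),  # E polymorphic
    c(refA, refA, refG, refG, refA, refA, refA, "A/G"),# E/T fixed diff
    c(refA, refA, refA, refA, refA, refA, refA, "A/G"),# hybrid apomorphy
    c(refA, refA, refA, refA, refA, refA, refG, refA), # outgroup only
    c(NA,  NA,  refA, refA, refA, refA, refA, refA))   # E uncalled
  gt <- .gtFromRows(rows)
  cats <- classifySiteCategories(gt)
  expect_equal(cats$category,
               c("intraspecific", "interspecific_fixed", "private_asexual",
                 "unclassified", "unclassified"))
  expect_equal(cats$focal[1], "E")
  expect_true(grepl("ExT", cats$focal[2]))
  expect_equal(cats$focal[5], "no_calls_species")
  # hybrid genotypes never influence the first two categories
  expect_false(grepl("EN", cats$focal[2]))
})

test_that("synonymity is annotated from the standard code, phase-free", {
  # ORF: ATG TTT TAC GGG TAT TAA on a bare contig
  reference <- Biostrings::DNAStringSet(c(c1 = "ATGTTTTACGGGTATTAA"))
  orfs <- data.frame(orf_id = "o1", contig = "c1", start = 0L, end = 18L,
                     n_codons = 5L)
  df <- data.frame(
    contig = "c1",
    pos = c(5L, 5L, 8L, 3L, 14L),
    a1 = c("T", "T", "C", "T", "T"),
    a2 = c("C", "A", "A", "C", "G"),
    orf_id = "o1", codon_index = c(1L, 1L, 2L, 1L, 4L),
    codon_pos = c(2L, 2L, 2L, 0L, 2L),
    coding = TRUE, masked = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  syn <- annotateSynonymity(df, reference, orfs)
  expect_equal(syn[1], "synonymous")      # TTT -> TTC, Phe/Phe
  expect_equal(syn[2], "nonsynonymous")   # TTT -> TTA, Phe/Leu
  expect_equal(syn[3], "stop_gain")       # TAC -> TAA mid-ORF
  expect_equal(syn[4], "masked")
  expect_equal(syn[5], "nonsynonymous")   # stop in final sense codon
  # synonymity is invariant to which allele is called a1 vs a2
  sw <- df; sw$a1 <- df$a2; sw$a2 <- df$a1
  expect_equal(annotateSynonymity(sw, reference, orfs), syn)
  bad <- df; bad$a2[1] <- "N"
  expect_error(annotateSynonymity(bad, reference, orfs), "non-A/C/G/T")
})

test_that("polarisation uses the sister taxon, with outgroup fallback", {
  refA <- "A/A"; refG <- "G/G"
  rows <- list(
    c(refA, refA, "A/G", refA, refA, refA, refA, refA), # T poly, sister N = A
    c(refA, refA, "A/G", refA, refA, "A/G", "C/G", refA),# N poly -> L fallback
    c(refA, refA, refA, refA, refA, refA, refA, "A/G")) # private
  gt <- .gtFromRows(rows)
  cats <- classifySiteCategories(gt)
  tab <- cbind(siteInfo(gt), cats)
  pol <- polarizeDerived(tab, gt)
  expect_equal(pol$derived[1], "G")       # ancestral A from sister N
  expect_true(is.na(pol$derived[2]))      # sister poly, outgroup het -> none
  expect_equal(pol$derived[3], "G")       # sexuals are the outgroup state
  expect_error(polarizeDerived(transform(tab, focal = "Q"), gt), "sister map")
})

test_that("noiseless classification recovers every planted class", {
  sim <- tinySim()
  cls <- tinyCls()
  tab <- classificationTable(cls)
  tr <- simTruth(sim)$sites
  m <- match(paste(tab$contig, tab$pos), paste(tr$contig, tr$pos))
  expect_false(anyNA(m))
  planted <- tr$class[m]
  ing <- planted != "outgroup_divergence"
  expect_true(all(tab$category[ing] == planted[ing]))
  expect_true(all(tab$category[!ing] == "unclassified"))
  # category partition: every retained site maps to exactly one category
  expect_true(all(tab$category %in% c("intraspecific", "interspecific_fixed",
                                      "private_asexual", "unclassified")))
  # planted synonymity agrees where codons stayed unmasked
  live <- tab$coding & !tab$masked
  syn_map <- c(syn = "synonymous", non = "nonsynonymous", stop = "stop_gain")
  expect_true(all(tab$synonymity[live] == syn_map[tr$syn_planted[m][live]]))
})
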