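# Orchestration: classify -> spectra -> radicality -> dN/dS -> LOH -> group
# tests, producing one machine-readable report. Stage outputs are pure
# functions of inputs + config, so the same inputs and seed give a
# byte-identical report.

.stageMsg <- function(stage, quiet) if (!quiet) message("[clonedecay] ", stage)

#' Run the full clonal-decay analysis
#'
#' Executes the whole pipeline on a simulated complex (or on inputs read from
#' a directory written by [writeSimOutputs()]): site classification, category
#' and synonymity tallies, site-frequency and clone-sharing spectra,
#' amino-acid radicality, within-individual and simulated-hybrid-null dN/dS,
#' heterozygosity, LOH and private-SNP accounting with the constrained
#' quadratic fit, K2P mtDNA clone ages, and the group-level tests. Every
#' reported number is computed at run time.
#'
#' @param sim a [HybridComplexSim-class]; alternatively give \code{input_dir}.
#' @param input_dir directory with reference.fasta, orfs.bed, samples.tsv,
#'   variants.vcf, mt.fasta (validated before any computation).
#' @param seed integer governing all stochastic steps (pseudo-haplotype
#'   sampling, permutations).
#' @param min_codons ORF eligibility threshold for dN/dS.
#' @param dnds_max_pairs cap on cross-species pairs per null distribution.
#' @param n_perm permutations for permutation tests.
#' @param out optional path for the JSON report.
#' @param quiet suppress stage messages.
#' @return the report as a nested list (invisibly written to \code{out}).
#' @export
runFull <- function(sim = NULL, input_dir = NULL, seed = 1L,
                    min_codons = 50L, dnds_max_pairs = 30L, n_perm = 999L,
                    out = NULL, quiet = FALSE) {
  if (is.null(sim)) {
    if (is.null(input_dir)) stop("give either a simulation or an input_dir")
    need <- file.path(input_dir, c("reference.fasta", "orfs.bed",
                                   "samples.tsv", "variants.vcf", "mt.fasta"))
    ok <- file.exists(need)
    if (!all(ok)) stop("missing input file(s): ",
                       paste(basename(need[!ok]), collapse = ", "))
    reference <- Biostrings::readDNAStringSet(need[1L])
    names(reference) <- sub(" .*", "", names(reference))
    orfs <- readOrfBed(need[2L])
    gt <- readGenotypeTable(need[4L], need[3L])
    mt <- Biostrings::readDNAStringSet(need[5L])
    names(mt) <- sub(" .*", "", names(mt))
  } else {
    reference <- referenceSeqs(sim); orfs <- orfTable(sim)
    gt <- genotypes(sim); mt <- mtHaplotypes(sim)
  }
  meta <- sampleMeta(gt)
  .stageMsg("classify", quiet)
  cls <- classifySites(gt, reference, orfs)
  tab <- classificationTable(cls)
  strat <- .synStratum(tab$synonymity)
  ns_by_cat <- table(tab$category, strat)
  .stageMsg("spectra", quiet)
  spp <- .ingroupSpecies(meta)
  sfs <- lapply(spp, function(sp) siteFrequencySpectrum(gt, cls, sp))
  names(sfs) <- spp
  clone_sizes <- table(meta$clone_id[!is.na(meta$clone_id)])
  big_clones <- names(clone_sizes)[clone_sizes >= 2L]
  sharing <- lapply(big_clones, function(cid)
    cloneSharingSpectrum(gt, cls, cid))
  names(sharing) <- big_clones
  .stageMsg("radicality", quiet)
  # the matrices are symmetric, so the two observed alleles suffice and
  # unpolarised (e.g. interspecific) sites are scored too
  rad_rows <- tab$synonymity == "nonsynonymous" & !is.na(tab$a2)
  radicality <- if (any(rad_rows)) {
    oi <- match(tab$orf_id[rad_rows], orfs$orf_id)
    cstart <- orfs$start[oi] + 3L * tab$codon_index[rad_rows]
    codon0 <- substring(as.character(reference)[orfs$contig[oi]],
                        cstart + 1L, cstart + 3L)
    p <- tab$codon_pos[rad_rows] + 1L
    c1 <- codon0; substr(c1, p, p) <- tab$a1[rad_rows]
    c2 <- codon0; substr(c2, p, p) <- tab$a2[rad_rows]
    aa1 <- translateCodon(c1); aa2 <- translateCodon(c2)
    ok <- aa1 != "*" & aa2 != "*"   # final-codon stops are not scored
    data.frame(category = tab$category[rad_rows][ok],
               pam100 = radicalityScore(aa1[ok], aa2[ok], "PAM100"),
               blosum90 = radicalityScore(aa1[ok], aa2[ok], "BLOSUM90"),
               stringsAsFactors = FALSE)
  } else data.frame(category = character(0), pam100 = integer(0),
                    blosum90 = integer(0))
  .stageMsg("dnds", quiet)
  hybrids <- .hybridSamples(meta)
  elig <- eligibleOrfs(gt, cls, orfs, min_codons = min_codons)
  elig_ids <- names(elig)[elig]
  within_dnds <- do.call(rbind, lapply(hybrids, function(h) {
    r <- do.call(rbind, lapply(elig_ids, function(o)
      withinIndividualDnDs(h, o, gt, cls, reference, orfs)))
    cbind(data.frame(sample_id = h, category =
                       meta$category[match(h, meta$sample_id)],
                     orf_id = elig_ids, stringsAsFactors = FALSE), r)
  }))
  null_pairs <- list(c("E", "T"), c("E", "N"))
  nulls <- lapply(null_pairs, function(pr) {
    if (!all(pr %in% spp)) return(NULL)
    ids_a <- .speciesSamples(meta, pr[1L]); ids_b <- .speciesSamples(meta, pr[2L])
    res <- betweenIndividualDnDs(gt, cls, reference, orfs,
                                 ids_a, ids_b, min_codons = min_codons,
                                 seed = seed)
    pair_id <- paste(res$sample_a, res$sample_b)
    keep_pairs <- utils::head(unique(pair_id), dnds_max_pairs)
    res[pair_id %in% keep_pairs, , drop = FALSE]
  })
  names(nulls) <- vapply(null_pairs, paste, "", collapse = "x")
  .stageMsg("loh", quiet)
  het <- heterozygosity(gt)
  loh <- callLOH(gt, cls)
  priv <- privateSnpProportion(gt, cls, hybrids)
  hompriv <- homozygousPrivateFraction(gt, cls, hybrids)
  sexual_ids <- meta$sample_id[meta$category == "sexual"]
  k2p <- vapply(hybrids, function(h)
    nearestSexualDistance(mt[[h]], mt[sexual_ids])$distance, 0)
  dip <- loh$ploidy == 2L
  quad <- if (sum(dip) >= 4L)
    fitLohVsPrivate(priv[loh$sample_id[dip]], loh$proportion[dip]) else NULL
  .stageMsg("stats", quiet)
  tests <- list()
  cnt <- function(cat) {
    i <- tab$category == cat & !is.na(strat)
    c(non = sum(strat[i] == "nonsynonymous"), tot = sum(i))
  }
  ci <- cnt("intraspecific"); cf <- cnt("interspecific_fixed")
  cp <- cnt("private_asexual")
  tests$ns_intra_vs_inter <- binomialLRT(
    c(ci["non"], cf["non"]), c(ci["tot"], cf["tot"]),
    c("intraspecific", "interspecific"))
  tests$ns_private_vs_inter <- binomialLRT(
    c(cp["non"], cf["non"]), c(cp["tot"], cf["tot"]),
    c("private", "interspecific"))
  tests$loh_vs_private_r <- if (sum(dip) >= 4L)
    pearsonCI(priv[loh$sample_id[dip]], loh$proportion[dip]) else NULL
  tests$private_vs_k2p_r <- if (length(hybrids) >= 4L)
    pearsonCI(k2p, priv[hybrids]) else NULL
  report <- list(
    provenance = list(package = "clonedecay",
                      version = as.character(utils::packageVersion("clonedecay")),
                      seed = seed, min_codons = min_codons,
                      n_perm = n_perm),
    classification = list(
      n_sites = nrow(tab),
      removed = cls@removed,
      by_category = as.list(table(tab$category)),
      ns_by_category = as.data.frame.matrix(ns_by_cat)),
    spectra = list(sfs = sfs, sharing = sharing),
    radicality = list(
      mean_pam100 = tapply(radicality$pam100, radicality$category, mean),
      mean_blosum90 = tapply(radicality$blosum90, radicality$category, mean)),
    dnds = list(
      within_median_by_category =
        tapply(within_dnds$ratio[within_dnds$valid],
               within_dnds$category[within_dnds$valid], stats::median),
      null_median = lapply(nulls, function(x)
        if (is.null(x)) NULL else stats::median(x$ratio[x$valid]))),
    heterozygosity = list(
      by_category = tapply(het, meta$category, mean)),
    loh = list(profiles = loh, private_proportion = priv,
               homozygous_private = hompriv, k2p_nearest = k2p,
               quadratic = quad),
    tests = tests)
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows", force = TRUE)
  }
  report
}
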