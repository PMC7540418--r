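#' Construct a CloneSpec
#'
#' @param clone_id label of the lineage.
#' @param genomotype string over species letters, e.g. \code{"EEN"}.
#' @param age_tau generations since hybrid origin.
#' @param n_individuals sampled individuals.
#' @param category \code{"F1"}, \code{"young_clone"} or \code{"old_clone"};
#'   derived from \code{age_tau} when \code{NULL} (0 = F1, <= 5e4 = young).
#' @return a [CloneSpec-class] object.
#' @examples
#' cloneSpec("9", "EEN", age_tau = 3e5, n_individuals = 5)
#' @export
cloneSpec <- function(clone_id, genomotype, age_tau, n_individuals,
                      category = NULL) {
  if (is.null(category))
    category <- if (age_tau == 0) "F1" else if (age_tau <= 5e4) "young_clone"
                else "old_clone"
  new("CloneSpec", clone_id = as.character(clone_id),
      genomotype = toupper(genomotype), age_tau = as.numeric(age_tau),
      n_individuals = as.integer(n_individuals), category = category)
}

#' Default clonal lineages of the simulated complex
#'
#' Diploid F1 elongatoides-taenia hybrids, Holocene-aged young clones (EET,
#' ETT) and ~300 ky old diploid and triploid elongatoides-tanaitica clones
#' (EN, EEN), mirroring the categories sampled in the studied complex.
#'
#' @param tau_young,tau_old clone ages in generations.
#' @return list of [CloneSpec-class].
#' @export
defaultClones <- function(tau_young = 1e4, tau_old = 3e5) {
  list(
    cloneSpec("F1",  "ET",  0,        2),
    cloneSpec("c1",  "EET", tau_young, 3),
    cloneSpec("c53", "ETT", tau_young, 2),
    cloneSpec("c9",  "EEN", tau_old,   5),
    cloneSpec("cEN", "EN",  tau_old,   2)
  )
}

#' Construct a simulator configuration
#'
#' Defaults describe a desk-scale Cobitis-like complex: three ingroup sexual
#' species (E, T, N) plus a divergent outgroup (L), 200 ORFs of 60 codons
#' (36,000 coding sites), interspecific fixed differences dominated by
#' synonymous changes, intraspecific polymorphism enriched for nonsynonymous
#' changes held at low frequency by the selection shift, and clones ranging
#' from F1 to 300 ky with private mutations and rare LOH.
#'
#' @param n_orfs,orf_len_codons reference dimensions.
#' @param species_labels,outgroup_label,n_ind_sexual species setup.
#' @param d_fix,f_inter_nonsyn fixed interspecific divergence per pair and its
#'   nonsynonymous fraction.
#' @param theta,f_intra_nonsyn,sel_shift segregating polymorphism density, its
#'   nonsynonymous fraction, and the frequency shift exponent a (nonsynonymous
#'   derived counts i weighted i^(-1-a)).
#' @param clones list of [CloneSpec-class]; see [defaultClones()].
#' @param mu,f_priv_nonsyn,p_stop,trunk_fraction private-mutation process.
#' @param lambda_loh per-site LOH rate per generation.
#' @param mt_len,mt_mu,mt_div mitochondrial locus parameters.
#' @param flank_len,codon_retry technical placement parameters.
#' @param seed integer seed.
#' @return a [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(n_orfs = 5, seed = 1)
#' @export
simConfig <- function(n_orfs = 200L, orf_len_codons = 60L,
                      species_labels = c("E", "T", "N"),
                      outgroup_label = "L",
                      n_ind_sexual = c(E = 8L, T = 10L, N = 4L, L = 1L),
                      d_fix = 0.005, f_inter_nonsyn = 0.30,
                      theta = 0.003, f_intra_nonsyn = 0.55,
                      sel_shift = 1,
                      clones = defaultClones(),
                      mu = 1e-8, f_priv_nonsyn = 0.55, p_stop = 0.05,
                      trunk_fraction = 0.5,
                      lambda_loh = 3.5e-7,
                      mt_len = 2000L, mt_mu = 5e-8, mt_div = 0.02,
                      flank_len = 9L, codon_retry = 20L, seed = 1L) {
  new("SimConfig",
      n_orfs = as.integer(n_orfs), orf_len_codons = as.integer(orf_len_codons),
      species_labels = species_labels, outgroup_label = outgroup_label,
      n_ind_sexual = stats::setNames(as.integer(n_ind_sexual), names(n_ind_sexual)),
      d_fix = d_fix, f_inter_nonsyn = f_inter_nonsyn,
      theta = theta, f_intra_nonsyn = f_intra_nonsyn, sel_shift = sel_shift,
      clones = clones, mu = mu, f_priv_nonsyn = f_priv_nonsyn, p_stop = p_stop,
      trunk_fraction = trunk_fraction, lambda_loh = lambda_loh,
      mt_len = as.integer(mt_len), mt_mu = mt_mu, mt_div = mt_div,
      flank_len = as.integer(flank_len), codon_retry = as.integer(codon_retry),
      seed = as.integer(seed))
}

#' Construct a GenotypeTable
#'
#' @param sites data.frame with contig, pos (0-based), ref, alt.
#' @param geno character matrix sites x samples of "A/G"-style calls, NA = missing.
#' @param samples data.frame with sample_id, genomotype, ploidy, category, clone_id.
#' @return a [GenotypeTable-class].
#' @export
genotypeTable <- function(sites, geno, samples) {
  geno <- as.matrix(geno)
  rownames(geno) <- NULL
  colnames(geno) <- samples$sample_id
  new("GenotypeTable", sites = as.data.frame(sites), geno = geno,
      samples = as.data.frame(samples))
}

#' @rdname nSites
#' @export
setMethod("nSites", "GenotypeTable", function(x) nrow(x@sites))

#' @rdname nSamples
#' @export
setMethod("nSamples", "GenotypeTable", function(x) nrow(x@samples))

#' @rdname sampleMeta
#' @export
setMethod("sampleMeta", "GenotypeTable", function(x) x@samples)

#' @rdname siteInfo
#' @export
setMethod("siteInfo", "GenotypeTable", function(x) x@sites)

#' @rdname genotypes
#' @export
setMethod("genotypes", "GenotypeTable", function(x) x@geno)

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", nSites(object), "sites x", nSamples(object),
      "samples\n")
  tab <- table(object@samples$category)
  cat("  samples:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  missing calls:",
      sprintf("%.2f%%", 100 * mean(is.na(object@geno))), "\n")
})

#' Subset a GenotypeTable by site index and/or sample id
#'
#' @param gt a [GenotypeTable-class].
#' @param sites integer or logical index over sites.
#' @param samples character sample ids or index over samples.
#' @return a [GenotypeTable-class].
#' @export
subsetGenotypes <- function(gt, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_len(nSites(gt)) else sites
  sa <- if (is.null(samples)) seq_len(nSamples(gt))
        else if (is.character(samples)) match(samples, gt@samples$sample_id)
        else samples
  genotypeTable(gt@sites[si, , drop = FALSE],
                gt@geno[si, sa, drop = FALSE],
                gt@samples[sa, , drop = FALSE])
}

# parsed allele lists for one sample column or the full matrix
.alleleList <- function(g) strsplit(g, "/", fixed = TRUE)

# distinct alleles per genotype string; NA -> NULL entries
.distinctAlleles <- function(g) lapply(.alleleList(g), unique)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_orfs, "ORFs x", object@orf_len_codons, "codons;",
      length(object@species_labels), "species + outgroup",
      object@outgroup_label, "\n")
  cat("  d_fix =", object@d_fix, " theta =", object@theta,
      " sel_shift a =", object@sel_shift, "\n")
  cat("  mu =", object@mu, " lambda_loh =", object@lambda_loh,
      " clones:", length(object@clones), " seed =", object@seed, "\n")
})

setMethod("show", "CloneSpec", function(object) {
  cat(sprintf("CloneSpec %s (%s, %s): tau = %g, n = %d\n", object@clone_id,
              object@genomotype, object@category, object@age_tau,
              object@n_individuals))
})

#' @rdname referenceSeqs
#' @export
setMethod("referenceSeqs", "HybridComplexSim", function(x) x@reference)

#' @rdname orfTable
#' @export
setMethod("orfTable", "HybridComplexSim", function(x) x@orfs)

#' @rdname genotypes
#' @export
setMethod("genotypes", "HybridComplexSim", function(x) x@genotypes)

#' @rdname mtHaplotypes
#' @export
setMethod("mtHaplotypes", "HybridComplexSim", function(x) x@mt)

#' @rdname simTruth
#' @export
setMethod("simTruth", "HybridComplexSim", function(x) x@truth)

#' @rdname simulationConfig
#' @export
setMethod("simulationConfig", "HybridComplexSim", function(x) x@config)

setMethod("show", "HybridComplexSim", function(object) {
  cat("HybridComplexSim:", length(object@reference), "contigs,",
      nSites(object@genotypes), "variant sites,",
      nSamples(object@genotypes), "samples\n")
  cls <- table(object@truth$sites$class[object@truth$sites$emitted])
  cat("  emitted site classes:",
      paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
})

#' @rdname classificationTable
#' @export
setMethod("classificationTable", "SnpClassification", function(x) x@table)

setMethod("show", "SnpClassification", function(object) {
  cat("SnpClassification:", nrow(object@table), "retained sites\n")
  cat("  categories:",
      paste(names(table(object@table$category)), table(object@table$category),
            sep = "=", collapse = ", "), "\n")
  cat("  removed:", paste(names(object@removed), unlist(object@removed),
                          sep = "=", collapse = ", "), "\n")
})
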