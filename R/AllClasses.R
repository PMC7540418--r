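#' @import methods
NULL

#' Specification of one clonal lineage
#'
#' A clone is defined by its genomotype (the combination of haploid parental
#' genomes it carries, e.g. \code{"EEN"} = two elongatoides + one tanaitica
#' genome), its age in generations since the hybridisation event that founded
#' it, and the number of sampled individuals.
#'
#' @slot clone_id character label of the lineage.
#' @slot genomotype string over the species letters; length 2 (diploid) or 3
#'   (triploid); must contain at least two distinct letters.
#' @slot age_tau generations since hybrid origin (>= 0).
#' @slot n_individuals number of individuals sampled from the clone.
#' @slot category one of \code{"F1"}, \code{"young_clone"}, \code{"old_clone"}.
#' @exportClass CloneSpec
setClass("CloneSpec", representation(
  clone_id = "character",
  genomotype = "character",
  age_tau = "numeric",
  n_individuals = "integer",
  category = "character"
))

setValidity("CloneSpec", function(object) {
  msg <- NULL
  letters_ <- strsplit(object@genomotype, "")[[1]]
  if (!nchar(object@genomotype) %in% 2:3)
    msg <- c(msg, "genomotype must have length 2 or 3")
  if (length(unique(letters_)) < 2)
    msg <- c(msg, "genomotype must combine at least two distinct parental genomes")
  if (object@age_tau < 0) msg <- c(msg, "age_tau must be >= 0")
  if (object@n_individuals < 1L) msg <- c(msg, "n_individuals must be >= 1")
  if (!object@category %in% c("F1", "young_clone", "old_clone"))
    msg <- c(msg, "category must be F1, young_clone or old_clone")
  if (is.null(msg)) TRUE else msg
})

#' Configuration of the hybrid-complex simulator
#'
#' Holds every tunable parameter of the forward-time generator: the reference
#' ORF set, the divergence and polymorphism of the sexual species, the
#' selection shift acting on nonsynonymous allele frequencies, the clonal
#' lineages with their private-mutation and loss-of-heterozygosity rates, and
#' the mitochondrial clock. Construct with [simConfig()].
#'
#' @slot n_orfs number of reference ORFs.
#' @slot orf_len_codons sense codons per ORF (start codon included, stop excluded).
#' @slot species_labels ingroup sexual species letters (default E, T, N).
#' @slot outgroup_label outgroup species letter (default L).
#' @slot n_ind_sexual named integer vector: diploid individuals per species
#'   (ingroup and outgroup).
#' @slot d_fix probability per coding site that an ingroup species *pair* is
#'   fixed for a difference (placed as independent per-branch substitutions at
#'   rate \code{d_fix/2}; the outgroup branch runs at \code{d_fix}).
#' @slot f_inter_nonsyn nonsynonymous fraction among fixed differences.
#' @slot theta per-site density of segregating polymorphism within a species.
#' @slot f_intra_nonsyn nonsynonymous fraction among segregating variants.
#' @slot sel_shift exponent a >= 0; nonsynonymous derived-allele counts i are
#'   drawn with weight i^(-1-a) (synonymous use a = 0, the neutral 1/i spectrum).
#' @slot clones list of [CloneSpec-class] objects.
#' @slot mu private-mutation rate per nucleotide site per generation.
#' @slot f_priv_nonsyn nonsynonymous fraction among private mutations.
#' @slot p_stop fraction of nonsynonymous private mutations that are premature
#'   stop-gains.
#' @slot trunk_fraction fraction of a clone's private mutations on the lineage
#'   trunk (shared by all members) versus individual-specific tips.
#' @slot lambda_loh per-site loss-of-heterozygosity rate per generation; a
#'   heterozygous diagnostic site resolves with probability 1 - exp(-lambda*tau).
#' @slot mt_len,mt_mu,mt_div mitochondrial locus length, substitution rate per
#'   site per generation, and per-branch species-level divergence.
#' @slot flank_len noncoding flank length on each side of an ORF.
#' @slot codon_retry times a variant colliding with an occupied codon is
#'   re-drawn before the collision is accepted (masking fodder).
#' @slot seed integer seed governing all randomness.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  n_orfs = "integer",
  orf_len_codons = "integer",
  species_labels = "character",
  outgroup_label = "character",
  n_ind_sexual = "integer",
  d_fix = "numeric",
  f_inter_nonsyn = "numeric",
  theta = "numeric",
  f_intra_nonsyn = "numeric",
  sel_shift = "numeric",
  clones = "list",
  mu = "numeric",
  f_priv_nonsyn = "numeric",
  p_stop = "numeric",
  trunk_fraction = "numeric",
  lambda_loh = "numeric",
  mt_len = "integer",
  mt_mu = "numeric",
  mt_div = "numeric",
  flank_len = "integer",
  codon_retry = "integer",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- NULL
  probs <- c(d_fix = object@d_fix, f_inter_nonsyn = object@f_inter_nonsyn,
             theta = object@theta, f_intra_nonsyn = object@f_intra_nonsyn,
             f_priv_nonsyn = object@f_priv_nonsyn, p_stop = object@p_stop,
             trunk_fraction = object@trunk_fraction, mt_div = object@mt_div)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    msg <- c(msg, paste("rates must lie in [0, 1]:",
                        paste(names(probs)[bad], collapse = ", ")))
  if (object@orf_len_codons < 1L) msg <- c(msg, "orf_len_codons must be >= 1")
  if (object@n_orfs < 1L) msg <- c(msg, "n_orfs must be >= 1")
  if (object@sel_shift < 0) msg <- c(msg, "sel_shift must be >= 0")
  if (object@mu < 0 || object@lambda_loh < 0 || object@mt_mu < 0)
    msg <- c(msg, "mu, lambda_loh and mt_mu must be >= 0")
  if (!all(vapply(object@clones, inherits, logical(1), "CloneSpec")))
    msg <- c(msg, "clones must be a list of CloneSpec objects")
  cl_letters <- unique(unlist(strsplit(vapply(object@clones, slot, "",
                                              "genomotype"), "")))
  if (!all(cl_letters %in% object@species_labels))
    msg <- c(msg, "every genomotype letter needs a sexual species pool")
  if (!all(c(object@species_labels, object@outgroup_label) %in%
           names(object@n_ind_sexual)))
    msg <- c(msg, "n_ind_sexual must name every species and the outgroup")
  if (is.null(msg)) TRUE else msg
})

#' Ploidy-aware genotype table
#'
#' The central genotype container: one row per biallelic (or still unfiltered)
#' SNP site, one column per sample. Calls are unphased allele multisets of
#' size equal to the sample's ploidy, encoded as \code{"A/G"} (diploid) or
#' \code{"A/G/G"} (triploid) strings; \code{NA} marks a missing call.
#'
#' @slot sites data.frame with columns \code{contig}, \code{pos} (0-based),
#'   \code{ref}, \code{alt}.
#' @slot geno character matrix, sites x samples.
#' @slot samples data.frame with columns \code{sample_id}, \code{genomotype},
#'   \code{ploidy}, \code{category} (one of sexual, outgroup, F1, young_clone,
#'   old_clone) and \code{clone_id}.
#' @exportClass GenotypeTable
setClass("GenotypeTable", representation(
  sites = "data.frame",
  geno = "matrix",
  samples = "data.frame"
))

setValidity("GenotypeTable", function(object) {
  msg <- NULL
  if (!all(c("contig", "pos", "ref", "alt") %in% names(object@sites)))
    msg <- c(msg, "sites needs columns contig, pos, ref, alt")
  if (!all(c("sample_id", "genomotype", "ploidy", "category", "clone_id") %in%
           names(object@samples)))
    msg <- c(msg, "samples needs sample_id, genomotype, ploidy, category, clone_id")
  if (nrow(object@geno) != nrow(object@sites))
    msg <- c(msg, "geno rows must match sites")
  if (ncol(object@geno) != nrow(object@samples))
    msg <- c(msg, "geno columns must match samples")
  if (!all(object@samples$ploidy %in% 2:3))
    msg <- c(msg, "ploidy must be 2 or 3")
  if (is.null(msg) && nrow(object@geno) > 0L) {
    # allele multiset size must equal ploidy wherever called
    n_al <- matrix(lengths(strsplit(object@geno, "/", fixed = TRUE)),
                   nrow = nrow(object@geno))
    n_al[is.na(object@geno)] <- NA_integer_
    exp_pl <- matrix(object@samples$ploidy, nrow = nrow(object@geno),
                     ncol = ncol(object@geno), byrow = TRUE)
    if (any(n_al != exp_pl, na.rm = TRUE))
      msg <- c(msg, "called genotypes must have as many alleles as the sample ploidy")
  }
  if (is.null(msg)) TRUE else msg
})

#' Simulated hybrid complex with planted truth
#'
#' The full output of [simulateComplex()]: the reference ORF set, the genotype
#' table over sexual individuals, the outgroup and clone members, per-sample
#' mitochondrial haplotypes, and a truth ledger recording the class of every
#' planted variant, every private-mutation event and every LOH event, so that
#' downstream inference can be scored against what was planted.
#'
#' @slot config the [SimConfig-class] used.
#' @slot reference \code{DNAStringSet} of contigs.
#' @slot orfs data.frame: \code{orf_id}, \code{contig}, \code{start},
#'   \code{end} (0-based half-open, stop codon included), \code{n_codons}
#'   (sense codons).
#' @slot genotypes a [GenotypeTable-class].
#' @slot mt \code{DNAStringSet} of per-sample mtDNA haplotypes.
#' @slot truth list with elements \code{sites} (planted site classes),
#'   \code{private} (per-mutation events), \code{loh} (per-individual events)
#'   and \code{rates} (realised process summaries).
#' @exportClass HybridComplexSim
setClass("HybridComplexSim", representation(
  config = "SimConfig",
  reference = "ANY",
  orfs = "data.frame",
  genotypes = "GenotypeTable",
  mt = "ANY",
  truth = "list"
))

#' Classified SNP set
#'
#' Result of [classifySites()]: the retained sites with their category
#' (intraspecific / interspecific_fixed / private_asexual / unclassified),
#' codon placement, synonymity and derived-allele polarisation, together with
#' filtering tallies.
#'
#' @slot table data.frame, one row per retained site.
#' @slot removed named list of removal/filter counts.
#' @slot params list of thresholds used.
#' @exportClass SnpClassification
setClass("SnpClassification", representation(
  table = "data.frame",
  removed = "list",
  params = "list"
))
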