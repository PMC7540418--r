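#' @describeIn GenotypeTable number of SNP sites
#' @param x,object a \code{GenotypeTable} (or other container as documented)
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @describeIn GenotypeTable number of samples
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @describeIn GenotypeTable sample metadata data.frame
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @describeIn GenotypeTable site table (contig, pos, ref, alt)
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @describeIn GenotypeTable genotype string matrix (sites x samples)
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @describeIn HybridComplexSim reference contig sequences
#' @export
setGeneric("referenceSeqs", function(x) standardGeneric("referenceSeqs"))

#' @describeIn HybridComplexSim ORF coordinate table
#' @export
setGeneric("orfTable", function(x) standardGeneric("orfTable"))

#' @describeIn HybridComplexSim per-sample mtDNA haplotypes
#' @export
setGeneric("mtHaplotypes", function(x) standardGeneric("mtHaplotypes"))

#' @describeIn HybridComplexSim planted-truth ledger
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @describeIn HybridComplexSim the simulation configuration
#' @export
setGeneric("simulationConfig", function(x) standardGeneric("simulationConfig"))

#' @describeIn SnpClassification classified site table
#' @export
setGeneric("classificationTable", function(x) standardGeneric("classificationTable"))
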