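# Site-frequency spectra (within sexual species or clones), clone-sharing
# spectra for private SNPs, and per-individual heterozygosity. Stop-gain
# sites are counted inside the nonsynonymous stratum (they are a subset of
# nonsynonymous changes); masked and noncoding sites are excluded.

.synStratum <- function(synonymity) {
  ifelse(synonymity == "synonymous", "synonymous",
  ifelse(synonymity %in% c("nonsynonymous", "stop_gain"), "nonsynonymous",
         NA_character_))
}

# derived-allele copies carried by each sample at given gt rows
.derivedCopies <- function(gt, rows, derived, samples) {
  geno <- genotypes(gt)[rows, samples, drop = FALSE]
  al <- .alleleList(geno)
  cnt <- matrix(mapply(function(a, d) sum(a == d), al,
                       rep(derived, times = length(samples))),
                nrow = length(rows))
  cnt[is.na(geno)] <- NA_integer_
  cnt
}

#' Site frequency spectrum of polarised SNPs in one population
#'
#' For a sexual species, tallies the derived-allele count of every polarised
#' intraspecific SNP segregating in that species over its called chromosomes;
#' for a clone, tallies derived copies of its private SNPs over the member
#' chromosomes. Synonymous and nonsynonymous sites form separate strata.
#' Unpolarised sites are skipped and counted in the \code{"skipped"}
#' attribute.
#'
#' @param gt a [GenotypeTable-class].
#' @param classification a [SnpClassification-class].
#' @param population a sexual species letter (e.g. \code{"E"}) or a clone id.
#' @return data.frame \code{population, synonymity, k, count} with attributes
#'   \code{"n_polarized"} and \code{"skipped"}.
#' @export
siteFrequencySpectrum <- function(gt, classification, population) {
  tab <- classificationTable(classification)
  samples <- sampleMeta(gt)
  if (population %in% .ingroupSpecies(samples)) {
    ids <- .speciesSamples(samples, population)
    in_pop <- tab$category == "intraspecific" &
      vapply(strsplit(tab$focal, ","), function(f) population %in% f, TRUE)
  } else if (population %in% samples$clone_id) {
    ids <- samples$sample_id[!is.na(samples$clone_id) &
                             samples$clone_id == population]
    in_pop <- tab$category == "private_asexual"
  } else stop("unknown population: ", population)
  strat <- .synStratum(tab$synonymity)
  use <- in_pop & !is.na(strat)
  polar <- use & !is.na(tab$derived)
  rows <- .matchSites(tab[polar, , drop = FALSE], gt)
  cnt <- .derivedCopies(gt, rows, tab$derived[polar], ids)
  k <- rowSums(cnt, na.rm = TRUE)
  keep <- k > 0L          # a clone-restricted view may not carry the allele
  df <- data.frame(population = population,
                   synonymity = strat[polar][keep], k = k[keep],
                   stringsAsFactors = FALSE)
  out <- stats::aggregate(cbind(count = rep(1L, nrow(df))) ~
                            population + synonymity + k, data = df, FUN = sum)
  out <- out[order(out$synonymity, out$k), ]
  rownames(out) <- NULL
  attr(out, "n_polarized") <- sum(keep)
  attr(out, "skipped") <- sum(use) - sum(polar)
  attr(out, "n_chrom") <- sum(samples$ploidy[match(ids, samples$sample_id)])
  out
}

#' Clone-sharing spectrum of private SNPs
#'
#' For every private asexual SNP carried by a clone, k is the number of
#' same-clone individuals sharing the derived allele. Lineage-trunk mutations
#' appear at k = clone size, fresh tip mutations as singletons; purifying
#' selection within the clone shows up as nonsynonymous variants skewed
#' towards singletons.
#'
#' @param gt a [GenotypeTable-class].
#' @param classification a [SnpClassification-class].
#' @param clone_id clone identifier from the sample metadata.
#' @return data.frame \code{clone_id, synonymity, k, count}; warns when the
#'   clone has a single member (degenerate spectrum).
#' @export
cloneSharingSpectrum <- function(gt, classification, clone_id) {
  samples <- sampleMeta(gt)
  ids <- samples$sample_id[!is.na(samples$clone_id) &
                           samples$clone_id == clone_id]
  if (!length(ids)) stop("unknown clone: ", clone_id)
  if (length(ids) < 2L)
    warning("clone of size 1: sharing spectrum is degenerate (all k = 1)")
  tab <- classificationTable(classification)
  strat <- .synStratum(tab$synonymity)
  use <- tab$category == "private_asexual" & !is.na(tab$derived) &
    !is.na(strat)
  rows <- .matchSites(tab[use, , drop = FALSE], gt)
  cnt <- .derivedCopies(gt, rows, tab$derived[use], ids)
  k <- rowSums(cnt > 0L, na.rm = TRUE)   # members carrying, dosage ignored
  keep <- k > 0L
  df <- data.frame(clone_id = rep(clone_id, sum(keep)),
                   synonymity = strat[use][keep],
                   k = k[keep], stringsAsFactors = FALSE)
  if (!nrow(df))
    return(data.frame(clone_id = character(0), synonymity = character(0),
                      k = integer(0), count = integer(0)))
  out <- stats::aggregate(cbind(count = rep(1L, nrow(df))) ~
                            clone_id + synonymity + k, data = df, FUN = sum)
  out <- out[order(out$synonymity, out$k), ]
  rownames(out) <- NULL
  attr(out, "clone_size") <- length(ids)
  out
}

#' Per-sample genome-wide heterozygosity
#'
#' Fraction of called SNP sites where the sample's allele multiset contains
#' at least two distinct alleles. Hybrids freeze interspecific divergence as
#' heterozygosity, so they sit far above their sexual progenitors.
#'
#' @param gt a [GenotypeTable-class].
#' @param samples sample ids; default all.
#' @return named numeric vector; NA (with a warning) for samples with no
#'   called site.
#' @export
heterozygosity <- function(gt, samples = NULL) {
  if (is.null(samples)) samples <- sampleMeta(gt)$sample_id
  geno <- genotypes(gt)[, samples, drop = FALSE]
  het <- matrix(vapply(.alleleList(geno), function(a)
    length(unique(a)) >= 2L, TRUE), nrow = nrow(geno))
  het[is.na(geno)] <- NA
  out <- colMeans(het, na.rm = TRUE)
  ncall <- colSums(!is.na(geno))
  if (any(ncall == 0L)) {
    warning("sample(s) with zero called sites: heterozygosity undefined")
    out[ncall == 0L] <- NA_real_
  }
  stats::setNames(out, samples)
}
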