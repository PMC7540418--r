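# Site filtering, paralog flagging, codon masking, SNP category assignment,
# synonymity annotation and derived-allele polarisation. Categories follow
# the hybrid-complex logic: a site segregating within any ingroup sexual
# species is intraspecific; a site monomorphic within every species but
# differing between some pair is a fixed interspecific difference (frozen as
# heterozygosity in hybrids); a site invariant in all sexual species where a
# hybrid carries an apomorphic allele is a private asexual SNP. Hybrid
# genotypes never influence the first two categories.

.ingroupSpecies <- function(samples) {
  sx <- samples[samples$category == "sexual", ]
  sort(unique(substr(sx$genomotype, 1L, 1L)))
}

.speciesSamples <- function(samples, sp) {
  samples$sample_id[samples$category == "sexual" &
                    samples$genomotype == paste0(sp, sp)]
}

.hybridSamples <- function(samples) {
  samples$sample_id[samples$category %in% c("F1", "young_clone", "old_clone")]
}

# per-site distinct observed alleles over a sample subset
.observedAlleles <- function(geno_sub) {
  apply(geno_sub, 1L, function(g)
    unique(unlist(strsplit(g[!is.na(g)], "/", fixed = TRUE))),
    simplify = FALSE)
}

#' Filter sites to biallelic, sufficiently called positions
#'
#' Retains sites with at most two distinct observed alleles across all
#' samples and a called fraction of at least \code{min_called_fraction}
#' (inclusive) over the ingroup samples (the outgroup is excluded from the
#' denominator by default).
#'
#' @param gt a [GenotypeTable-class].
#' @param min_called_fraction minimum fraction of successfully called
#'   individuals, default 0.8.
#' @param biallelic_only drop sites with >2 observed alleles.
#' @param include_outgroup count the outgroup in the called fraction.
#' @return filtered [GenotypeTable-class] with a \code{"removed"} attribute
#'   (named counts). Warns when nothing survives.
#' @export
filterSites <- function(gt, min_called_fraction = 0.8, biallelic_only = TRUE,
                        include_outgroup = FALSE) {
  geno <- genotypes(gt)
  samples <- sampleMeta(gt)
  denom_cols <- if (include_outgroup) seq_len(nrow(samples))
               else which(samples$category != "outgroup")
  called_frac <- rowMeans(!is.na(geno[, denom_cols, drop = FALSE]))
  n_alleles <- lengths(.observedAlleles(geno))
  keep_bi <- if (biallelic_only) n_alleles <= 2L else rep(TRUE, nSites(gt))
  keep_call <- called_frac >= min_called_fraction
  keep <- keep_bi & keep_call
  removed <- list(multiallelic = sum(!keep_bi),
                  undercalled = sum(keep_bi & !keep_call))
  if (!any(keep)) warning("no sites remain after filtering")
  out <- subsetGenotypes(gt, sites = which(keep))
  attr(out, "removed") <- removed
  out
}

#' Flag putatively paralogous contigs by shared heterozygosity
#'
#' A site is spurious when it is heterozygous in at least one individual of
#' every ingroup sexual species *and* in the outgroup: identical heterozygous
#' positions across distantly related species are the signature of paralogous
#' reads collapsed onto one contig, not of shared polymorphism. Contigs with
#' at least \code{min_shared_het_sites} spurious sites are flagged.
#'
#' @param gt a [GenotypeTable-class] containing outgroup samples.
#' @param min_shared_het_sites flagging threshold, default 1.
#' @return character vector of flagged contigs, with attribute
#'   \code{"spurious_sites"} (row indices).
#' @export
flagParalogContigs <- function(gt, min_shared_het_sites = 1L) {
  samples <- sampleMeta(gt)
  if (!any(samples$category == "outgroup"))
    stop("paralog flagging requires an outgroup sample")
  geno <- genotypes(gt)
  is_het <- function(cols) {
    sub <- geno[, cols, drop = FALSE]
    het <- matrix(vapply(.alleleList(sub), function(a)
      length(unique(a)) >= 2L, TRUE), nrow = nrow(sub))
    het[is.na(sub)] <- FALSE
    rowSums(het) > 0L
  }
  spp <- .ingroupSpecies(samples)
  het_all <- vapply(spp, function(sp) is_het(.speciesSamples(samples, sp)),
                    logical(nSites(gt)))
  het_out <- is_het(samples$sample_id[samples$category == "outgroup"])
  spurious <- which(rowSums(cbind(het_all, het_out)) == length(spp) + 1L)
  tab <- table(siteInfo(gt)$contig[spurious])
  flagged <- as.character(names(tab)[tab >= min_shared_het_sites])
  attr(flagged, "spurious_sites") <- spurious
  flagged
}

#' Map sites to ORF codons
#'
#' Assigns each site its ORF, 0-based codon index and within-codon position.
#' Sites outside any ORF's sense-codon span (flanks and stop codons) are
#' marked noncoding.
#'
#' @param sites data.frame with \code{contig}, \code{pos} (0-based).
#' @param orfs ORF table (\code{orf_id}, \code{contig}, \code{start},
#'   \code{end}, \code{n_codons}), coordinates 0-based half-open.
#' @return data.frame with \code{orf_id}, \code{codon_index},
#'   \code{codon_pos}, \code{coding}.
#' @export
mapSitesToCodons <- function(sites, orfs) {
  idx <- match(sites$contig, orfs$contig)
  start <- orfs$start[idx]
  n_cod <- orfs$n_codons[idx]
  off <- sites$pos - start
  coding <- !is.na(idx) & off >= 0L & off < 3L * n_cod
  data.frame(
    orf_id = ifelse(coding, orfs$orf_id[idx], NA_character_),
    codon_index = ifelse(coding, off %/% 3L, NA_integer_),
    codon_pos = ifelse(coding, off %% 3L, NA_integer_),
    coding = coding, stringsAsFactors = FALSE)
}

#' Mask codons containing more than one polymorphic site
#'
#' Without phase information the amino-acid translation of a codon carrying
#' two variable positions is ambiguous, so all its sites are masked and
#' excluded from synonymity-based analyses.
#'
#' @param codon_map result of [mapSitesToCodons()].
#' @return logical vector: TRUE where the site's codon holds >= 2 sites.
#' @export
maskMultiVariantCodons <- function(codon_map) {
  key <- paste(codon_map$orf_id, codon_map$codon_index)
  key[!codon_map$coding] <- NA
  dup <- stats::ave(seq_along(key), key, FUN = length) >= 2L
  dup & !is.na(key)
}

# per-species monomorphic allele (NA when polymorphic or uncalled)
.speciesAlleleMatrix <- function(gt) {
  samples <- sampleMeta(gt)
  geno <- genotypes(gt)
  spp <- .ingroupSpecies(samples)
  out <- list()
  for (sp in spp) {
    obs <- .observedAlleles(geno[, .speciesSamples(samples, sp), drop = FALSE])
    out[[sp]] <- list(
      allele = vapply(obs, function(a)
        if (length(a) == 1L) a else NA_character_, ""),
      n_obs = lengths(obs))
  }
  out
}

#' Assign each site its SNP category
#'
#' Categories are mutually exclusive and assessed on the ingroup sexual
#' species only: \code{intraspecific} if any species is polymorphic at the
#' site; else \code{interspecific_fixed} if every species is monomorphic and
#' at least one pair differs; else \code{private_asexual} if all sexual
#' species share one allele and at least one hybrid carries the other;
#' otherwise \code{unclassified}. A species with no called individual at a
#' site renders it unclassified rather than guessed.
#'
#' @param gt a filtered [GenotypeTable-class].
#' @return data.frame with \code{category}, \code{focal} (polymorphic species,
#'   differing pairs, or NA), \code{a1}/\code{a2} (observed alleles), and one
#'   \code{allele_<species>} column per ingroup species.
#' @export
classifySiteCategories <- function(gt) {
  samples <- sampleMeta(gt)
  geno <- genotypes(gt)
  spp <- .ingroupSpecies(samples)
  spal <- .speciesAlleleMatrix(gt)
  obs_all <- .observedAlleles(geno)
  hyb <- .hybridSamples(samples)
  obs_hyb <- if (length(hyb))
    .observedAlleles(geno[, hyb, drop = FALSE]) else NULL
  n <- nSites(gt)
  n_obs_m <- vapply(spp, function(sp) spal[[sp]]$n_obs, integer(n))
  al_m <- vapply(spp, function(sp) spal[[sp]]$allele, character(n))
  if (n == 1L) { n_obs_m <- matrix(n_obs_m, 1L); al_m <- matrix(al_m, 1L) }
  poly_m <- n_obs_m >= 2L
  any_poly <- rowSums(poly_m) > 0L
  any_uncalled <- rowSums(n_obs_m == 0L) > 0L
  category <- character(n); focal <- rep(NA_character_, n)
  category[any_poly] <- "intraspecific"
  focal[any_poly] <- apply(poly_m[any_poly, , drop = FALSE], 1L,
                           function(p) paste(spp[p], collapse = ","))
  idx_unc <- !any_poly & any_uncalled
  category[idx_unc] <- "unclassified"
  focal[idx_unc] <- "no_calls_species"
  prs <- utils::combn(spp, 2L)
  for (i in which(!any_poly & !any_uncalled)) {
    al <- al_m[i, ]
    if (length(unique(al)) > 1L) {
      category[i] <- "interspecific_fixed"
      dif <- al[prs[1L, ]] != al[prs[2L, ]]
      focal[i] <- paste(paste0(prs[1L, dif], "x", prs[2L, dif]),
                        collapse = ",")
    } else {
      apo <- if (is.null(obs_hyb)) character(0) else
        setdiff(obs_hyb[[i]], al[1L])
      category[i] <- if (length(apo)) "private_asexual" else "unclassified"
    }
  }
  a12 <- t(vapply(obs_all, function(a) c(a, NA_character_)[1:2],
                  c("", "")))
  out <- data.frame(category = category, focal = focal,
                    a1 = a12[, 1L], a2 = a12[, 2L], stringsAsFactors = FALSE)
  for (sp in spp) out[[paste0("allele_", sp)]] <- spal[[sp]]$allele
  out
}

#' Annotate the synonymity of a biallelic coding site
#'
#' Translates the site's codon with each of the two observed alleles in the
#' reference context (valid because masking guarantees at most one variable
#' site per codon, so no phase is needed). Equal amino acids are synonymous;
#' an allele producing a stop in a non-final sense codon is a premature
#' stop-gain; a stop arising in the final sense codon is counted
#' nonsynonymous.
#'
#' @param class_df site table with \code{a1}, \code{a2} plus codon columns
#'   (\code{orf_id}, \code{codon_index}, \code{codon_pos}, \code{coding},
#'   \code{masked}).
#' @param reference \code{DNAStringSet} of contigs.
#' @param orfs ORF coordinate table.
#' @return character vector: synonymous / nonsynonymous / stop_gain /
#'   masked / noncoding.
#' @export
annotateSynonymity <- function(class_df, reference, orfs) {
  n <- nrow(class_df)
  syn <- rep(NA_character_, n)
  syn[!class_df$coding] <- "noncoding"
  syn[class_df$coding & class_df$masked] <- "masked"
  todo <- which(class_df$coding & !class_df$masked)
  if (!length(todo)) return(syn)
  oi <- match(class_df$orf_id[todo], orfs$orf_id)
  cstart <- orfs$start[oi] + 3L * class_df$codon_index[todo]
  refs <- as.character(reference)
  codon0 <- substring(refs[orfs$contig[oi]], cstart + 1L, cstart + 3L)
  p <- class_df$codon_pos[todo] + 1L
  a1 <- class_df$a1[todo]; a2 <- class_df$a2[todo]
  bad <- !(a1 %in% .NTS) | !(a2 %in% .NTS) | is.na(a2)
  if (any(bad))
    stop("non-A/C/G/T allele at coding site(s): ",
         paste(utils::head(todo[bad]), collapse = ", "))
  c1 <- codon0; substr(c1, p, p) <- a1
  c2 <- codon0; substr(c2, p, p) <- a2
  aa1 <- translateCodon(c1); aa2 <- translateCodon(c2)
  final <- class_df$codon_index[todo] == orfs$n_codons[oi] - 1L
  res <- ifelse(aa1 == aa2, "synonymous",
         ifelse((aa1 == "*" | aa2 == "*") & !final, "stop_gain",
                "nonsynonymous"))
  syn[todo] <- res
  syn
}

#' Default sister-taxon map for derived-allele polarisation
#'
#' T and N polarise each other; E uses the consensus of T and N (both must
#' agree); the outgroup is the fallback whenever the primary sister is
#' polymorphic or uncalled.
#'
#' @param outgroup outgroup label, default \code{"L"}.
#' @return named list mapping each focal taxon to its sister taxa.
#' @export
defaultSisterMap <- function(outgroup = "L") {
  list(T = "N", N = "T", E = c("T", "N"), .fallback = outgroup)
}

#' Polarise intraspecific and private SNPs into ancestral/derived alleles
#'
#' The ancestral state of an intraspecific SNP is the allele monomorphic in
#' the sister taxon (consensus required when the sister set has two members;
#' outgroup fallback otherwise); the other observed allele is derived. For
#' private asexual SNPs the sexual species themselves carry the ancestral
#' state, so the hybrid's apomorphic allele is derived. Sites whose sister is
#' polymorphic or uncalled stay unpolarised and are excluded from spectra.
#'
#' @param class_df output of [classifySiteCategories()] (with
#'   \code{allele_<species>} columns).
#' @param gt the [GenotypeTable-class] (for outgroup calls).
#' @param sister_map see [defaultSisterMap()].
#' @return data.frame with \code{ancestral} and \code{derived} (NA when
#'   unpolarised).
#' @export
polarizeDerived <- function(class_df, gt, sister_map = defaultSisterMap()) {
  samples <- sampleMeta(gt)
  geno <- genotypes(gt)
  out_cols <- samples$sample_id[samples$category == "outgroup"]
  out_allele <- if (length(out_cols)) {
    obs <- .observedAlleles(geno[, out_cols, drop = FALSE])
    vapply(obs, function(a) if (length(a) == 1L) a else NA_character_, "")
  } else rep(NA_character_, nSites(gt))
  n <- nrow(class_df)
  anc <- rep(NA_character_, n)
  is_priv <- class_df$category == "private_asexual"
  anc[is_priv] <-
    class_df[[paste0("allele_", .polFirstSpecies(class_df))]][is_priv]
  is_intra <- class_df$category == "intraspecific"
  foc_all <- sub(",.*", "", class_df$focal)
  for (foc in unique(foc_all[is_intra])) {
    sisters <- sister_map[[foc]]
    if (is.null(sisters)) stop("sister map lacks focal taxon: ", foc)
    idx <- which(is_intra & foc_all == foc)
    sal <- vapply(sisters, function(s) {
      col <- paste0("allele_", s)
      if (col %in% names(class_df)) class_df[[col]][idx]
      else rep(NA_character_, length(idx))
    }, character(length(idx)))
    if (length(idx) == 1L) sal <- matrix(sal, 1L)
    agree <- rowSums(is.na(sal)) == 0L &
      apply(sal, 1L, function(a) length(unique(a)) == 1L)
    anc[idx[agree]] <- sal[agree, 1L]
    anc[idx[!agree]] <- out_allele[idx[!agree]]  # outgroup fallback
  }
  a1 <- class_df$a1; a2 <- class_df$a2
  valid <- !is.na(anc) & (anc == a1 | (!is.na(a2) & anc == a2))
  derived <- rep(NA_character_, n)
  derived[valid] <- ifelse(anc[valid] == a1[valid], a2[valid], a1[valid])
  anc[!valid] <- NA_character_
  data.frame(ancestral = anc, derived = derived, stringsAsFactors = FALSE)
}

.polFirstSpecies <- function(class_df) {
  sub("allele_", "", grep("^allele_", names(class_df), value = TRUE)[1L])
}

#' Full site classification pipeline
#'
#' Chains [filterSites()], [flagParalogContigs()], codon mapping and
#' [maskMultiVariantCodons()], [classifySiteCategories()],
#' [annotateSynonymity()] and [polarizeDerived()], and asserts that after
#' masking no analysed codon retains two variable positions.
#'
#' @param gt a [GenotypeTable-class].
#' @param reference \code{DNAStringSet} of contigs.
#' @param orfs ORF coordinate table.
#' @param min_called_fraction,biallelic_only passed to [filterSites()].
#' @param drop_paralogs,min_shared_het_sites paralog contig removal.
#' @param sister_map see [defaultSisterMap()].
#' @return a [SnpClassification-class].
#' @examples
#' sim <- simulateComplex(simConfig(n_orfs = 10, seed = 3))
#' cls <- classifySites(genotypes(sim), referenceSeqs(sim), orfTable(sim))
#' cls
#' @export
classifySites <- function(gt, reference, orfs,
                          min_called_fraction = 0.8, biallelic_only = TRUE,
                          drop_paralogs = TRUE, min_shared_het_sites = 1L,
                          sister_map = defaultSisterMap()) {
  ft <- filterSites(gt, min_called_fraction, biallelic_only)
  removed <- attr(ft, "removed")
  if (drop_paralogs && any(sampleMeta(ft)$category == "outgroup")) {
    flagged <- flagParalogContigs(ft, min_shared_het_sites)
    n_par <- sum(siteInfo(ft)$contig %in% flagged)
    removed$paralog_contig_sites <- n_par
    if (n_par > 0L)
      ft <- subsetGenotypes(ft, sites = !(siteInfo(ft)$contig %in% flagged))
  }
  sites <- siteInfo(ft)
  cmap <- mapSitesToCodons(sites, orfs)
  cmap$masked <- maskMultiVariantCodons(cmap)
  cats <- classifySiteCategories(ft)
  tab <- cbind(sites, cmap, cats)
  tab$synonymity <- annotateSynonymity(tab, reference, orfs)
  pol <- polarizeDerived(tab, ft, sister_map)
  tab$ancestral <- pol$ancestral
  tab$derived <- pol$derived
  # hard assertion: analysed codons carry exactly one variable position
  live <- tab$coding & !tab$masked
  key <- paste(tab$orf_id[live], tab$codon_index[live])
  if (anyDuplicated(key))
    stop("internal error: analysed codon with two variable positions")
  new("SnpClassification", table = tab, removed = removed,
      params = list(min_called_fraction = min_called_fraction,
                    biallelic_only = biallelic_only,
                    drop_paralogs = drop_paralogs,
                    min_shared_het_sites = min_shared_het_sites))
}
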