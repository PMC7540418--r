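# ORF-level dN/dS: eligibility filtering (>= 50 intact codons fully resolved
# in all individuals), within-individual subgenome estimates for hybrids, and
# the simulated-hybrid null built from all cross-species sexual pairs.

.siteKey <- function(contig, pos) paste(contig, pos, sep = ":")

# rows of gt@sites matching the classification table rows
.matchSites <- function(tab, gt) {
  match(.siteKey(tab$contig, tab$pos),
        .siteKey(siteInfo(gt)$contig, siteInfo(gt)$pos))
}

#' Coding sequence of one ORF (sense codons, stop excluded)
#'
#' @param reference \code{DNAStringSet} of contigs.
#' @param orfs ORF coordinate table.
#' @param orf_id ORF identifier.
#' @return character vector of codons.
#' @export
orfCodingSeq <- function(reference, orfs, orf_id) {
  i <- match(orf_id, orfs$orf_id)
  if (is.na(i)) stop("unknown ORF: ", orf_id)
  seq <- as.character(Biostrings::subseq(reference[[orfs$contig[i]]],
                                         orfs$start[i] + 1L,
                                         orfs$start[i] + 3L * orfs$n_codons[i]))
  .codonsOf(seq)
}

#' ORF eligibility for dN/dS: intact codons fully resolved in all samples
#'
#' A codon is intact when it is unmasked and carries no missing call in any
#' listed sample; an ORF is eligible when at least \code{min_codons} (default
#' 50, inclusive) of its sense codons are intact.
#'
#' @param gt a [GenotypeTable-class] (sites matched by contig/pos).
#' @param classification a [SnpClassification-class].
#' @param orfs ORF coordinate table.
#' @param samples sample ids to require resolution in; default all.
#' @param min_codons eligibility threshold.
#' @return named logical vector over ORFs, with attribute \code{"intact"}
#'   (codon counts).
#' @export
eligibleOrfs <- function(gt, classification, orfs, samples = NULL,
                         min_codons = 50L) {
  tab <- classificationTable(classification)
  if (is.null(samples)) samples <- sampleMeta(gt)$sample_id
  rows <- .matchSites(tab, gt)
  geno <- genotypes(gt)[, samples, drop = FALSE]
  has_missing <- rowSums(is.na(geno)) > 0L
  bad <- tab$coding & (tab$masked | has_missing[rows])
  key <- paste(tab$orf_id, tab$codon_index)
  bad_codons <- table(unique(data.frame(orf = tab$orf_id[bad],
                                        cod = tab$codon_index[bad]))$orf)
  intact <- stats::setNames(orfs$n_codons, orfs$orf_id)
  hit <- intersect(names(bad_codons), names(intact))
  intact[hit] <- intact[hit] - as.integer(bad_codons[hit])
  out <- intact >= min_codons
  attr(out, "intact") <- intact
  out
}

#' @rdname eligibleOrfs
#' @param orf_id single ORF to test.
#' @export
orfEligible <- function(gt, classification, orfs, orf_id, samples = NULL,
                        min_codons = 50L) {
  unname(eligibleOrfs(gt, classification, orfs, samples,
                      min_codons)[orf_id])
}

# the two distinct-variant codon sequences carried by one individual over an
# ORF, plus the codons to skip (masked, or missing in this sample)
.individualVariantSeqs <- function(sample, orf_id, gt, tab, ref_codons) {
  sub <- tab[tab$orf_id %in% orf_id & tab$coding, , drop = FALSE]
  seq_a <- seq_b <- ref_codons
  skip <- integer(0)
  if (!nrow(sub)) return(list(a = seq_a, b = seq_b, skip = skip))
  rows <- .matchSites(sub, gt)
  calls <- genotypes(gt)[rows, sample]
  for (i in seq_len(nrow(sub))) {
    ci <- sub$codon_index[i] + 1L
    if (sub$masked[i] || is.na(calls[i])) { skip <- c(skip, ci); next }
    al <- sort(unique(strsplit(calls[i], "/", fixed = TRUE)[[1]]))
    p <- sub$codon_pos[i] + 1L
    substr(seq_a[ci], p, p) <- al[1L]
    substr(seq_b[ci], p, p) <- al[length(al)]
  }
  list(a = seq_a, b = seq_b, skip = unique(skip))
}

#' Within-individual (subgenome) dN/dS for one hybrid and ORF
#'
#' Hybrids freeze one haplotype per parental genome, so the divergence
#' between the distinct alleles carried by one individual measures subgenome
#' divergence plus any post-origin mutations. For every codon where the
#' individual carries at least two distinct alleles (a triploid with alleles
#' \{A, A, G\} counts once, dosage ignored), the two distinct codon variants
#' accumulate NG86 pathway counts; homozygous codons contribute sites only.
#' For an F1 this reproduces the parental-haplotype pairwise estimate
#' exactly.
#'
#' @param sample sample id (ploidy 2 or 3).
#' @param orf_id ORF identifier.
#' @param gt a [GenotypeTable-class].
#' @param classification a [SnpClassification-class].
#' @param reference \code{DNAStringSet}; \code{orfs} its coordinate table.
#' @param orfs ORF coordinate table.
#' @param c pseudo-constant, default 0.01.
#' @return one-row data.frame as [pairwiseDnDs()].
#' @export
withinIndividualDnDs <- function(sample, orf_id, gt, classification,
                                 reference, orfs, c = 0.01) {
  pl <- sampleMeta(gt)$ploidy[match(sample, sampleMeta(gt)$sample_id)]
  if (is.na(pl) || pl < 2L) stop("sample must be a di- or triploid individual")
  tab <- classificationTable(classification)
  ref_codons <- orfCodingSeq(reference, orfs, orf_id)
  v <- .individualVariantSeqs(sample, orf_id, gt, tab, ref_codons)
  pairwiseDnDs(v$a, v$b, c = c, skip_codons = v$skip)
}

# seeded pseudo-haplotype: one allele drawn per site from the call multiset
.pseudoHaplotype <- function(sample, orf_id, gt, tab, ref_codons) {
  sub <- tab[tab$orf_id %in% orf_id & tab$coding, , drop = FALSE]
  seq_h <- ref_codons
  skip <- integer(0)
  if (!nrow(sub)) return(list(seq = seq_h, skip = skip))
  rows <- .matchSites(sub, gt)
  calls <- genotypes(gt)[rows, sample]
  for (i in seq_len(nrow(sub))) {
    ci <- sub$codon_index[i] + 1L
    if (sub$masked[i] || is.na(calls[i])) { skip <- c(skip, ci); next }
    al <- strsplit(calls[i], "/", fixed = TRUE)[[1]]
    p <- sub$codon_pos[i] + 1L
    substr(seq_h[ci], p, p) <- al[sample.int(length(al), 1L)]
  }
  list(seq = seq_h, skip = unique(skip))
}

#' Between-individual per-ORF dN/dS over sample pairs
#'
#' Heterozygous calls are collapsed by seeded pseudo-haplotype sampling (one
#' allele drawn per site per individual and ORF); every listed pair is then
#' compared codon-wise over the eligible ORFs.
#'
#' @param gt,classification,reference,orfs as elsewhere.
#' @param samples_a,samples_b sample id vectors; with \code{samples_b = NULL}
#'   all unordered pairs within \code{samples_a} are used.
#' @param min_codons ORF eligibility threshold (resolution required in all
#'   samples of the table).
#' @param c pseudo-constant.
#' @param seed seed for pseudo-haplotype sampling.
#' @return data.frame: orf_id, sample_a, sample_b, Nd, Sd, N, S, dN, dS,
#'   ratio, valid.
#' @export
betweenIndividualDnDs <- function(gt, classification, reference, orfs,
                                  samples_a, samples_b = NULL,
                                  min_codons = 50L, c = 0.01, seed = 1L) {
  set.seed(.normSeed(seed))
  elig <- eligibleOrfs(gt, classification, orfs, min_codons = min_codons)
  orf_ids <- names(elig)[elig]
  tab <- classificationTable(classification)
  pairs <- if (is.null(samples_b)) {
    if (length(samples_a) < 2L) stop("need at least two samples")
    m <- utils::combn(samples_a, 2L)
    data.frame(a = m[1L, ], b = m[2L, ], stringsAsFactors = FALSE)
  } else expand.grid(a = samples_a, b = samples_b,
                     stringsAsFactors = FALSE)
  out <- vector("list", length(orf_ids))
  for (k in seq_along(orf_ids)) {
    oid <- orf_ids[k]
    ref_codons <- orfCodingSeq(reference, orfs, oid)
    ids <- unique(c(pairs$a, pairs$b))
    haps <- lapply(ids, .pseudoHaplotype, orf_id = oid, gt = gt, tab = tab,
                   ref_codons = ref_codons)
    names(haps) <- ids
    res <- lapply(seq_len(nrow(pairs)), function(i) {
      ha <- haps[[pairs$a[i]]]; hb <- haps[[pairs$b[i]]]
      est <- pairwiseDnDs(ha$seq, hb$seq, c = c,
                          skip_codons = union(ha$skip, hb$skip))
      cbind(data.frame(orf_id = oid, sample_a = pairs$a[i],
                       sample_b = pairs$b[i], stringsAsFactors = FALSE), est)
    })
    out[[k]] <- do.call(rbind, res)
  }
  do.call(rbind, out)
}

#' Simulated-hybrid null distribution of dN/dS ratios
#'
#' All cross-species pairs of sexual individuals (e.g. every
#' elongatoides x taenia pair) emulate hybrids without any post-origin
#' asexual process: their per-ORF dN/dS ratios form the null distribution
#' against which real hybrid genomotypes are compared.
#'
#' @param gt,classification,reference,orfs as elsewhere.
#' @param species_a,species_b single species letters (sexual samples with
#'   genomotype \code{"EE"} etc. are selected).
#' @param min_codons,c,seed passed through.
#' @return data.frame as [betweenIndividualDnDs()].
#' @export
simulatedHybridNull <- function(gt, classification, reference, orfs,
                                species_a, species_b, min_codons = 50L,
                                c = 0.01, seed = 1L) {
  samples <- sampleMeta(gt)
  ids_a <- .speciesSamples(samples, species_a)
  ids_b <- .speciesSamples(samples, species_b)
  if (!length(ids_a) || !length(ids_b))
    stop("need at least one sexual sample per species")
  betweenIndividualDnDs(gt, classification, reference, orfs, ids_a, ids_b,
                        min_codons = min_codons, c = c, seed = seed)
}
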