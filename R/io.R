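# On-disk interchange: VCF 4.2 (GT only) + FASTA + BED6 + sample TSV + truth
# JSON. Internal coordinates are 0-based half-open; the VCF is 1-based.
# Reading goes through vcfR; the GT-only writer is a minimal text formatter
# so that outputs stay plain text.

#' Write simulation outputs to a directory
#'
#' Emits \code{reference.fasta}, \code{mt.fasta}, \code{orfs.bed} (BED6,
#' 0-based half-open), \code{samples.tsv}, \code{variants.vcf} (VCF 4.2,
#' 1-based, GT-only, ploidy-aware) and \code{truth.json}.
#'
#' @param sim a [HybridComplexSim-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeSimOutputs <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(reference = file.path(dir, "reference.fasta"),
             mt = file.path(dir, "mt.fasta"),
             bed = file.path(dir, "orfs.bed"),
             samples = file.path(dir, "samples.tsv"),
             vcf = file.path(dir, "variants.vcf"),
             truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(referenceSeqs(sim), paths[["reference"]])
  Biostrings::writeXStringSet(mtHaplotypes(sim), paths[["mt"]])
  orfs <- orfTable(sim)
  utils::write.table(
    data.frame(orfs$contig, orfs$start, orfs$end, orfs$orf_id, 0L, "+"),
    paths[["bed"]], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  utils::write.table(sampleMeta(genotypes(sim)), paths[["samples"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeGenotypeVCF(genotypes(sim), paths[["vcf"]],
                   contig_lengths = Biostrings::width(referenceSeqs(sim)))
  truth <- simTruth(sim)
  jsonlite::write_json(truth, paths[["truth"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}

#' Write a GenotypeTable as a GT-only VCF 4.2 file
#'
#' @param gt a [GenotypeTable-class].
#' @param path output path.
#' @param contig_lengths optional named lengths for \code{##contig} headers.
#' @return invisibly, \code{path}.
#' @export
writeGenotypeVCF <- function(gt, path, contig_lengths = NULL) {
  sites <- siteInfo(gt)
  samples <- sampleMeta(gt)
  geno <- genotypes(gt)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=clonedecay",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), contig_lengths))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples$sample_id),
                      collapse = "\t"))
  enc <- matrix("", nrow(sites), nrow(samples))
  for (j in seq_len(nrow(samples))) {
    pl <- samples$ploidy[j]
    miss <- paste(rep(".", pl), collapse = "/")
    al <- .alleleList(geno[, j])
    enc[, j] <- vapply(seq_len(nrow(sites)), function(i) {
      a <- al[[i]]
      if (is.null(a) || is.na(geno[i, j])) return(miss)
      idx <- sort(ifelse(a == sites$ref[i], 0L, 1L))
      paste(idx, collapse = "/")
    }, "")
  }
  body <- paste(sites$contig, sites$pos + 1L, ".", sites$ref, sites$alt,
                ".", "PASS", ".", "GT",
                apply(enc, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a GenotypeTable from a VCF and a sample TSV
#'
#' Parses the VCF with vcfR, decodes GT indices back into allele strings
#' (canonically sorted, so a written-then-read table reproduces the allele
#' multisets exactly) and attaches the sample metadata.
#'
#' @param vcf_path VCF 4.2 file with GT calls.
#' @param samples_path TSV with sample_id, genomotype, ploidy, category,
#'   clone_id.
#' @return a [GenotypeTable-class].
#' @export
readGenotypeTable <- function(vcf_path, samples_path) {
  if (!file.exists(vcf_path)) stop("missing VCF: ", vcf_path)
  if (!file.exists(samples_path)) stop("missing sample TSV: ", samples_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  samples$clone_id <- as.character(samples$clone_id)
  fix <- vcfR::getFIX(v)
  sites <- data.frame(contig = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]) - 1L,
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  gtm <- vcfR::extract.gt(v, element = "GT")
  ord <- match(colnames(gtm), samples$sample_id)
  if (anyNA(ord)) stop("VCF samples missing from the sample TSV")
  samples <- samples[ord, , drop = FALSE]
  geno <- matrix(NA_character_, nrow(sites), ncol(gtm))
  for (j in seq_len(ncol(gtm))) {
    parts <- strsplit(gtm[, j], "[/|]")
    geno[, j] <- vapply(seq_len(nrow(sites)), function(i) {
      p <- parts[[i]]
      if (is.null(p) || anyNA(p) || any(p == ".")) return(NA_character_)
      paste(sort(ifelse(p == "0", sites$ref[i], sites$alt[i])),
            collapse = "/")
    }, "")
  }
  genotypeTable(sites, geno, samples)
}

#' Read an ORF table from a BED6 file
#'
#' @param path BED6 file (0-based half-open, name = orf_id).
#' @return data.frame with orf_id, contig, start, end, n_codons (sense
#'   codons; the recorded span includes the stop codon).
#' @export
readOrfBed <- function(path) {
  if (!file.exists(path)) stop("missing BED: ", path)
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(orf_id = bed$V4, contig = bed$V1, start = bed$V2, end = bed$V3,
             n_codons = (bed$V3 - bed$V2) %/% 3L - 1L,
             stringsAsFactors = FALSE)
}

#' Validate that every emitted variant is covered by the truth ledger
#'
#' @param dir directory written by [writeSimOutputs()].
#' @return TRUE invisibly; errors on any VCF site absent from the truth.
#' @export
validateSimOutputs <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  gt <- readGenotypeTable(file.path(dir, "variants.vcf"),
                          file.path(dir, "samples.tsv"))
  vk <- .siteKey(siteInfo(gt)$contig, siteInfo(gt)$pos)
  tk <- .siteKey(truth$sites$contig, truth$sites$pos)
  missing <- setdiff(vk, tk)
  if (length(missing))
    stop("VCF site(s) absent from the truth ledger: ",
         paste(utils::head(missing), collapse = ", "))
  invisible(TRUE)
}
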