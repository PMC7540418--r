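# Loss-of-heterozygosity calling at diagnostic (fixed interspecific) sites,
# private-SNP accounting per hybrid, and the constrained quadratic model of
# LOH proportion against private-SNP proportion.

#' Call loss of heterozygosity in hybrid individuals
#'
#' Informative sites are fixed interspecific differences between the parental
#' genomes the hybrid carries, where an intact hybrid must be heterozygous.
#' In diploids LOH is called where the genotype is homozygous; in triploids
#' only where every observed allele derives from a single parental species
#' (a conservative call: with three homologues, partial losses cannot be
#' separated from allelic dropout). The parental origin of the retained
#' allele is tallied.
#'
#' @param gt a [GenotypeTable-class].
#' @param classification a [SnpClassification-class].
#' @param samples hybrid sample ids; default all hybrids in the table.
#' @return data.frame, one row per sample: \code{sample_id, genomotype,
#'   ploidy, n_informative, n_loh, proportion}, plus one
#'   \code{retained_<letter>} column per parental genome present.
#' @export
callLOH <- function(gt, classification, samples = NULL) {
  meta <- sampleMeta(gt)
  if (is.null(samples)) samples <- .hybridSamples(meta)
  tab <- classificationTable(classification)
  inter <- tab$category == "interspecific_fixed"
  rows_gt <- .matchSites(tab, gt)
  geno <- genotypes(gt)
  all_letters <- .ingroupSpecies(meta)
  res <- lapply(samples, function(sid) {
    mi <- match(sid, meta$sample_id)
    letters_ <- unique(strsplit(meta$genomotype[mi], "")[[1]])
    if (length(letters_) < 2L)
      stop(sid, " is not a hybrid (genomotype ", meta$genomotype[mi], ")")
    al_cols <- paste0("allele_", letters_)
    pa <- as.matrix(tab[, al_cols, drop = FALSE])
    informative <- inter &
      apply(pa, 1L, function(a) !anyNA(a) && length(unique(a)) > 1L)
    g <- geno[rows_gt, ][cbind(which(informative),
                               rep(match(sid, colnames(geno)),
                                   sum(informative)))]
    called <- !is.na(g)
    obs <- .distinctAlleles(g[called])
    pa_i <- pa[informative, , drop = FALSE][called, , drop = FALSE]
    one_parent <- vapply(seq_along(obs), function(i) {
      a <- obs[[i]]
      length(a) == 1L && a %in% pa_i[i, ]
    }, TRUE)
    retained <- character(0)
    if (any(one_parent)) {
      ra <- vapply(obs[one_parent], `[`, "", 1L)
      pm <- pa_i[one_parent, , drop = FALSE]
      retained <- vapply(seq_along(ra), function(i)
        letters_[which(pm[i, ] == ra[i])[1L]], "")
    }
    row <- data.frame(sample_id = sid, genomotype = meta$genomotype[mi],
                      ploidy = meta$ploidy[mi],
                      n_informative = sum(called),
                      n_loh = sum(one_parent),
                      proportion = if (sum(called)) sum(one_parent) / sum(called)
                                   else NA_real_,
                      stringsAsFactors = FALSE)
    for (l in all_letters)
      row[[paste0("retained_", l)]] <- sum(retained == l)
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Private-SNP proportion per sample
#'
#' Numerator: private asexual sites where the sample carries the apomorphic
#' (derived) allele; denominator: all retained SNP sites called in that
#' sample. Older clones accumulate proportionally more private SNPs.
#'
#' @param gt a [GenotypeTable-class].
#' @param classification a [SnpClassification-class].
#' @param samples sample ids; default all.
#' @return named numeric vector.
#' @export
privateSnpProportion <- function(gt, classification, samples = NULL) {
  meta <- sampleMeta(gt)
  if (is.null(samples)) samples <- meta$sample_id
  tab <- classificationTable(classification)
  rows_gt <- .matchSites(tab, gt)
  geno <- genotypes(gt)[rows_gt, samples, drop = FALSE]
  priv <- which(tab$category == "private_asexual" & !is.na(tab$derived))
  carries <- matrix(FALSE, length(priv), length(samples))
  if (length(priv)) {
    sub <- geno[priv, , drop = FALSE]
    al <- .alleleList(sub)
    carries <- matrix(mapply(function(a, d) !is.null(a) && d %in% a, al,
                             rep(tab$derived[priv], length(samples))),
                      nrow = length(priv))
    carries[is.na(sub)] <- FALSE
  }
  called <- colSums(!is.na(geno))
  out <- colSums(carries) / called
  out[called == 0L] <- NA_real_
  stats::setNames(out, samples)
}

#' Fraction of a sample's private SNPs in homozygous state
#'
#' New clonal mutations arise on one homologue and stay heterozygous unless
#' an LOH event fixes them; the homozygous fraction therefore measures the
#' overlap of the LOH process with accumulated mutations (near zero in
#' intact clones).
#'
#' @inheritParams privateSnpProportion
#' @return named numeric vector; NA for samples carrying no private SNP.
#' @export
homozygousPrivateFraction <- function(gt, classification, samples = NULL) {
  meta <- sampleMeta(gt)
  if (is.null(samples)) samples <- meta$sample_id
  tab <- classificationTable(classification)
  priv <- which(tab$category == "private_asexual" & !is.na(tab$derived))
  rows_gt <- .matchSites(tab[priv, , drop = FALSE], gt)
  geno <- genotypes(gt)[rows_gt, samples, drop = FALSE]
  out <- vapply(seq_along(samples), function(j) {
    al <- .alleleList(geno[, j])
    d <- tab$derived[priv]
    has <- vapply(seq_along(al), function(i)
      !is.na(geno[i, j]) && d[i] %in% al[[i]], TRUE)
    if (!sum(has)) return(NA_real_)
    hom <- vapply(which(has), function(i) all(al[[i]] == d[i]), TRUE)
    mean(hom)
  }, 0)
  stats::setNames(out, samples)
}

#' Quadratic models of LOH proportion against private-SNP proportion
#'
#' Fits the unconstrained second-order polynomial g(x) by ordinary least
#' squares and the constrained fit f(x) with the quadratic coefficient forced
#' non-negative (boundary permitted: when the free fit is concave, f
#' collapses to the best-fitting line). A convex f is what an LOH process
#' that increasingly overwrites accumulated private SNPs would produce; the
#' t-test of the free quadratic coefficient quantifies any deviation from
#' linearity.
#'
#' @param x private-SNP proportions (diploid hybrids).
#' @param y LOH proportions.
#' @return list with \code{unconstrained} and \code{constrained} fits (each
#'   \code{a0, a1, a2, rss, constrained}), and \code{a2_p_value}.
#' @export
fitLohVsPrivate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4L)
    stop("need at least 4 (x, y) points")
  g <- stats::lm(y ~ x + I(x^2))
  cg <- stats::coef(g)
  # noiseless input fits exactly; the t-test is then moot, not an error
  sg <- suppressWarnings(summary(g))$coefficients
  unc <- list(a0 = unname(cg[1L]), a1 = unname(cg[2L]), a2 = unname(cg[3L]),
              rss = sum(stats::residuals(g)^2), constrained = FALSE)
  a2_p <- if (nrow(sg) >= 3L) sg[3L, 4L] else NA_real_
  if (!is.na(unc$a2) && unc$a2 >= 0) {
    con <- unc; con$constrained <- TRUE
  } else {
    f <- stats::lm(y ~ x)      # a2 pinned to the boundary
    cf <- stats::coef(f)
    con <- list(a0 = unname(cf[1L]), a1 = unname(cf[2L]), a2 = 0,
                rss = sum(stats::residuals(f)^2), constrained = TRUE)
  }
  list(unconstrained = unc, constrained = con, a2_p_value = a2_p)
}
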