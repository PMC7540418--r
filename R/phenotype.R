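# Fitness-proxy indices and their group comparisons: Clark's condition
# factor, length-weight residuals, somatic indices, vertebrae index,
# fecundity, and Dahl-Lea growth back-calculation.

#' Compute fitness-proxy indices from a trait table
#'
#' CC = We/SL^3 (Clark's condition factor); LWR = residual of the ordinary
#' least-squares regression of log Wt on log SL over the cohort; HI, SSI,
#' HSI, GSI = organ mass over body mass (standard fisheries convention; the
#' denominator is selectable between total and eviscerated weight); VI =
#' vertebra size over SL; absolute fecundity = oocyte count; relative
#' fecundity = count per body weight. Rows with missing or non-positive SL
#' are excluded with a warning.
#'
#' @param specimens trait data.frame as produced by [simulatePhenotypes()].
#' @param weight_basis denominator for somatic indices and relative
#'   fecundity: \code{"Wt"} (default) or \code{"We"}.
#' @return data.frame of indices, keeping specimen and group columns.
#' @export
computeIndices <- function(specimens, weight_basis = c("Wt", "We")) {
  weight_basis <- match.arg(weight_basis)
  bad <- is.na(specimens$SL) | specimens$SL <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing/non-positive SL excluded")
    specimens <- specimens[!bad, , drop = FALSE]
  }
  W <- specimens[[weight_basis]]
  lwr_fit <- stats::lm(log(Wt) ~ log(SL), data = specimens)
  keep <- intersect(c("specimen_id", "age_class", "season", "site"),
                    names(specimens))
  out <- specimens[, keep, drop = FALSE]
  out$CC <- specimens$We / specimens$SL^3
  out$LWR <- unname(stats::residuals(lwr_fit))
  out$HI <- specimens$heart_g / W
  out$SSI <- specimens$spleen_g / W
  out$HSI <- specimens$liver_g / W
  out$GSI <- specimens$gonad_g / W
  out$VI <- specimens$vert_mm / specimens$SL
  out$abs_fecundity <- specimens$oocyte_count
  out$rel_fecundity <- specimens$oocyte_count / W
  out
}

#' Back-calculate length-at-age from vertebral annuli (Dahl-Lea)
#'
#' Length at annulus i is estimated by direct proportion,
#' \eqn{L_i = SL \cdot r_i / R}, from the distances of each annual ring and
#' of the vertebra edge from the vertebra centre.
#'
#' @param annuli_radii increasing radii of the annual rings (mm).
#' @param vertebra_radius radius R of the vertebra edge (mm).
#' @param SL standard length at capture (mm).
#' @return numeric vector of back-calculated lengths, monotone and <= SL.
#' @examples
#' backcalcGrowth(c(0.3, 0.5, 0.8), 1, 100)
#' @export
backcalcGrowth <- function(annuli_radii, vertebra_radius, SL) {
  if (is.unsorted(annuli_radii, strictly = TRUE))
    stop("annuli radii must be strictly increasing")
  if (any(annuli_radii > vertebra_radius))
    stop("annulus radius exceeds the vertebra radius")
  SL * annuli_radii / vertebra_radius
}

#' Compare fitness indices between clone-age groups
#'
#' Runs, per index and season stratum, a Welch t test and a permutation test
#' of the old-vs-young contrast; compares oocyte-diameter distributions by
#' the permutation Kolmogorov-Smirnov test; and compares clutch sizes and
#' survival proportions by cluster permutation with the female as the
#' nesting unit. Rows are canonically ordered first, so shuffled input
#' produces identical results.
#'
#' @param indices output of [computeIndices()].
#' @param oocytes,clutches optional tables from [simulatePhenotypes()].
#' @param group,strata column names for the contrast and the stratification.
#' @param n_perm,seed permutation settings.
#' @return data.frame: one row per (test, index, stratum) with p-values.
#' @export
compareGroups <- function(indices, oocytes = NULL, clutches = NULL,
                          group = "age_class", strata = "season",
                          n_perm = 999L, seed = 1L) {
  indices <- indices[order(indices$specimen_id), , drop = FALSE]
  idx_cols <- intersect(c("CC", "LWR", "HI", "SSI", "HSI", "GSI", "VI",
                          "abs_fecundity", "rel_fecundity"), names(indices))
  strata_levels <- sort(unique(indices[[strata]]))
  res <- list()
  add <- function(test, index, stratum, tr) {
    res[[length(res) + 1L]] <<- cbind(
      data.frame(test = test, index = index, stratum = stratum,
                 stringsAsFactors = FALSE), tr)
  }
  for (st in strata_levels) {
    sub <- indices[indices[[strata]] == st, , drop = FALSE]
    gl <- sort(unique(sub[[group]]))
    if (length(gl) < 2L) { warning("stratum ", st, " dropped: one group"); next }
    for (ix in idx_cols) {
      a <- sub[[ix]][sub[[group]] == gl[1L]]
      b <- sub[[ix]][sub[[group]] == gl[2L]]
      add("welch_t", ix, st, welchT(a, b))
      add("permutation", ix, st,
          permutationTest(sub[[ix]], sub[[group]], n_perm = n_perm,
                          seed = seed))
    }
    if (!is.null(oocytes)) {
      os <- oocytes[oocytes[[strata]] == st, , drop = FALSE]
      os <- os[order(os$specimen_id), , drop = FALSE]
      a <- os$diameter[os[[group]] == gl[1L]]
      b <- os$diameter[os[[group]] == gl[2L]]
      if (length(a) && length(b))
        add("ks_permutation", "oocyte_diameter", st,
            ksPermutation(a, b, n_perm = n_perm, seed = seed))
    }
  }
  if (!is.null(clutches)) {
    cl <- clutches[order(clutches$female_id, clutches$clutch), , drop = FALSE]
    add("cluster_permutation", "clutch_size", "all",
        permutationTest(cl$clutch_size, cl[[group]], n_perm = n_perm,
                        seed = seed, cluster = cl$female_id))
    add("cluster_permutation", "survival", "all",
        permutationTest(cl$survived / pmax(cl$clutch_size, 1L), cl[[group]],
                        n_perm = n_perm, seed = seed,
                        cluster = cl$female_id))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
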