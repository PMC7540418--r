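test_that("NG86 site counts match enumeration on landmark codons", {
  expect_equal(ng86SiteCounts("TTT"), c(n = 8 / 3, s = 1 / 3))
  expect_equal(ng86SiteCounts("ATG"), c(n = 3, s = 0))   # Met: no syn change
  # GGG: fully degenerate third position contributes a full synonymous site
  expect_gte(ng86SiteCounts("GGG")[["s"]], 1)
  expect_error(ng86SiteCounts("TAA"), "sense")
  for (cod in c("TTT", "ATG", "GGG", "TAT", "TGG", "CGA"))
    expect_equal(ng86SiteCounts(cod), bruteForceSites(cod), tolerance = 1e-12)
})

test_that("site counts sum to 3 except at stop-adjacent codons", {
  tots <- vapply(senseCodons(), function(cod) sum(ng86SiteCounts(cod)), 0)
  expect_true(all(tots <= 3 + 1e-12))
  # codons with no stop reachable in one step must sum to exactly 3
  no_stop_adj <- vapply(senseCodons(), function(cod) {
    muts <- unlist(lapply(1:3, function(p)
      vapply(setdiff(c("A", "C", "G", "T"), substr(cod, p, p)),
             function(nt) { m <- cod; substr(m, p, p) <- nt; m }, "")))
    all(GC[muts] != "*")
  }, TRUE)
  expect_true(any(no_stop_adj))
  expect_equal(unname(tots[no_stop_adj]),
               rep(3, sum(no_stop_adj)), tolerance = 1e-12)
})

test_that("pathway counts: identity, single step, and random-pair oracle", {
  expect_equal(ng86PathwayCounts("TTT", "TTT"), c(Nd = 0, Sd = 0))
  expect_equal(ng86PathwayCounts("TTT", "TTA"), c(Nd = 1, Sd = 0))
  set.seed(7)
  sense <- senseCodons()
  for (i in 1:150) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    got <- ng86PathwayCounts(a, b)
    expect_equal(got, bruteForcePathway(a, b), tolerance = 1e-12)
    ham <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(unname(sum(got)), ham, tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction: closed form, domain, monotonicity", {
  expect_identical(jukesCantor(0), 0)
  expect_lt(abs(jukesCantor(0.1) - 0.107326), 1e-6)
  expect_error(jukesCantor(0.75), "saturation")
  p <- seq(0.01, 0.7, by = 0.01)
  d <- jukesCantor(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("pairwise dN/dS: identity, hand computation, symmetry", {
  same <- pairwiseDnDs("ATGTTT", "ATGTTT")
  expect_identical(same$ratio, 1)          # (0 + 0.01)/(0 + 0.01)
  # ATG TTT ATG TTT vs ATG TTA ATG TTT: one Phe->Leu nonsynonymous step
  est <- pairwiseDnDs("ATGTTTATGTTT", "ATGTTAATGTTT")
  expect_equal(est$Nd, 1); expect_equal(est$Sd, 0)
  # hand-computed NG86 sites: ATG n=3 s=0; TTT s=1/3; TTA s=2/3
  expect_equal(est$N, (12 + 8 / 3 + 8 / 3 + 7 / 3 + 8 / 3) / 2,
               tolerance = 1e-12)
  expect_equal(est$S, (1 / 3 + 1 / 3 + 2 / 3 + 1 / 3) / 2, tolerance = 1e-12)
  expect_equal(est$dS, 0)
  expect_gt(est$dN, 0)
  expect_equal(est$ratio, (est$dN + 0.01) / 0.01, tolerance = 1e-12)
  swapped <- pairwiseDnDs("ATGTTAATGTTT", "ATGTTTATGTTT")
  expect_equal(est$ratio, swapped$ratio)
  # masked/ambiguous codons are skipped; nothing usable -> flagged
  none <- pairwiseDnDs("NNN", "NNN")
  expect_false(none$valid)
  expect_equal(none$codons_used, 0)
})

test_that("K2P distance: closed form, bound and saturation", {
  expect_equal(k2pDistance(strrep("A", 50), strrep("A", 50))$d, 0)
  one_ts <- k2pDistance(strrep("A", 100), paste0(strrep("A", 99), "G"))
  expect_equal(one_ts$d, -0.5 * log(0.98) - 0.25 * log(1), tolerance = 1e-9)
  expect_lt(abs(one_ts$d - 0.010101), 1e-6)
  set.seed(3)
  nts <- c("A", "C", "G", "T")
  for (i in 1:20) {
    a <- sample(nts, 200, replace = TRUE)
    b <- a; flip <- sample(200, 15)
    b[flip] <- vapply(b[flip], function(x) sample(setdiff(nts, x), 1), "")
    k <- k2pDistance(paste(a, collapse = ""), paste(b, collapse = ""))
    expect_gte(k$d, k$P + k$Q)   # correction never shrinks the p-distance
  }
  expect_error(
    k2pDistance(strrep("A", 10), strrep("G", 10)), "saturation")
  # ambiguity skipped pairwise
  expect_equal(k2pDistance("ANAA", "AAAN")$n_sites, 2)
})

test_that("JC and K2P agree to first order for small divergence", {
  expect_lt(abs(jukesCantor(1e-4) - 1e-4), 1e-6)
  k <- k2pDistance(strrep("C", 10000), paste0(strrep("C", 9999), "T"))
  expect_lt(abs(k$d - 1e-4), 1e-6)
})

test_that("radicality scores are symmetric, canonical and ordered", {
  for (m in c("PAM100", "BLOSUM90")) {
    mat <- substitutionMatrix(m)
    aa <- setdiff(rownames(mat), c("B", "Z", "X", "*"))
    expect_true(all(mat[aa, aa] == t(mat[aa, aa])))
    prs <- t(utils::combn(aa, 2))
    expect_equal(radicalityScore(prs[, 1], prs[, 2], m),
                 radicalityScore(prs[, 2], prs[, 1], m))
    # conservative exchange scores above a radical one
    expect_gt(radicalityScore("I", "L", m), radicalityScore("W", "G", m))
  }
  expect_identical(radicalityScore("W", "G", "BLOSUM90"), -4L)
  expect_error(radicalityScore("W", "*"), "stop")
  expect_error(radicalityScore("W", "7"), "unknown")
})
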