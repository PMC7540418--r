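# Independent oracles and toy fixtures, built in code at test time.

GC <- Biostrings::GENETIC_CODE

# brute-force pathway enumeration: recursive walk over every ordering of the
# differing positions, independent of the package implementation
bruteForcePathway <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(pos)) return(c(Nd = 0, Sd = 0))
  paths <- list()
  recurse <- function(cur, remaining, nd, sd, blocked) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(nd = nd, sd = sd,
                                        blocked = as.numeric(blocked))
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      syn <- GC[[cur]] == GC[[nxt]]
      recurse(nxt, setdiff(remaining, p), nd + !syn, sd + syn,
              blocked || (GC[[nxt]] == "*" && nxt != b))
    }
  }
  recurse(a, pos, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  use <- m[, "blocked"] == 0
  if (!any(use)) use <- rep(TRUE, nrow(m))
  c(Nd = mean(m[use, "nd"]), Sd = mean(m[use, "sd"]))
}

# independent site-count oracle: explicit enumeration of the 9 neighbours
bruteForceSites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  n <- s <- 0
  for (pos in 1:3) {
    cls <- character(0)
    for (nt in setdiff(nts, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      cls <- c(cls, if (GC[[mut]] == "*") "stop"
               else if (GC[[mut]] == GC[[codon]]) "syn" else "non")
    }
    cnt <- sum(cls != "stop")
    if (cnt > 0) {
      s <- s + sum(cls == "syn") / cnt
      n <- n + sum(cls == "non") / cnt
    }
  }
  c(n = n, s = s)
}

# toy genotype table: explicit genotype strings, default metadata panel
toyTable <- function(geno, contig = "c1", pos = NULL, ref = NULL, alt = NULL,
                     samples = NULL) {
  geno <- as.matrix(geno)
  if (is.null(samples))
    samples <- data.frame(
      sample_id = colnames(geno),
      genomotype = sub("_.*", "", colnames(geno)),
      ploidy = lengths(strsplit(geno[1, ], "/")),
      category = ifelse(grepl("^LL", colnames(geno)), "outgroup",
                 ifelse(grepl("^[A-Z]{2}_", colnames(geno)) &
                        substr(colnames(geno), 1, 1) ==
                        substr(colnames(geno), 2, 2), "sexual", "F1")),
      clone_id = NA_character_, stringsAsFactors = FALSE)
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(n) - 1L
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  genotypeTable(data.frame(contig = rep(contig, n), pos = pos, ref = ref,
                           alt = alt, stringsAsFactors = FALSE),
                geno, samples)
}

# small simulation shared across tests (cached per session)
.tiny_env <- new.env()
tinySim <- function() {
  if (is.null(.tiny_env$sim))
    .tiny_env$sim <- simulateComplex(simConfig(n_orfs = 40, seed = 11))
  .tiny_env$sim
}
tinyCls <- function() {
  if (is.null(.tiny_env$cls)) {
    sim <- tinySim()
    .tiny_env$cls <- classifySites(genotypes(sim), referenceSeqs(sim),
                                   orfTable(sim))
  }
  .tiny_env$cls
}
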