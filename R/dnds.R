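# Nei-Gojobori (1986) evolutionary-pathway dN/dS with Jukes-Cantor correction,
# plus Kimura two-parameter distances for mtDNA. Mutations creating stop
# codons are excluded from site counts, and pathways passing through a stop
# codon are excluded from the pathway average (classic NG86 practice); when
# every pathway between two codons is blocked, the average falls back to all
# pathways.

#' NG86 synonymous/nonsynonymous site counts for one codon
#'
#' Each codon position contributes (synonymous one-step changes)/(counted
#' one-step changes) synonymous sites, where changes creating stop codons are
#' excluded from both numerator and denominator. Positions whose every change
#' creates a stop contribute nothing, so n + s <= 3.
#'
#' @param codon a sense codon string.
#' @return named numeric vector \code{c(n = , s = )}.
#' @examples
#' ng86SiteCounts("TTT")  # s = 1/3
#' ng86SiteCounts("ATG")  # s = 0: no synonymous single change for Met
#' @export
ng86SiteCounts <- function(codon) {
  codon <- toupper(codon)
  tab <- .ng86Table()
  if (!codon %in% rownames(tab))
    stop("ng86SiteCounts requires a sense codon, got: ", codon)
  c(n = tab[codon, "n"], s = tab[codon, "s"])
}

.ng86Table <- function() {
  if (!is.null(.cd_env$ng86)) return(.cd_env$ng86)
  sense <- senseCodons()
  nts <- c("A", "C", "G", "T")
  tab <- t(vapply(sense, function(cod) {
    aa0 <- translateCodon(cod)
    n <- s <- 0
    for (pos in 1:3) {
      alts <- setdiff(nts, substr(cod, pos, pos))
      mut <- .mutateCodon(rep(cod, 3L), pos, alts)
      aam <- unname(.geneticCode()[mut])
      keep <- aam != "*"
      cnt <- sum(keep)
      if (cnt > 0) {
        syn <- sum(aam[keep] == aa0)
        s <- s + syn / cnt
        n <- n + (cnt - syn) / cnt
      }
    }
    c(n = n, s = s)
  }, c(n = 0, s = 0)))
  .cd_env$ng86 <- tab
  tab
}

#' NG86 pathway-averaged substitution counts between two codons
#'
#' Averages synonymous and nonsynonymous step counts over all orderings of
#' the differing positions. Pathways through stop codons are excluded; if all
#' pathways are blocked the average is taken over all of them. Nd + Sd always
#' equals the number of differing positions.
#'
#' @param codon_a,codon_b sense codon strings.
#' @return named numeric vector \code{c(Nd = , Sd = )}.
#' @examples
#' ng86PathwayCounts("TTT", "TTA")  # one nonsynonymous step (Phe -> Leu)
#' @export
ng86PathwayCounts <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (.isStopCodon(codon_a) || .isStopCodon(codon_b))
    stop("ng86PathwayCounts requires sense codons")
  key <- paste0(codon_a, codon_b)
  if (is.null(.cd_env$pw)) .cd_env$pw <- new.env(parent = emptyenv())
  hit <- .cd_env$pw[[key]]
  if (!is.null(hit)) return(hit)
  res <- .pathwayCounts(codon_a, codon_b)
  .cd_env$pw[[key]] <- res
  res
}

.pathwayCounts <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(Nd = 0, Sd = 0))
  orders <- switch(k,
    list(pos),
    list(pos, rev(pos)),
    {
      p <- pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    })
  gc <- .geneticCode()
  res <- lapply(orders, function(ord) {
    cur <- a
    nd <- sd <- 0
    blocked <- FALSE
    for (p in ord) {
      nxt <- .mutateCodon(cur, p, substr(b, p, p))
      if (gc[[nxt]] == "*" && nxt != b) blocked <- TRUE
      if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nd = nd, sd = sd, blocked = as.numeric(blocked))
  })
  m <- do.call(rbind, res)
  use <- m[, "blocked"] == 0
  if (!any(use)) use <- rep(TRUE, nrow(m))  # fallback: all pathways blocked
  c(Nd = mean(m[use, "nd"]), Sd = mean(m[use, "sd"]))
}

#' Jukes-Cantor distance correction
#'
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}: converts a proportion of
#' differing sites into an estimated number of substitutions per site.
#'
#' @param p proportion of differences, in \code{[0, 3/4)}.
#' @return corrected distance(s), \code{d >= p}.
#' @examples
#' jukesCantor(0.1)
#' @export
jukesCantor <- function(p) {
  if (any(p < 0) || any(p >= 0.75))
    stop("Jukes-Cantor saturation: p must lie in [0, 3/4)")
  -0.75 * log(1 - 4 * p / 3)
}

.codonsOf <- function(seq) {
  seq <- toupper(as.character(seq))
  if (length(seq) > 1L) {
    if (any(nchar(seq) != 3L)) stop("codon vector entries must have length 3")
    return(seq)                      # already split into codons
  }
  if (nchar(seq) %% 3 != 0) stop("sequence length must be a multiple of 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Pairwise NG86 + Jukes-Cantor dN/dS between two coding sequences
#'
#' N and S are averaged over the two sequences (NG86 convention); codons that
#' are masked, ambiguous or stop in either sequence are skipped in both. A
#' small constant (default 0.01) is added to both dN and dS before taking the
#' ratio, so identical sequences give a ratio of exactly 1.
#'
#' @param seq_a,seq_b equal-length in-frame coding sequences (character or
#'   \code{DNAString}).
#' @param c pseudo-constant added to dN and dS.
#' @param skip_codons 1-based codon indices to skip (e.g. masked codons).
#' @return one-row data.frame: \code{codons_used, Nd, Sd, N, S, pN, pS, dN,
#'   dS, constant, ratio, valid}. \code{valid} is FALSE when no usable codons
#'   remain or a Jukes-Cantor correction saturates.
#' @examples
#' pairwiseDnDs("ATGTTT", "ATGTTA")$ratio
#' @export
pairwiseDnDs <- function(seq_a, seq_b, c = 0.01, skip_codons = integer(0)) {
  ca <- .codonsOf(seq_a); cb <- .codonsOf(seq_b)
  if (length(ca) != length(cb)) stop("sequences must have equal codon length")
  sense <- senseCodons()
  usable <- ca %in% sense & cb %in% sense
  if (length(skip_codons)) usable[skip_codons] <- FALSE
  out <- data.frame(codons_used = sum(usable), Nd = NA_real_, Sd = NA_real_,
                    N = NA_real_, S = NA_real_, pN = NA_real_, pS = NA_real_,
                    dN = NA_real_, dS = NA_real_, constant = c,
                    ratio = NA_real_, valid = FALSE)
  if (!any(usable)) return(out)
  tab <- .ng86Table()
  ua <- ca[usable]; ub <- cb[usable]
  # per-codon averaging: bitwise invariant to which sequence holds which
  # variant at a codon
  N <- sum((tab[ua, "n"] + tab[ub, "n"]) / 2)
  S <- sum((tab[ua, "s"] + tab[ub, "s"]) / 2)
  Nd <- Sd <- 0
  dif <- which(ua != ub)
  for (i in dif) {
    st <- ng86PathwayCounts(ua[i], ub[i])
    Nd <- Nd + st[["Nd"]]; Sd <- Sd + st[["Sd"]]
  }
  pN <- if (N > 0) Nd / N else 0
  pS <- if (S > 0) Sd / S else 0
  out$Nd <- Nd; out$Sd <- Sd; out$N <- N; out$S <- S
  out$pN <- pN; out$pS <- pS
  if (pN >= 0.75 || pS >= 0.75) return(out)  # saturated; flagged invalid
  out$dN <- jukesCantor(pN); out$dS <- jukesCantor(pS)
  out$ratio <- (out$dN + c) / (out$dS + c)
  out$valid <- TRUE
  out
}

#' Kimura two-parameter distance
#'
#' Separates transition (P) and transversion (Q) proportions:
#' \eqn{d = -\frac12\ln(1-2P-Q) - \frac14\ln(1-2Q)}. Positions where either
#' sequence is not A/C/G/T are skipped pairwise.
#'
#' @param seq_a,seq_b aligned equal-length sequences.
#' @return list with \code{P}, \code{Q}, \code{d} and \code{n_sites} compared.
#' @examples
#' k2pDistance(strrep("A", 100), paste0(strrep("A", 99), "G"))$d
#' @export
k2pDistance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(as.character(seq_a)), "")[[1]]
  b <- strsplit(toupper(as.character(seq_b)), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned to equal length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop("no comparable sites")
  dif <- a != b
  purine <- c("A", "G")
  ts <- dif & ((a %in% purine) == (b %in% purine))  # A<->G, C<->T
  P <- sum(ts) / n
  Q <- sum(dif & !ts) / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    stop("K2P saturation: log argument not positive")
  list(P = P, Q = Q, d = -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q),
       n_sites = n)
}

#' Minimum K2P distance from a hybrid mtDNA haplotype to any sexual haplotype
#'
#' Used as the molecular-clock proxy for clone age: older clones carry mtDNA
#' more divergent from every extant sexual haplotype.
#'
#' @param hybrid_mt hybrid haplotype (character or \code{DNAString}).
#' @param sexual_mts named list/\code{DNAStringSet} of sexual haplotypes.
#' @return list with \code{distance} and \code{nearest} (name of the closest
#'   sexual haplotype).
#' @export
nearestSexualDistance <- function(hybrid_mt, sexual_mts) {
  ds <- vapply(seq_along(sexual_mts), function(i)
    k2pDistance(hybrid_mt, sexual_mts[[i]])$d, 0)
  nm <- names(sexual_mts)
  if (is.null(nm)) nm <- as.character(seq_along(sexual_mts))
  i <- which.min(ds)
  list(distance = ds[i], nearest = nm[i])
}
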