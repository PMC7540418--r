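# Forward-time generator of a sexual-asexual hybrid complex with full planted
# truth. Three ingroup sexual species diverge by per-branch fixed
# substitutions and carry segregating polymorphism whose nonsynonymous
# derived-allele frequencies are shifted towards rarity; hybrid clones freeze
# one haplotype per genomotype letter, accumulate heterozygous private
# mutations at rate mu per site per generation, and lose heterozygosity at
# diagnostic sites at rate lambda_loh. Every emitted non-reference allele is
# recorded in the truth ledger.

.normSeed <- function(seed) as.integer(abs(as.numeric(seed)) %% 900000000)

.NTS <- c("A", "C", "G", "T")

#' Simulate the reference ORF set
#'
#' Builds one contig per ORF: a noncoding flank, an ATG start, random sense
#' codons, a stop codon, and a second flank. ORF coordinates are recorded
#' 0-based half-open on the forward strand (stop codon included in the span;
#' \code{n_codons} counts sense codons only).
#'
#' @param config a [SimConfig-class].
#' @param seed integer; defaults to the config seed.
#' @return list with \code{reference} (\code{DNAStringSet}), \code{orfs}
#'   (coordinate data.frame), \code{coding} (per-coding-site map: orf_id,
#'   contig, pos, codon_index, codon_pos, ref_nt, codon) and \code{alt_class}
#'   (site x A/C/G/T matrix classifying each possible change as "syn", "non"
#'   or "stop"; NA at the reference nucleotide).
#' @export
simulateReference <- function(config, seed = config@seed) {
  set.seed(.normSeed(seed))
  L <- config@orf_len_codons
  n <- config@n_orfs
  fl <- config@flank_len
  sense <- senseCodons()
  stops <- c("TAA", "TAG", "TGA")
  orf_ids <- sprintf("orf%04d", seq_len(n))
  contigs <- sprintf("contig%04d", seq_len(n))
  codons <- matrix(sample(sense, n * L, replace = TRUE), nrow = n)
  codons[, 1] <- "ATG"
  stop_cod <- sample(stops, n, replace = TRUE)
  flank5 <- vapply(seq_len(n), function(i)
    paste(sample(.NTS, fl, replace = TRUE), collapse = ""), "")
  flank3 <- vapply(seq_len(n), function(i)
    paste(sample(.NTS, fl, replace = TRUE), collapse = ""), "")
  coding_str <- apply(codons, 1, paste, collapse = "")
  seqs <- paste0(flank5, coding_str, stop_cod, flank3)
  reference <- Biostrings::DNAStringSet(stats::setNames(seqs, contigs))
  orfs <- data.frame(orf_id = orf_ids, contig = contigs, start = fl,
                     end = fl + 3L * (L + 1L), n_codons = L,
                     stringsAsFactors = FALSE)
  # per-coding-site map (stop codon excluded: no variants are planted there)
  codon_v <- as.vector(t(codons))                     # orf-major, codon order
  site_codon <- rep(codon_v, each = 3L)
  coding <- data.frame(
    orf_id = rep(orf_ids, each = 3L * L),
    contig = rep(contigs, each = 3L * L),
    codon_index = rep(rep(seq_len(L) - 1L, each = 3L), times = n),
    codon_pos = rep(0:2, times = n * L),
    codon = site_codon,
    stringsAsFactors = FALSE)
  coding$pos <- fl + 3L * coding$codon_index + coding$codon_pos
  coding$ref_nt <- substr(coding$codon, coding$codon_pos + 1L,
                          coding$codon_pos + 1L)
  # classify every possible point change once
  gc <- .geneticCode()
  aa0 <- gc[coding$codon]
  alt_class <- matrix(NA_character_, nrow = nrow(coding), ncol = 4L,
                      dimnames = list(NULL, .NTS))
  for (nt in .NTS) {
    mut <- coding$codon
    substr(mut, coding$codon_pos + 1L, coding$codon_pos + 1L) <- nt
    aam <- gc[mut]
    cls <- ifelse(aam == "*", "stop", ifelse(aam == aa0, "syn", "non"))
    cls[coding$ref_nt == nt] <- NA_character_
    alt_class[, nt] <- cls
  }
  list(reference = reference, orfs = orfs, coding = coding,
       alt_class = alt_class)
}

# draw one variant with the desired functional class; retries codon
# collisions (masking fodder) config@codon_retry times before accepting
.placeVariant <- function(desired, used, used_codon, ref, config) {
  n_sites <- nrow(ref$coding)
  final_codon <- config@orf_len_codons - 1L
  tries_codon <- 0L
  repeat {
    g <- sample.int(n_sites, 1L)
    if (used[g]) next
    if (desired == "stop" && ref$coding$codon_index[g] >= final_codon) next
    cand <- which(ref$alt_class[g, ] == desired)
    if (!length(cand)) next
    cg <- (g - 1L) %/% 3L + 1L
    if (used_codon[cg] && tries_codon < config@codon_retry) {
      tries_codon <- tries_codon + 1L
      next
    }
    alt <- .NTS[cand[sample.int(length(cand), 1L)]]
    return(list(g = g, alt = alt))
  }
}

.drawClasses <- function(n, f_nonsyn, p_stop = 0) {
  if (n == 0L) return(character(0))
  cls <- ifelse(stats::runif(n) < f_nonsyn, "non", "syn")
  if (p_stop > 0) {
    ns <- cls == "non"
    cls[ns][stats::runif(sum(ns)) < p_stop] <- "stop"
  }
  cls
}

#' Simulate the sexual species pools
#'
#' Places fixed interspecific substitutions on independent per-species
#' branches (rate \code{d_fix/2} per ingroup branch, \code{d_fix} for the
#' outgroup, so an ingroup species pair differs at \code{~d_fix} per coding
#' site) and segregating polymorphism within each ingroup species at density
#' \code{theta}. Nonsynonymous derived-allele counts are drawn from the
#' \code{i^(-1-a)} spectrum (synonymous use the neutral \code{1/i}). Species
#' mtDNA haplotypes diverge from a common ancestor at \code{mt_div} per
#' branch. Each variant occupies its own site; codon collisions between
#' different sites are retried \code{codon_retry} times, then accepted.
#'
#' @param ref result of [simulateReference()].
#' @param config a [SimConfig-class].
#' @param seed integer; defaults to config seed + 1.
#' @return list with \code{pools} (per-species chromosome pools), \code{sites}
#'   (planted truth rows), \code{mt} (species mtDNA haplotypes), \code{used}
#'   and \code{used_codon} occupancy masks.
#' @export
simulateSexualSpecies <- function(ref, config, seed = config@seed + 1L) {
  set.seed(.normSeed(seed))
  n_sites <- nrow(ref$coding)
  used <- logical(n_sites)
  used_codon <- logical(n_sites %/% 3L)
  all_sp <- c(config@species_labels, config@outgroup_label)
  pools <- list()
  site_rows <- list()
  for (sp in all_sp) {
    is_out <- sp == config@outgroup_label
    n_chrom <- 2L * config@n_ind_sexual[[sp]]
    rate <- if (is_out) config@d_fix else config@d_fix / 2
    n_fix <- stats::rbinom(1L, n_sites, rate)
    cls_fix <- .drawClasses(n_fix, config@f_inter_nonsyn)
    n_seg <- if (is_out) 0L else stats::rbinom(1L, n_sites, config@theta)
    cls_seg <- .drawClasses(n_seg, config@f_intra_nonsyn)
    n_var <- n_fix + n_seg
    gs <- integer(n_var); alts <- character(n_var)
    carrier <- matrix(FALSE, n_var, n_chrom)
    freq <- integer(n_var)
    for (i in seq_len(n_fix)) {
      v <- .placeVariant(cls_fix[i], used, used_codon, ref, config)
      used[v$g] <- TRUE; used_codon[(v$g - 1L) %/% 3L + 1L] <- TRUE
      gs[i] <- v$g; alts[i] <- v$alt
      carrier[i, ] <- TRUE; freq[i] <- n_chrom
    }
    if (n_seg > 0L) {
      i_class <- seq_len(n_chrom - 1L)
      w_non <- i_class^(-1 - config@sel_shift)
      w_syn <- i_class^(-1)
      for (i in seq_len(n_seg)) {
        v <- .placeVariant(cls_seg[i], used, used_codon, ref, config)
        used[v$g] <- TRUE; used_codon[(v$g - 1L) %/% 3L + 1L] <- TRUE
        j <- n_fix + i
        gs[j] <- v$g; alts[j] <- v$alt
        k <- sample(i_class, 1L,
                    prob = if (cls_seg[i] == "syn") w_syn else w_non)
        carrier[j, sample.int(n_chrom, k)] <- TRUE
        freq[j] <- k
      }
    }
    pools[[sp]] <- list(n_chrom = n_chrom, g = gs, alt = alts,
                        carrier = carrier)
    cls_all <- c(cls_fix, cls_seg)
    site_rows[[sp]] <- data.frame(
      g = gs, alt = alts,
      class = c(rep(if (is_out) "outgroup_divergence" else
                    "interspecific_fixed", n_fix),
                rep("intraspecific", n_seg)),
      focal = rep(sp, n_var), syn_planted = cls_all, freq_count = freq,
      n_chrom = rep(n_chrom, n_var), stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL
  # species mtDNA: star phylogeny around a common ancestor
  anc <- sample(.NTS, config@mt_len, replace = TRUE)
  mt <- lapply(all_sp, function(sp) {
    h <- anc
    n_sub <- stats::rbinom(1L, config@mt_len, config@mt_div)
    if (n_sub > 0L) {
      at <- sample.int(config@mt_len, n_sub)
      h[at] <- vapply(h[at], function(x)
        sample(setdiff(.NTS, x), 1L), "")
    }
    paste(h, collapse = "")
  })
  names(mt) <- all_sp
  list(pools = pools, sites = sites, mt = mt, used = used,
       used_codon = used_codon)
}

.mutateSeq <- function(seq, n_sub) {
  h <- strsplit(seq, "")[[1]]
  if (n_sub > 0L) {
    at <- sample.int(length(h), min(n_sub, length(h)))
    h[at] <- vapply(h[at], function(x) sample(setdiff(.NTS, x), 1L), "")
  }
  paste(h, collapse = "")
}

#' Simulate one clonal lineage
#'
#' The founder freezes one random haplotype per genomotype letter. Private
#' mutations arrive as Poisson(mu x coding_nt x tau) per member, split into a
#' lineage trunk shared by all members (fraction \code{trunk_fraction}) and
#' member-specific tips; each lands heterozygous on one haplotype, with
#' synonymity drawn per \code{f_priv_nonsyn} and \code{p_stop} (stop-gains
#' only in non-final codons). Each diagnostic heterozygous site (fixed
#' difference between the carried parental genomes) and each carried private
#' site independently resolves with probability \code{1 - exp(-lambda_loh x
#' tau)}; the retained allele is chosen uniformly, so a private mutation is
#' either fixed (homozygous) or erased by its LOH event. The clone's mtDNA
#' diverges from the maternal species (first genomotype letter) by
#' Poisson(mt_mu x mt_len x tau) substitutions shared by all members.
#'
#' @param ref result of [simulateReference()].
#' @param sexual result of [simulateSexualSpecies()].
#' @param clone_spec a [CloneSpec-class].
#' @param config a [SimConfig-class].
#' @param used,used_codon site-occupancy masks (default: those in
#'   \code{sexual}); pass updated masks when simulating several clones.
#' @param seed integer.
#' @return list with \code{spec}, \code{founder} (letter + chromosome per
#'   haplotype), \code{members} (per-member private/LOH event tables),
#'   \code{private} (all mutation definitions), \code{mt} haplotype, and the
#'   updated \code{used}/\code{used_codon} masks.
#' @export
simulateClone <- function(ref, sexual, clone_spec, config,
                          used = sexual$used, used_codon = sexual$used_codon,
                          seed = config@seed + 2L) {
  set.seed(.normSeed(seed))
  letters_ <- strsplit(clone_spec@genomotype, "")[[1]]
  missing_pool <- setdiff(letters_, names(sexual$pools))
  if (length(missing_pool))
    stop("no species pool for genomotype letter(s): ",
         paste(missing_pool, collapse = ", "))
  ploidy <- length(letters_)
  tau <- clone_spec@age_tau
  n_coding <- nrow(ref$coding)
  founder <- data.frame(
    hap = seq_len(ploidy), letter = letters_,
    chrom = vapply(letters_, function(l)
      sample.int(sexual$pools[[l]]$n_chrom, 1L), 0L),
    stringsAsFactors = FALSE)
  p_loh <- 1 - exp(-config@lambda_loh * tau)
  # diagnostic sites: fixed interspecific differences between carried genomes
  lset <- unique(letters_)
  diag_idx <- sexual$sites$class == "interspecific_fixed" &
    sexual$sites$focal %in% lset
  diag_g <- sexual$sites$g[diag_idx]
  diag_alt <- sexual$sites$alt[diag_idx]
  diag_ref <- ref$coding$ref_nt[diag_g]
  # private mutations: shared trunk + member-specific tips
  mean_total <- config@mu * n_coding * tau
  n_trunk <- stats::rpois(1L, config@trunk_fraction * mean_total)
  draw_priv <- function(n, scope) {
    if (n == 0L) return(NULL)
    cls <- .drawClasses(n, config@f_priv_nonsyn, config@p_stop)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      v <- .placeVariant(cls[i], used, used_codon, ref, config)
      used[v$g] <<- TRUE; used_codon[(v$g - 1L) %/% 3L + 1L] <<- TRUE
      out[[i]] <- data.frame(g = v$g, alt = v$alt, syn_class = cls[i],
                             hap = sample.int(ploidy, 1L), scope = scope,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  trunk <- draw_priv(n_trunk, "trunk")
  members <- vector("list", clone_spec@n_individuals)
  private_all <- list(trunk)
  for (m in seq_len(clone_spec@n_individuals)) {
    sample_id <- paste0(clone_spec@clone_id, "_", m)
    n_tip <- stats::rpois(1L, (1 - config@trunk_fraction) * mean_total)
    tip <- draw_priv(n_tip, sample_id)
    private_all[[m + 1L]] <- tip
    mine <- rbind(trunk, tip)
    # LOH on carried private sites: retained allele uniform between the
    # derived and the ancestral copy -> homozygous derived or erased
    if (!is.null(mine) && nrow(mine)) {
      hit <- stats::runif(nrow(mine)) < p_loh
      keep_derived <- stats::runif(nrow(mine)) < 0.5
      mine$state <- ifelse(!hit, "het", ifelse(keep_derived, "hom", "erased"))
    }
    # LOH on diagnostic heterozygous sites
    hit_d <- which(stats::runif(length(diag_g)) < p_loh)
    retained <- ifelse(stats::runif(length(hit_d)) < 0.5,
                       diag_alt[hit_d], diag_ref[hit_d])
    loh_diag <- data.frame(g = diag_g[hit_d], retained = retained,
                           stringsAsFactors = FALSE)
    members[[m]] <- list(sample_id = sample_id, private = mine,
                         loh_diag = loh_diag)
  }
  mt_mother <- sexual$mt[[founder$letter[1L]]]
  mt <- .mutateSeq(mt_mother, stats::rpois(1L, config@mt_mu * config@mt_len * tau))
  list(spec = clone_spec, founder = founder, members = members,
       private = do.call(rbind, private_all), mt = mt,
       diag_g = diag_g, used = used, used_codon = used_codon)
}

#' Simulate the full hybrid complex
#'
#' Chains [simulateReference()], [simulateSexualSpecies()] and
#' [simulateClone()] for every configured lineage, assembles the ploidy-aware
#' genotype table over all sexual individuals, the outgroup and all clone
#' members, and records the complete planted truth. Fully reproducible from
#' the config seed.
#'
#' @param config a [SimConfig-class].
#' @return a [HybridComplexSim-class].
#' @examples
#' sim <- simulateComplex(simConfig(n_orfs = 10, seed = 7))
#' sim
#' @export
simulateComplex <- function(config) {
  base <- .normSeed(config@seed)
  ref <- simulateReference(config, seed = base)
  sexual <- simulateSexualSpecies(ref, config, seed = base + 1L)
  used <- sexual$used; used_codon <- sexual$used_codon
  clones <- list()
  for (i in seq_along(config@clones)) {
    cl <- simulateClone(ref, sexual, config@clones[[i]], config,
                        used = used, used_codon = used_codon,
                        seed = base + 1L + i)
    used <- cl$used; used_codon <- cl$used_codon
    clones[[i]] <- cl
  }
  .assembleComplex(config, ref, sexual, clones)
}

# build sample metadata, the emitted-site set, the genotype matrix, the mt
# haplotype set and the truth ledger
.assembleComplex <- function(config, ref, sexual, clones) {
  all_sp <- c(config@species_labels, config@outgroup_label)
  samp_rows <- list()
  for (sp in all_sp) {
    n_ind <- config@n_ind_sexual[[sp]]
    samp_rows[[sp]] <- data.frame(
      sample_id = paste0(sp, sp, "_", seq_len(n_ind)),
      genomotype = paste0(sp, sp), ploidy = 2L,
      category = if (sp == config@outgroup_label) "outgroup" else "sexual",
      clone_id = NA_character_, stringsAsFactors = FALSE)
  }
  for (cl in clones) {
    samp_rows[[cl$spec@clone_id]] <- data.frame(
      sample_id = vapply(cl$members, `[[`, "", "sample_id"),
      genomotype = cl$spec@genomotype,
      ploidy = nchar(cl$spec@genomotype),
      category = cl$spec@category, clone_id = cl$spec@clone_id,
      stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, samp_rows)
  rownames(samples) <- NULL

  # truth site table: sexual/outgroup variants + private mutations
  priv_rows <- list()
  for (cl in clones) {
    if (is.null(cl$private) || !nrow(cl$private)) next
    priv_rows[[cl$spec@clone_id]] <- data.frame(
      g = cl$private$g, alt = cl$private$alt, class = "private_asexual",
      focal = cl$spec@clone_id, syn_planted = cl$private$syn_class,
      freq_count = NA_integer_, n_chrom = NA_integer_,
      stringsAsFactors = FALSE)
  }
  sites_truth <- rbind(sexual$sites, do.call(rbind, priv_rows))
  rownames(sites_truth) <- NULL
  if (anyDuplicated(sites_truth$g))
    stop("internal error: two planted variants share a site")
  sites_truth$contig <- ref$coding$contig[sites_truth$g]
  sites_truth$pos <- ref$coding$pos[sites_truth$g]
  sites_truth$ref <- ref$coding$ref_nt[sites_truth$g]

  ord <- order(sites_truth$contig, sites_truth$pos)
  sites_truth <- sites_truth[ord, ]
  g2row <- stats::setNames(seq_len(nrow(sites_truth)), sites_truth$g)
  n_site <- nrow(sites_truth)

  # genotype matrix
  geno <- matrix(NA_character_, n_site, nrow(samples),
                 dimnames = list(NULL, samples$sample_id))
  ref_al <- sites_truth$ref
  hom_ref2 <- paste(ref_al, ref_al, sep = "/")
  hom_ref3 <- paste(ref_al, ref_al, ref_al, sep = "/")
  for (j in seq_len(nrow(samples))) {
    geno[, j] <- if (samples$ploidy[j] == 2L) hom_ref2 else hom_ref3
  }
  gt_string <- function(alleles) paste(sort(alleles), collapse = "/")
  # sexual individuals
  for (sp in all_sp) {
    pool <- sexual$pools[[sp]]
    n_ind <- config@n_ind_sexual[[sp]]
    if (!length(pool$g)) next
    rows <- g2row[as.character(pool$g)]
    for (jj in seq_len(n_ind)) {
      sid <- paste0(sp, sp, "_", jj)
      cnt <- pool$carrier[, 2L * jj - 1L] + pool$carrier[, 2L * jj]
      het <- which(cnt == 1L)
      hom <- which(cnt == 2L)
      if (length(het))
        geno[rows[het], sid] <- mapply(function(r, a) gt_string(c(ref_al[r], a)),
                                       rows[het], pool$alt[het])
      if (length(hom))
        geno[rows[hom], sid] <- paste(pool$alt[hom], pool$alt[hom], sep = "/")
    }
  }
  # clone members
  loh_rows <- list(); priv_state_rows <- list()
  for (cl in clones) {
    ploidy <- nrow(cl$founder)
    # base allele per haplotype at every site (ref unless the founder
    # chromosome carries a variant)
    base_al <- matrix(rep(ref_al, ploidy), nrow = ploidy, byrow = TRUE)
    for (h in seq_len(ploidy)) {
      pool <- sexual$pools[[cl$founder$letter[h]]]
      if (!length(pool$g)) next
      has <- pool$carrier[, cl$founder$chrom[h]]
      if (any(has))
        base_al[h, g2row[as.character(pool$g[has])]] <- pool$alt[has]
    }
    for (m in cl$members) {
      al <- base_al
      if (nrow(m$loh_diag)) {
        idx <- g2row[as.character(m$loh_diag$g)]
        al[, idx] <- rep(m$loh_diag$retained, each = ploidy)
        loh_rows[[length(loh_rows) + 1L]] <- data.frame(
          sample_id = m$sample_id, g = m$loh_diag$g, kind = "diagnostic",
          retained = m$loh_diag$retained, stringsAsFactors = FALSE)
      }
      if (!is.null(m$private) && nrow(m$private)) {
        pv <- m$private
        idx <- g2row[as.character(pv$g)]
        for (i in seq_len(nrow(pv))) {
          if (pv$state[i] == "het") al[pv$hap[i], idx[i]] <- pv$alt[i]
          else if (pv$state[i] == "hom") al[, idx[i]] <- pv$alt[i]
        }
        loh_priv <- pv$state != "het"
        if (any(loh_priv))
          loh_rows[[length(loh_rows) + 1L]] <- data.frame(
            sample_id = m$sample_id, g = pv$g[loh_priv], kind = "private",
            retained = ifelse(pv$state[loh_priv] == "hom",
                              pv$alt[loh_priv], ref_al[idx[loh_priv]]),
            stringsAsFactors = FALSE)
        priv_state_rows[[length(priv_state_rows) + 1L]] <- data.frame(
          clone_id = cl$spec@clone_id, sample_id = m$sample_id,
          g = pv$g, alt = pv$alt, scope = pv$scope,
          syn_class = pv$syn_class, state = pv$state,
          stringsAsFactors = FALSE)
      }
      geno[, m$sample_id] <- apply(al, 2, gt_string)
    }
  }
  # emitted = at least one sample carries a non-reference allele
  emitted <- if (n_site == 0L) logical(0) else {
    ref_gt2 <- matrix(hom_ref2, n_site, nrow(samples))
    ref_gt3 <- matrix(hom_ref3, n_site, nrow(samples))
    pl <- matrix(rep(samples$ploidy, each = n_site), n_site)
    nonref <- (pl == 2L & geno != ref_gt2) | (pl == 3L & geno != ref_gt3)
    rowSums(nonref, na.rm = TRUE) > 0L
  }
  sites_truth$emitted <- emitted

  sites <- data.frame(contig = sites_truth$contig, pos = sites_truth$pos,
                      ref = sites_truth$ref, alt = sites_truth$alt,
                      stringsAsFactors = FALSE)
  gt <- genotypeTable(sites[emitted, , drop = FALSE],
                      geno[emitted, , drop = FALSE], samples)

  loh <- if (length(loh_rows)) do.call(rbind, loh_rows) else
    data.frame(sample_id = character(0), g = integer(0), kind = character(0),
               retained = character(0))
  priv <- if (length(priv_state_rows)) do.call(rbind, priv_state_rows) else
    data.frame(clone_id = character(0), sample_id = character(0),
               g = integer(0), alt = character(0), scope = character(0),
               syn_class = character(0), state = character(0))
  if (nrow(loh)) {
    loh$contig <- ref$coding$contig[loh$g]
    loh$pos <- ref$coding$pos[loh$g]
  }
  if (nrow(priv)) {
    priv$contig <- ref$coding$contig[priv$g]
    priv$pos <- ref$coding$pos[priv$g]
  }
  mt_seqs <- character(nrow(samples))
  names(mt_seqs) <- samples$sample_id
  for (sp in all_sp)
    mt_seqs[samples$genomotype == paste0(sp, sp)] <- sexual$mt[[sp]]
  for (cl in clones)
    mt_seqs[vapply(cl$members, `[[`, "", "sample_id")] <- cl$mt
  founders <- do.call(rbind, lapply(clones, function(cl)
    cbind(clone_id = cl$spec@clone_id, cl$founder)))
  truth <- list(
    sites = sites_truth,
    private = priv,
    loh = loh,
    founders = founders,
    clone_ages = stats::setNames(
      vapply(clones, function(cl) cl$spec@age_tau, 0),
      vapply(clones, function(cl) cl$spec@clone_id, "")),
    rates = list(coding_nt = nrow(ref$coding), mu = config@mu,
                 lambda_loh = config@lambda_loh,
                 n_diagnostic = stats::setNames(
                   vapply(clones, function(cl) length(cl$diag_g), 0L),
                   vapply(clones, function(cl) cl$spec@clone_id, ""))))
  new("HybridComplexSim", config = config, reference = ref$reference,
      orfs = ref$orfs, genotypes = gt,
      mt = Biostrings::DNAStringSet(mt_seqs), truth = truth)
}
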