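# Gene-dropping simulator: founder genotypes under Hardy-Weinberg
# equilibrium are propagated through a pedigree with Poisson recombination
# (intensity 1 crossover per 100 cM along the genetic map, no interference).
# Haplotype labels are tracked so that the true IBD1/IBD2 intervals between
# the two target individuals are exact.
#
# A haplotype mosaic on one chromosome is a pair of parallel vectors
# (ends, labs): founder-haplotype label labs[i] covers the genetic interval
# (ends[i-1], ends[i]] in cM, with ends[length] = chromosome map length.

#' Simulate founder genotypes under HWE
#'
#' Draws each locus independently for each founder: alternate-allele dosage
#' ~ Binomial(2, alt_freq). Founders are mutually unrelated and in linkage
#' equilibrium.
#'
#' @param manifest A `panel_manifest`.
#' @param n Number of founders.
#' @param seed Integer seed (deterministic output).
#' @return Integer matrix n x loci, rows named `F1..Fn`.
#' @export
simulate_founders <- function(manifest, n, seed = NULL) {
  stopifnot(n >= 1)
  L <- nrow(manifest)
  with_seed(seed, {
    codes <- matrix(stats::rbinom(n * L, 2L, rep(manifest$alt_freq, each = n)),
                    nrow = n, dimnames = list(paste0("F", seq_len(n)), manifest$id))
    storage.mode(codes) <- "integer"
    codes
  })
}

# -- mosaic primitives --------------------------------------------------------

# Piece of mosaic `h` over the genetic interval (lo, hi].
slice_mosaic <- function(h, lo, hi) {
  starts <- c(0, h$ends[-length(h$ends)])
  sel <- h$ends > lo & starts < hi
  list(ends = pmin(h$ends[sel], hi), labs = h$labs[sel])
}

# One meiosis: recombine the two parental mosaics with Poisson crossovers.
meiosis_gamete <- function(hap1, hap2, len_cm) {
  nx <- stats::rpois(1L, len_cm / 100)
  first <- if (stats::runif(1) < 0.5) 1L else 2L
  if (nx == 0L) return(if (first == 1L) hap1 else hap2)
  cuts <- sort(stats::runif(nx, 0, len_cm))
  bounds <- c(cuts, len_cm)
  src <- rep_len(c(first, 3L - first), nx + 1L)
  ends <- numeric(0); labs <- integer(0); lo <- 0
  for (i in seq_along(bounds)) {
    piece <- slice_mosaic(if (src[i] == 1L) hap1 else hap2, lo, bounds[i])
    ends <- c(ends, piece$ends)
    labs <- c(labs, piece$labs)
    lo <- bounds[i]
  }
  n <- length(labs)
  if (n > 1L) {
    keep <- c(labs[-n] != labs[-1L], TRUE)  # merge adjacent equal labels
    ends <- ends[keep]; labs <- labs[keep]
  }
  list(ends = ends, labs = labs)
}

# Label of mosaic `h` at genetic positions `x` (vectorised).
mosaic_label_at <- function(h, x) {
  idx <- pmin(findInterval(x, h$ends, left.open = TRUE) + 1L, length(h$labs))
  h$labs[idx]
}

# True IBD state intervals (cM) between two individuals' mosaics on one
# chromosome. Returns data frame lo, hi, state (1 = IBD1, 2 = IBD2).
mosaic_ibd_states <- function(ma, mb) {
  cuts <- sort(unique(c(ma$h1$ends, ma$h2$ends, mb$h1$ends, mb$h2$ends)))
  los <- c(0, cuts[-length(cuts)])
  mids <- (los + cuts) / 2
  la1 <- mosaic_label_at(ma$h1, mids); la2 <- mosaic_label_at(ma$h2, mids)
  lb1 <- mosaic_label_at(mb$h1, mids); lb2 <- mosaic_label_at(mb$h2, mids)
  ibd2 <- (la1 == lb1 & la2 == lb2) | (la1 == lb2 & la2 == lb1)
  any_shared <- la1 == lb1 | la1 == lb2 | la2 == lb1 | la2 == lb2
  state <- ifelse(ibd2, 2L, ifelse(any_shared, 1L, 0L))
  # merge adjacent intervals with identical state
  if (length(state) > 1L) {
    brk <- c(TRUE, state[-1L] != state[-length(state)])
    grp <- cumsum(brk)
    data.frame(lo = tapply(los, grp, min), hi = tapply(cuts, grp, max),
               state = state[brk])
  } else {
    data.frame(lo = los, hi = cuts, state = state)
  }
}

# -- gene dropping ------------------------------------------------------------

#' Gene-drop a pedigree and emit one sample pair with true IBD
#'
#' Simulates inheritance through the pedigree of `spec`: founder haplotypes
#' receive unique labels, every meiosis places crossovers as a Poisson
#' process with intensity 1 per 100 cM along `map` (no crossover
#' interference), and the two target individuals' genotypes are read off at
#' the manifest loci. Haplotype labels give the exact true IBD1/IBD2
#' intervals between the targets.
#'
#' @param spec A `relationship_spec`.
#' @param founders Founder genotype matrix from [simulate_founders()] with at
#'   least `length(spec$founders)` rows (rows are assigned to pedigree
#'   founders in order). Heterozygous founder genotypes are phased uniformly
#'   at random, which is exact under linkage equilibrium. May be `NULL` when
#'   `return_genotypes = FALSE`.
#' @param map A `genetic_map` covering every manifest chromosome.
#' @param manifest A `panel_manifest`.
#' @param seed Integer seed.
#' @param return_genotypes If `FALSE`, skip genotype read-off and return the
#'   true IBD record only (much faster; used for segment-sharing theory
#'   checks at scale).
#' @return List with `genotypes` (2 x loci integer matrix, rows named after
#'   the targets, or `NULL`), and `ibd`: data frame
#'   `chrom, start_bp, end_bp, state` of true IBD intervals (state 1 or 2),
#'   empty for unrelated targets.
#' @export
gene_drop_pair <- function(spec, founders, map, manifest, seed = NULL,
                           return_genotypes = TRUE) {
  stopifnot(inherits(spec, "relationship_spec"))
  chroms <- sort(unique(manifest$chrom))
  for (ci in chroms) map_require_chrom(map, ci)
  ped <- spec$ped
  n_f <- length(spec$founders)
  if (return_genotypes) {
    if (is.null(founders) || nrow(founders) < n_f)
      stop_input("pedigree %s needs %d founders but %d supplied",
                 spec$name, n_f, if (is.null(founders)) 0L else nrow(founders))
    if (anyNA(founders[seq_len(n_f), ]))
      stop_input("founder genotypes must not contain missing codes")
  }
  founder_row <- stats::setNames(seq_len(n_f), spec$founders)
  fa_idx <- match(ped$father, ped$id)
  mo_idx <- match(ped$mother, ped$id)
  t_idx <- match(spec$targets, ped$id)

  with_seed(seed, {
    # phase founders into haplotype allele matrix (2 * n_f) x loci
    hap_alleles <- NULL
    if (return_genotypes) {
      G <- founders[seq_len(n_f), , drop = FALSE]
      L <- ncol(G)
      h1 <- matrix(0L, n_f, L); h2 <- matrix(0L, n_f, L)
      h1[G == 2L] <- 1L; h2[G == 2L] <- 1L
      het <- which(G == 1L)
      coin <- stats::rbinom(length(het), 1L, 0.5)
      h1[het] <- coin
      h2[het] <- 1L - coin
      hap_alleles <- matrix(0L, 2L * n_f, L)
      hap_alleles[seq(1L, 2L * n_f, by = 2L), ] <- h1
      hap_alleles[seq(2L, 2L * n_f, by = 2L), ] <- h2
    }
    geno <- if (return_genotypes)
      matrix(NA_integer_, 2L, nrow(manifest),
             dimnames = list(spec$targets, manifest$id))
    else NULL
    ibd_rows <- vector("list", length(chroms))

    for (k in seq_along(chroms)) {
      ci <- chroms[k]
      len_cm <- map_length_cm(map, ci)
      mosaics <- vector("list", nrow(ped))
      for (i in seq_len(nrow(ped))) {
        if (is.na(fa_idx[i])) {
          f <- founder_row[[ped$id[i]]]
          mosaics[[i]] <- list(
            h1 = list(ends = len_cm, labs = 2L * f - 1L),
            h2 = list(ends = len_cm, labs = 2L * f))
        } else {
          fa <- mosaics[[fa_idx[i]]]
          mo <- mosaics[[mo_idx[i]]]
          mosaics[[i]] <- list(
            h1 = meiosis_gamete(fa$h1, fa$h2, len_cm),
            h2 = meiosis_gamete(mo$h1, mo$h2, len_cm))
        }
      }
      ma <- mosaics[[t_idx[1]]]; mb <- mosaics[[t_idx[2]]]
      states <- mosaic_ibd_states(ma, mb)
      states <- states[states$state > 0L, , drop = FALSE]
      if (nrow(states)) {
        ibd_rows[[k]] <- data.frame(
          chrom = ci,
          start_bp = round(map_pos_at(map, ci, states$lo)),
          end_bp = round(map_pos_at(map, ci, states$hi)),
          state = states$state)
      }
      if (return_genotypes) {
        loc <- manifest_chrom_index(manifest, ci)
        cm <- map_cm_at(map, ci, manifest$pos[loc])
        col <- loc
        a1 <- hap_alleles[cbind(mosaic_label_at(ma$h1, cm), col)]
        a2 <- hap_alleles[cbind(mosaic_label_at(ma$h2, cm), col)]
        b1 <- hap_alleles[cbind(mosaic_label_at(mb$h1, cm), col)]
        b2 <- hap_alleles[cbind(mosaic_label_at(mb$h2, cm), col)]
        geno[1L, loc] <- a1 + a2
        geno[2L, loc] <- b1 + b2
      }
    }
    ibd <- do.call(rbind, ibd_rows[!vapply(ibd_rows, is.null, logical(1))])
    if (is.null(ibd))
      ibd <- data.frame(chrom = integer(), start_bp = numeric(),
                        end_bp = numeric(), state = integer())
    rownames(ibd) <- NULL
    list(genotypes = geno, ibd = ibd)
  })
}

# Genome-wide true kinship of a pair from its IBD record:
# phi = (1/4) * frac(IBD1) + (1/2) * frac(IBD2), fractions over `total_mbp`.
true_kinship_from_ibd <- function(ibd, total_mbp) {
  if (!nrow(ibd)) return(0)
  len <- (ibd$end_bp - ibd$start_bp) / 1e6
  (sum(len[ibd$state == 1L]) / 4 + sum(len[ibd$state == 2L]) / 2) / total_mbp
}
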