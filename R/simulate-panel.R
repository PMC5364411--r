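#' Simulate a haplotype reference panel with block LD structure
#'
#' Generates a binary haplotype panel whose variants are partitioned into LD
#' blocks.  Within a block each haplotype is built by a copying process: the
#' allele at a variant copies the allele at the previous variant with
#' probability `exp(-d / decayCm)` (d = map distance in cM), otherwise it is
#' drawn fresh from the variant's base frequency.  This gives monotone LD
#' decay with map distance inside blocks; blocks are generated independently
#' so across-block LD is zero by construction.
#'
#' @param nHaplotypes number of haplotypes (>= 50).
#' @param nVariants number of variants (>= 100).
#' @param blockSizeMean mean LD-block size in variants (Poisson-distributed,
#'   minimum 2).
#' @param seed integer random seed; identical seeds yield identical panels.
#' @param decayCm map-distance scale (cM) of the allele-copying probability;
#'   the default 0.02 cM gives adjacent-pair r2 around 0.8 at the default
#'   1 kb spacing.
#' @param spacingBp mean physical spacing between adjacent variants (bp);
#'   map positions follow at 1 cM/Mb.
#' @return a [HaplotypePanel-class].
#' @examples
#' panel <- simulateReferencePanel(100, 200, blockSizeMean = 20, seed = 1)
#' panel
#' @export
simulateReferencePanel <- function(nHaplotypes, nVariants, blockSizeMean = 50,
                                   seed = 1, decayCm = 0.02,
                                   spacingBp = 1000) {
  if (nHaplotypes < 50) stop("nHaplotypes must be >= 50")
  if (nVariants < 100) stop("nVariants must be >= 100")
  if (blockSizeMean < 2) stop("blockSizeMean must be >= 2")
  set.seed(seed)

  # block partition: Poisson sizes, floored at 2, trimmed to nVariants
  sizes <- integer(0)
  while (sum(sizes) < nVariants)
    sizes <- c(sizes, pmax(2L, rpois(ceiling(nVariants / blockSizeMean) + 8L,
                                     blockSizeMean)))
  cs <- cumsum(sizes)
  sizes <- sizes[seq_len(which(cs >= nVariants)[1])]
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - nVariants)
  if (sizes[length(sizes)] < 1L) sizes <- sizes[-length(sizes)]
  sizes[length(sizes)] <- nVariants - sum(head(sizes, -1))
  ends <- cumsum(sizes)
  starts <- c(0L, head(ends, -1))
  bounds <- cbind(start = as.integer(starts), end = as.integer(ends))

  pos <- cumsum(pmax(1L, rpois(nVariants, spacingBp)))
  cm <- pos * 1e-6
  pbase <- runif(nVariants, 0.05, 0.95)

  H <- matrix(0L, nHaplotypes, nVariants)
  for (b in seq_len(nrow(bounds))) {
    idx <- (bounds[b, 1] + 1L):bounds[b, 2]
    H[, idx[1]] <- rbinom(nHaplotypes, 1L, pbase[idx[1]])
    if (length(idx) > 1L) for (k in 2:length(idx)) {
      j <- idx[k]
      pc <- exp(-(cm[j] - cm[idx[k - 1]]) / decayCm)
      copy <- runif(nHaplotypes) < pc
      fresh <- rbinom(nHaplotypes, 1L, pbase[j])
      H[, j] <- ifelse(copy, H[, idx[k - 1]], fresh)
    }
  }
  # keep every column polymorphic within the validity band
  f <- colMeans(H)
  for (j in which(f < 0.005 | f > 0.995)) {
    nFlip <- max(1L, ceiling(0.005 * nHaplotypes))
    if (f[j] < 0.005) H[sample(which(H[, j] == 0L), nFlip), j] <- 1L
    else H[sample(which(H[, j] == 1L), nFlip), j] <- 0L
  }
  f <- colMeans(H)

  vt <- VariantTable(chrom = rep(1L, nVariants), pos = pos, cm = cm,
                     id = sprintf("snp%06d", seq_len(nVariants)),
                     maf = pmin(f, 1 - f))
  new("HaplotypePanel", variants = vt, haplotypes = H, blockBounds = bounds)
}

#' Empirical r-squared between two panel variants
#'
#' @param panel a [HaplotypePanel-class].
#' @param i,j column indices or variant ids.
#' @return squared Pearson correlation between the two haplotype columns.
#' @export
panelR2 <- function(panel, i, j) {
  if (is.character(i)) i <- match(i, panel@variants@id)
  if (is.character(j)) j <- match(j, panel@variants@id)
  cor(panel@haplotypes[, i], panel@haplotypes[, j])^2
}
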