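#' @importFrom data.table fread fwrite data.table as.data.table
NULL

.hashLine <- function(params, seed) {
  h <- sum(utf8ToInt(paste(deparse(params), collapse = ""))) %% 1e9
  sprintf("# seed=%s params_hash=%09.0f", as.character(seed), h)
}

#' Write summary statistics (tab-delimited SNP CHR BP A1 A2 Z P N)
#'
#' Missing values are written as "NA".  An optional "#"-prefixed header
#' line embeds the seed and a parameter hash; readers skip such lines.
#'
#' @param stats a [SummaryStats-class].
#' @param path output path.
#' @param seed optional seed to embed in the comment header.
#' @export
writeSummaryStats <- function(stats, path, seed = NULL) {
  vt <- stats@variants
  df <- data.frame(SNP = vt@id, CHR = vt@chrom, BP = vt@pos, A1 = vt@a1,
                   A2 = vt@a2, Z = stats@z, P = stats@p, N = stats@n)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(.hashLine(list(n = nrow(df)), seed), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(df, as.character), sep = "\t")), con)
  invisible(path)
}

#' Read summary statistics
#'
#' Accepts the dialect SNP CHR BP A1 A2 plus either a Z column or an OR
#' column with P; when only OR is present it is log-converted to beta and
#' z is reconstituted from the p-value with the sign of the beta.
#' Malformed rows are counted and skipped; strand-ambiguous (A/T, G/C)
#' variants are flagged in the `"ambiguous"` attribute.
#'
#' @param path input path.
#' @return a [SummaryStats-class] with attributes `"skipped"` (row count)
#'   and `"ambiguous"` (logical vector).
#' @export
readSummaryStats <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, na.strings = "NA",
              data.table = FALSE)
  need <- c("SNP", "CHR", "BP", "A1", "A2", "P")
  if (!all(need %in% names(dt)) ||
      !any(c("Z", "OR") %in% names(dt)))
    stop("no recognizable effect column; found: ",
         paste(names(dt), collapse = ", "))
  for (cc in c("CHR", "BP", "P", "N")) if (cc %in% names(dt))
    dt[[cc]] <- suppressWarnings(as.numeric(dt[[cc]]))
  beta <- NULL
  if ("Z" %in% names(dt)) {
    dt$Z <- suppressWarnings(as.numeric(dt$Z))
    z <- dt$Z
    if ("OR" %in% names(dt))
      beta <- log(suppressWarnings(as.numeric(dt$OR)))
  } else {
    orv <- suppressWarnings(as.numeric(dt$OR))
    beta <- log(orv)
    z <- sign(beta) * qnorm(pmin(dt$P, 1) / 2, lower.tail = FALSE)
  }
  if (!"N" %in% names(dt)) dt$N <- NA_real_
  ok <- is.finite(dt$CHR) & is.finite(dt$BP) & is.finite(z) &
        is.finite(dt$P) & !is.na(dt$SNP)
  skipped <- sum(!ok)
  if (skipped) message(skipped, " malformed row(s) skipped")
  dt <- dt[ok, , drop = FALSE]; z <- z[ok]
  if (!is.null(beta)) beta <- beta[ok]
  ord <- order(dt$CHR, dt$BP)
  dt <- dt[ord, , drop = FALSE]; z <- z[ord]
  if (!is.null(beta)) beta <- beta[ord]
  vt <- VariantTable(chrom = dt$CHR, pos = dt$BP, id = dt$SNP,
                     a1 = dt$A1, a2 = dt$A2)
  st <- SummaryStats(vt, z = z, n = ifelse(is.na(dt$N), 1, dt$N),
                     p = 2 * pnorm(-abs(z)), beta = beta)
  amb <- (dt$A1 == "A" & dt$A2 == "T") | (dt$A1 == "T" & dt$A2 == "A") |
         (dt$A1 == "G" & dt$A2 == "C") | (dt$A1 == "C" & dt$A2 == "G")
  attr(st, "skipped") <- skipped
  attr(st, "ambiguous") <- amb
  st
}

#' Write variant metadata in BIM dialect
#'
#' Tab-delimited chrom, id, cm, pos, a1, a2, no header.
#'
#' @param vt a [VariantTable-class].
#' @param path output path.
#' @export
writeBim <- function(vt, path) {
  df <- data.frame(vt@chrom, vt@id, vt@cm, vt@pos, vt@a1, vt@a2)
  fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read variant metadata in BIM dialect
#'
#' @param path input path.
#' @return a [VariantTable-class].
#' @export
readBim <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  names(dt) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  VariantTable(chrom = dt$chrom, pos = dt$pos, cm = dt$cm, id = dt$id,
               a1 = dt$a1, a2 = dt$a2)
}

#' Write genotype dosages in RAW dialect
#'
#' Text dosage table with header
#' `FID IID PAT MAT SEX PHENOTYPE <id>_<allele> ...`; phenotype is coded
#' 1 (control) / 2 (case).
#'
#' @param cohort a [LiabilityCohort-class].
#' @param path output path.
#' @export
writeRaw <- function(cohort, path) {
  vt <- variants(cohort)
  G <- genotypes(cohort)
  n <- nrow(G)
  df <- data.frame(FID = sprintf("F%05d", seq_len(n)),
                   IID = sprintf("I%05d", seq_len(n)),
                   PAT = 0L, MAT = 0L, SEX = 0L,
                   PHENOTYPE = phenotype(cohort) + 1L)
  gdf <- as.data.frame(G)
  names(gdf) <- paste0(vt@id, "_", vt@a1)
  fwrite(cbind(df, gdf), path, sep = " ")
  invisible(path)
}

#' Read genotype dosages in RAW dialect
#'
#' @param path input path.
#' @return a list with `genotypes` (matrix, columns named by variant id),
#'   `phenotype` (0/1), and `allele` (the counted allele per variant).
#' @export
readRaw <- function(path) {
  dt <- fread(path, sep = " ", header = TRUE, data.table = FALSE)
  meta <- dt[, 1:6]
  G <- as.matrix(dt[, -(1:6), drop = FALSE])
  ids <- sub("_[^_]*$", "", colnames(G))
  allele <- sub("^.*_", "", colnames(G))
  colnames(G) <- ids
  list(genotypes = G, phenotype = as.integer(meta$PHENOTYPE - 1L),
       allele = allele)
}

#' Write LD scores (tab-delimited CHR SNP BP L2)
#'
#' @param scores an [LDScoreTable-class].
#' @param path output path.
#' @export
writeLdScores <- function(scores, path) {
  vt <- scores@variants
  df <- data.frame(CHR = vt@chrom, SNP = vt@id, BP = vt@pos,
                   L2 = scores@ell)
  fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read LD scores
#'
#' @param path input path.
#' @return an [LDScoreTable-class].
#' @export
readLdScores <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  vt <- VariantTable(chrom = dt$CHR, pos = dt$BP, id = dt$SNP)
  new("LDScoreTable", variants = vt, ell = dt$L2,
      nHaplotypes = NA_integer_)
}

#' Serialize an LDSC or bivariate fit to a JSON record
#'
#' @param fit an [LdscFit-class] or [BivariateFit-class].
#' @param path optional path; when NULL the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
fitToJson <- function(fit, path = NULL) {
  rec <- if (is(fit, "LdscFit")) {
    list(slope = fit@slope, intercept = fit@intercept, h2_obs = fit@h2Obs,
         h2_liab = fit@h2Liab, se_h2 = fit@seH2, mean_chi2 = fit@meanChi2,
         n_blocks = fit@nBlocks, constrained = fit@constrained)
  } else {
    list(rho_g = fit@rhoG, r_g = fit@rg, se_rg = fit@seRg, p_rg = fit@pRg,
         cross_intercept = fit@crossIntercept,
         h2_obs_1 = fit@fit1@h2Obs, h2_obs_2 = fit@fit2@h2Obs)
  }
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
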