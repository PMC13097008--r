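# Post-calling SNP quality control: depth masking at load, mean-depth / MAF /
# missingness filters, sliding-window LD pruning, and modal imputation.
# Upstream hard filtering (caller annotations) is assumed already applied;
# the loader can optionally re-check FILTER == PASS.

new_qc_report <- function(n_input, parameters) {
  structure(list(n_input = n_input,
                 steps = data.frame(filter = character(0),
                                    removed = integer(0),
                                    n_after = integer(0)),
                 parameters = parameters),
            class = "qc_report")
}

add_qc_step <- function(report, name, removed, n_after) {
  report$steps <- rbind(report$steps,
                        data.frame(filter = name, removed = removed,
                                   n_after = n_after))
  stopifnot(all(diff(c(report$n_input, report$steps$n_after)) <= 0))
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", x$n_input, "variants in\n")
  if (nrow(x$steps)) {
    for (i in seq_len(nrow(x$steps)))
      cat(sprintf("  %-22s -%d  -> %d\n", x$steps$filter[i],
                  x$steps$removed[i], x$steps$n_after[i]))
  }
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

gt_to_dosage <- function(gt) {
  # diploid GT string -> alt-allele count; any missing allele -> NA
  out <- rep(NA_integer_, length(gt))
  gt <- sub(":.*", "", gt)
  known <- !is.na(gt) & !grepl("\\.", gt)
  alleles <- strsplit(gsub("\\|", "/", gt[known]), "/", fixed = FALSE)
  out[known] <- vapply(alleles, function(a) sum(a == "1"), 0L)
  out
}

#' Load a genotype matrix from a VCF file
#'
#' Reads GT (and DP when present) from a VCF, keeps biallelic SNP records
#' only, and masks individual genotypes sequenced at depth below
#' `min_gt_depth`. When the file carries no DP the depth mask is skipped with
#' a message.
#'
#' @param vcf_path path to a VCF 4.x file.
#' @param min_gt_depth genotypes with depth strictly below this are set
#'   missing (default 5; a genotype at exactly the threshold is retained).
#' @param check_filter_pass if `TRUE`, drop records whose FILTER column is
#'   neither `PASS` nor `.`.
#' @return A [genotype_matrix()]; the attribute `"load_report"` records the
#'   record counts (input, multi-allelic/non-SNP dropped, genotypes masked).
#' @export
load_genotypes <- function(vcf_path, min_gt_depth = 5, check_filter_pass = FALSE) {
  if (!file.exists(vcf_path)) abort_ctx("VCF not found: ", vcf_path)
  vcf <- tryCatch(vcfR::read.vcfR(vcf_path, verbose = FALSE),
                  error = function(e) abort_ctx("malformed VCF '", vcf_path,
                                                "': ", conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  n_input <- nrow(fix)
  keep <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 & !is.na(fix$ALT)
  n_multi <- sum(!keep)
  if (check_filter_pass)
    keep <- keep & (fix$FILTER %in% c("PASS", "."))
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  dos <- apply(gt, 2, gt_to_dosage)
  dos <- matrix(dos, nrow = sum(keep),
                dimnames = list(NULL, colnames(gt)))

  has_dp <- any(grepl("(^|:)DP(:|$)", vcf@gt[, "FORMAT"]))
  n_masked <- 0L
  depth <- NULL
  if (has_dp) {
    dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)[keep, , drop = FALSE]
    mask <- !is.na(dp) & dp < min_gt_depth
    n_masked <- sum(mask & !is.na(dos))
    dos[mask] <- NA
    depth <- t(dp)
  } else {
    message("load_genotypes: no DP field; depth mask skipped")
  }

  fixk <- fix[keep, , drop = FALSE]
  ids <- ifelse(is.na(fixk$ID) | fixk$ID == ".",
                paste0(fixk$CHROM, ":", fixk$POS), fixk$ID)
  mean_depth <- if (has_dp) rowMeans(dp, na.rm = TRUE) else rep(NA_real_, sum(keep))
  variants <- data.frame(id = ids, chrom = fixk$CHROM,
                         pos = as.integer(fixk$POS), ref = fixk$REF,
                         alt = fixk$ALT, mean_depth = mean_depth)
  samples <- data.frame(id = colnames(gt), lon = NA_real_, lat = NA_real_,
                        site = NA_character_)
  gm <- genotype_matrix(t(dos), variants, samples, depth = depth)
  attr(gm, "load_report") <- list(n_records = n_input,
                                  n_non_biallelic_snp = n_multi,
                                  n_genotypes_depth_masked = n_masked,
                                  min_gt_depth = if (has_dp) min_gt_depth else NA)
  gm
}

#' Filter variants on mean depth, minor allele frequency and missingness
#'
#' Drops SNPs with mean depth below `min_mean_depth`, minor allele frequency
#' (computed on non-missing dosages) below `min_maf`, or a missing fraction
#' of at least `max_missing` (the boundary itself is removed). The order of
#' surviving SNPs is preserved and the operation is idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @param max_missing missing-fraction threshold; SNPs with missingness
#'   `>= max_missing` are removed (default 0.10).
#' @param min_mean_depth minimum mean depth across samples (default 5);
#'   skipped when the matrix carries no depth information.
#' @return A list with elements `gm` (filtered matrix) and `report`
#'   (`qc_report`).
#' @export
filter_variants <- function(gm, min_maf = 0.01, max_missing = 0.10,
                            min_mean_depth = 5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n0 <- ncol(gm$dosages)
  if (n0 == 0) abort_ctx("empty genotype matrix")
  report <- new_qc_report(n0, list(min_maf = min_maf, max_missing = max_missing,
                                   min_mean_depth = min_mean_depth))
  keep <- rep(TRUE, n0)

  md <- gm$variants$mean_depth
  if (all(is.na(md))) {
    message("filter_variants: no depth information; mean-depth filter skipped")
  } else {
    keep <- keep & (md >= min_mean_depth)
  }
  report <- add_qc_step(report, "mean_depth", n0 - sum(keep), sum(keep))

  p <- colMeans(gm$dosages, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  n_before <- sum(keep)
  keep <- keep & (maf >= min_maf)
  report <- add_qc_step(report, "maf", n_before - sum(keep), sum(keep))

  missf <- colMeans(is.na(gm$dosages))
  n_before <- sum(keep)
  keep <- keep & (missf < max_missing)
  report <- add_qc_step(report, "missingness", n_before - sum(keep), sum(keep))

  if (!any(keep)) warning("filter_variants: all SNPs removed")
  out <- subset_variants(gm, which(keep))
  list(gm = out, report = report)
}

subset_variants <- function(gm, idx) {
  genotype_matrix(gm$dosages[, idx, drop = FALSE],
                  gm$variants[idx, , drop = FALSE],
                  gm$samples,
                  depth = if (!is.null(gm$depth)) gm$depth[, idx, drop = FALSE])
}

#' Prune variants for linkage disequilibrium in sliding windows
#'
#' Windows of `window` variants advance by `step` within each chromosome.
#' Within a window, while any pair of retained variants has squared Pearson
#' correlation of dosages above `r2_max` (computed on pairwise-complete
#' observations), the later variant (by position) of the worst offending pair
#' is removed. Greedy and deterministic; the surviving set contains no
#' within-window pair with r-squared above the threshold.
#'
#' @param gm a [genotype_matrix()].
#' @param window window size in variants (default 50).
#' @param step window shift in variants (default 10).
#' @param r2_max squared-correlation threshold (default 0.1).
#' @return A list with elements `gm` and `report`.
#' @export
ld_prune <- function(gm, window = 50, step = 10, r2_max = 0.1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (window < 2) abort_ctx("ld_prune: window must be at least 2 variants")
  n0 <- ncol(gm$dosages)
  removed <- rep(FALSE, n0)
  # sweep windows over the surviving variants, repeating until a full pass
  # removes nothing, so no within-window pair of the *output* exceeds the
  # threshold
  repeat {
    removed_this_pass <- FALSE
    for (ch in unique(gm$variants$chrom)) {
      cols <- which(gm$variants$chrom == ch & !removed)
      n_ch <- length(cols)
      if (n_ch < 2) next
      starts <- unique(seq(1, max(n_ch - window + 1, 1), by = step))
      for (s in starts) {
        widx <- cols[s:min(s + window - 1, n_ch)]
        active <- widx[!removed[widx]]
        if (length(active) < 2) next
        r2 <- suppressWarnings(
          cor(gm$dosages[, active, drop = FALSE],
              use = "pairwise.complete.obs"))^2
        r2[is.na(r2)] <- 0
        r2[lower.tri(r2, diag = TRUE)] <- -Inf
        repeat {
          worst <- which.max(r2)
          if (r2[worst] <= r2_max) break
          ij <- arrayInd(worst, dim(r2))
          # drop the later variant (columns are in position order)
          drop_local <- max(ij)
          removed[active[drop_local]] <- TRUE
          removed_this_pass <- TRUE
          r2[drop_local, ] <- -Inf
          r2[, drop_local] <- -Inf
        }
      }
    }
    if (!removed_this_pass) break
  }
  report <- new_qc_report(n0, list(window = window, step = step, r2_max = r2_max))
  report <- add_qc_step(report, "ld_prune", sum(removed), sum(!removed))
  list(gm = subset_variants(gm, which(!removed)), report = report)
}

#' Impute missing genotypes with the modal dosage
#'
#' Each missing entry is replaced by its SNP's most common non-missing dosage
#' class; ties are broken toward the smaller dosage. Errors if a SNP has no
#' observed genotype at all.
#'
#' @param gm a [genotype_matrix()].
#' @return A [genotype_matrix()] with no missing dosages.
#' @export
impute_major <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  dos <- gm$dosages
  nmiss <- colSums(is.na(dos))
  all_missing <- which(nmiss == nrow(dos))
  if (length(all_missing))
    abort_ctx("cannot impute: all genotypes missing at ",
              paste(head(gm$variants$id[all_missing], 5), collapse = ", "))
  for (j in which(nmiss > 0)) {
    counts <- tabulate(dos[, j] + 1L, nbins = 3L)
    dos[is.na(dos[, j]), j] <- which.max(counts) - 1L  # which.max takes first tie
  }
  gm$dosages <- dos
  gm
}

#' Write a genotype matrix to a VCF 4.2 file
#'
#' Emits one record per SNP with GT and DP FORMAT fields. Missing genotypes
#' are written as `./.`; per-genotype depths come from the matrix's stored
#' depth (when absent, 20 for observed and 0 for missing genotypes).
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path) {
  dos <- gm$dosages
  depth <- gm$depth
  if (is.null(depth)) depth <- ifelse(is.na(dos), 0L, 20L)
  gt <- matrix("./.", nrow(dos), ncol(dos))
  gt[!is.na(dos) & dos == 0] <- "0/0"
  gt[!is.na(dos) & dos == 1] <- "0/1"
  gt[!is.na(dos) & dos == 2] <- "1/1"
  field <- matrix(paste0(gt, ":", depth), nrow(dos), ncol(dos))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=adaptscape",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$id), collapse = "\t"))
  body <- paste(gm$variants$chrom, gm$variants$pos, gm$variants$id,
                gm$variants$ref, gm$variants$alt, ".", "PASS", ".", "GT:DP",
                apply(field, 2, paste, collapse = "\t"), sep = "\t")
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort_ctx("cannot write VCF '", path,
                                                "': ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
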