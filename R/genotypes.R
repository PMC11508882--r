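#' Construct a genotype matrix container
#'
#' Constructor shared by the VCF reader and the simulator. Dosages
#' are ALT-allele expected counts in `[0, 2]` (missing allowed), one row per
#' sample and one column per biallelic variant.
#'
#' @param dosage Numeric matrix, samples x variants.
#' @param variants Tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `rsq`, `call_rate`.
#' @param sample_ids Character vector of unique sample identifiers.
#' @return A `genotype_matrix` object.
#' @export
new_genotype_matrix <- function(dosage, variants, sample_ids) {
  stopifnot(nrow(dosage) == length(sample_ids),
            ncol(dosage) == nrow(variants),
            !anyDuplicated(sample_ids))
  if (length(dosage) > 0 && !all(is.na(dosage))) {
    rng <- range(dosage, na.rm = TRUE)
    if (rng[1] < -1e-9 || rng[2] > 2 + 1e-9) {
      stop("dosages outside [0, 2]", call. = FALSE)
    }
  }
  rownames(dosage) <- sample_ids
  if (nrow(variants) > 0) {
    colnames(dosage) <- paste0(variants$chrom, ":", variants$pos)
  }
  structure(
    list(dosage = dosage, variants = variants, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
}

#' Read cohort genotypes from a VCF
#'
#' Loads a (optionally bgzipped) VCF through \pkg{vcfR} and returns ALT-allele
#' dosages. Per-sample `DS` is preferred; when absent, hard `GT` calls are
#' converted to ALT counts. Imputation quality is taken from the `Rsq` (or
#' `R2`) INFO key; variants without it are treated as passing. Multi-allelic
#' records are excluded (dosage semantics would be ambiguous) and their count
#' reported in a message.
#'
#' @param path Path to a VCF file.
#' @param rsq_min Minimum imputation quality; variants with `Rsq < rsq_min`
#'   are dropped at load. Default 0.6, the conventional post-imputation cut.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, rsq_min = 0.6) {
  stopifnot(file.exists(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(vcf@gt) <= 1L) stop("VCF '", path, "' contains no samples",
                               call. = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)

  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT)
  if (any(multi)) {
    message("read_genotypes: excluded ", sum(multi),
            " multi-allelic or ALT-less records")
  }

  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("DS" %in% fmt_keys) {
    dos <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt_keys) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dos <- apply(gt, 2, gt_to_dosage)
    dim(dos) <- dim(gt)
  } else {
    stop("VCF '", path, "' has neither DS nor GT per-sample fields",
         call. = FALSE)
  }

  rsq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "Rsq")))
  if (all(is.na(rsq))) {
    rsq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "R2")))
  }
  rsq[is.na(rsq)] <- 1.0

  keep <- !multi & rsq >= rsq_min
  dropped_rsq <- sum(!multi & rsq < rsq_min)
  if (dropped_rsq > 0) {
    message("read_genotypes: excluded ", dropped_rsq,
            " variants with Rsq < ", rsq_min)
  }

  dos <- t(dos[keep, , drop = FALSE])
  variants <- tibble::tibble(
    chrom = fix$CHROM[keep],
    pos   = as.integer(fix$POS[keep]),
    id    = fix$ID[keep],
    ref   = toupper(fix$REF[keep]),
    alt   = toupper(fix$ALT[keep]),
    rsq   = rsq[keep],
    call_rate = colMeans(!is.na(dos))
  )
  new_genotype_matrix(dos, variants, colnames(vcf@gt)[-1L])
}

gt_to_dosage <- function(gt) {
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0 || any(a == "." | is.na(a))) return(NA_real_)
    sum(a == "1")
  }, numeric(1))
}

#' Filter variants on call rate
#'
#' Removes variants whose per-variant call rate falls below a threshold and
#' reports the number removed.
#'
#' @param geno A `genotype_matrix`.
#' @param call_rate_min Minimum fraction of non-missing dosages, in `[0, 1]`.
#' @return A filtered `genotype_matrix`.
#' @export
variant_qc <- function(geno, call_rate_min = 0.95) {
  stopifnot(inherits(geno, "genotype_matrix"),
            call_rate_min >= 0, call_rate_min <= 1)
  keep <- geno$variants$call_rate >= call_rate_min
  removed <- sum(!keep)
  if (removed > 0) {
    message("variant_qc: removed ", removed, " variants with call rate < ",
            call_rate_min)
  }
  if (!any(keep)) warning("variant_qc: no variants passed the filter")
  subset_variants(geno, which(keep))
}

subset_variants <- function(geno, idx) {
  new_genotype_matrix(
    geno$dosage[, idx, drop = FALSE],
    geno$variants[idx, , drop = FALSE],
    geno$sample_ids
  )
}

#' Subset a genotype matrix to a set of samples
#'
#' @param geno A `genotype_matrix`.
#' @param ids Sample identifiers to retain (order preserved as given).
#' @return A `genotype_matrix` restricted to `ids`.
#' @export
subset_samples <- function(geno, ids) {
  stopifnot(inherits(geno, "genotype_matrix"))
  idx <- match(ids, geno$sample_ids)
  if (anyNA(idx)) {
    stop("unknown sample ids: ", paste(utils::head(ids[is.na(idx)], 3),
                                       collapse = ", "), call. = FALSE)
  }
  new_genotype_matrix(geno$dosage[idx, , drop = FALSE], geno$variants,
                      geno$sample_ids[idx])
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$sample_ids), " samples x ",
      nrow(x$variants), " variants\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)
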