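#' Harmonize a scoring file against cohort genotypes
#'
#' Reconciles each score variant with the genotype record at the same
#' (chromosome, position): a *direct* match when the effect/other alleles
#' equal the genotype REF/ALT pair, a *flip* match when their strand
#' complements do, and a *mismatch* when the alleles are irreconcilable.
#' Strand-ambiguous variants (A/T or C/G pairs, where direct and flip are
#' indistinguishable) are dropped by default. Each match carries an
#' orientation flag telling the scorer whether the effect allele is the ALT
#' allele (use dosage `d`) or the REF allele (use `2 - d`).
#'
#' @param score A `scoring_file`.
#' @param geno A `genotype_matrix`. Positions must be unique.
#' @param ambiguous_policy `"drop"` (default) discards strand-ambiguous
#'   variants; `"keep"` accepts them on an as-is allele comparison.
#' @return A `pgs_match` object: list with `matches` (tibble: `geno_col`,
#'   `identifier`, `weight`, `effect_is_alt`) and `report`, a one-row
#'   `harmonization_report` tibble with the count partition
#'   (`n_matched_direct`, `n_matched_flip`, `n_ambiguous_dropped`,
#'   `n_mismatch_dropped`, `n_absent`) and `coverage`.
#' @examples
#' geno <- new_genotype_matrix(
#'   matrix(c(0, 1, 2), 3, 1),
#'   tibble::tibble(chrom = "1", pos = 100L, id = "rs1", ref = "G",
#'                  alt = "A", rsq = 1, call_rate = 1),
#'   c("s1", "s2", "s3"))
#' sf <- new_scoring_file("PGSX", NA_character_, character(),
#'   tibble::tibble(identifier = "rs1", chrom = "1", pos = 100L,
#'                  effect_allele = "A", other_allele = "G", weight = 0.5))
#' harmonize(sf, geno)$report
#' @export
harmonize <- function(score, geno, ambiguous_policy = c("drop", "keep")) {
  stopifnot(inherits(score, "scoring_file"), inherits(geno, "genotype_matrix"))
  ambiguous_policy <- match.arg(ambiguous_policy)

  gkey <- paste(geno$variants$chrom, geno$variants$pos)
  dup <- gkey[duplicated(gkey)]
  if (length(dup) > 0) {
    stop("duplicate genotype positions: ", dup[[1L]], call. = FALSE)
  }

  v <- score$variants
  n <- nrow(v)
  col <- match(paste(v$chrom, v$pos), gkey)
  status <- character(n)
  effect_is_alt <- rep(NA, n)

  ref <- geno$variants$ref[col]
  alt <- geno$variants$alt[col]

  for (i in seq_len(n)) {
    if (is.na(col[i])) { status[i] <- "absent"; next }
    cls <- classify_alleles(v$effect_allele[i], v$other_allele[i],
                            ref[i], alt[i], ambiguous_policy)
    status[i] <- cls$status
    effect_is_alt[i] <- cls$effect_is_alt
  }

  matched <- status %in% c("direct", "flip")
  matches <- tibble::tibble(
    geno_col = col[matched],
    identifier = v$identifier[matched],
    weight = v$weight[matched],
    effect_is_alt = effect_is_alt[matched]
  )

  report <- tibble::tibble(
    pgs_id = score$pgs_id,
    n_score_variants = n,
    n_matched_direct = sum(status == "direct"),
    n_matched_flip = sum(status == "flip"),
    n_ambiguous_dropped = sum(status == "ambiguous"),
    n_mismatch_dropped = sum(status == "mismatch"),
    n_absent = sum(status == "absent"),
    coverage = if (n > 0) sum(matched) / n else NA_real_
  )
  class(report) <- c("harmonization_report", class(report))

  structure(list(matches = matches, report = report, pgs_id = score$pgs_id),
            class = "pgs_match")
}

#' Complement alleles to the opposite strand
#' @param x Character vector of allele strings over A/C/G/T.
#' @return The strand complement of each allele.
#' @export
flip_strand <- function(x) chartr("ACGT", "TGCA", x)

classify_alleles <- function(ea, oa, ref, alt, ambiguous_policy) {
  out <- function(status, effect_is_alt = NA) {
    list(status = status, effect_is_alt = effect_is_alt)
  }
  if (is.na(oa) || !nzchar(oa)) {
    # single-allele record: ambiguity judged on the genotype pair
    if (alt == flip_strand(ref) && ambiguous_policy == "drop") {
      return(out("ambiguous"))
    }
    if (ea == alt) return(out("direct", TRUE))
    if (ea == ref) return(out("direct", FALSE))
    if (flip_strand(ea) == alt) return(out("flip", TRUE))
    if (flip_strand(ea) == ref) return(out("flip", FALSE))
    return(out("mismatch"))
  }
  if (oa == flip_strand(ea) && ambiguous_policy == "drop") {
    return(out("ambiguous"))
  }
  if (ea == alt && oa == ref) return(out("direct", TRUE))
  if (ea == ref && oa == alt) return(out("direct", FALSE))
  fe <- flip_strand(ea); fo <- flip_strand(oa)
  if (fe == alt && fo == ref) return(out("flip", TRUE))
  if (fe == ref && fo == alt) return(out("flip", FALSE))
  out("mismatch")
}

#' @export
print.pgs_match <- function(x, ...) {
  r <- x$report
  cat("<pgs_match> ", x$pgs_id %||% "?", ": ", nrow(x$matches), "/",
      r$n_score_variants, " variants matched (coverage ",
      sprintf("%.1f%%", 100 * r$coverage), "; ", r$n_matched_flip,
      " strand-flipped, ", r$n_ambiguous_dropped, " ambiguous dropped, ",
      r$n_mismatch_dropped, " mismatched, ", r$n_absent, " absent)\n",
      sep = "")
  invisible(x)
}

#' Write harmonization reports as a TSV
#'
#' One row per score, mirroring the count partition and coverage.
#'
#' @param reports A `harmonization_report` tibble or a list of them
#'   (rows are bound together).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_harmonization_report <- function(reports, path) {
  if (!inherits(reports, "data.frame")) {
    reports <- dplyr::bind_rows(reports)
  }
  readr::write_tsv(reports, path)
  invisible(path)
}
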