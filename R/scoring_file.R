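#' Read a PGS-Catalog-format scoring file
#'
#' Parses the tab-separated scoring-file dialect used by the PGS Catalog:
#' `#key=value` metadata lines, then a header row, then one variant per row.
#' Both identifier dialects are recognized — rsID-keyed (`rsID`) and
#' position-keyed (`chr_name`/`chr_position`) — and unknown columns are
#' ignored. At minimum an effect-allele column and an effect-weight column
#' must be present.
#'
#' @param path Path to a scoring file.
#' @return A `scoring_file` object: a list with `pgs_id`, `trait_label`,
#'   `metadata` (named character vector of the `#` header), and `variants`,
#'   a tibble with columns `identifier`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `weight` in file order.
#' @examples
#' path <- tempfile(fileext = ".txt")
#' writeLines(c(
#'   "#pgs_id=PGSTEST", "#trait_reported=example",
#'   "rsID\tchr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
#'   "rs1\t1\t1000\tA\tG\t0.1", "rs2\t2\t2000\tC\tT\t-0.2"), path)
#' sf <- read_scoring_file(path)
#' sf$variants
#' @export
read_scoring_file <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1L) {
    stop("scoring file '", path, "' has no header row", call. = FALSE)
  }

  meta <- parse_score_metadata(meta_lines)

  header <- strsplit(body[[1L]], "\t", fixed = TRUE)[[1L]]
  ea_col <- match_score_col(header, c("effect_allele", "A1", "ea"))
  wt_col <- match_score_col(header, c("effect_weight", "beta", "weight"))
  if (is.na(ea_col) || is.na(wt_col)) {
    stop("scoring file '", path,
         "' lacks an effect_allele or effect_weight column", call. = FALSE)
  }
  oa_col  <- match_score_col(header, c("other_allele", "A2", "reference_allele"))
  id_col  <- match_score_col(header, c("rsID", "rsid", "variant_id"))
  chr_col <- match_score_col(header, c("chr_name", "chromosome", "chr"))
  pos_col <- match_score_col(header, c("chr_position", "position", "pos"))

  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  get <- function(col) {
    if (is.na(col)) return(rep(NA_character_, length(rows)))
    vapply(rows, function(r) if (length(r) >= col) r[[col]] else NA_character_,
           character(1))
  }

  weight_chr <- get(wt_col)
  weight <- suppressWarnings(as.numeric(weight_chr))
  bad <- which(!is.na(weight_chr) & is.na(weight))
  if (length(bad) > 0L) {
    stop("non-numeric effect weight in scoring file '", path,
         "' at data row ", bad[[1L]], " ('", weight_chr[[bad[[1L]]]], "')",
         call. = FALSE)
  }

  variants <- tibble::tibble(
    identifier   = get(id_col),
    chrom        = get(chr_col),
    pos          = suppressWarnings(as.integer(get(pos_col))),
    effect_allele = toupper(get(ea_col)),
    other_allele  = toupper(get(oa_col)),
    weight       = weight
  )
  if (all(is.na(variants$identifier)) && !is.na(chr_col) && !is.na(pos_col)) {
    variants$identifier <- paste0(variants$chrom, ":", variants$pos)
  }

  declared <- suppressWarnings(as.integer(get_meta(meta, "variants_number")))
  if (length(declared) == 1L && !is.na(declared) &&
      declared != nrow(variants)) {
    stop("scoring file '", path, "' declares variants_number=", declared,
         " but contains ", nrow(variants), " variant rows", call. = FALSE)
  }

  sf <- new_scoring_file(
    pgs_id = get_meta(meta, "pgs_id"),
    trait_label = get_meta(meta, "trait_reported"),
    metadata = meta,
    variants = variants
  )
  validate_scoring_file(sf)
  sf
}

get_meta <- function(meta, key) {
  if (key %in% names(meta)) meta[[key]] else NA_character_
}

parse_score_metadata <- function(meta_lines) {
  kv <- sub("^#+\\s*", "", meta_lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  if (length(kv) == 0L) return(character(0))
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(trimws(vals), trimws(keys))
}

match_score_col <- function(header, candidates) {
  hit <- match(tolower(candidates), tolower(header))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0L) NA_integer_ else hit[[1L]]
}

#' Construct a scoring file object
#'
#' @param pgs_id Accession-like identifier.
#' @param trait_label Free-text trait label (may be `NA`).
#' @param metadata Named character vector of header metadata.
#' @param variants Tibble with columns `identifier`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `weight`.
#' @return A `scoring_file` object.
#' @export
new_scoring_file <- function(pgs_id, trait_label, metadata, variants) {
  structure(
    list(pgs_id = pgs_id, trait_label = trait_label,
         metadata = metadata, variants = variants),
    class = "scoring_file"
  )
}

validate_scoring_file <- function(sf) {
  v <- sf$variants
  ok_allele <- grepl("^[ACGT]+$", v$effect_allele)
  if (!all(ok_allele)) {
    stop("scoring file has ", sum(!ok_allele),
         " variants with an invalid effect allele", call. = FALSE)
  }
  if (any(!is.na(v$pos) & v$pos < 1L)) {
    stop("scoring file has variant positions < 1", call. = FALSE)
  }
  if (any(!is.finite(v$weight))) {
    stop("scoring file has non-finite effect weights", call. = FALSE)
  }
  key <- paste(v$chrom, v$pos, v$effect_allele)
  complete <- !is.na(v$chrom) & !is.na(v$pos)
  if (anyDuplicated(key[complete]) > 0L) {
    stop("scoring file has duplicate (chrom, pos, effect_allele) rows",
         call. = FALSE)
  }
  invisible(sf)
}

#' Write a scoring file in PGS-Catalog format
#'
#' Inverse of [read_scoring_file()]: emits the `#key=value` metadata header
#' (always including `pgs_id` and `variants_number`) followed by the
#' tab-separated variant table.
#'
#' @param sf A `scoring_file` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scoring_file <- function(sf, path) {
  stopifnot(inherits(sf, "scoring_file"))
  v <- sf$variants
  meta <- sf$metadata
  meta[["pgs_id"]] <- sf$pgs_id
  if (!is.na(sf$trait_label)) meta[["trait_reported"]] <- sf$trait_label
  meta[["variants_number"]] <- as.character(nrow(v))
  hdr <- paste0("#", names(meta), "=", unname(meta))
  cols <- c("rsID", "chr_name", "chr_position", "effect_allele",
            "other_allele", "effect_weight")
  fmt <- function(x) ifelse(is.na(x), "", as.character(x))
  body <- paste(fmt(v$identifier), fmt(v$chrom), fmt(v$pos),
                fmt(v$effect_allele), fmt(v$other_allele),
                formatC(v$weight, format = "g", digits = 15),
                sep = "\t")
  writeLines(c(hdr, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' @export
print.scoring_file <- function(x, ...) {
  cat("<scoring_file> ", x$pgs_id %||% "?", ": ", nrow(x$variants),
      " variants", sep = "")
  if (!is.na(x$trait_label)) cat(" (", x$trait_label, ")", sep = "")
  cat("\n")
  print(utils::head(x$variants, 5))
  invisible(x)
}
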