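# small in-code fixtures shared across the suite

# hand-built genotype container: 3 samples x 4 variants, all call rates 1
tiny_geno <- function() {
  variants <- tibble::tibble(
    chrom = c("1", "1", "2", "2"),
    pos = c(100L, 200L, 100L, 300L),
    id = c("rs1", "rs2", "rs3", "rs4"),
    ref = c("G", "C", "T", "A"),
    alt = c("A", "T", "C", "G"),
    rsq = c(1, 0.9, 0.8, 1),
    call_rate = 1
  )
  dosage <- matrix(c(0, 1, 2,
                     2, 1, 0,
                     1, 1, 1,
                     0, 0, 2), nrow = 3)
  new_genotype_matrix(dosage, variants, c("s1", "s2", "s3"))
}

# scoring file over a subset of tiny_geno variants
tiny_score <- function(weights = c(0.5, -0.25),
                       ea = c("A", "T"), oa = c("G", "C"),
                       chrom = c("1", "1"), pos = c(100L, 200L)) {
  new_scoring_file(
    "PGSTINY", "test trait", character(),
    tibble::tibble(identifier = paste0("v", seq_along(weights)),
                   chrom = chrom, pos = pos,
                   effect_allele = ea, other_allele = oa, weight = weights))
}

# small simulation configuration keeping test runtimes low
small_sim_config <- function(seed = 11, ...) {
  args <- list(
    areas = c("North", "South"),
    n_per_area = c(North = 150, South = 150),
    fst = c(North = 0.01, South = 0.02),
    n_variants = 160,
    n_confounded = 40,
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

write_score_lines <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}
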