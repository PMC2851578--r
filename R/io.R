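## Plain-text exports: phased VCF, dosage / pedigree / scenario /
## phenotype TSV files, and a key = value configuration format.

#' Export phased genotypes as VCF
#'
#' Diploid phased GT records; contigs chr1..chrK; POS is the 1-based
#' integer surrogate round(position * 1e6) + 1 of the genetic position.
#'
#' @param pop a \code{haplotype_set}.
#' @param map genetic map.
#' @param file output path.
#' @param loci locus ids to export (default: polymorphic loci).
#' @return invisibly, the file path.
#' @export
export_vcf <- function(pop, map, file, loci = NULL) {
  if (is.null(loci)) {
    freq <- allele_frequencies(pop)
    loci <- which(freq > 0 & freq < 1)
  }
  n <- n_individuals(pop)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=mebvsim",
               sprintf("##contig=<ID=chr%d>", unique(map$chromosome)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", paste0("ind", seq_len(n))),
                   collapse = "\t"), con)
  a <- pop$alleles[, loci, drop = FALSE]
  odd <- seq(1L, nrow(a), by = 2L)
  gt <- matrix(paste0(a[odd, , drop = FALSE], "|", a[odd + 1L, , drop = FALSE]),
               nrow = length(odd))
  body <- vapply(seq_along(loci), function(k) {
    l <- loci[k]
    paste(c(paste0("chr", map$chromosome[l]),
            round(map$position[l] * 1e6) + 1L,
            paste0("locus", l), "A", "T", ".", "PASS", ".", "GT",
            gt[, k]), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(file)
}

#' Export a genotype dosage matrix as TSV
#'
#' @param pop a \code{haplotype_set}.
#' @param file output path.
#' @param loci locus ids (columns); default all loci.
#' @return invisibly, the file path.
#' @export
export_dosage_tsv <- function(pop, file, loci = NULL) {
  g <- genotype_matrix(pop, loci)
  colnames(g) <- paste0("locus",
                        if (is.null(loci)) seq_len(ncol(g)) else loci)
  df <- data.frame(id = seq_len(nrow(g)), g, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export a pedigree as TSV
#'
#' @param pedigree data.frame with columns id, sire, dam, family.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
export_pedigree_tsv <- function(pedigree, file) {
  write.table(pedigree[, c("id", "sire", "dam", "family")], file,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export a QTL scenario as TSV
#'
#' @param scenario a \code{qtl_scenario}.
#' @param map genetic map.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
export_scenario_tsv <- function(scenario, map, file) {
  idx <- scenario$qtl_indices
  df <- data.frame(locus_id = idx, chromosome = map$chromosome[idx],
                   position = map$position[idx], Vq = scenario$Vq,
                   effect = scenario$effects,
                   scenario_id = scenario$scenario_id)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export phenotypes as TSV
#'
#' @param trait a \code{trait}.
#' @param pedigree training-generation pedigree.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
export_phenotypes_tsv <- function(trait, pedigree, file) {
  df <- data.frame(id = pedigree$id, family = pedigree$family,
                   tbv = trait$tbv, phenotype = trait$phenotypes,
                   h2 = trait$h2)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write / read a simulation configuration
#'
#' Plain "key = value" text mirroring the [sim_config()] fields, for
#' provenance and the command-line interface.
#'
#' @param config a \code{sim_config}.
#' @param file path.
#' @return \code{write_sim_config}: invisibly the path;
#'   \code{read_sim_config}: a \code{sim_config}.
#' @export
write_sim_config <- function(config, file) {
  keys <- setdiff(names(config), NULL)
  writeLines(sprintf("%s = %s", keys,
                     vapply(config[keys], function(v)
                       format(v, scientific = FALSE), character(1))),
             file)
  invisible(file)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[`, character(1), 2L))
  args <- list()
  for (i in seq_along(keys)) {
    v <- vals[i]
    args[[keys[i]]] <- if (v %in% c("TRUE", "FALSE")) as.logical(v)
                       else as.numeric(v)
  }
  do.call(sim_config, args)
}
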