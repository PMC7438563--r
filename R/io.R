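#' Export a panel dosage matrix as TSV
#'
#' Loci in rows, individuals in columns, header row of individual IDs;
#' entries are 0/1/2 reference-allele dosages.
#'
#' @param state a `population_state`
#' @param tracked a [tracked_loci()]
#' @param panel panel name
#' @param file output path
#' @return `file`, invisibly
#' @export
export_dosage_tsv <- function(state, tracked, panel, file) {
  D <- t(panel_dosage(state, tracked, panel))
  colnames(D) <- sprintf("ind_%d", seq_len(state$n))
  pi <- tracked$panels[[panel]]
  lt <- locus_table(tracked$map, tracked$pos[pi$cols])
  out <- cbind(locus_id = sprintf("%s_%d", panel, seq_len(nrow(D))),
               as.data.frame(D))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export the locus map as TSV
#'
#' Columns: chromosome, locus_id, genetic position (Morgans, within
#' chromosome), physical position (bp).
#'
#' @param tracked a [tracked_loci()]
#' @param file output path
#' @param panel optional panel restriction
#' @return `file`, invisibly
#' @export
export_map_tsv <- function(tracked, file, panel = NULL) {
  cols <- if (is.null(panel)) seq_along(tracked$pos) else tracked$panels[[panel]]$cols
  lt <- locus_table(tracked$map, tracked$pos[cols])
  out <- data.frame(chromosome = lt$chr,
                    locus_id = sprintf("L%d", cols),
                    genetic_pos_Morgan = lt$gen_pos,
                    physical_pos_bp = round(lt$phys_pos))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export phased genotypes as VCF
#'
#' Writes the individuals' phased genotypes at a panel's loci as a diploid
#' VCF (GT field, "|"-phased). Requires the vcfR package.
#'
#' @param state a `population_state`
#' @param tracked a [tracked_loci()]
#' @param panel panel name
#' @param file output path (".vcf.gz")
#' @return `file`, invisibly
#' @export
export_vcf <- function(state, tracked, panel, file) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required for VCF export")
  }
  pi <- tracked$panels[[panel]]
  lt <- locus_table(tracked$map, tracked$pos[pi$cols])
  n <- state$n
  L <- length(pi$cols)
  h1 <- state$hap[pi$cols, seq(1, 2 * n, 2), drop = FALSE]
  h2 <- state$hap[pi$cols, seq(2, 2 * n, 2), drop = FALSE]
  # orient on the panel's reference allele; the VCF ALT code "1" marks
  # carriers of the non-reference allele
  a1 <- matrix(as.integer(h1), L); a2 <- matrix(as.integer(h2), L)
  flip <- !pi$ref_derived
  a1[flip, ] <- 1L - a1[flip, ]; a2[flip, ] <- 1L - a2[flip, ]
  gt <- matrix(sprintf("%d|%d", 1L - a1, 1L - a2), L)
  colnames(gt) <- sprintf("ind_%d", seq_len(n))
  fix <- cbind(CHROM = as.character(lt$chr),
               POS = as.character(round(lt$phys_pos)),
               ID = sprintf("%s_%d", panel, seq_along(pi$cols)),
               REF = "A", ALT = "T", QUAL = ".", FILTER = "PASS", INFO = ".")
  vcf <- new("vcfR",
             meta = c("##fileformat=VCFv4.2",
                      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             fix = fix,
             gt = cbind(FORMAT = "GT", gt))
  vcfR::write.vcf(vcf, file)
  invisible(file)
}

#' Export a relationship matrix with a metadata sidecar
#'
#' Square CSV with individual IDs as header row and first column, plus a
#' JSON sidecar recording the matrix label, measure type, repair alpha and
#' panel.
#'
#' @param G a `relationship_matrix`
#' @param file output CSV path (sidecar gets ".json" appended)
#' @param ids optional individual IDs
#' @return `file`, invisibly
#' @export
export_relmat <- function(G, file, ids = sprintf("ind_%d", seq_len(nrow(G)))) {
  M <- as.data.frame(unclass(G))
  colnames(M) <- ids
  write.csv(cbind(id = ids, M), file, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- list(label = attr(G, "label"), measure = attr(G, "measure"),
                 repair = attr(G, "repair"), alpha = attr(G, "alpha"),
                 panel = attr(G, "panel"))
    jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE)
  }
  invisible(file)
}

#' Export a phenotype / breeding-value table
#'
#' @param state a `population_state`
#' @param file output CSV path
#' @return `file`, invisibly
#' @export
export_phenotypes <- function(state, file) {
  out <- data.frame(individual_id = state$id, generation = state$gen,
                    sex = state$sex, role = state$role,
                    y = state$pheno, tbv = state$tbv)
  write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' Export a contribution solution
#'
#' @param solution a [solve_oc()] result
#' @param gebv the breeding values used
#' @param file output CSV path
#' @return `file`, invisibly
#' @export
export_contributions <- function(solution, gebv, file) {
  out <- data.frame(individual_id = seq_along(solution$c),
                    sex = solution$sex, gebv = gebv,
                    contribution = solution$c)
  write.csv(out, file, row.names = FALSE)
  invisible(file)
}
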