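# On-disk formats.  Readers lean on the established parsers (vcfR,
# rtracklayer, fgsea); writers format the simple shapes this pipeline
# exchanges.  All tables are plain TSV with a header row.

#' Write / read a pedigree TSV
#'
#' Three tab-separated columns \code{animal}, \code{sire}, \code{dam};
#' unknown parents are written as \code{0}.
#'
#' @param ped pedigree data frame (\code{NA} = unknown parent).
#' @param path file path.
#' @return \code{write_pedigree_tsv}: the path, invisibly;
#'   \code{read_pedigree_tsv}: a validated pedigree data frame.
#' @export
write_pedigree_tsv <- function(ped, path) {
  out <- data.frame(animal = ped$animal,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_tsv
#' @export
read_pedigree_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = "character")
  d$sire[d$sire == "0"] <- NA_character_
  d$dam[d$dam == "0"] <- NA_character_
  class(d) <- c("pedigree", "data.frame")
  validate_pedigree(d)
  d
}

#' Write / read a genotype matrix TSV
#'
#' SNPs in rows: columns \code{snp_id}, \code{chrom}, \code{pos_bp}
#' followed by one column per animal with genotypes coded -1/0/1 and
#' missing calls as \code{NA}.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param path file path.
#' @return the path / a \code{geno_matrix}.
#' @export
write_genotype_tsv <- function(geno, path) {
  out <- cbind(geno$map[, c("snp_id", "chrom", "pos_bp")],
               as.data.frame(t(geno$genotypes)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  map <- d[, c("snp_id", "chrom", "pos_bp")]
  vals <- t(as.matrix(d[, -(1:3), drop = FALSE]))
  storage.mode(vals) <- "integer"
  genotype_matrix(vals, map)
}

#' Write a genotype matrix as VCF, read one back
#'
#' Minimal VCFv4.2 with a GT field per animal: -1 is written as
#' \code{0/0}, 0 as \code{0/1}, 1 as \code{1/1} and missing as \code{./.};
#' REF/ALT are the placeholder alleles A/G.  Reading uses \pkg{vcfR} and
#' inverts the same coding (any heterozygous call becomes 0).
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param path file path (uncompressed \code{.vcf}).
#' @return the path / a \code{geno_matrix}.
#' @export
write_genotype_vcf <- function(geno, path) {
  G <- geno$genotypes
  gt <- matrix("./.", nrow(G), ncol(G))
  gt[!is.na(G) & G == -1L] <- "0/0"
  gt[!is.na(G) & G == 0L] <- "0/1"
  gt[!is.na(G) & G == 1L] <- "1/1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=funcblup",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(G)),
                     collapse = "\t")), con)
  body <- cbind(geno$map$chrom, geno$map$pos_bp, geno$map$snp_id,
                "A", "G", ".", ".", ".", "GT", t(gt))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_genotype_vcf
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0", "0|0")] <- -1L
    out[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 0L
    out[x %in% c("1/1", "1|1")] <- 1L
    out
  }
  vals <- t(matrix(code(gt), nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt)))
  map <- data.frame(snp_id = vcfR::getID(v), chrom = vcfR::getCHROM(v),
                    pos_bp = vcfR::getPOS(v), stringsAsFactors = FALSE)
  genotype_matrix(vals[, map$snp_id, drop = FALSE], map)
}

#' Write / read a phenotype TSV
#'
#' Columns \code{animal}, \code{trait}, \code{drp}, \code{edc}; one row per
#' bull and trait.
#'
#' @param trait data frame (\code{animal}, \code{drp}, \code{edc}).
#' @param path file path.
#' @param trait_name label written in the \code{trait} column.
#' @return the path / a named list of trait data frames.
#' @export
write_phenotypes_tsv <- function(trait, path, trait_name = "trait1") {
  out <- data.frame(animal = trait$animal, trait = trait_name,
                    drp = trait$drp, edc = trait$edc)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  lapply(split(d, d$trait), function(x)
    data.frame(animal = as.character(x$animal), drp = x$drp, edc = x$edc,
               stringsAsFactors = FALSE))
}

#' Write / read gene coordinates as GFF3 (gene features only)
#'
#' @param genes gene table (\code{gene_id}, \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{strand}).
#' @param path file path (\code{.gff3}).
#' @return the path / a gene table.
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start_bp, genes$end_bp),
    strand = genes$strand %||% "*")
  gr$type <- "gene"
  gr$source <- "funcblup"
  gr$ID <- genes$gene_id
  gr$gene_id <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_genes_gff3
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- gr$gene_id
  if (is.null(ids)) ids <- gr$ID
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start_bp = GenomicRanges::start(gr),
             end_bp = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write / read gene sets in GMT format
#'
#' One term per line: term id, description, then the member gene ids, all
#' tab-separated.  Reading uses \code{fgsea::gmtPathways}.
#'
#' @param terms named list of character vectors of gene ids.
#' @param path file path (\code{.gmt}).
#' @param descriptions optional named character vector of descriptions.
#' @return the path / a named list of gene-id vectors.
#' @export
write_gmt <- function(terms, path, descriptions = NULL) {
  lines <- vapply(names(terms), function(t) {
    d <- if (is.null(descriptions) || is.na(descriptions[t])) "na"
         else descriptions[[t]]
    paste(c(t, d, terms[[t]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a SNP or term effect table as TSV
#'
#' @param table a data frame from \code{\link{wald_tests}} or
#'   \code{\link{fit_term_model}}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_effects_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
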