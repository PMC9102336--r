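#' Simulate gene coordinates and overlapping functional terms
#'
#' Genes are placed without overlap: each chromosome is divided into equal
#' slots for the genes it carries, and a gene of exponential length (mean
#' \code{mean_gene_length_bp}, truncated to fit) is placed uniformly inside
#' its slot.  Terms emulate GO/KEGG gene sets: each term samples its genes
#' without replacement, but genes are shared across terms, so terms overlap.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return a list with \code{genes} (data frame \code{gene_id},
#'   \code{chrom}, \code{start_bp}, \code{end_bp}, \code{strand}) and
#'   \code{terms} (named list of character vectors of gene ids).
#' @export
simulate_annotation <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, "annotation"))

  n_per <- tabulate(sort(sample.int(cfg$n_chromosomes, cfg$n_genes,
                                    replace = TRUE)),
                    nbins = cfg$n_chromosomes)
  gene_rows <- list()
  gi <- 1L
  for (ch in seq_len(cfg$n_chromosomes)) {
    k <- n_per[ch]
    if (!k) next
    slot <- floor(cfg$chromosome_length_bp / k)
    if (slot < 3)
      stop("cannot place ", k, " non-overlapping genes on a ",
           cfg$chromosome_length_bp, " bp chromosome")
    for (j in seq_len(k)) {
      len <- ceiling(stats::rexp(1, 1 / cfg$mean_gene_length_bp))
      len <- max(1L, min(len, slot - 2L))
      lo <- (j - 1L) * slot + 1L
      start <- lo + sample.int(slot - len, 1L) - 1L
      gene_rows[[gi]] <- data.frame(
        gene_id = sprintf("GENE%05d", gi), chrom = paste0("chr", ch),
        start_bp = as.integer(start), end_bp = as.integer(start + len - 1),
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
      gi <- gi + 1L
    }
  }
  genes <- do.call(rbind, gene_rows)
  genes <- genes[order(genes$chrom, genes$start_bp), , drop = FALSE]
  rownames(genes) <- NULL

  sizes <- cfg$genes_per_term_low +
    sample.int(cfg$genes_per_term_high - cfg$genes_per_term_low + 1L,
               cfg$n_terms, replace = TRUE) - 1L
  sizes <- pmin(sizes, nrow(genes))
  terms <- lapply(sizes, function(k) sort(sample(genes$gene_id, k)))
  names(terms) <- sprintf("TERM%04d", seq_len(cfg$n_terms))
  list(genes = genes, terms = terms)
}
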