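#' Map SNPs to genes within a distance window
#'
#' A SNP is assigned every gene whose interval it falls inside (distance 0)
#' or whose nearest edge lies within \code{max_dist} base pairs:
#' distance = 0 if \code{start <= pos <= end}, otherwise
#' \code{min(|pos - start|, |pos - end|)}.  Strand is ignored.  The overlap
#' search runs on \pkg{GenomicRanges}.
#'
#' @param map SNP map: data frame with \code{snp_id}, \code{chrom},
#'   \code{pos_bp} (a \code{\link{genotype_matrix}} may be passed; its map
#'   is used).
#' @param genes gene table: data frame with \code{gene_id}, \code{chrom},
#'   \code{start_bp}, \code{end_bp} (1-based inclusive).
#' @param max_dist maximum SNP-gene distance in bp (default 5000); a SNP
#'   exactly \code{max_dist} away is assigned, one base farther is not.
#' @return data frame \code{snp_id}, \code{gene_id}, \code{distance_bp},
#'   one row per assignment.
#' @export
map_snps_to_genes <- function(map, genes, max_dist = 5000) {
  if (inherits(map, "geno_matrix")) map <- map$map
  stopifnot(all(c("snp_id", "chrom", "pos_bp") %in% names(map)),
            all(c("gene_id", "chrom", "start_bp", "end_bp") %in% names(genes)))
  if (max_dist < 0) stop("max_dist must be >= 0")
  shared <- intersect(unique(map$chrom), unique(genes$chrom))
  if (!length(shared))
    stop("no chromosome shared between the SNP map (",
         paste(utils::head(unique(map$chrom), 3), collapse = ", "),
         ", ...) and the gene table (",
         paste(utils::head(unique(genes$chrom), 3), collapse = ", "), ", ...)")
  snp_gr <- GenomicRanges::GRanges(map$chrom,
                                   IRanges::IRanges(map$pos_bp, width = 1))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start_bp,
                                                     genes$end_bp))
  # maxgap counts the positions strictly between the ranges, i.e. our
  # edge-to-edge distance minus one; filter to the exact window afterwards.
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr, maxgap = max_dist,
                                      ignore.strand = TRUE)
  si <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  pos <- map$pos_bp[si]
  lo <- genes$start_bp[gi]
  hi <- genes$end_bp[gi]
  d <- ifelse(pos >= lo & pos <= hi, 0L,
              pmin(abs(pos - lo), abs(pos - hi)))
  keep <- d <= max_dist
  out <- data.frame(snp_id = map$snp_id[si][keep],
                    gene_id = genes$gene_id[gi][keep],
                    distance_bp = as.integer(d[keep]),
                    stringsAsFactors = FALSE)
  out[order(match(out$snp_id, map$snp_id), out$gene_id), , drop = FALSE]
}

#' Overlap covariance between functional terms
#'
#' Builds the term-by-term covariance matrix whose off-diagonal entries are
#' the fraction of shared genes between two terms and whose diagonal is 1.
#' The symmetric sharing convention is configurable:
#' \code{"jaccard"} (intersection over union, the default),
#' \code{"min-size"} (intersection over the smaller set) or
#' \code{"geometric-mean"} (intersection over the geometric mean of the
#' sizes).  If the smallest eigenvalue falls below \code{1e-8} the spectrum
#' is floored there and the matrix rescaled back to unit diagonal; the
#' repair is recorded in attribute \code{"repaired"}.
#'
#' @param terms named list of character vectors (term id -> gene ids).
#' @param restrict_to optional gene universe; genes outside it are dropped
#'   from every term before overlaps are computed (terms emptied by the
#'   restriction are dropped with a warning).
#' @param convention overlap denominator convention (see above).
#' @return symmetric positive-definite matrix with term ids as dimnames.
#' @export
term_overlap_covariance <- function(terms, restrict_to = NULL,
                                    convention = c("jaccard", "min-size",
                                                   "geometric-mean")) {
  convention <- match.arg(convention)
  if (!length(terms)) stop("empty term set")
  if (!is.null(restrict_to)) {
    terms <- lapply(terms, intersect, restrict_to)
    empty <- lengths(terms) == 0
    if (any(empty)) {
      warning("dropping ", sum(empty),
              " term(s) with no gene in the universe: ",
              paste(utils::head(names(terms)[empty], 5), collapse = ", "))
      terms <- terms[!empty]
    }
    if (!length(terms)) stop("no term survives the gene-universe restriction")
  }
  t_ids <- names(terms)
  k <- length(terms)
  P <- diag(1, k)
  dimnames(P) <- list(t_ids, t_ids)
  if (k > 1) {
    for (s in seq_len(k - 1)) {
      for (t in seq(s + 1, k)) {
        ninter <- length(intersect(terms[[s]], terms[[t]]))
        denom <- switch(convention,
          "jaccard" = length(union(terms[[s]], terms[[t]])),
          "min-size" = min(length(terms[[s]]), length(terms[[t]])),
          "geometric-mean" = sqrt(length(terms[[s]])) *
                             sqrt(length(terms[[t]])))
        P[s, t] <- P[t, s] <- ninter / denom
      }
    }
  }
  repaired <- FALSE
  eig <- eigen(P, symmetric = TRUE)
  if (min(eig$values) < 1e-8) {
    repaired <- TRUE
    vals <- pmax(eig$values, 1e-8)
    P <- eig$vectors %*% (vals * t(eig$vectors))
    s <- 1 / sqrt(diag(P))
    P <- P * tcrossprod(s)
    P <- (P + t(P)) / 2
    diag(P) <- 1
    dimnames(P) <- list(t_ids, t_ids)
  }
  attr(P, "repaired") <- repaired
  attr(P, "convention") <- convention
  P
}

#' Build the inputs of the term-level mixed model
#'
#' Assembles, in SNP order: the response \eqn{y^*_j = |\hat g_j|}; the
#' SNP-by-term incidence \eqn{Z^*} with \eqn{Z^*_{jt} = 1} iff any gene
#' assigned to SNP \eqn{j} belongs to term \eqn{t}; and the residual
#' weights \eqn{L_{jj} = 1} for SNPs assigned to at least one term and
#' \code{unassigned_weight} (default 10) for SNPs carrying no functional
#' assignment.
#'
#' @param assignments SNP-gene table from \code{\link{map_snps_to_genes}}.
#' @param terms named list of gene-id vectors; terms whose genes are all
#'   unknown to \code{assignments}' gene universe are kept (their column is
#'   zero unless \code{drop_unmatched}).
#' @param effects SNP effect table from \code{\link{wald_tests}} covering
#'   every SNP to model.
#' @param p_cov optional precomputed overlap covariance (defaults to
#'   \code{\link{term_overlap_covariance}} on \code{terms} restricted to
#'   the genes reachable from the SNPs).
#' @param unassigned_weight residual weight for SNPs without any term
#'   (default 10).
#' @param convention passed to \code{\link{term_overlap_covariance}}.
#' @return a list of class \code{"term_model_inputs"}: \code{y_star},
#'   \code{z_star} (0/1 matrix, SNPs x terms), \code{p_cov},
#'   \code{l_weights}, \code{snp_ids}, \code{term_ids},
#'   \code{genes_per_term} (genes behind each term's incident SNPs).
#' @export
build_term_inputs <- function(assignments, terms, effects, p_cov = NULL,
                              unassigned_weight = 10,
                              convention = "jaccard") {
  stopifnot(all(c("snp_id", "gene_id") %in% names(assignments)),
            all(c("snp_id", "effect") %in% names(effects)))
  unknown <- setdiff(assignments$snp_id, effects$snp_id)
  if (length(unknown))
    stop("assignments reference SNPs without effects: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  universe <- unique(assignments$gene_id)
  matched <- vapply(terms, function(g) any(g %in% universe), logical(1))
  if (any(!matched)) {
    warning("dropping ", sum(!matched),
            " term(s) with no gene reachable from the SNPs: ",
            paste(utils::head(names(terms)[!matched], 5), collapse = ", "))
    terms <- terms[matched]
  }
  if (!length(terms))
    stop("no SNP maps to any term: empty incidence matrix")

  snp_ids <- effects$snp_id
  t_ids <- names(terms)
  gene_by_snp <- split(assignments$gene_id, assignments$snp_id)
  Z <- matrix(0, length(snp_ids), length(t_ids),
              dimnames = list(snp_ids, t_ids))
  genes_per_term <- stats::setNames(integer(length(t_ids)), t_ids)
  for (t in t_ids) {
    hit_snps <- names(gene_by_snp)[vapply(gene_by_snp, function(g)
      any(g %in% terms[[t]]), logical(1))]
    Z[hit_snps, t] <- 1
    genes_per_term[t] <- length(unique(unlist(
      lapply(gene_by_snp[hit_snps], intersect, terms[[t]]))))
  }
  if (!any(Z > 0)) stop("no SNP maps to any term: empty incidence matrix")
  assigned <- rowSums(Z) > 0
  l_weights <- ifelse(assigned, 1, unassigned_weight)
  if (is.null(p_cov))
    p_cov <- term_overlap_covariance(terms, restrict_to = universe,
                                     convention = convention)
  stopifnot(identical(rownames(p_cov), t_ids))
  y_star <- abs(effects$effect)
  structure(list(y_star = stats::setNames(y_star, snp_ids), z_star = Z,
                 p_cov = p_cov, l_weights = stats::setNames(l_weights,
                                                            snp_ids),
                 snp_ids = snp_ids, term_ids = t_ids,
                 genes_per_term = genes_per_term),
            class = "term_model_inputs")
}
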