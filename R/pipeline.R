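#' Default pipeline configuration
#'
#' Builds the full configuration list for \code{\link{run_pipeline}}, with
#' every pipeline constant surfaced as a named option: MAF floor 0.01,
#' call-rate floor 0.99, SNP-gene window 5000 bp, polygenic ratio 0.4,
#' unassigned-SNP residual weight 10, significance level 0.05.
#'
#' @param sim a \code{\link{sim_config}} describing the synthetic inputs.
#' @param traits named list of per-trait settings; each element may set
#'   \code{h2} (variances then derive from the realised DRP variance) or
#'   \code{sigma2_a}/\code{sigma2_e} (explicit components); when neither is
#'   given the generator variances are reused, which keeps the analysis
#'   model matched to the simulation.
#' @param shared_causal if TRUE and \code{sim$n_causal} is set, all traits
#'   share one causal SNP set (a pleiotropy scenario).
#' @param alpha family-wise significance level.
#' @param min_maf,min_call_rate genotype QC thresholds.
#' @param max_dist SNP-gene assignment window in bp.
#' @param unassigned_weight residual weight for SNPs without a term.
#' @param overlap_convention denominator convention of the term overlap
#'   covariance (\code{"jaccard"}, \code{"min-size"},
#'   \code{"geometric-mean"}).
#' @param term_variances \code{"reml"} to estimate the stage-2 variances on
#'   a ratio grid, or a list with \code{sigma2_p} and \code{sigma2_e_star}.
#' @param ratio_grid grid of \eqn{\sigma^2_{e^*}/\sigma^2_p} ratios used
#'   when \code{term_variances = "reml"}.
#' @param write_vcf also write the simulated genotypes as VCF.
#' @param seed pipeline seed; trait replicates derive their seeds from it.
#' @return a configuration list of class \code{"run_config"}.
#' @export
default_run_config <- function(sim = sim_config(),
                               traits = list(trait1 = list()),
                               shared_causal = FALSE,
                               alpha = 0.05,
                               min_maf = 0.01,
                               min_call_rate = 0.99,
                               max_dist = 5000,
                               unassigned_weight = 10,
                               overlap_convention = "jaccard",
                               term_variances = "reml",
                               ratio_grid = 10^seq(-2, 2, length.out = 41),
                               write_vcf = TRUE,
                               seed = sim$seed) {
  if (is.null(names(traits)) || anyDuplicated(names(traits)))
    stop("traits must be a uniquely named list")
  structure(list(sim = sim, traits = traits, shared_causal = shared_causal,
                 alpha = alpha, min_maf = min_maf,
                 min_call_rate = min_call_rate, max_dist = max_dist,
                 unassigned_weight = unassigned_weight,
                 overlap_convention = overlap_convention,
                 term_variances = term_variances, ratio_grid = ratio_grid,
                 write_vcf = write_vcf, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar options override the defaults of
#' \code{\link{default_run_config}}; \code{sim:} entries override
#' \code{\link{sim_config}} defaults; \code{traits:} is a named mapping of
#' per-trait settings.
#'
#' @param path YAML file path.
#' @return a \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  args <- y[setdiff(names(y), c("sim", "traits"))]
  args$sim <- sim
  if (!is.null(y$traits)) args$traits <- y$traits
  do.call(default_run_config, args)
}

#' Run the full two-stage pipeline on synthetic data
#'
#' Simulates pedigree, genotypes, annotation and per-trait phenotypes, then
#' per trait: genotype QC, mean imputation, the SNP-BLUP mixed model, Wald
#' tests, the inflation factor and variance explained; then SNP-gene
#' assignment and the term-level mixed model.  Writes all inputs and result
#' tables as TSV (plus GFF3/GMT/VCF for the annotation and genotypes), a
#' pleiotropy summary when several traits are run, and a machine-readable
#' \code{manifest.json} recording seeds, thresholds and filter counts.
#'
#' @param cfg a \code{"run_config"} from \code{\link{default_run_config}}
#'   or \code{\link{read_run_config}}, or a path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the per-trait SNP and term tables, the
#'   pleiotropy summary and the manifest.
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  res <- tryCatch({
    sim <- cfg$sim
    ped <- simulate_pedigree(sim)
    geno <- simulate_genotypes(ped, sim)
    ann <- simulate_annotation(sim)
    write_pedigree_tsv(ped, file.path(out_dir, "pedigree.tsv"))
    write_genotype_tsv(geno, file.path(out_dir, "genotypes.tsv"))
    if (isTRUE(cfg$write_vcf))
      write_genotype_vcf(geno, file.path(out_dir, "genotypes.vcf"))
    write_genes_gff3(ann$genes, file.path(out_dir, "genes.gff3"))
    write_gmt(ann$terms, file.path(out_dir, "terms.gmt"))

    stage <- "kinship"
    a_inv <- build_a_inverse(ped)

    stage <- "qc"
    qcd <- qc_filter(geno, cfg$min_maf, cfg$min_call_rate)
    qc_report <- attr(qcd, "qc_report")
    imputed <- impute_mean(qcd)

    stage <- "annotate"
    assignments <- map_snps_to_genes(imputed$map, ann$genes, cfg$max_dist)
    write.table(assignments, file.path(out_dir, "snp_gene_assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    trait_names <- names(cfg$traits)
    shared_causal_ids <- NULL
    snp_tables <- list()
    term_tables <- list()
    summaries <- list()
    for (ti in seq_along(cfg$traits)) {
      tn <- trait_names[ti]
      tspec <- cfg$traits[[ti]]
      stage <- paste0("simulate_phenotypes[", tn, "]")
      phen <- simulate_phenotypes(geno, ped, sim,
                                  seed = cfg$seed + 1000L * ti,
                                  causal_ids = if (isTRUE(cfg$shared_causal))
                                    shared_causal_ids)
      if (isTRUE(cfg$shared_causal) && is.null(shared_causal_ids))
        shared_causal_ids <- phen$truth$causal_snp_ids
      trait <- phen$trait
      write_phenotypes_tsv(trait,
                           file.path(out_dir,
                                     paste0("phenotypes_", tn, ".tsv")),
                           trait_name = tn)

      stage <- paste0("gwas[", tn, "]")
      vs <- if (!is.null(tspec$h2))
        variances_from_h2(trait$drp, tspec$h2, sim$polygenic_ratio)
      else if (!is.null(tspec$sigma2_a))
        variance_spec(tspec$sigma2_a, tspec$sigma2_e, sim$polygenic_ratio)
      else variance_spec(sim$sigma2_a, sim$sigma2_e, sim$polygenic_ratio)
      mme_sys <- mme_system(imputed,
                            stats::setNames(trait$edc, trait$animal),
                            a_inv, vs)
      fit <- solve_mme(mme_sys, trait$drp)
      snp_tab <- wald_tests(fit, alpha = cfg$alpha)
      lam <- inflation_lambda(snp_tab)
      ve <- variance_explained(snp_tab, imputed, trait)
      write_effects_tsv(snp_tab,
                        file.path(out_dir, paste0("snp_effects_", tn,
                                                  ".tsv")))

      stage <- paste0("terms[", tn, "]")
      inputs <- build_term_inputs(assignments, ann$terms, snp_tab,
                                  unassigned_weight = cfg$unassigned_weight,
                                  convention = cfg$overlap_convention)
      tvs <- if (identical(cfg$term_variances, "reml"))
        estimate_term_variances(inputs, grid = cfg$ratio_grid)
      else term_variance_spec(cfg$term_variances$sigma2_p,
                              cfg$term_variances$sigma2_e_star)
      term_tab <- fit_term_model(inputs, tvs, alpha = cfg$alpha)
      write_effects_tsv(term_tab,
                        file.path(out_dir, paste0("term_effects_", tn,
                                                  ".tsv")))

      snp_tables[[tn]] <- snp_tab
      term_tables[[tn]] <- term_tab
      summaries[[tn]] <- list(
        n_snps_tested = nrow(snp_tab),
        n_significant_snps = sum(snp_tab$significant),
        lambda = lam,
        variance_explained_pct = ve,
        n_terms_tested = nrow(term_tab),
        n_significant_terms = sum(term_tab$significant),
        sigma2_p = tvs$sigma2_p, sigma2_e_star = tvs$sigma2_e_star,
        term_variances_estimated = tvs$estimated)
    }

    stage <- "pleiotropy"
    pleio <- if (length(snp_tables) >= 2) pleiotropy_table(snp_tables)
             else NULL
    if (!is.null(pleio))
      write.table(pleio$pairs, file.path(out_dir, "pleiotropy.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("funcblup")),
      seed = cfg$seed,
      alpha = cfg$alpha, min_maf = cfg$min_maf,
      min_call_rate = cfg$min_call_rate, max_dist = cfg$max_dist,
      polygenic_ratio = sim$polygenic_ratio,
      unassigned_weight = cfg$unassigned_weight,
      overlap_convention = cfg$overlap_convention,
      sim = unclass(sim),
      qc = qc_report,
      n_snp_gene_assignments = nrow(assignments),
      traits = summaries)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    list(snp_tables = snp_tables, term_tables = term_tables,
         pleiotropy = pleio, manifest = manifest, out_dir = out_dir)
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Pleiotropy summary across traits
#'
#' Counts, for every pair of traits analysed on the same SNP panel, the
#' SNPs significant in both (a significant SNP shared by two traits is the
#' operational definition of pleiotropy here).
#'
#' @param tables named list (>= 2) of SNP effect tables from
#'   \code{\link{wald_tests}}, all on the identical SNP panel.
#' @return a list with \code{per_trait} (trait, n_significant) and
#'   \code{pairs} (trait_a, trait_b, n_shared_significant), pairs stored
#'   once with \code{trait_a < trait_b}.
#' @export
pleiotropy_table <- function(tables) {
  if (length(tables) < 2) stop("need at least 2 trait tables")
  if (is.null(names(tables))) stop("tables must be named by trait")
  panel <- tables[[1]]$snp_id
  for (tn in names(tables)) {
    if (!identical(tables[[tn]]$snp_id, panel))
      stop("trait ", tn, " was analysed on a different SNP panel")
  }
  sig <- lapply(tables, function(t) t$snp_id[t$significant])
  per_trait <- data.frame(trait = names(tables),
                          n_significant = lengths(sig),
                          row.names = NULL, stringsAsFactors = FALSE)
  cmb <- utils::combn(sort(names(tables)), 2)
  pairs <- data.frame(trait_a = cmb[1, ], trait_b = cmb[2, ],
                      n_shared_significant = apply(cmb, 2, function(p)
                        length(intersect(sig[[p[1]]], sig[[p[2]]]))),
                      stringsAsFactors = FALSE)
  list(per_trait = per_trait, pairs = pairs)
}
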