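.pipelineDefaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    log_level = "info",
    sim = list(ne = 35, n_chrom = 11, chrom_len_bp = 30e6, n_markers = 9000,
               n_families = 20, progeny_per_family = 15, fst = 0.10,
               n_qtl = 200, h2_true = 0.4, n_blocks = 40, block_sd = 0.25,
               missing_rate = 0.01, cm_per_mbp = 20, genic_fraction = 0.5),
    filter = list(cr_min = 0.90, maf_min = 0),
    ld = list(max_dist_bp = 2e6, corrections = c("V", "S", "VS"),
              level = 0.2, max_fit_pairs = 20000),
    ne = list(maf_cutoff = 0.05, max_pairs = 5000),
    predict = list(methods = c("ablup", "gblup", "brr"), k_folds = 10,
                   chain = list(n_iter = 1500, burn_in = 500, thin = 5)),
    subsets = list(schemes = list(list(scheme = "random_noncumulative",
                                       size = 300),
                                  list(scheme = "evenly_spaced",
                                       window_bp = 1e6),
                                  list(scheme = "genic"),
                                  list(scheme = "intergenic"),
                                  list(scheme = "ld_pruned")),
                   per_chromosome = TRUE, method = "gblup"),
    split = list(n_pcs = 2, outlier_sd = 6, n_random = 10),
    gwas = list(models = c("lma", "mlma"), alpha = 0.05, fdr = 0.05,
                structure_covariate = TRUE)
  )
}

.mergeConfig <- function(def, user, path = "") {
  errs <- character(0)
  for (k in names(user)) {
    full <- if (path == "") k else paste0(path, "$", k)
    if (!k %in% names(def)) {
      errs <- c(errs, paste0("unknown key: ", full))
    } else if (is.list(def[[k]]) && !is.null(names(def[[k]])) &&
               k != "schemes" && k != "chain") {
      sub <- .mergeConfig(def[[k]], as.list(user[[k]]), full)
      def[[k]] <- sub$cfg
      errs <- c(errs, sub$errs)
    } else {
      def[[k]] <- user[[k]]
    }
  }
  list(cfg = def, errs = errs)
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a nested list or a YAML file path, fills every default, rejects
#' unknown keys, and applies consistency rules (fold count, scheme
#' parameters, thresholds). Errors are aggregated into one message.
#'
#' @param config nested list, YAML path, or `NULL` for all defaults.
#' @return the fully resolved configuration list.
#' @export
validateConfig <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  merged <- .mergeConfig(.pipelineDefaults(), config)
  cfg <- merged$cfg
  errs <- merged$errs
  if (cfg$predict$k_folds < 2)
    errs <- c(errs, "predict$k_folds must be at least 2")
  if (cfg$filter$cr_min < 0 || cfg$filter$cr_min > 1)
    errs <- c(errs, "filter$cr_min must be in [0,1]")
  for (i in seq_along(cfg$subsets$schemes)) {
    sp <- cfg$subsets$schemes[[i]]
    pars <- intersect(names(sp), c("size", "window_bp", "chrom"))
    if (length(pars) > 1)
      errs <- c(errs, paste0("subsets$schemes[[", i, "]]: conflicting keys ",
                             paste(pars, collapse = " and ")))
    if (is.null(sp$scheme))
      errs <- c(errs, paste0("subsets$schemes[[", i, "]]: scheme missing"))
  }
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  cfg$predict$chain <- utils::modifyList(.pipelineDefaults()$predict$chain,
                                         as.list(cfg$predict$chain))
  cfg$predict$methods <- unlist(cfg$predict$methods)
  cfg$ld$corrections <- unlist(cfg$ld$corrections)
  cfg$gwas$models <- unlist(cfg$gwas$models)
  cfg
}

.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 59999 * 7919 + k * 104729) %% 2147483629L)
}

.log <- function(level, cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), ...)
}

# single relatedness-controlled prediction: train on train_ids, predict
# valid_ids by GBLUP kinship projection, return predictive ability
.splitPredict <- function(y, X, Km, ids, train, valid) {
  t <- match(train, ids); v <- match(valid, ids)
  fit <- remlFit(y[t], X[t, , drop = FALSE], Km[t, t])
  r <- y[t] - X[t, fit$kept_cols, drop = FALSE] %*% fit$b_hat
  sol <- solve(fit$lambda * Km[t, t] + diag(length(t)), r)
  pred <- drop(fit$lambda * Km[v, t, drop = FALSE] %*% sol)
  yv <- y[v] - drop(X[v, fit$kept_cols, drop = FALSE] %*% fit$b_hat)
  if (sd(pred) == 0) return(0)
  cor(yv, pred)
}

#' Run the full synthetic study pipeline
#'
#' Executes the fixed stage order simulate -> filter -> LD/Ne -> kinship ->
#' prediction (methods, SNP subsets, relatedness splits) -> GWAS -> report
#' on one synthetic population, writing per-stage artifacts when
#' `out_dir` is set. Every random stage derives its own child seed from the
#' global seed, so any report number is reproducible from config + seed
#' alone; the same seed gives a bit-identical report.
#'
#' @param config configuration list or YAML path (see [validateConfig()]).
#' @return invisibly, the report: a list of tables (`methods`, `subsets`,
#'   `chromosomes`, `decay`, `ne`, `split`, `gwas`) plus the resolved
#'   config and per-stage seeds.
#' @export
runPipeline <- function(config = NULL) {
  cfg <- validateConfig(config)
  seeds <- setNames(lapply(1:8, function(k) .childSeed(cfg$seed, k)),
                    c("simulate", "filter", "ld", "kinship", "predict",
                      "subsets", "split", "gwas"))
  out <- cfg$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)

  .log("info", cfg, "stage simulate (seed ", seeds$simulate, ")")
  scfg <- do.call(simConfig, c(cfg$sim, list(seed = seeds$simulate)))
  study <- simulateStudy(scfg)
  y <- study$phen$trait
  names(y) <- study$phen$id

  .log("info", cfg, "stage filter")
  geno <- filterSnps(study$geno, cfg$filter$cr_min, cfg$filter$maf_min)
  genoI <- imputeMean(geno)

  .log("info", cfg, "stage kinship")
  A <- pedigreeA(study$pedigree)
  G <- grmVanRaden(genoI)
  Gp <- grmPowell(genoI)
  pca <- genoPca(G, n_components = min(10, nSamples(geno)))

  .log("info", cfg, "stage ld/ne")
  set.seed(seeds$ld)
  ld <- pairwiseLD(geno, max_dist_bp = cfg$ld$max_dist_bp,
                   corrections = cfg$ld$corrections, kinship = Gp,
                   struct_covar = pca$scores[, 1])
  stats <- c("r2", paste0("r2_", tolower(cfg$ld$corrections)))
  ldFit <- if (nrow(ld) > cfg$ld$max_fit_pairs)
    ld[sample.int(nrow(ld), cfg$ld$max_fit_pairs), ] else ld
  decay <- do.call(rbind, lapply(stats, function(s) {
    fit <- tryCatch(fitLdDecay(ldFit, n = nSamples(geno),
                               level = cfg$ld$level, stat = s),
                    error = function(e) NULL)
    data.frame(stat = s, mean_ld = mean(ld[[s]], na.rm = TRUE),
               c_per_bp = if (is.null(fit)) NA else fit$c_per_bp,
               d_threshold_bp = if (is.null(fit)) NA else fit$d_threshold_bp)
  }))
  ne <- estimateNe(geno, maf_cutoff = cfg$ne$maf_cutoff,
                   max_pairs = cfg$ne$max_pairs, seed = seeds$ld)

  .log("info", cfg, "stage predict")
  X <- .blockDesign(study$phen$block)
  Zall <- dosages(genoI)
  methodRows <- lapply(cfg$predict$methods, function(mth) {
    sd0 <- .childSeed(seeds$predict, match(mth, cfg$predict$methods))
    if (mth == "ablup") {
      fit <- remlFit(y, X, A)
      cv <- crossValidate(y, X, K = A, method = "ablup",
                          k_folds = cfg$predict$k_folds, seed = sd0)
      h2 <- fit$h2
    } else if (mth %in% c("gblup", "rrblup")) {
      fit <- remlFit(y, X, G)
      cv <- crossValidate(y, X, g = geno, K = G, method = "gblup",
                          k_folds = cfg$predict$k_folds, seed = sd0)
      h2 <- fit$h2
    } else {
      fit <- gibbsFit(y, X, Zall, method = mth,
                      n_iter = cfg$predict$chain$n_iter,
                      burn_in = cfg$predict$chain$burn_in,
                      thin = cfg$predict$chain$thin, seed = sd0)
      cv <- crossValidate(y, X, g = geno, method = mth,
                          k_folds = cfg$predict$k_folds, seed = sd0,
                          chain = cfg$predict$chain)
      h2 <- fit$h2_mean
    }
    data.frame(method = mth, n_snps = nMarkers(geno), h2 = h2,
               r_gy = cv$mean_r, se_r = cv$se_r)
  })
  tableMethods <- do.call(rbind, methodRows)

  .log("info", cfg, "stage subsets")
  subsetRow <- function(label, ids, sd0) {
    gs <- genoI[, ids]
    Gs <- grmVanRaden(gs)
    fit <- remlFit(y, X, Gs)
    cv <- crossValidate(y, X, K = Gs, method = "gblup",
                        k_folds = cfg$predict$k_folds, seed = sd0)
    data.frame(subset = label, n_snps = length(ids), h2 = fit$h2,
               r_gy = cv$mean_r, se_r = cv$se_r)
  }
  tableSubsets <- do.call(rbind, lapply(seq_along(cfg$subsets$schemes),
    function(i) {
      sp <- cfg$subsets$schemes[[i]]
      sd0 <- .childSeed(seeds$subsets, i)
      ids <- sampleSubset(geno, scheme = sp$scheme, size = sp$size,
                          window_bp = sp$window_bp, chrom = sp$chrom,
                          annotation = study$genes, seed = sd0)
      lbl <- paste0(sp$scheme,
                    if (!is.null(sp$size)) paste0("_", sp$size) else "",
                    if (!is.null(sp$window_bp))
                      paste0("_", sp$window_bp / 1000, "kb") else "")
      subsetRow(lbl, ids, sd0)
    }))
  tableChrom <- NULL
  if (isTRUE(cfg$subsets$per_chromosome)) {
    chroms <- unique(geno@map$chrom)
    tableChrom <- do.call(rbind, lapply(seq_along(chroms), function(i) {
      ids <- sampleSubset(geno, "single_chromosome", chrom = chroms[i])
      row <- subsetRow(chroms[i], ids, .childSeed(seeds$subsets, 100 + i))
      names(row)[1] <- "chrom"
      row
    }))
  }

  .log("info", cfg, "stage split")
  Gm <- as.matrix(G)
  ids <- sampleIds(geno)
  plan <- makeSplit(pca$scores, "unrelated", n_pcs = cfg$split$n_pcs,
                    outlier_sd = cfg$split$outlier_sd, seed = seeds$split)
  rUnrel <- .splitPredict(y, X, Gm, ids, plan$train_ids, plan$valid_ids)
  rRand <- vapply(seq_len(cfg$split$n_random), function(k) {
    pr <- makeSplit(pca$scores, "random",
                    sizes = c(length(plan$train_ids),
                              length(plan$valid_ids)),
                    seed = .childSeed(seeds$split, k))
    .splitPredict(y, X, Gm, ids, pr$train_ids, pr$valid_ids)
  }, numeric(1))
  tableSplit <- data.frame(
    basis = c("pca_clusters", "random"),
    n_train = length(plan$train_ids), n_valid = length(plan$valid_ids),
    n_outliers = length(plan$excluded_outliers),
    r_gy = c(rUnrel, mean(rRand)))

  .log("info", cfg, "stage gwas")
  covar <- if (isTRUE(cfg$gwas$structure_covariate))
    cbind(X, pc1 = pca$scores[, 1]) else X
  gwasRows <- lapply(cfg$gwas$models, function(mdl) {
    scan <- if (mdl == "lma") lmaScan(y, covar, geno, cfg$gwas$alpha,
                                      cfg$gwas$fdr)
            else mlmaScan(y, covar, geno, G, cfg$gwas$alpha, cfg$gwas$fdr)
    if (!is.null(out))
      writeGwasResult(scan, file.path(out, paste0("gwas_", mdl, ".tsv")))
    data.frame(model = mdl, lambda_gc = lambdaGC(scan),
               n_bonf = sum(scan$sig_bonf), n_bh = sum(scan$sig_bh))
  })
  tableGwas <- do.call(rbind, gwasRows)

  report <- list(methods = tableMethods, subsets = tableSubsets,
                 chromosomes = tableChrom, decay = decay, ne = ne,
                 split = tableSplit, gwas = tableGwas,
                 realized_h2 = study$truth$realized_h2,
                 config = cfg, seeds = seeds)
  if (!is.null(out)) {
    for (nm in c("methods", "subsets", "chromosomes", "decay", "split",
                 "gwas"))
      if (!is.null(report[[nm]]))
        write.table(report[[nm]], file.path(out, paste0(nm, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report["ne"], file.path(out, "ne.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLdTable(ld, file.path(out, "ld_table.tsv"))
    writeKinship(G, file.path(out, "grm_vanraden.tsv"))
    writeSplitPlan(plan, file.path(out, "split_plan.json"))
    writeVcfGeno(geno, file.path(out, "genotypes.vcf"))
    writeGenesBed(study$genes, file.path(out, "genes.bed"))
    write.table(study$phen, file.path(out, "phenotypes.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
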