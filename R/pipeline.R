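#' Pipeline run configuration
#'
#' Assembles and validates the configuration of a full analysis run. Either
#' input file paths (`vcf`, `samples`, `phenotypes`) or a simulation spec
#' must be supplied. Every analysis threshold is a named key with the
#' study's conventional value as default: 1% top Fst quantile, elevated
#' window flags at mean 0.05 and 95%-quantile 0.25, 1 Mb windows for
#' elevated-window calling, 2 Mb for diversity reporting, 100 kb for
#' Manhattan export, and a 5 kb flank for candidate-locus allele-frequency
#' reports.
#'
#' @param vcf,samples,phenotypes input file paths (all three or none)
#' @param sim_spec a [cohort_spec()] used when no input paths are given
#' @param traits traits to analyse; default: all phenotype columns
#' @param window_bp window size for elevated-window calling
#' @param pi_window_bp window size for diversity reporting
#' @param manhattan_window_bp window size for the Manhattan export
#' @param top_quantile upper tail mass for selection-locus calling
#' @param mean_threshold,q95_threshold elevated-window flag thresholds
#' @param scan_alpha genome-wide alpha for stepwise QTL inclusion
#' @param min_distance_bp exclusion radius around accepted QTL
#' @param flank_bp flank for candidate allele-frequency reports
#' @param min_call_rate,min_maf marker QC thresholds
#' @param overlap_criterion window flag used for QTL/Fst overlap
#' @param seed integer seed for any simulation
#' @param out_dir output directory
#' @return list of class `run_config`
#' @export
run_config <- function(vcf = NULL, samples = NULL, phenotypes = NULL,
                       sim_spec = NULL, traits = NULL,
                       window_bp = 1e6, pi_window_bp = 2e6,
                       manhattan_window_bp = 1e5,
                       top_quantile = 0.01,
                       mean_threshold = 0.05, q95_threshold = 0.25,
                       scan_alpha = 0.05, min_distance_bp = 1e6,
                       flank_bp = 5000,
                       min_call_rate = 0.8, min_maf = 0.01,
                       overlap_criterion = "elevated_q95",
                       seed = 1L, out_dir = tempfile("divergescan_run_")) {
  paths_given <- !is.null(vcf)
  if (paths_given && (is.null(samples) || is.null(phenotypes))) {
    stop("vcf, samples and phenotypes paths must be given together")
  }
  if (!paths_given && is.null(sim_spec)) {
    stop("either input paths or a simulation spec must be supplied")
  }
  structure(as.list(environment())[setdiff(ls(), "paths_given")],
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a `sim_spec`
#' mapping mirrors [cohort_spec()] (its `qtl_list` is a sequence of
#' mappings with `trait`, `marker` and `effect` or `cp`).
#'
#' @param path YAML file
#' @param ... overrides passed on to [run_config()]
#' @return a `run_config`
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim_spec)) {
    ss <- y$sim_spec
    if (!is.null(ss$varcomp_true)) {
      ss$varcomp_true <- do.call(varcomp, ss$varcomp_true)
    }
    y$sim_spec <- do.call(cohort_spec, ss)
  }
  over <- list(...)
  y[names(over)] <- over
  do.call(run_config, y)
}

#' Run the full divergence-scan pipeline
#'
#' Executes simulate/load, marker QC, GRM and PCA, the Weir-Cockerham Fst
#' and nucleotide-diversity window scan with selection-locus calling, the
#' stepwise mixed-model QTL scan per trait, and the QTL-by-window overlap,
#' writing every stage's table under `config$out_dir` together with a run
#' manifest (parameter values, seed, input checksums, output checksums).
#' The same configuration and seed reproduce identical output checksums.
#'
#' @param config a [run_config()]
#' @return the manifest, invisibly (list; also written as `manifest.json`)
#' @examples
#' \donttest{
#' spec <- cohort_spec(n_families = 6, n_markers = 300,
#'                     n_selection_families = 4, seed = 2)
#' man <- run_pipeline(run_config(sim_spec = spec, traits = "Bwt8m",
#'                                out_dir = tempfile()))
#' names(man$outputs)
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load"
  manifest <- list(
    package_version = as.character(utils::packageVersion("divergescan")),
    seed = config$seed,
    parameters = config[!(names(config) %in%
                            c("sim_spec", "out_dir"))],
    stages = list(), outputs = list()
  )
  manifest$parameters <- manifest$parameters[
    vapply(manifest$parameters, function(z)
      is.numeric(z) || is.character(z) || is.logical(z), logical(1))]
  persist <- function() {
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  fail <- function(e) {
    manifest$failed_stage <<- stage
    persist()
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    if (!is.null(config$vcf)) {
      geno <- read_vcf(config$vcf)
      samples <- read_sample_table(config$samples)
      phen <- read_phenotype_table(config$phenotypes)
      samples <- merge(samples, phen, by = "sample_id", sort = FALSE)
      manifest$inputs <- as.list(tools::md5sum(
        c(config$vcf, config$samples, config$phenotypes)))
    } else {
      spec <- config$sim_spec
      spec$seed <- config$seed
      cohort <- simulate_cohort(spec)
      geno <- cohort$genotypes
      samples <- cohort$samples
      sim_dir <- file.path(config$out_dir, "simulated")
      write_cohort(cohort, sim_dir)
      manifest$inputs <- list(simulated = TRUE, sim_seed = spec$seed)
    }
    traits <- config$traits
    if (is.null(traits)) {
      traits <- setdiff(names(samples),
                        c("sample_id", "family_id", "line", "cage_id", "role"))
      traits <- traits[vapply(samples[traits], is.numeric, logical(1))]
    }
    manifest$stages$load <- list(n_samples = n_samples(geno),
                                 n_markers = n_markers(geno),
                                 traits = traits)

    stage <- "qc"
    geno <- qc_filter(geno, config$min_call_rate, config$min_maf)
    manifest$stages$qc <- attr(geno, "qc_report")

    stage <- "relationship"
    grm <- vanraden_grm(geno)
    pca <- genotype_pca(geno, n_components = 2)
    out <- function(name, writer) {
      path <- file.path(config$out_dir, name)
      writer(path)
      manifest$outputs[[name]] <<- unname(tools::md5sum(path))
      path
    }
    out("grm.tsv", function(p) write_grm(grm, p))
    out("pca_scores.tsv", function(p) write_pca_scores(pca, p, samples))

    stage <- "popgen_scan"
    sites <- wc_fst_site(geno, samples)
    wins <- window_stats(sites, config$window_bp,
                         config$mean_threshold, config$q95_threshold)
    pi_wins <- window_stats(sites, config$pi_window_bp,
                            config$mean_threshold, config$q95_threshold)
    man_wins <- window_stats(sites, config$manhattan_window_bp,
                             config$mean_threshold, config$q95_threshold)
    top <- top_quantile_loci(sites, config$top_quantile)
    wtsv <- function(df) function(p) utils::write.table(
      df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    out("site_stats.tsv", wtsv(as.data.frame(sites)))
    out("window_stats.tsv", wtsv(as.data.frame(wins)))
    out("pi_windows.tsv", wtsv(as.data.frame(pi_wins)))
    out("manhattan_windows.tsv", wtsv(as.data.frame(man_wins)))
    out("selection_loci.tsv", wtsv(top))
    elev <- wins[wins$elevated_q95, , drop = FALSE]
    out("elevated_windows.bed", function(p) utils::write.table(
      data.frame(elev$chrom, format(elev$start - 1, scientific = FALSE,
                                    trim = TRUE),
                 format(elev$end - 1, scientific = FALSE, trim = TRUE)),
      p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE))
    manifest$stages$popgen <- list(
      n_sites = nrow(sites), n_defined = sum(sites$defined),
      n_selection_loci = nrow(top),
      n_elevated_q95 = sum(wins$elevated_q95))

    stage <- "qtl_scan"
    qtl_all <- list()
    vc_rows <- list()
    gebv <- data.frame(sample_id = samples$sample_id)
    for (tr in traits) {
      fit <- steplmm(stats::as.formula(paste(tr, "~ line")),
                     data = samples, genotypes = geno, K = grm,
                     alpha = config$scan_alpha,
                     min_distance_bp = config$min_distance_bp)
      qtl_all[[tr]] <- fit$qtl
      v <- fit$varcomp
      vc_rows[[tr]] <- data.frame(
        trait = tr, polygenic_var = v$polygenic,
        genetic_var = v$polygenic + v$qtl, error_var = v$residual,
        cage_var = v$cage, qtl_var = v$qtl, h2 = fit$h2,
        vq_vg = if (v$polygenic + v$qtl > 0)
          v$qtl / (v$polygenic + v$qtl) else NA_real_)
      gebv[[tr]] <- fit$gebv[match(samples$sample_id, names(fit$gebv))]
    }
    qtl <- do.call(rbind, qtl_all)
    rownames(qtl) <- NULL
    out("qtl_hits.tsv", wtsv(qtl))
    out("variance_components.tsv", wtsv(do.call(rbind, vc_rows)))
    out("gebv.tsv", wtsv(gebv))
    manifest$stages$qtl <- list(n_qtl = nrow(qtl))

    stage <- "overlap"
    hits <- overlap_qtl_windows(qtl, wins,
                                criterion = config$overlap_criterion,
                                top_loci = top)
    out("overlap_hits.tsv", wtsv(as.data.frame(hits)))
    for (i in seq_len(nrow(hits))) {
      fr <- flank_allele_frequencies(geno, samples, hits$chrom[i],
                                     hits$pos[i], hits$pos[i],
                                     config$flank_bp)
      out(sprintf("flank_%s_%d.tsv", hits$chrom[i], hits$pos[i]), wtsv(fr))
    }
    manifest$stages$overlap <- list(n_hits = nrow(hits))

    stage <- "manifest"
    persist()
  }, error = fail)
  invisible(manifest)
}
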