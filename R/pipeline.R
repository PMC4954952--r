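#' Assemble and validate a pipeline configuration
#'
#' Either file paths (`map_path`, `genotype_path`, `trait_path`) or
#' in-memory objects (`map`, `genotypes`, `traits`) supply the inputs. All
#' randomness flows from `seed` through fixed per-stage substreams, so a
#' rerun with the same config reproduces every output byte for byte.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer master seed (mandatory).
#' @param map,genotypes,traits in-memory inputs (optional).
#' @param map_path,genotype_path,trait_path input CSVs (optional).
#' @param datasets scan datasets, subset of c("combined","exp1","exp2").
#' @param stages pipeline stages to run, in order, subset of
#'   c("heritability","scan","hotspots","epistasis","cv").
#' @param step scan-grid pseudomarker step (cM).
#' @param n_perm permutations for LOD thresholds.
#' @param n_perm_hotspot permutations for hotspot count thresholds.
#' @param n_perm_validate permutations for hotspot validation / epistasis
#'   enrichment nulls.
#' @param alpha genome-wide / validation significance level.
#' @param fdr within-model BH threshold.
#' @param window hotspot sliding-window width (cM).
#' @param merge_radius hotspot merge radius (cM).
#' @param max_qtl cap on QTLs per trait.
#' @param normalize median-normalize the trait table first.
#' @param yaml_path optionally load settings from a YAML file (keys defined
#'   there override the argument defaults).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed, map = NULL, genotypes = NULL,
                            traits = NULL, map_path = NULL,
                            genotype_path = NULL, trait_path = NULL,
                            datasets = c("combined", "exp1", "exp2"),
                            stages = c("heritability", "scan", "hotspots",
                                       "epistasis", "cv"),
                            step = 1, n_perm = 1000, n_perm_hotspot = 1000,
                            n_perm_validate = 200, alpha = 0.05, fdr = 0.05,
                            window = 10, merge_radius = 10, max_qtl = 10,
                            normalize = FALSE, yaml_path = NULL) {
  cfg <- list(out_dir = out_dir, seed = seed, map = map,
              genotypes = genotypes, traits = traits, map_path = map_path,
              genotype_path = genotype_path, trait_path = trait_path,
              datasets = datasets, stages = stages, step = step,
              n_perm = n_perm, n_perm_hotspot = n_perm_hotspot,
              n_perm_validate = n_perm_validate, alpha = alpha, fdr = fdr,
              window = window, merge_radius = merge_radius,
              max_qtl = max_qtl, normalize = normalize)
  if (!is.null(yaml_path)) {
    y <- yaml::read_yaml(yaml_path)
    for (k in names(y)) cfg[[k]] <- y[[k]]
  }
  if (is.null(cfg$seed)) stop("seed is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  stopifnot(cfg$alpha > 0, cfg$alpha < 1)
  bad <- setdiff(cfg$datasets, c("combined", "exp1", "exp2"))
  if (length(bad)) stop("unknown dataset(s): ", paste(bad, collapse = ", "))
  for (p in c("map_path", "genotype_path", "trait_path")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("path not found for ", p, ": ", cfg[[p]])
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

# fixed per-stage seed substreams off the master seed (kept below 2^31)
.stage_seed <- function(seed, stage) {
  off <- c(scan_combined = 11L, scan_exp1 = 12L, scan_exp2 = 13L,
           hotspot = 23L, validate = 37L, epistasis = 41L, cv_scan = 53L,
           cv_hotspot = 59L)
  (as.integer(seed) * 101L + off[[stage]]) %% 2147483113L
}

.log_stage <- function(log_path, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  message(line)
  cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: heritability/G x E decomposition, Haley-Knott scans
#' with stepwise multi-QTL models for each configured dataset, sliding-window
#' hotspot detection with permutation thresholds and merging across
#' datasets, hotspot validation and marker x experiment partitioning,
#' pairwise epistasis with permutation enrichment and network export, and
#' the CV (stochastic-variation) branch which rebuilds per-line CV traits
#' and reuses the identical scan machinery. Every stage writes its table
#' under `out_dir`; a JSON manifest with config snapshot and per-file MD5
#' checksums is written last. Removing a stage from `config$stages` skips it
#' (and anything downstream that needs its output).
#'
#' @param config a `pipeline_config`.
#' @return The manifest, invisibly (list: config, version, outputs,
#'   checksums, timestamps).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  t_start <- Sys.time()
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    .log_stage(log_path, sprintf("stage %-12s done in %.1fs", name,
                                 as.numeric(Sys.time() - t0, units = "secs")))
    out
  }
  # ---- inputs -------------------------------------------------------------
  inputs <- run_stage("load", {
    if (!is.null(config$map_path)) {
      gm <- read_genotype_map(config$map_path, config$genotype_path)
      traits <- read_trait_table(config$trait_path)
      list(map = gm$map, genotypes = gm$genotypes, traits = traits)
    } else {
      stopifnot(!is.null(config$map), !is.null(config$genotypes),
                !is.null(config$traits))
      list(map = config$map, genotypes = config$genotypes,
           traits = config$traits)
    }
  })
  traits <- inputs$traits
  if (config$normalize) traits <- median_normalize(traits)
  grid <- build_scan_grid(inputs$map, step = config$step)
  probs <- genotype_probs(inputs$genotypes, grid)
  outputs <- character(0)
  put <- function(d, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(d, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  # ---- heritability -------------------------------------------------------
  if ("heritability" %in% config$stages) {
    h2 <- run_stage("heritability", heritability_table(traits))
    put(h2, "heritability.csv")
  }
  # ---- scans --------------------------------------------------------------
  qtls <- NULL
  if ("scan" %in% config$stages) {
    qtls <- list()
    for (ds in config$datasets) {
      qtls[[ds]] <- run_stage(paste0("scan_", ds), scan_trait_panel(
        traits, ds, inputs$genotypes, grid, n_perm = config$n_perm,
        alpha = config$alpha, seed = .stage_seed(config$seed,
                                                 paste0("scan_", ds)),
        max_qtl = config$max_qtl, probs = probs))
    }
    put(do.call(rbind, qtls), "qtl.csv")
  }
  # ---- hotspots -----------------------------------------------------------
  hotspot_markers <- NULL
  if ("hotspots" %in% config$stages && !is.null(qtls)) {
    hs <- run_stage("hotspots", {
      peaks <- list()
      profiles <- list()
      for (ds in names(qtls)) {
        prof <- window_counts(qtls[[ds]], grid, window = config$window)
        profiles[[ds]] <- data.frame(dataset = ds, prof,
                                     stringsAsFactors = FALSE)
        if (nrow(qtls[[ds]])) {
          thr <- hotspot_permutation_threshold(
            nrow(qtls[[ds]]), grid, window = config$window,
            n_perm = config$n_perm_hotspot, alpha = config$alpha,
            seed = .stage_seed(config$seed, "hotspot"))
          peaks[[ds]] <- find_hotspots(prof, as.numeric(thr), inputs$map, ds)
        }
      }
      all_peaks <- if (length(peaks)) do.call(rbind, peaks) else NULL
      merged <- if (!is.null(all_peaks) && nrow(all_peaks)) {
        merge_hotspots(all_peaks, inputs$map, radius = config$merge_radius)
      } else NULL
      list(profiles = do.call(rbind, profiles), peaks = all_peaks,
           merged = merged)
    })
    put(hs$profiles, "hotspot_profile.csv")
    if (!is.null(hs$merged)) {
      val <- run_stage("validate", {
        v <- validate_hotspots_marker_model(
          traits, hs$merged$marker, inputs$genotypes,
          n_perm = config$n_perm_validate, alpha = config$alpha,
          fdr = config$fdr,
          seed = .stage_seed(config$seed, "validate"))
        mx <- marker_by_experiment_model(traits, hs$merged$marker,
                                         inputs$genotypes, fdr = config$fdr)
        cbind(hs$merged[match(v$marker, hs$merged$marker),
                        c("chromosome", "peak_cM", "count")],
              v, mx[match(v$marker, mx$marker), c("n_main", "n_gxe")])
      })
      put(val, "hotspots.csv")
      hotspot_markers <- val$marker[val$validated %in% TRUE]
    }
  }
  # ---- epistasis ----------------------------------------------------------
  if ("epistasis" %in% config$stages && length(hotspot_markers) >= 2) {
    epi <- run_stage("epistasis", epistasis_enrichment(
      traits, hotspot_markers, inputs$genotypes,
      n_perm = config$n_perm_validate, alpha = config$alpha,
      fdr = config$fdr, seed = .stage_seed(config$seed, "epistasis")))
    put(epi, "epistasis_edges.csv")
    vf <- run_stage("variance_fractions", {
      trs <- unique(traits$trait)
      data.frame(trait = trs, epistatic_pct = vapply(trs, function(t) {
        a <- pairwise_epistasis_anova(traits[traits$trait == t, ],
                                      hotspot_markers, inputs$genotypes)
        suppressWarnings(epistatic_variance_fraction(a))
      }, numeric(1)), stringsAsFactors = FALSE)
    })
    put(vf, "epistatic_variance.csv")
    sif <- file.path(config$out_dir, "epistasis_network.sif")
    export_network(epi[epi$retained %in% TRUE, , drop = FALSE], sif)
    outputs <- c(outputs, sif, sub("\\.sif$", ".edges.tsv", sif))
  }
  # ---- CV branch ----------------------------------------------------------
  if ("cv" %in% config$stages) {
    cvq <- run_stage("cv", {
      cvt <- cv_trait_table(traits)
      put(cvt, "cv_traits.csv")
      scan_trait_panel(cvt, "combined", inputs$genotypes, grid,
                       n_perm = config$n_perm, alpha = config$alpha,
                       seed = .stage_seed(config$seed, "cv_scan"),
                       max_qtl = config$max_qtl, probs = probs)
    })
    put(cvq, "cv_qtl.csv")
  }
  # ---- manifest -----------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("ricemqtl")),
    seed = config$seed,
    config = config[setdiff(names(config),
                            c("map", "genotypes", "traits"))],
    outputs = basename(outputs),
    checksums = as.list(tools::md5sum(sort(outputs))),
    elapsed_s = as.numeric(Sys.time() - t_start, units = "secs"))
  names(manifest$checksums) <- basename(sort(outputs))
  jsonlite::write_json(manifest[setdiff(names(manifest), "elapsed_s")],
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .log_stage(log_path, sprintf("pipeline done in %.1fs", manifest$elapsed_s))
  invisible(manifest)
}
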